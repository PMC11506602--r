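test_that("pair energies follow the SALR table with cross signs flipped", {
  p <- params_default
  expect_equal(pair_energy(1, 1, "nn", p), -1)
  expect_equal(pair_energy(1, 2, "nn", p), +1)
  expect_equal(pair_energy(2, 2, "third", p), 0.75)
  expect_equal(pair_energy(2, 1, "third", p), -0.75)
  expect_equal(pair_energy(2, 2, "nn", p), pair_energy(1, 1, "nn", p))
  expect_error(pair_energy(0, 1, "nn", p), "species")
  # J is a free shape parameter
  p3 <- model_params(J = 3)
  expect_equal(pair_energy(1, 1, "third", p3), 3)
})

test_that("total energy counts each unordered pair once", {
  g <- build_geometry(12)
  expect_equal(total_energy(new_configuration(g), params_default), 0)
  # hexagonal flower: 12 nn pairs at -1 and 3 third pairs at +J
  flower <- make_fixture(fixture_spec("isolated-motif", motif = "flower", L = 12,
                                      species = 2))
  expect_equal(total_energy(flower, params_default), -12 + 3 * 0.75)
  # two unlike particles in contact
  occ <- integer(g$n)
  occ[1] <- 1L
  occ[2] <- 2L
  expect_equal(total_energy(new_configuration(g, occ), params_default), +1)
})

test_that("the thermodynamic Hamiltonian subtracts mu_i N_i", {
  g <- build_geometry(12)
  p <- params_default
  flower <- make_fixture(fixture_spec("isolated-motif", motif = "flower", L = 12,
                                      species = 2))
  mu2_zero <- (3 * p$J - 12) / 7
  expect_equal(hamiltonian(flower, p, thermo_state(0.1, -50, mu2_zero)), 0)
  expect_equal(hamiltonian(new_configuration(g), p, thermo_state(1, 5, 5)), 0)
  occ <- integer(g$n); occ[5] <- 1L
  expect_equal(hamiltonian(new_configuration(g, occ), p, thermo_state(1, -2, 0)), 2)
})

test_that("single-site increments match the total-energy oracle", {
  g <- build_geometry(8)
  p <- params_default
  st <- thermo_state(0.5, -0.7, -1.3)
  set.seed(4)
  cfg <- new_configuration(g, sample(0:2, g$n, replace = TRUE))
  # trivial increments
  empty <- new_configuration(g)
  expect_equal(delta_H_site_change(empty, 1, 1L, p, thermo_state(1, 0, 0)), 0)
  one <- new_configuration(g)
  one$occ[1] <- 1L
  expect_equal(delta_H_site_change(one, g$nn[1, 1], 1L, p, thermo_state(1, 0, 0)), -1)
  expect_error(delta_H_site_change(one, 1, 1L, p, st), "equals")
  # 200 random changes against H(after) - H(before)
  for (i in 1:200) {
    s <- sample.int(g$n, 1)
    ns <- sample(setdiff(0:2, cfg$occ[s]), 1)
    dH <- delta_H_site_change(cfg, s, ns, p, st)
    after <- cfg
    after$occ[s] <- as.integer(ns)
    expect_equal(dH, hamiltonian(after, p, st) - hamiltonian(cfg, p, st),
                 tolerance = 1e-12)
    cfg <- after
  }
})

test_that("H is invariant under species relabelling with swapped mus", {
  g <- build_geometry(8)
  p <- params_default
  set.seed(9)
  occ <- sample(0:2, g$n, replace = TRUE)
  swapped <- occ
  swapped[occ == 1L] <- 2L
  swapped[occ == 2L] <- 1L
  st <- thermo_state(0.3, -0.8, -1.7)
  st_swap <- thermo_state(0.3, -1.7, -0.8)
  expect_equal(hamiltonian(new_configuration(g, occ), p, st),
               hamiltonian(new_configuration(g, swapped), p, st_swap))
})

test_that("energy is extensive under p x p tiling of a unit cell", {
  p <- params_default
  for (nm in c("m2m2", "ll", "c72", "c4l")) {
    pt <- lib_default[[nm]]
    L1 <- salrmix:::commensurate_L(pt)
    for (mult in 1:2) {
      g <- build_geometry(L1 * mult)
      E <- total_energy(tile_pattern(pt, g), p)
      expect_equal(E, pt$E_cell * g$n / pt$Ac, tolerance = 1e-12)
    }
  }
})
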