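test_that("the library holds the expected motifs with exact per-cell energies", {
  lib <- lib_default
  expect_true(all(c("v", "dp1", "dp2", "c71", "c72", "b1", "b2", "m2m2", "ll",
                    "m2m3", "m3m2", "c2l", "lc2", "c4l", "lc4", "c4b", "bc4",
                    "c1b", "bc1", "l1", "l2") %in% names(lib)))
  expect_equal(h_per_cell(lib$v, params_default, -3, 2), 0)
  # flower cluster: 7 particles of one species, E = -12 + 3J
  expect_equal(lib$c72$n2, 7)
  expect_equal(lib$c72$n1, 0)
  expect_equal(lib$c72$E_cell, -12 + 3 * 0.75)
  cfg <- tile_pattern(lib$c72, build_geometry(19))
  cs <- cluster_stats(cfg, 2)
  expect_true(all(cs$sizes == 7))
  # the bubble phase is the complement of the flower superlattice
  expect_equal(lib$b2$n2, 19 - 7)
  # densely packed: every site has 3 like nn bonds and 3 like third bonds
  expect_equal(lib$dp2$E_cell, -3 + 3 * 0.75)
  expect_equal(lib$ll$E_cell / lib$ll$Ac, -1 - 0.75)
})

test_that("h is linear in mu and mirrors swap species exactly", {
  p <- lib_default$m2m3
  h1 <- h_per_cell(p, params_default, -1, -2)
  h2 <- h_per_cell(p, params_default, -3, -2)
  h_mid <- h_per_cell(p, params_default, -2, -2)
  expect_equal((h1 + h2) / 2, h_mid, tolerance = 1e-12)
  m <- swap_species_pattern(p)
  expect_equal(h_per_cell(m, params_default, -2, -1), h_per_cell(p, params_default, -1, -2))
  expect_equal(m$E_cell, p$E_cell)
})

test_that("diagonal phase boundaries solve the piecewise-linear crossings", {
  lib <- lib_default
  expect_equal(diagonal_crossing(lib$v, lib$m2m2), -25 / 12, tolerance = 1e-12)
  expect_equal(diagonal_crossing(lib$m2m2, lib$ll), -3 / 4, tolerance = 1e-12)
  expect_error(diagonal_crossing(lib$m2m2, lib$m2m2), "parallel")
})

test_that("the ground-state diagram reports minimizers and coexistence", {
  lib <- lib_default
  gs <- ground_state_diagram(lib, params_default,
                             mu1_grid = c(-10, -1.5, 0), mu2_grid = c(-10, -1.5, 0))
  at <- function(m1, m2) gs$label[gs$mu1 == m1 & gs$mu2 == m2]
  expect_equal(at(-10, -10), "v")
  expect_equal(at(-1.5, -1.5), "m2m2")
  expect_equal(at(0, 0), "ll")
  # at the boundary both phases are co-minimal
  gsb <- ground_state_diagram(lib, params_default, -3 / 4, -3 / 4)
  expect_setequal(strsplit(gsb$label, ",")[[1]], c("m2m2", "ll"))
})

test_that("GS concentration of species 1 grows with mu1 at fixed mu2", {
  lib <- lib_default
  rho1 <- vapply(lib, function(p) p$n1 / p$Ac, 0)
  for (mu2 in c(-3, -1, 0)) {
    gs <- ground_state_diagram(lib, params_default, seq(-4, 1, 0.1), mu2)
    labs <- strsplit(gs$label, ",")
    c1max <- vapply(labs, function(z) max(rho1[z]), 0)
    expect_true(all(diff(c1max) >= -1e-12))
  }
})

test_that("exhaustive enumeration reproduces closed-form small-cell ground states", {
  # 2x2 cell at strongly negative mu: vacuum wins
  e <- enumerate_ground_state(2, 2, params_default, -10, -10)
  expect_equal(e$h_min, 0)
  expect_equal(nrow(e$classes), 1)
  expect_equal(e$classes$N1, 0)
  expect_true(all(e$motifs[[1]] == 0))
  # 1x1 cell at mu = 0: the densely packed state has h = -3 + 3J
  e1 <- enumerate_ground_state(1, 1, params_default, 0, -50)
  expect_equal(e1$h_min, -0.75)
  expect_equal(e1$classes$N1, 1)
  expect_error(enumerate_cell_scan(5, 4), "too large")
})

test_that("the m2m2 motif is the exact minimum of its own sheared cell", {
  scan <- enumerate_cell_scan(4, 2, params_default, shear = 3)
  e <- enumerate_ground_state(4, 2, params_default, -1.5, -1.5, scan = scan)
  expect_equal(e$h_min, h_per_cell(lib_default$m2m2, params_default, -1.5, -1.5),
               tolerance = 1e-12)
  expect_equal(e$h_min, -0.4375)
  cls <- e$classes
  expect_true(any(cls$N1 == 3 & cls$N2 == 3))
})

test_that("tiling is exact and rejects incommensurate lattices", {
  g <- build_geometry(8)
  expect_equal(sum(tile_pattern(lib_default$v, g)$occ), 0)
  cfg <- tile_pattern(lib_default$m2m2, g)
  n <- particle_counts(cfg)
  expect_equal(unname(n["N1"]), 8 * 8 * 3 / 8)
  expect_error(tile_pattern(lib_default$c72, g), "not commensurate")
})
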