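test_that("kappa and Cv implement the fluctuation definitions exactly", {
  s <- observable_series(N1 = c(0.4, 0.6) * 16, N2 = c(0.1, 0.1) * 16,
                         E = c(-10, -12), L = 4)
  expect_equal(kappa(s), 0.5 * 0.01 + 0.1 * 0)    # population variance
  expect_equal(specific_heat(s), 1 / 16)
  const <- observable_series(c(3, 3), c(2, 2), c(-5, -5), 6)
  expect_equal(kappa(const), 0)
  expect_equal(specific_heat(const), 0)
  swapped <- observable_series(s$N2, s$N1, s$E, 4)
  expect_equal(kappa(swapped), kappa(s))
  expect_error(kappa(observable_series(1, 1, 1, 4)), "2 samples")
  expect_error(specific_heat(observable_series(1, 1, 1, 4)), "2 samples")
  expect_equal(specific_heat(c(-10, -12), L = 4, conventional = TRUE, T_star = 0.5),
               (1 / 16) / 0.25)
})

test_that("structure factors obey the normalization and symmetry conventions", {
  g <- build_geometry(16)
  empty <- new_configuration(g)
  expect_true(all(structure_factor(empty)$S == 0))
  full <- new_configuration(g, rep(2L, g$n))
  S <- structure_factor(full)$S
  expect_equal(S[1, 1], g$n)
  expect_lt(max(S[-1]), 1e-18)
  # Parseval: sum of S equals L^2 for any occupancy
  cfg <- make_fixture(fixture_spec("random", c1 = 0.2, c2 = 0.15, L = 16, seed = 7))
  expect_equal(sum(structure_factor(cfg)$S), g$n, tolerance = 1e-9)
  # S(k) = S(-k) for the real occupancy field
  sf <- structure_factor(cfg)
  for (idx in list(c(2, 5), c(4, 16), c(9, 2))) {
    neg <- ((16 - (idx - 1)) %% 16) + 1
    expect_equal(sf$S[idx[1], idx[2]], sf$S[neg[1], neg[2]], tolerance = 1e-9)
  }
  # translation invariance of S
  occ <- cfg$occ
  m <- matrix(occ, 16, 16)
  shifted <- new_configuration(g, as.vector(m[c(4:16, 1:3), c(10:16, 1:9)]))
  expect_equal(structure_factor(shifted)$S, sf$S, tolerance = 1e-8)
})

test_that("dominant periods of the tiled library motifs are recovered", {
  # independent oracle: the smallest axial translation period of the tiling
  axial_period <- function(cfg) {
    L <- cfg$geometry$L
    m <- matrix(cfg$occ, L, L)
    shifts <- list(function(m, p) m[(seq_len(L) - 1 + p) %% L + 1, ],
                   function(m, p) m[, (seq_len(L) - 1 + p) %% L + 1],
                   function(m, p) {  # along a1 - a2: q+p, r-p
                     q <- (rep(0:(L - 1), L) + p) %% L
                     r <- (rep(0:(L - 1), each = L) - p) %% L
                     matrix(m[q + L * r + 1], L, L)
                   })
    best <- Inf
    for (sh in shifts) {
      p_ax <- Inf
      for (p in 1:L)   # p = L is the torus identity: axial period L
        if (identical(sh(m, p), m)) { p_ax <- p; break }
      if (is.finite(p_ax) && p_ax > 1) best <- min(best, p_ax)
    }
    best
  }
  for (nm in c("m2m2", "ll", "l2", "c2l", "m2m3", "c72")) {
    pt <- lib_default[[nm]]
    L <- salrmix:::commensurate_L(pt, L_min = 8)
    cfg <- tile_pattern(pt, build_geometry(L))
    expect_equal(dominant_period(structure_factor(cfg)), axial_period(cfg),
                 info = nm)
  }
  # featureless spectra give the no-period sentinel
  g <- build_geometry(8)
  expect_true(is.na(dominant_period(structure_factor(tile_pattern(lib_default$dp2, g)))))
  # hand-built stripes of period 6 on L = 24
  g24 <- build_geometry(24)
  occ <- ifelse(g24$coords[, "r"] %% 6 < 2, 1L, 0L)
  expect_equal(dominant_period(structure_factor(new_configuration(g24, occ))), 6)
})

test_that("per-species spectra isolate each component's order", {
  g <- build_geometry(8)
  cfg <- tile_pattern(lib_default$l2, g)   # single species
  expect_equal(per_species_spectrum(cfg, 2)$S, structure_factor(cfg)$S)
  ll <- tile_pattern(lib_default$ll, g)
  expect_equal(dominant_period(per_species_spectrum(ll, 1)), 4)
  c7 <- tile_pattern(lib_default$c72, build_geometry(19))
  sp <- per_species_spectrum(c7, 2)
  pk <- peak_height(sp, lambda_range = c(3, 6))
  expect_equal(pk$lambda, sqrt(19) * sqrt(3) / 2, tolerance = 1e-9)
  expect_gt(pk$height, 10)
})

test_that("cluster statistics count connected components correctly", {
  g <- build_geometry(12)
  expect_equal(cluster_stats(new_configuration(g))$n_clusters, 0)
  flower <- make_fixture(fixture_spec("isolated-motif", motif = "flower",
                                      L = 12, species = 2))
  cs <- cluster_stats(flower, 2)
  expect_equal(cs$sizes, 7L)
  expect_equal(count_flowers(flower), 1)
  # two flowers far apart are separate clusters
  two <- flower
  off <- which(flower$occ != 0)
  shift <- function(s) {
    q <- (s - 1) %% 12
    r <- (s - 1) %/% 12
    ((q + 6) %% 12) + 12 * ((r + 6) %% 12) + 1
  }
  two$occ[vapply(off, shift, 1)] <- 2L
  cs2 <- cluster_stats(two, 2)
  expect_equal(cs2$sizes, c(7L, 7L))
  expect_equal(count_flowers(two), 2)
  expect_equal(sum(cs2$sizes), sum(two$occ == 2L))
  # a rhomb is not a flower
  rhomb <- make_fixture(fixture_spec("isolated-motif", motif = "rhomb", L = 12))
  expect_equal(count_flowers(rhomb), 0)
})

test_that("the superlattice order parameter fires on c7 and not on stripes", {
  c7 <- tile_pattern(lib_default$c72, build_geometry(19))
  ord <- superlattice_order(c7)
  expect_gt(ord$height, 1)
  expect_gte(ord$ratio, 1)
  stripes <- tile_pattern(lib_default$l2, build_geometry(20))
  expect_equal(superlattice_order(stripes)$height, 0)
})

test_that("the motif classifier identifies every ideal tiling and tolerates defects", {
  occupied <- Filter(function(p) p$n1 + p$n2 > 0, lib_default)
  for (nm in names(occupied)) {
    pt <- occupied[[nm]]
    cfg <- tile_pattern(pt, build_geometry(salrmix:::commensurate_L(pt)))
    sc <- classify_motifs(cfg, region = "all")
    expect_equal(sc$label[1], nm)
    expect_gt(sc$score[1], sc$score[2] + 0.1)
  }
  defected <- make_fixture(fixture_spec("defected-pattern", label = "m2m2",
                                        L = 24, defect_rate = 0.05, seed = 12))
  sc <- classify_motifs(defected, region = "all")
  expect_equal(sc$label[1], "m2m2")
  # the correlation method agrees on a clean single-orientation tiling
  sc2 <- classify_motifs(tile_pattern(lib_default$ll, build_geometry(8)),
                         region = "all", method = "correlation")
  expect_equal(sc2$label[1], "ll")
  expect_equal(sc2$score[1], 1)
})
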