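test_that("annealing schedules validate and interpolate", {
  sch <- anneal_schedule(2, 0.125, 24, 1000)
  expect_equal(sch$temps[1], 2)
  expect_equal(sch$temps[24], 0.125)
  expect_true(all(diff(sch$temps) < 0))
  lin <- anneal_schedule(1, 0.5, 6, 10, interpolation = "linear")
  expect_equal(diff(lin$temps), rep(-0.1, 5))
  expect_error(anneal_schedule(0.1, 0.2), "T_start > T_end")
  expect_error(anneal_schedule(1, 0.5, 0), "stage")
})

test_that("displacement moves conserve composition and accept free moves", {
  g <- build_geometry(8)
  occ <- integer(g$n)
  occ[20] <- 1L
  cfg <- new_configuration(g, occ)
  set.seed(3)
  for (i in 1:20) {
    out <- canonical_step(cfg, params_default, T_star = 0.5)
    expect_true(out$accepted)       # isolated particle: every hop has dE = 0
    cfg <- out$config
    expect_equal(unname(particle_counts(cfg)), c(1, 0))
  }
})

test_that("annealing conserves (N1, N2) exactly and is deterministic", {
  sch <- anneal_schedule(1.5, 0.3, 4, 200)
  res <- anneal(15, 9, 12, sch, params_default, seed = 8)
  for (cfg in res$stage_configs)
    expect_equal(unname(particle_counts(cfg)), c(15, 9))
  res2 <- anneal(15, 9, 12, sch, params_default, seed = 8)
  expect_identical(res$final$occ, res2$final$occ)
  expect_identical(res$E, res2$E)
  expect_error(anneal(100, 100, 12, sch), "overfilled")
  # empty system short-circuits
  e <- anneal(0, 0, 12, sch)
  expect_equal(sum(e$final$occ), 0)
})

test_that("cooling lowers the mean energy across stages", {
  sch <- anneal_schedule(2.0, 0.2, 8, 2000)
  res <- anneal(30, 30, 16, sch, params_default, seed = 5)
  expect_lt(res$E_stage_mean[8], res$E_stage_mean[1])
})

test_that("fixed-temperature dynamics samples the canonical Boltzmann law", {
  # 2 particles of species 1 + 1 of species 2 on a 5x5 lattice; the energy
  # histogram from a long kernel run must match exact enumeration
  g <- build_geometry(5)
  p <- params_default
  combs <- utils::combn(g$n, 3)
  exactE <- numeric(0)
  for (j in seq_len(ncol(combs))) {
    sites <- combs[, j]
    for (k in 1:3) {
      occ <- integer(g$n)
      occ[sites] <- 1L
      occ[sites[k]] <- 2L
      exactE <- c(exactE, total_energy(new_configuration(g, occ), p))
    }
  }
  Tst <- 1.0
  w <- exp(-exactE / Tst)
  pE <- tapply(w / sum(w), factor(round(exactE, 9)), sum)
  occ0 <- integer(g$n)
  occ0[c(1, 8, 17)] <- c(1L, 1L, 2L)
  out <- salrmix:::canonical_run_cpp(occ0, g$nn - 1L, g$third - 1L, p$J,
                                     Tst, 120000L, 3L, 19)
  obs <- table(factor(round(out$E[, 1], 9), levels = names(pE)))
  stat <- chisq_stat(as.numeric(obs), as.numeric(pE))
  df <- sum(sum(obs) * pE >= 5) - 1
  expect_lt(stat, df + 3 * sqrt(2 * df))
})
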