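test_that("single Metropolis steps accept downhill moves and track dH", {
  g <- build_geometry(6)
  st <- thermo_state(1, 0, 0)
  set.seed(1)
  out <- gcmc_step(new_configuration(g), params_default, st)
  expect_true(out$accepted)   # insertion into vacuum at mu = 0 has dH = 0
  expect_equal(out$dH, 0)
  expect_equal(sum(out$config$occ != 0), 1)
})

test_that("replica-exchange probability follows the two-species exchange rule", {
  expect_equal(tempering_swap_probability(c(-1, -1), c(-1, -1), c(10, 3), c(2, 8), 0.1), 1)
  expect_equal(tempering_swap_probability(c(-1, -2), c(-1.1, -2.2), c(5, 5), c(5, 5), 0.1), 1)
  # closed form for an asymmetric case
  p <- tempering_swap_probability(c(-1, -2), c(-1.1, -1.9), c(6, 4), c(3, 9), 0.5)
  expect_equal(p, min(1, exp((0.1 * (3 - 6) + (-0.1) * (9 - 4)) / 0.5)))
  expect_error(tempering_swap_probability(c(0, 0), c(0, 0), c(1, 1), c(1, 1), -1), "positive")
})

test_that("runs are exactly reproducible and respect spec validation", {
  g <- build_geometry(6)
  run <- gcmc_spec(g, params_default, T_star = 0.8, mu1 = c(-1, -0.5),
                   mu2 = c(-1, -0.5), sweeps = 300, equil = 100,
                   sample_interval = 5, seed = 33)
  r1 <- run_isotherm(run)
  r2 <- run_isotherm(run)
  expect_identical(r1$isotherm, r2$isotherm)
  expect_identical(r1$series[[1]]$E, r2$series[[1]]$E)
  expect_error(gcmc_spec(g, params_default, T_star = 0, mu1 = 0, mu2 = 0), "positive")
  expect_error(gcmc_spec(g, params_default, T_star = 1, mu1 = 0, mu2 = 0,
                         sweeps = 10, equil = 10), "smaller")
})

test_that("deep vacuum and dense lamellar limits are recovered", {
  g <- build_geometry(12)
  vac <- run_isotherm(gcmc_spec(g, params_default, T_star = 0.1, mu1 = -10,
                                mu2 = -10, sweeps = 2000, equil = 500,
                                sample_interval = 5, seed = 2))
  expect_lt(vac$isotherm$c1_mean + vac$isotherm$c2_mean, 0.01)
  dense <- run_isotherm(gcmc_spec(g, params_default, T_star = 0.1, mu1 = 1,
                                  mu2 = 1, sweeps = 4000, equil = 2000,
                                  sample_interval = 5, seed = 2))
  expect_gt(dense$isotherm$c1_mean + dense$isotherm$c2_mean, 0.95)
  expect_lt(abs(dense$isotherm$c1_mean - dense$isotherm$c2_mean), 0.2)
  # fluctuation observables are non-negative wherever sampled
  expect_gte(min(vac$isotherm$kappa, dense$isotherm$kappa), 0)
  expect_gte(min(vac$isotherm$cv, dense$isotherm$cv), 0)
})

test_that("swap moves preserve the product of grand-canonical laws", {
  # two replicas, one active site each, different mu: after swaps the joint
  # law is still the product of the single-site grand-canonical laws
  g <- build_geometry(5)
  Tst <- 1.0
  mu <- list(a = c(-0.2, -0.8), b = c(-0.9, -0.1))
  run <- gcmc_spec(g, params_default, T_star = Tst,
                   mu1 = c(mu$a[1], mu$b[1]), mu2 = c(mu$a[2], mu$b[2]),
                   sweeps = 60000, equil = 2000, sample_interval = 3,
                   swap_interval = 1, seed = 17, init = "empty",
                   active_sites = 1L)
  res <- run_isotherm(run)
  state_of <- function(s) s$N1 * 1 + s$N2 * 2  # 0, 1, 2 for a single site
  joint <- paste(state_of(res$series[[1]]), state_of(res$series[[2]]))
  w_site <- function(m) c(1, exp(m[1] / Tst), exp(m[2] / Tst))
  pa <- w_site(mu$a) / sum(w_site(mu$a))
  pb <- w_site(mu$b) / sum(w_site(mu$b))
  pj <- as.vector(outer(pa, pb))
  names(pj) <- as.vector(outer(0:2, 0:2, function(x, y) paste(x, y)))
  obs <- table(factor(joint, levels = names(pj)))
  stat <- chisq_stat(as.numeric(obs), pj)
  df <- length(pj) - 1
  expect_lt(stat, df + 3 * sqrt(2 * df))
})

test_that("swapping the chemical potentials swaps the concentrations", {
  g <- build_geometry(10)
  base <- function(m1, m2, seed)
    run_isotherm(gcmc_spec(g, params_default, T_star = 1, mu1 = m1, mu2 = m2,
                           sweeps = 4000, equil = 1000, sample_interval = 5,
                           seed = seed))$isotherm
  a <- base(-0.5, -1.5, 21)
  b <- base(-1.5, -0.5, 22)
  expect_equal(a$c1_mean, b$c2_mean, tolerance = 0.05)
  expect_equal(a$c2_mean, b$c1_mean, tolerance = 0.05)
})

test_that("hysteresis pairs require identical grids and are deterministic", {
  g <- build_geometry(8)
  mk <- function(init, seed = 5)
    gcmc_spec(g, params_default, T_star = 0.1, mu1 = c(-1.6, -1.2),
              mu2 = c(-1.6, -1.2), sweeps = 500, equil = 200,
              sample_interval = 5, seed = seed, init = init)
  hp <- hysteresis_pair(mk("random"), mk("m2m2"))
  expect_s3_class(hp, "hysteresis_pair")
  # ordered start keeps the ordered branch denser at these low mu
  expect_gte(mean(hp$ordered$isotherm$c1_mean), mean(hp$random$isotherm$c1_mean) - 0.05)
  hp2 <- hysteresis_pair(mk("random"), mk("random"))
  expect_identical(hp2$random$isotherm, hp2$ordered$isotherm)
  bad <- gcmc_spec(g, params_default, T_star = 0.1, mu1 = c(-2, -1),
                   mu2 = c(-2, -1), sweeps = 500, equil = 200, seed = 5)
  expect_error(hysteresis_pair(mk("random"), bad), "same")
})
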