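#' @title Grand-canonical Monte Carlo with parallel tempering
#' @description Metropolis sampling of the open mixture at fixed reduced
#'   temperature T* and chemical potentials (mu1, mu2), with replica exchange
#'   along a one-dimensional ladder of chemical potentials.  One sweep
#'   proposes one single-site occupancy change per lattice cell: a uniformly
#'   chosen site is set to one of the other two of \{empty, species-1,
#'   species-2\} chosen uniformly (a symmetric proposal realizing insertion,
#'   deletion, and in-place mutation) and accepted with probability
#'   min(1, exp(-dH/T*)).
#' @name gcmc
NULL

#' Specify a grand-canonical run
#'
#' @param geometry a \code{lattice_geometry}.
#' @param params a \code{model_params}.
#' @param T_star reduced temperature (> 0).
#' @param mu1,mu2 chemical-potential ladders; recycled to a common length,
#'   one replica per ladder state, ordered along the scanned axis.
#' @param sweeps total Monte Carlo sweeps (1 sweep = L^2 proposed changes).
#' @param equil equilibration sweeps discarded before sampling.
#' @param sample_interval sweeps between samples of (N1, N2, E).
#' @param swap_interval sweeps between replica-exchange attempts (adjacent
#'   pairs, alternating parity); 0 disables tempering.
#' @param seed integer seed for the run's own 64-bit generator.
#' @param init initial condition: \code{"random"} (each cell independently
#'   empty or either species), \code{"empty"}, a pattern label from
#'   [pattern_library()] (ordered start), or an occupancy vector of length
#'   L^2 used for every replica.
#' @param init_conc for random starts, probabilities of species 1 and 2 per
#'   cell (default 1/3 each).
#' @param n_snapshots number of configuration snapshots stored per replica,
#'   evenly spaced over the sampling window.
#' @param active_sites optional 1-based site indices to which proposals are
#'   restricted (all other sites stay frozen); one "sweep" then proposes one
#'   change per active site.  Used for exact small-system validation.
#' @return an object of class \code{gcmc_run} (a specification; execute it
#'   with [run_isotherm()]).
#' @export
gcmc_spec <- function(geometry, params = model_params(), T_star, mu1, mu2,
                      sweeps = 70000, equil = 20000, sample_interval = 10,
                      swap_interval = 10, seed = 1, init = "random",
                      init_conc = c(1 / 3, 1 / 3), n_snapshots = 5,
                      active_sites = NULL) {
  if (T_star <= 0) stop("T* must be positive")
  nrep <- max(length(mu1), length(mu2))
  mu1 <- rep_len(mu1, nrep)
  mu2 <- rep_len(mu2, nrep)
  if (equil >= sweeps) stop("equil must be smaller than sweeps")
  structure(list(geometry = geometry, params = params, T_star = T_star,
                 mu1 = mu1, mu2 = mu2, sweeps = as.integer(sweeps),
                 equil = as.integer(equil),
                 sample_interval = as.integer(sample_interval),
                 swap_interval = as.integer(swap_interval),
                 seed = seed, init = init, init_conc = init_conc,
                 n_snapshots = as.integer(n_snapshots),
                 active_sites = active_sites),
            class = "gcmc_run")
}

# build the n x R matrix of initial occupancies for a run spec
init_occupancies <- function(run) {
  g <- run$geometry
  n <- g$n
  R <- length(run$mu1)
  occ_one <- function() {
    if (is.numeric(run$init)) {
      stopifnot(length(run$init) == n)
      as.integer(run$init)
    } else if (identical(run$init, "empty")) {
      integer(n)
    } else if (identical(run$init, "random")) {
      u <- stats::runif(n)
      ifelse(u < run$init_conc[1], 1L,
             ifelse(u < run$init_conc[1] + run$init_conc[2], 2L, 0L))
    } else {
      lib <- pattern_library(run$params)
      if (!run$init %in% names(lib))
        stop("unknown initial condition '", run$init, "'")
      tile_pattern(lib[[run$init]], g)$occ
    }
  }
  with_seed(run$seed + 7919,
            matrix(vapply(seq_len(R), function(i) occ_one(), integer(n)),
                   nrow = n))
}

#' Execute a grand-canonical run and collect isotherms
#'
#' Runs the replica ladder defined by a \code{gcmc_run}, samples (N1, N2, E)
#' after equilibration, and summarizes per replica the equilibrium averages
#' of the concentrations together with the fluctuation observables: the
#' compressibility proxy kappa = c1*Var(c1) + c2*Var(c2) and the
#' specific-heat proxy Cv = (<E^2> - <E>^2)/L^2 (as defined, without a 1/T^2
#' factor; these serve as transition signatures).
#'
#' @param run a \code{gcmc_run} specification.
#' @return an object of class \code{gcmc_result}: a list with
#'   \code{isotherm} (data.frame: mu1, mu2, c1_mean, c2_mean, c1_var, c2_var,
#'   kappa, cv, acceptance, swap_acceptance), \code{series} (list of
#'   \code{observable_series}), \code{snapshots} (list over replicas of
#'   lists of \code{lattice_config}), \code{final} (final configurations)
#'   and \code{run} (the specification).
#' @export
run_isotherm <- function(run) {
  stopifnot(inherits(run, "gcmc_run"))
  g <- run$geometry
  occ0 <- init_occupancies(run)
  out <- gcmc_run_cpp(occ0, g$nn - 1L, g$third - 1L,
                      run$params$J, run$T_star, run$mu1, run$mu2,
                      run$sweeps, run$equil, run$sample_interval,
                      run$swap_interval, as.double(run$seed),
                      (run$active_sites %||% seq_len(g$n)) - 1L,
                      run$n_snapshots)
  R <- length(run$mu1)
  series <- lapply(seq_len(R), function(r)
    observable_series(out$N1[, r], out$N2[, r], out$E[, r], g$L))
  iso <- data.frame(
    mu1 = run$mu1, mu2 = run$mu2,
    c1_mean = vapply(series, function(s) mean(s$c1), 0),
    c2_mean = vapply(series, function(s) mean(s$c2), 0),
    c1_var = vapply(series, function(s) var_pop(s$c1), 0),
    c2_var = vapply(series, function(s) var_pop(s$c2), 0),
    kappa = vapply(series, kappa, 0),
    cv = vapply(series, specific_heat, 0),
    acceptance = out$acceptance,
    swap_acceptance = out$swap_acceptance)
  snaps <- lapply(seq_len(R), function(r) {
    m <- out$snapshots[[r]]
    lapply(seq_len(ncol(m)), function(k) new_configuration(g, m[, k]))
  })
  final <- lapply(seq_len(R), function(r) new_configuration(g, out$occ_final[, r]))
  structure(list(isotherm = iso, series = series, snapshots = snaps,
                 final = final, run = run),
            class = "gcmc_result")
}

#' @export
print.gcmc_result <- function(x, ...) {
  cat("GCMC result:", nrow(x$isotherm), "replicas, T* =", x$run$T_star,
      ", L =", x$run$geometry$L, "\n")
  print(utils::head(x$isotherm, 10))
  invisible(x)
}

#' One grand-canonical Metropolis step (reference implementation)
#'
#' Proposes a single uniformly chosen site change to a uniformly chosen other
#' state and accepts with probability min(1, exp(-dH/T*)).  Uses R's RNG;
#' intended for didactic use and unit tests (production sampling runs in the
#' compiled kernel).
#'
#' @param config a \code{lattice_config}.
#' @param params a \code{model_params}.
#' @param state a \code{thermo_state}.
#' @return list(config, accepted, dH, site, proposed).
#' @export
gcmc_step <- function(config, params = model_params(), state) {
  site <- sample.int(config$geometry$n, 1)
  cur <- config$occ[site]
  new_state <- sample(setdiff(0:2, cur), 1)
  dH <- delta_H_site_change(config, site, new_state, params, state)
  accepted <- dH <= 0 || stats::runif(1) < exp(-dH / state$T_star)
  if (accepted) config$occ[site] <- as.integer(new_state)
  list(config = config, accepted = accepted, dH = dH,
       site = site, proposed = new_state)
}

#' Replica-exchange acceptance probability
#'
#' Two replicas at equal T* but different chemical potentials exchange
#' configurations with probability
#' min(1, exp\{[(mu1a-mu1b)(N1b-N1a) + (mu2a-mu2b)(N2b-N2a)]/T*\}),
#' which preserves the product of the grand-canonical distributions.
#'
#' @param mu_a,mu_b length-2 vectors (mu1, mu2) of the two ladder states.
#' @param n_a,n_b length-2 vectors (N1, N2) of the two configurations.
#' @param T_star common reduced temperature (exchanging replicas at
#'   different temperatures is not supported).
#' @return the acceptance probability.
#' @export
tempering_swap_probability <- function(mu_a, mu_b, n_a, n_b, T_star) {
  if (T_star <= 0) stop("T* must be positive")
  larg <- ((mu_a[1] - mu_b[1]) * (n_b[1] - n_a[1]) +
             (mu_a[2] - mu_b[2]) * (n_b[2] - n_a[2])) / T_star
  min(1, exp(larg))
}

#' Hysteresis scan: the same ladder from two initial conditions
#'
#' Runs the identical thermodynamic grid twice, typically once from a random
#' start and once from an ordered pattern, and returns both isotherms for
#' overlay.  Metastability shows up as a lag between the two transition
#' locations; the pair is reported, not asserted.
#'
#' @param run_random,run_ordered \code{gcmc_run} specs on identical
#'   (T*, mu1, mu2) grids, differing in the initial condition.
#' @return list of two \code{gcmc_result}s (class \code{hysteresis_pair}).
#' @export
hysteresis_pair <- function(run_random, run_ordered) {
  same <- isTRUE(all.equal(run_random$mu1, run_ordered$mu1)) &&
    isTRUE(all.equal(run_random$mu2, run_ordered$mu2)) &&
    identical(run_random$T_star, run_ordered$T_star)
  if (!same) stop("the two runs must share the same (T*, mu1, mu2) grid")
  structure(list(random = run_isotherm(run_random),
                 ordered = run_isotherm(run_ordered)),
            class = "hysteresis_pair")
}
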