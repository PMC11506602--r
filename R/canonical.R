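#' @title Canonical-ensemble dynamics and annealing
#' @description At fixed particle numbers (N1, N2) the mixture evolves by
#'   nearest-neighbour particle displacements: a uniformly chosen particle
#'   attempts a hop along a uniformly chosen lattice direction, the move is
#'   rejected outright if the target cell is occupied, and otherwise accepted
#'   with the Metropolis probability min(1, exp(-dE/T*)).  The
#'   direction-uniform proposal is exactly symmetric, so detailed balance
#'   holds at every fixed temperature.  Slow cooling through a staged
#'   temperature schedule drives the mixture through successive equilibrium
#'   states towards its low-temperature pattern.
#' @name canonical
NULL

#' Annealing schedule
#'
#' @param T_start,T_end initial and final reduced temperatures
#'   (T_start > T_end > 0); defaults 2.0 and 0.125.
#' @param n_stages number of temperature stages (>= 1).
#' @param sweeps_per_stage Monte Carlo sweeps per stage (1 sweep = N proposed
#'   displacements).
#' @param interpolation \code{"geometric"} (default) or \code{"linear"}
#'   spacing of the stage temperatures.
#' @return an object of class \code{anneal_schedule}; element \code{temps}
#'   holds the stage temperatures.
#' @export
anneal_schedule <- function(T_start = 2.0, T_end = 0.125, n_stages = 24,
                            sweeps_per_stage = 50000,
                            interpolation = c("geometric", "linear")) {
  interpolation <- match.arg(interpolation)
  if (!(T_start > T_end && T_end > 0)) stop("need T_start > T_end > 0")
  if (n_stages < 1) stop("need at least one stage")
  temps <- if (n_stages == 1) T_end
  else if (interpolation == "geometric")
    exp(seq(log(T_start), log(T_end), length.out = n_stages))
  else seq(T_start, T_end, length.out = n_stages)
  structure(list(T_start = T_start, T_end = T_end, n_stages = as.integer(n_stages),
                 sweeps_per_stage = as.integer(sweeps_per_stage),
                 interpolation = interpolation, temps = temps),
            class = "anneal_schedule")
}

#' One canonical displacement step (reference implementation)
#'
#' Reference R implementation of the displacement move, used in unit tests;
#' production annealing runs in the compiled kernel.
#'
#' @param config a \code{lattice_config} with at least one particle.
#' @param params a \code{model_params}.
#' @param T_star reduced temperature.
#' @return list(config, accepted, dE).
#' @export
canonical_step <- function(config, params = model_params(), T_star) {
  if (T_star <= 0) stop("T* must be positive")
  occ <- config$occ
  parts <- which(occ != 0L)
  if (length(parts) == 0) stop("no particles to move")
  from <- parts[sample.int(length(parts), 1)]
  to <- config$geometry$nn[from, sample.int(6, 1)]
  if (occ[to] != 0L)
    return(list(config = config, accepted = FALSE, dE = NA_real_))
  sp <- occ[from]
  st <- thermo_state(T_star, 0, 0)  # mu cancels for displacement moves
  dE <- delta_H_site_change(config, from, 0L, params, st)
  config$occ[from] <- 0L
  dE <- dE + delta_H_site_change(config, to, sp, params, st)
  accepted <- dE <= 0 || stats::runif(1) < exp(-dE / T_star)
  if (accepted) config$occ[to] <- sp else config$occ[from] <- sp
  list(config = config, accepted = accepted, dE = dE)
}

#' Anneal a fixed-composition mixture
#'
#' Places N1 + N2 particles at random (an exact multiset shuffle), then cools
#' through the schedule, recording the configuration at the end of every
#' stage.  Deterministic for a fixed seed.
#'
#' @param N1,N2 particle numbers of the two species (N1 + N2 <= L^2).
#' @param L lattice linear size.
#' @param schedule an \code{anneal_schedule}.
#' @param params a \code{model_params}.
#' @param seed integer seed.
#' @param sample_interval sweeps between energy samples within a stage.
#' @return an object of class \code{anneal_result}: \code{final}
#'   (a \code{lattice_config}), \code{stage_configs}, \code{stage_temps},
#'   \code{E} (samples per stage, one column per stage), \code{E_stage_mean},
#'   \code{acceptance}, and run metadata.
#' @export
anneal <- function(N1, N2, L, schedule = anneal_schedule(),
                   params = model_params(), seed = 1, sample_interval = 100) {
  g <- build_geometry(L)
  if (N1 + N2 > g$n) stop("overfilled lattice: N1 + N2 > L^2")
  if (N1 + N2 == 0) {
    cfg <- new_configuration(g)
    return(structure(list(final = cfg,
                          stage_configs = rep(list(cfg), schedule$n_stages),
                          stage_temps = schedule$temps,
                          E = matrix(0, 0, schedule$n_stages),
                          E_stage_mean = rep(0, schedule$n_stages),
                          acceptance = rep(NA_real_, schedule$n_stages),
                          N1 = N1, N2 = N2, L = L, seed = seed,
                          schedule = schedule),
                     class = "anneal_result"))
  }
  occ0 <- with_seed(seed, {
    v <- c(rep(1L, N1), rep(2L, N2), rep(0L, g$n - N1 - N2))
    sample(v)
  })
  out <- canonical_run_cpp(occ0, g$nn - 1L, g$third - 1L, params$J,
                           schedule$temps, schedule$sweeps_per_stage,
                           as.integer(sample_interval), as.double(seed))
  stage_configs <- lapply(seq_len(schedule$n_stages), function(s)
    new_configuration(g, out$stage_snapshots[, s]))
  res <- list(final = new_configuration(g, out$occ_final),
              stage_configs = stage_configs,
              stage_temps = schedule$temps,
              E = out$E,
              E_stage_mean = colMeans(out$E),
              acceptance = out$acceptance,
              N1 = N1, N2 = N2, L = L, seed = seed, schedule = schedule)
  # cooling monitor: mean energy should not increase along the schedule
  # (fluctuations are physical, so warn rather than fail)
  dE <- diff(res$E_stage_mean)
  if (any(dE > 0.05 * abs(res$E_stage_mean[-1]) + 1e-9))
    warning("stage-mean energy increased during cooling; ",
            "consider longer stages")
  class(res) <- "anneal_result"
  res
}

#' @export
print.anneal_result <- function(x, ...) {
  cat("Annealing result: L =", x$L, " N1 =", x$N1, " N2 =", x$N2,
      "\n  T*:", sprintf("%.3g", x$stage_temps[1]), "->",
      sprintf("%.3g", x$stage_temps[length(x$stage_temps)]),
      "in", length(x$stage_temps), "stages;",
      "final <E> =", sprintf("%.4g", x$E_stage_mean[length(x$E_stage_mean)]), "\n")
  invisible(x)
}
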