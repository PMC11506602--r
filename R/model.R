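#' Interaction model parameters
#'
#' The binary mixture interacts through a competing short-range attraction /
#' long-range repulsion (SALR) pair potential on the triangular lattice: like
#' particles attract with energy \code{-J1} at nearest-neighbour distance
#' (|dx| = 1) and repel with \code{+J2} at third-neighbour distance (|dx| = 2);
#' the cross interaction between unlike particles has the opposite sign at
#' both distances, and all pairs at other distances do not interact.  Energies
#' are measured in units of \code{J1} (so \code{J1 = 1} throughout) and the
#' single shape parameter is \code{J = J2/J1}.
#'
#' @param J repulsion-to-attraction ratio J2/J1 (default 3/4, the weak
#'   long-range repulsion regime; \code{J = 3} recovers the strong-repulsion
#'   system of earlier lattice studies).
#' @return an object of class \code{model_params} with elements \code{J1}
#'   (always 1), \code{J}, and \code{pair_table}, a 2 x 2 x 2 array of pair
#'   energies indexed by (species i, species j, shell).
#' @examples
#' p <- model_params(J = 3/4)
#' pair_energy(1, 1, "nn", p)     # -1
#' pair_energy(1, 2, "third", p)  # -0.75
#' @export
model_params <- function(J = 3 / 4) {
  stopifnot(is.numeric(J), length(J) == 1, is.finite(J))
  tab <- array(0, dim = c(2, 2, 2),
               dimnames = list(NULL, NULL, c("nn", "third")))
  tab[1, 1, "nn"] <- tab[2, 2, "nn"] <- -1
  tab[1, 2, "nn"] <- tab[2, 1, "nn"] <- +1
  tab[1, 1, "third"] <- tab[2, 2, "third"] <- +J
  tab[1, 2, "third"] <- tab[2, 1, "third"] <- -J
  structure(list(J1 = 1, J = J, pair_table = tab), class = "model_params")
}

#' Pair interaction energy
#'
#' @param si,sj species of the two particles (1 or 2); empty cells carry no
#'   interaction and are not valid arguments.
#' @param shell \code{"nn"} (|dx| = 1) or \code{"third"} (|dx| = 2).
#' @param params a \code{model_params}.
#' @return the pair energy in J1 units.
#' @export
pair_energy <- function(si, sj, shell, params = model_params()) {
  if (!all(c(si, sj) %in% c(1, 2)))
    stop("species must be 1 or 2; empty cells do not interact")
  shell <- match.arg(shell, c("nn", "third"))
  unname(params$pair_table[si, sj, shell])
}

#' Lattice configurations
#'
#' A configuration assigns each cell of the lattice an occupancy in
#' \{0 = empty, 1 = species-1, 2 = species-2\}; at most one particle per cell.
#'
#' @param geometry a \code{lattice_geometry}.
#' @param occ integer vector of length \code{geometry$n} with values 0, 1, 2;
#'   defaults to the empty lattice.
#' @return an object of class \code{lattice_config}.
#' @export
new_configuration <- function(geometry, occ = integer(geometry$n)) {
  stopifnot(inherits(geometry, "lattice_geometry"))
  occ <- as.integer(occ)
  if (length(occ) != geometry$n) stop("occupancy length must equal L^2")
  if (!all(occ %in% 0:2)) stop("occupancies must be 0 (empty), 1 or 2")
  structure(list(geometry = geometry, occ = occ), class = "lattice_config")
}

#' @export
print.lattice_config <- function(x, ...) {
  n <- particle_counts(x)
  cat("Lattice configuration: L =", x$geometry$L,
      " N1 =", n[1], " N2 =", n[2], "\n")
  invisible(x)
}

#' Particle numbers of a configuration
#'
#' @param config a \code{lattice_config}.
#' @return named numeric vector \code{c(N1, N2)}.
#' @export
particle_counts <- function(config) {
  c(N1 = sum(config$occ == 1L), N2 = sum(config$occ == 2L))
}

#' Occupancy as an L x L matrix
#'
#' Row index = axial q + 1, column index = axial r + 1.
#'
#' @param config a \code{lattice_config}.
#' @return an L x L integer matrix.
#' @export
occupancy_matrix <- function(config) {
  matrix(config$occ, config$geometry$L, config$geometry$L)
}

#' Total interaction energy of a configuration
#'
#' Sums the SALR pair potential over all interacting pairs (each unordered
#' pair once), i.e. E = 1/2 sum_x sum_x' rho_i(x) V_ij(x - x') rho_j(x').
#'
#' @param config a \code{lattice_config}.
#' @param params a \code{model_params}.
#' @return energy in J1 units.
#' @examples
#' g <- build_geometry(12)
#' total_energy(make_fixture(fixture_spec("isolated-motif", motif = "flower", L = 12)))
#' @export
total_energy <- function(config, params = model_params()) {
  occ <- config$occ
  g <- config$geometry
  shell_sum <- function(tbl, like, unlike) {
    a <- occ[rep(seq_along(occ), ncol(tbl))]
    b <- occ[tbl]
    pair <- a > 0L & b > 0L
    n_like <- sum(pair & a == b)
    n_unlike <- sum(pair) - n_like
    0.5 * (like * n_like + unlike * n_unlike)
  }
  shell_sum(g$nn, -1, +1) + shell_sum(g$third, +params$J, -params$J)
}

#' Thermodynamic state (reduced units)
#'
#' @param T_star reduced temperature kB*T/J1 (kB = 1 in reduced units).
#' @param mu1,mu2 chemical potentials of the two species, in J1 units.
#' @return an object of class \code{thermo_state}.
#' @export
thermo_state <- function(T_star, mu1, mu2) {
  stopifnot(is.finite(mu1), is.finite(mu2), is.numeric(T_star))
  if (T_star <= 0) stop("T* must be positive")
  structure(list(T_star = T_star, mu1 = mu1, mu2 = mu2),
            class = "thermo_state")
}

#' Thermodynamic Hamiltonian of an open system
#'
#' H = E - mu1*N1 - mu2*N2: the grand-potential Hamiltonian governing a
#' membrane patch exchanging inclusions with a bulk reservoir.
#'
#' @inheritParams total_energy
#' @param state a \code{thermo_state} (only mu1, mu2 are used).
#' @return H in J1 units.
#' @export
hamiltonian <- function(config, params = model_params(), state) {
  n <- particle_counts(config)
  total_energy(config, params) - state$mu1 * n[["N1"]] - state$mu2 * n[["N2"]]
}

#' Energy change of a single-site occupancy change
#'
#' Computes H(after) - H(before) for setting one site to a new occupancy,
#' using only the 12 sites of the two local shells.  This is the increment
#' driving Metropolis sampling.
#'
#' @inheritParams hamiltonian
#' @param site 1-based site index.
#' @param new_state new occupancy in \{0, 1, 2\}; must differ from the
#'   current one.
#' @return the increment dH in J1 units.
#' @export
delta_H_site_change <- function(config, site, new_state, params = model_params(),
                                state) {
  occ <- config$occ
  g <- config$geometry
  s_old <- occ[site]
  new_state <- as.integer(new_state)
  if (new_state == s_old) stop("new_state equals the current occupancy")
  if (!new_state %in% 0:2) stop("new_state must be 0, 1 or 2")

  local_e <- function(s) {
    if (s == 0L) return(0)
    e <- 0
    nb <- occ[g$nn[site, ]]
    e <- e - sum(nb == s) + sum(nb != s & nb > 0L)
    nb <- occ[g$third[site, ]]
    e + params$J * (sum(nb == s) - sum(nb != s & nb > 0L))
  }
  dE <- local_e(new_state) - local_e(s_old)
  d1 <- (new_state == 1L) - (s_old == 1L)
  d2 <- (new_state == 2L) - (s_old == 2L)
  dE - state$mu1 * d1 - state$mu2 * d2
}
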