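#' @title Periodic pattern library and ground-state phase diagram
#' @description The ordered phases of the mixture are periodic motifs on the
#'   triangular lattice.  Each motif is stored on a general periodic unit cell
#'   in Hermite normal form: basis vectors (w, 0) and (shear, h) in axial
#'   coordinates, i.e. crossing the cell in the r direction re-enters shifted
#'   by `shear` columns.  Plain rectangular cells have shear 0.  The per-cell
#'   thermodynamic Hamiltonian h = H/Ac of a motif is exact for arbitrarily
#'   small cells because periodic self-image pairs are counted with their
#'   proper weight.
#' @name patterns
NULL

# --- unit-cell machinery ----------------------------------------------------

#' Construct a pattern specification
#'
#' @param label pattern name.  One-component patterns carry the species as a
#'   suffix (\code{c72} = flowers of species 2, \code{b1} = bubbles in a
#'   species-1 liquid); two-component patterns are ordered symbol pairs with
#'   the first symbol describing species 1 (\code{c4l}, \code{m2m3}, ...).
#' @param w,h unit-cell dimensions (axial q and r extent).
#' @param shear column offset applied when wrapping across the r boundary
#'   (Hermite-normal-form cell basis (w, 0), (shear, h)).
#' @param motif integer vector of length \code{w*h} (q fastest) with
#'   occupancies 0, 1, 2.
#' @param params a \code{model_params}; used to precompute the cell energy.
#' @return an object of class \code{pattern_spec} with the motif, its particle
#'   numbers \code{n1}, \code{n2}, the cell size \code{Ac = w*h} and the
#'   interaction energy per unit cell \code{E_cell}.
#' @export
pattern_spec <- function(label, w, h, motif, shear = 0, params = model_params()) {
  motif <- as.integer(motif)
  stopifnot(length(motif) == w * h, all(motif %in% 0:2))
  structure(list(label = label, w = as.integer(w), h = as.integer(h),
                 shear = as.integer(shear) %% as.integer(w), motif = motif,
                 Ac = as.integer(w * h),
                 n1 = sum(motif == 1L), n2 = sum(motif == 2L),
                 E_cell = cell_energy(motif, w, h, shear, params$J)),
            class = "pattern_spec")
}

#' @export
print.pattern_spec <- function(x, ...) {
  cat(sprintf("pattern '%s': %d x %d cell (shear %d), N1=%d N2=%d, E/cell=%.6g\n",
              x$label, x$w, x$h, x$shear, x$n1, x$n2, x$E_cell / x$Ac))
  invisible(x)
}

# occupancy of the infinite tiling at axial (q, r) (vectors allowed)
motif_at <- function(pattern, q, r) {
  w <- pattern$w; h <- pattern$h; s <- pattern$shear
  wraps <- floor(r / h)
  rr <- r - wraps * h
  qq <- (q - s * wraps) %% w
  pattern$motif[qq + w * rr + 1L]
}

# exact interaction energy per unit cell of the infinite tiling:
# E = 1/2 sum_{site in cell} sum_{12 displacements} V(s_i, s_j), with
# displacements wrapping through the HNF cell; self-image pairs get weight
# 1/2 per displacement (they occur under d and -d).
cell_energy <- function(motif, w, h, shear, J) {
  motif <- as.integer(motif)
  dq <- c(1L, -1L, 0L, 0L, 1L, -1L, 2L, -2L, 0L, 0L, 2L, -2L)
  dr <- c(0L, 0L, 1L, -1L, -1L, 1L, 0L, 0L, 2L, -2L, -2L, 2L)
  q <- rep.int(0:(w - 1), h)
  r <- rep(0:(h - 1), each = w)
  E <- 0
  for (d in seq_len(12)) {
    wraps <- floor((r + dr[d]) / h)
    rr <- r + dr[d] - wraps * h
    qq <- (q + dq[d] - wraps * shear) %% w
    nb <- motif[qq + w * rr + 1L]
    a <- motif
    pair <- a > 0L & nb > 0L
    like <- pair & a == nb
    unlike <- pair & a != nb
    v <- if (d <= 6) -1 else J
    E <- E + 0.5 * v * (sum(like) - sum(unlike))
  }
  E
}

#' Thermodynamic Hamiltonian per lattice cell of a periodic pattern
#'
#' h = (E_cell - mu1*n1 - mu2*n2) / Ac, linear in (mu1, mu2).  This is the
#' T -> 0 stability criterion: the ground state at (mu1, mu2) is the pattern
#' with minimal h.
#'
#' @param pattern a \code{pattern_spec}.
#' @param params a \code{model_params}; if its J differs from the one the
#'   pattern was built with, the cell energy is recomputed.
#' @param mu1,mu2 chemical potentials (scalars or equal-length vectors).
#' @return h in J1 units per lattice cell.
#' @export
h_per_cell <- function(pattern, params = model_params(), mu1, mu2) {
  E <- cell_energy(pattern$motif, pattern$w, pattern$h, pattern$shear, params$J)
  (E - mu1 * pattern$n1 - mu2 * pattern$n2) / pattern$Ac
}

#' Species-swapped mirror of a pattern
#'
#' Exchanges species 1 and 2 in the motif and reverses a two-symbol label.
#'
#' @param pattern a \code{pattern_spec}.
#' @param label optional label for the mirror; by default derived from the
#'   original label.
#' @param params a \code{model_params}.
#' @return a \code{pattern_spec}.
#' @export
swap_species_pattern <- function(pattern, label = NULL, params = model_params()) {
  m <- pattern$motif
  m2 <- m
  m2[m == 1L] <- 2L
  m2[m == 2L] <- 1L
  if (is.null(label)) label <- paste0(pattern$label, "*")
  pattern_spec(label, pattern$w, pattern$h, m2, pattern$shear, params)
}

# --- the library ------------------------------------------------------------

#' Library of ordered ground-state patterns
#'
#' Encodes the periodic motifs that compete for the ground state of the
#' binary SALR mixture at weak long-range repulsion (J = 3/4), for the
#' species-2-rich side (mu2 > mu1), together with their species-swapped
#' mirrors.  Composition of the library:
#' \itemize{
#'   \item \code{v}: vacuum (empty lattice) and \code{dp1}/\code{dp2}:
#'     densely packed one-component liquids.
#'   \item \code{c71}/\code{c72}: seven-particle hexagonal 'flower' clusters
#'     on the densest hexagonal superlattice that keeps the clusters
#'     non-interacting (19 lattice cells per flower).
#'   \item \code{l1}/\code{l2}: one-component stripes of thickness 2
#'     separated by two empty rows.
#'   \item \code{b1}/\code{b2}: bubble phases, the complement of the flower
#'     superlattice: a dense one-component liquid with hexagonal seven-site
#'     voids.
#'   \item \code{m2m2}: alternating modulated stripes of the two species
#'     (thickness 2) separated by vacancy rows; spatial period 4.
#'   \item \code{ll}: fully occupied alternating lamellas of thickness 2;
#'     spatial period 4.
#'   \item \code{m2m3}/\code{m3m2}: modulated stripes of unequal thickness.
#'   \item \code{c2l}/\code{lc2}, \code{c4l}/\code{lc4}: chains of dimers or
#'     rhombic 4-clusters of the minority species between stripes of the
#'     majority species.
#'   \item \code{c4b}/\code{bc4}, \code{c1b}/\code{bc1}: rhombic 4-clusters
#'     or single particles of the minority species inside the voids of the
#'     majority bubble phase.
#' }
#'
#' @param params a \code{model_params}.
#' @return a named list of \code{pattern_spec} objects.
#' @examples
#' lib <- pattern_library()
#' h_per_cell(lib$v, model_params(), -1, -1)   # 0
#' @export
pattern_library <- function(params = model_params()) {
  P <- function(...) pattern_spec(..., params = params)
  lib <- list()

  lib$v <- P("v", 1, 1, 0L)
  lib$dp2 <- P("dp2", 1, 1, 2L)

  # one-component stripes: thickness 2, two empty rows, running along r
  lib$l2 <- P("l2", 4, 1, c(2L, 2L, 0L, 0L))

  # flower (c7) superlattice: one 7-site hexagonal cluster per 19 cells, on
  # the hexagonal sublattice generated by (3,2) and (-2,5); HNF (19,0),(11,1).
  # Flower offsets {(0,0),(+-1,0),(0,+-1),(1,-1),(-1,1)} map to columns
  # {0,1,18,8,11,12,7} of the 19 x 1 cell.
  c7 <- integer(19)
  c7[c(0, 1, 18, 8, 11, 12, 7) + 1L] <- 2L
  lib$c72 <- P("c72", 19, 1, c7, shear = 11)

  # bubble phase: complement of the flower superlattice (7-site voids in a
  # dense liquid), density 12/19
  lib$b2 <- P("b2", 19, 1, ifelse(c7 == 2L, 0L, 2L), shear = 11)

  # two-component stripes on the symmetric diagonal
  lib$m2m2 <- P("m2m2", 4, 2, c(2L, 2L, 1L, 1L,
                                2L, 0L, 1L, 0L), shear = 3)
  lib$ll <- P("ll", 4, 1, c(1L, 1L, 2L, 2L))

  # unequal modulated stripes: thickness 2 (species 1) and 3 (species 2)
  lib$m2m3 <- P("m2m3", 9, 1, c(2L, 2L, 2L, 2L, 0L, 1L, 1L, 1L, 0L), shear = 7)

  # minority chains between majority stripes: thin species-1 chains centred
  # between species-2 stripes of thickness 2, gaining the cross-species
  # third-neighbour attraction from both sides.  (A sparser variant with the
  # chain broken into dimers every other period is nearly degenerate and
  # takes over at the low-mu1 edge of the band; see the methods vignette.)
  lib$c2l <- P("c2l", 5, 1, c(2L, 2L, 0L, 1L, 0L))
  # rhombic 4-clusters of the minority centred between majority stripes, one
  # empty lane away on both sides (the cross-species attraction at |dx| = 2
  # binds the rhombs to the stripes without contact)
  lib$c4l <- P("c4l", 6, 3, c(2L, 2L, 0L, 1L, 1L, 0L,
                              2L, 2L, 0L, 1L, 1L, 0L,
                              2L, 2L, 0L, 0L, 0L, 0L), shear = 1)

  # minority clusters inside the voids of the bubble phase
  c4b <- ifelse(c7 == 2L, 0L, 2L)
  c4b[c(0, 1, 8, 7) + 1L] <- 1L          # rhomb {(0,0),(1,0),(0,1),(-1,1)}
  lib$c4b <- P("c4b", 19, 1, c4b, shear = 11)
  c1b <- ifelse(c7 == 2L, 0L, 2L)
  c1b[1L] <- 1L                          # single particle at the void centre
  lib$c1b <- P("c1b", 19, 1, c1b, shear = 11)

  # mirrors (mu2 < mu1 side); m2m2 and ll are symmetric under the swap
  mirror_label <- c(dp2 = "dp1", l2 = "l1", c72 = "c71", b2 = "b1",
                    m2m3 = "m3m2", c2l = "lc2", c4l = "lc4",
                    c4b = "bc4", c1b = "bc1")
  for (nm in names(mirror_label)) {
    ml <- mirror_label[[nm]]
    lib[[ml]] <- swap_species_pattern(lib[[nm]], label = ml, params = params)
  }
  lib
}

# --- ground-state diagram ---------------------------------------------------

#' Ground-state phase diagram over a chemical-potential grid
#'
#' At every (mu1, mu2) grid point the pattern(s) minimizing the per-cell
#' thermodynamic Hamiltonian are determined; ties within tolerance are
#' reported as coexistence.
#'
#' @param library a list of \code{pattern_spec} (see [pattern_library()]).
#' @param params a \code{model_params}.
#' @param mu1_grid,mu2_grid numeric vectors of chemical potentials; defaults
#'   cover [-4, 1] at step 0.05.
#' @param tol degeneracy tolerance for co-minimal h (relative to max(1, |h|)).
#' @return a data.frame with columns \code{mu1}, \code{mu2}, \code{label}
#'   (comma-separated co-minimal pattern labels) and \code{h_min}.
#' @export
ground_state_diagram <- function(library = pattern_library(params),
                                 params = model_params(),
                                 mu1_grid = seq(-4, 1, by = 0.05),
                                 mu2_grid = seq(-4, 1, by = 0.05),
                                 tol = 1e-9) {
  stopifnot(length(library) > 0, "v" %in% vapply(library, `[[`, "", "label"))
  grid <- expand.grid(mu1 = mu1_grid, mu2 = mu2_grid,
                      KEEP.OUT.ATTRS = FALSE)
  hmat <- vapply(library, function(p)
    (p$E_cell - grid$mu1 * p$n1 - grid$mu2 * p$n2) / p$Ac,
    numeric(nrow(grid)))
  if (is.null(dim(hmat))) hmat <- matrix(hmat, nrow = 1)
  hmin <- do.call(pmin, as.data.frame(hmat))
  labs <- vapply(library, `[[`, "", "label")
  eps <- tol * pmax(1, abs(hmin))
  label <- apply(hmat <= hmin + eps, 1L,
                 function(z) paste(labs[z], collapse = ","))
  data.frame(grid, label = label, h_min = hmin, stringsAsFactors = FALSE)
}

#' Phase boundaries along the symmetric diagonal mu1 = mu2
#'
#' Since h is piecewise linear in mu, the crossing of two phases along the
#' diagonal is found exactly by solving e_a - mu*rho_a = e_b - mu*rho_b.
#'
#' @param a,b \code{pattern_spec}s with different particle densities.
#' @return the crossing chemical potential mu (J1 units).
#' @examples
#' lib <- pattern_library()
#' diagonal_crossing(lib$v, lib$m2m2)   # -25/12
#' diagonal_crossing(lib$m2m2, lib$ll)  # -3/4
#' @export
diagonal_crossing <- function(a, b) {
  ea <- a$E_cell / a$Ac; rhoa <- (a$n1 + a$n2) / a$Ac
  eb <- b$E_cell / b$Ac; rhob <- (b$n1 + b$n2) / b$Ac
  if (abs(rhoa - rhob) < 1e-12)
    stop("patterns have equal density: h lines are parallel on the diagonal")
  (ea - eb) / (rhoa - rhob)
}

# --- brute-force enumeration oracle -----------------------------------------

#' Exhaustive scan of all occupancies of a small periodic cell
#'
#' Enumerates all 3^(w*h) occupancies of the periodic unit cell and records,
#' for each particle-number class (N1, N2), the minimal interaction energy
#' per unit cell together with minimizing motifs.  The scan is independent of
#' the chemical potentials, so a single scan answers ground-state queries for
#' every (mu1, mu2); see [enumerate_ground_state()].
#'
#' @param cell_w,cell_h unit-cell dimensions; \code{cell_w*cell_h} must not
#'   exceed 16 (3^16 ~ 4.3e7 states).
#' @param params a \code{model_params}.
#' @param shear HNF column offset of the cell (0 = rectangular).
#' @param keep maximal number of minimizing motifs stored per class.
#' @return an object of class \code{cell_scan}.
#' @export
enumerate_cell_scan <- function(cell_w, cell_h, params = model_params(),
                                shear = 0, keep = 8) {
  n <- cell_w * cell_h
  if (n > 16)
    stop("unit cell too large for exhaustive enumeration: ", n,
         " sites > 16 (3^16 states is the supported limit)")
  out <- enumerate_cell_scan_cpp(as.integer(cell_w), as.integer(cell_h),
                                 params$J, as.integer(keep), as.integer(shear))
  out$shear <- shear
  class(out) <- "cell_scan"
  out
}

#' Exact ground state of a small periodic cell at given chemical potentials
#'
#' Independent brute-force oracle for the pattern library: minimizes
#' h = (E - mu1 N1 - mu2 N2)/(w h) over all 3^(w h) periodic occupancies.
#'
#' @param cell_w,cell_h unit-cell dimensions (product <= 16), or pass a
#'   precomputed scan via \code{scan}.
#' @param params a \code{model_params}.
#' @param mu1,mu2 chemical potentials.
#' @param scan optional \code{cell_scan} to reuse.
#' @param tol degeneracy tolerance on h.
#' @return a list with \code{h_min}, \code{classes} (data.frame of co-minimal
#'   (N1, N2, E)), and \code{motifs}: minimizing occupancy vectors, de-duplicated
#'   up to cell translations (and, for square unsheared cells, the full
#'   point group).
#' @export
enumerate_ground_state <- function(cell_w, cell_h, params = model_params(),
                                   mu1, mu2, scan = NULL, tol = 1e-9) {
  if (is.null(scan)) scan <- enumerate_cell_scan(cell_w, cell_h, params)
  n <- scan$w * scan$h
  N1 <- row(scan$emin) - 1L
  N2 <- col(scan$emin) - 1L
  h <- (scan$emin - mu1 * N1 - mu2 * N2) / n
  h_min <- min(h)
  idx <- which(h <= h_min + tol * max(1, abs(h_min)), arr.ind = TRUE)
  classes <- data.frame(N1 = idx[, 1] - 1L, N2 = idx[, 2] - 1L)
  classes$E <- scan$emin[idx]
  classes$n_min <- scan$n_min[idx]
  motifs <- list()
  for (i in seq_len(nrow(classes))) {
    cls <- classes$N1[i] * (n + 1L) + classes$N2[i] + 1L
    m <- scan$motifs[[cls]]
    if (!is.null(m))
      for (k in seq_len(ncol(m))) motifs[[length(motifs) + 1L]] <- m[, k]
  }
  motifs <- dedupe_motifs(motifs, scan$w, scan$h, scan$shear)
  list(h_min = h_min, classes = classes, motifs = motifs)
}

# canonical form of a motif under cell translations (plus the lattice point
# group for square unsheared cells); used to report minimizers up to symmetry
dedupe_motifs <- function(motifs, w, h, shear) {
  if (length(motifs) == 0) return(motifs)
  canon <- function(m) {
    best <- NULL
    qs <- rep.int(0:(w - 1), h)
    rs <- rep(0:(h - 1), each = w)
    variants <- list(cbind(qs, rs))
    if (w == h && shear == 0) {
      # 12 point-group ops: 6 rotations x optional reflection (q,r)->(r,q)
      rot <- function(co) cbind(-co[, 2], co[, 1] + co[, 2])
      co <- cbind(qs, rs)
      for (k in 1:5) {
        co <- rot(co)
        variants[[length(variants) + 1L]] <- co
      }
      for (k in seq_along(variants)) {
        co <- variants[[k]]
        variants[[length(variants) + 1L]] <- cbind(co[, 2], co[, 1])
      }
    }
    for (co in variants) {
      for (dq in 0:(w - 1)) for (dr in 0:(h - 1)) {
        wraps <- floor((co[, 2] + dr) / h)
        rr <- co[, 2] + dr - wraps * h
        qq <- (co[, 1] + dq - shear * wraps) %% w
        v <- integer(w * h)
        v[qq + w * rr + 1L] <- m
        key <- paste(v, collapse = "")
        if (is.null(best) || key < best) best <- key
      }
    }
    best
  }
  keys <- vapply(motifs, canon, "")
  motifs[!duplicated(keys)]
}

# --- tiling -----------------------------------------------------------------

#' Tile a periodic pattern onto an L x L lattice
#'
#' @param pattern a \code{pattern_spec}.
#' @param geometry a \code{lattice_geometry}; L must be commensurate with the
#'   pattern (h divides L, w divides L, and the accumulated shear over L rows
#'   is a multiple of w).
#' @return a \code{lattice_config}.
#' @export
tile_pattern <- function(pattern, geometry) {
  L <- geometry$L
  ok <- (L %% pattern$h == 0) && (L %% pattern$w == 0) &&
    ((pattern$shear * (L / pattern$h)) %% pattern$w == 0)
  if (!ok)
    stop(sprintf(paste0("L = %d is not commensurate with pattern '%s' ",
                        "(needs L divisible by %d and %d with shear %d)"),
                 L, pattern$label, pattern$w, pattern$h, pattern$shear))
  occ <- motif_at(pattern, geometry$coords[, "q"], geometry$coords[, "r"])
  new_configuration(geometry, occ)
}
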