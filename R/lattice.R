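#' Triangular-lattice geometry with periodic boundaries
#'
#' Builds an \code{L} x \code{L} triangular lattice in axial integer
#' coordinates \code{(q, r)} (0-based) with basis vectors
#' \code{a1 = (1, 0)} and \code{a2 = (1/2, sqrt(3)/2)} in units of the cell
#' diameter, and resolves the two interacting neighbour shells under periodic
#' wrapping: the 6 nearest neighbours at Euclidean distance 1 and the 6 third
#' neighbours at distance 2 (the doubled nearest-neighbour vectors).  The 6
#' second neighbours at distance \code{sqrt(3)} do not interact in this model
#' and are deliberately not part of the geometry.
#'
#' @param L integer linear size (cells per axis); must be at least 5 so that
#'   the two shells of a site contain 12 distinct other sites under wrapping.
#' @return an object of class \code{lattice_geometry}: a list with elements
#'   \code{L}, \code{n} (= L^2), \code{coords} (n x 2 matrix of axial (q, r)),
#'   \code{nn} and \code{third} (n x 6 matrices of 1-based site indices).
#'   Site index convention: \code{site = q + L*r + 1}.
#' @examples
#' g <- build_geometry(8)
#' ncol(g$nn)  # 6
#' @export
build_geometry <- function(L) {
  if (length(L) != 1 || !is.numeric(L) || is.na(L) || L != round(L))
    stop("L must be a single integer")
  L <- as.integer(L)
  if (L < 5)
    stop("L must be >= 5: for smaller L the third shell wraps onto the ",
         "nearest-neighbour shell")
  n <- L * L
  q <- rep.int(0:(L - 1), L)
  r <- rep(0:(L - 1), each = L)

  shell_table <- function(disp) {
    m <- matrix(0L, n, 6)
    for (j in seq_len(6)) {
      qq <- (q + disp[j, 1]) %% L
      rr <- (r + disp[j, 2]) %% L
      m[, j] <- qq + L * rr + 1L
    }
    m
  }
  nn_disp <- rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                   c(1L, -1L), c(-1L, 1L))
  geom <- list(L = L, n = n, coords = cbind(q = q, r = r),
               nn = shell_table(nn_disp), third = shell_table(2L * nn_disp))
  class(geom) <- "lattice_geometry"
  geom
}

#' Cartesian coordinates of lattice sites
#'
#' Maps axial coordinates to Cartesian positions \code{x = q + r/2},
#' \code{y = r*sqrt(3)/2} (cell diameter = 1).
#'
#' @param geometry a \code{lattice_geometry}.
#' @return an n x 2 matrix of (x, y) positions.
#' @export
site_positions <- function(geometry) {
  stopifnot(inherits(geometry, "lattice_geometry"))
  q <- geometry$coords[, "q"]
  r <- geometry$coords[, "r"]
  cbind(x = q + r / 2, y = r * sqrt(3) / 2)
}

#' @export
print.lattice_geometry <- function(x, ...) {
  cat("Triangular lattice geometry: L =", x$L, "(", x$n, "cells ),",
      "periodic, shells at |dx| = 1 and 2\n")
  invisible(x)
}

# site index <-> axial helpers (internal)
site_index <- function(L, q, r) (q %% L) + L * (r %% L) + 1L
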