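#' @title Structural and thermodynamic observables
#' @description Structure factors on the reciprocal triangular lattice,
#'   cluster statistics, periodicity detection, motif classification, and
#'   the fluctuation estimators kappa and Cv.
#' @name observables
NULL

# --- observable series ------------------------------------------------------

#' Sampled observable series of a (grand-)canonical run
#'
#' @param N1,N2,E numeric vectors of sampled particle numbers and energy.
#' @param L lattice linear size (concentrations are ci = Ni/L^2).
#' @return an object of class \code{observable_series} with elements
#'   \code{N1}, \code{N2}, \code{E}, \code{c1}, \code{c2}, \code{L}.
#' @export
observable_series <- function(N1, N2, E, L) {
  stopifnot(length(N1) == length(N2), length(N1) == length(E))
  structure(list(N1 = N1, N2 = N2, E = E,
                 c1 = N1 / L^2, c2 = N2 / L^2, L = L),
            class = "observable_series")
}

#' Compressibility proxy kappa
#'
#' kappa = c1*Delta_c1 + c2*Delta_c2 with Delta_ci the population variance of
#' the species concentration over the sampled window.
#'
#' @param series an \code{observable_series} with at least two samples.
#' @return kappa (dimensionless).
#' @export
kappa <- function(series) {
  if (length(series$c1) < 2) stop("kappa is undefined for fewer than 2 samples")
  mean(series$c1) * var_pop(series$c1) + mean(series$c2) * var_pop(series$c2)
}

#' Specific-heat proxy Cv
#'
#' Cv = (<E^2> - <E>^2)/L^2, the energy variance per lattice cell, exactly as
#' used for locating transitions (no 1/T^2 factor by default).
#'
#' @param series an \code{observable_series} with at least two samples, or a
#'   numeric vector of energies (then \code{L} must be given).
#' @param L lattice linear size (taken from the series when omitted).
#' @param conventional if TRUE, divide additionally by T_star^2 (then
#'   \code{T_star} is required).
#' @param T_star reduced temperature, only used when \code{conventional}.
#' @return Cv in J1^2 per cell (or J1^2/T*^2 per cell if conventional).
#' @export
specific_heat <- function(series, L = NULL, conventional = FALSE, T_star = NULL) {
  if (inherits(series, "observable_series")) {
    E <- series$E
    if (is.null(L)) L <- series$L
  } else E <- series
  if (is.null(L)) stop("L is required")
  if (length(E) < 2) stop("Cv is undefined for fewer than 2 samples")
  cv <- var_pop(E) / L^2
  if (conventional) {
    if (is.null(T_star)) stop("T_star required for the conventional Cv")
    cv <- cv / T_star^2
  }
  cv
}

# --- structure factor -------------------------------------------------------

#' Structure factor of a configuration
#'
#' Bragg-spot diagnostic of periodic order on the reciprocal lattice of the
#' L x L triangular lattice.  The dispersion originates in the particles of
#' both species, so the default spectrum is the incoherent per-species sum
#' S(k) = (|FT rho_1|^2 + |FT rho_2|^2)/Np with Np the total particle count:
#' a fully occupied one-species lattice gives a single Bragg peak S = L^2 at
#' k = 0, and the fully occupied lamellar state shows its stripe spots even
#' though its species-summed occupancy is uniform.  The literal
#' species-summed field and the concentration-contrast field rho_1 - rho_2
#' are available through \code{field}.
#'
#' @param config a \code{lattice_config}.
#' @param species optional: restrict to one species (1 or 2); overrides
#'   \code{field}.
#' @param field \code{"particles"} (default, incoherent per-species sum),
#'   \code{"sum"} (species-summed occupancy) or \code{"difference"}
#'   (rho_1 - rho_2).
#' @return an object of class \code{structure_factor}: \code{S} (L x L
#'   matrix indexed by integer reciprocal coordinates m, n = 0..L-1),
#'   \code{kx}, \code{ky} (Cartesian components of k = (m b1 + n b2)/L, in
#'   units 1/a with a the lattice constant), \code{L}, \code{Np} and the
#'   normalization convention.
#' @export
structure_factor <- function(config, species = NULL,
                             field = c("particles", "sum", "difference")) {
  field <- match.arg(field)
  L <- config$geometry$L
  occ <- config$occ
  Np <- sum(occ > 0L)
  ft2 <- function(sigma) Mod(stats::fft(matrix(sigma, L, L)))^2  # [q+1, r+1]
  P <- if (!is.null(species)) {
    if (!species %in% 1:2) stop("species must be 1 or 2")
    Np <- sum(occ == as.integer(species))
    ft2(as.numeric(occ == as.integer(species)))
  } else switch(field,
    particles = ft2(as.numeric(occ == 1L)) + ft2(as.numeric(occ == 2L)),
    sum = ft2(as.numeric(occ > 0L)),
    difference = ft2(as.numeric(occ == 1L) - as.numeric(occ == 2L)))
  S <- if (Np == 0) matrix(0, L, L) else P / Np
  # reciprocal basis of a1=(1,0), a2=(1/2, sqrt(3)/2):
  # b1 = 2*pi*(1, -1/sqrt(3)), b2 = 2*pi*(0, 2/sqrt(3))
  m <- matrix(rep(0:(L - 1), L), L, L)
  n <- t(m)
  structure(list(S = S,
                 kx = 2 * pi * m / L,
                 ky = 2 * pi * (-m / sqrt(3) + 2 * n / sqrt(3)) / L,
                 L = L, Np = Np,
                 normalization = "S(k) = sum_i |FT rho_i|^2 / Np; sum_k S = L^2"),
            class = "structure_factor")
}

#' Per-species structure factor
#'
#' @param config a \code{lattice_config}.
#' @param species 1 or 2.
#' @return a \code{structure_factor} of the single-species occupancy field.
#' @export
per_species_spectrum <- function(config, species) {
  if (!species %in% 1:2) stop("species must be 1 or 2")
  structure_factor(config, species = species)
}

#' @export
print.structure_factor <- function(x, ...) {
  cat("Structure factor: L =", x$L, " Np =", x$Np, "\n ", x$normalization, "\n")
  invisible(x)
}

# centred integer reciprocal coordinates of every S entry, excluding k = 0;
# lambda is the Cartesian wavelength 2*pi/|k| in lattice constants
offorigin_peaks <- function(sf) {
  L <- sf$L
  m <- as.vector(matrix(rep(0:(L - 1), L), L, L))
  n <- as.vector(t(matrix(rep(0:(L - 1), L), L, L)))
  mc <- ifelse(m > L / 2, m - L, m)
  nc <- ifelse(n > L / 2, n - L, n)
  s <- as.vector(sf$S)
  keep <- !(m == 0 & n == 0)
  kx <- 2 * pi * mc / L
  ky <- 2 * pi * (-mc + 2 * nc) / (sqrt(3) * L)
  kk <- sqrt(kx^2 + ky^2)
  data.frame(m = mc[keep], n = nc[keep], S = s[keep],
             lambda = 2 * pi / kk[keep])
}

# spatial period (in lattice translations along the three lattice axes) of
# the plane wave with integer reciprocal coordinates (m, n) on an L-torus
wave_period <- function(m, n, L) {
  per_axis <- c(L / gcd_int(abs(m), L),            # along a1
                L / gcd_int(abs(n), L),            # along a2
                L / gcd_int(abs(m - n) %% L, L))   # along a1 - a2
  per_axis <- per_axis[per_axis > 1]
  if (length(per_axis) == 0) return(NA_real_)
  min(per_axis)
}

gcd_int <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0) { t <- a %% b; a <- b; b <- t }
  a
}

#' Dominant spatial period from a structure factor
#'
#' Locates the strongest off-origin peak and returns the spatial period of
#' the corresponding plane wave along the lattice axes, in lattice constants.
#' If no off-origin intensity exceeds \code{threshold_factor} times the
#' median off-origin S, the spectrum is considered featureless and \code{NA}
#' is returned (the "no-period" sentinel).
#'
#' @param sf a \code{structure_factor}.
#' @param threshold_factor peak threshold relative to the off-origin median.
#' @param period_range optional length-2 vector restricting the candidate
#'   peaks to waves with period inside the range (useful for isolating
#'   superlattice peaks).
#' @return integer period in lattice constants, or NA if featureless.
#' @export
dominant_period <- function(sf, threshold_factor = 5, period_range = NULL) {
  pk <- offorigin_peaks(sf)
  if (nrow(pk) == 0 || all(pk$S == 0)) return(NA_real_)
  pk$period <- mapply(wave_period, pk$m, pk$n, MoreArgs = list(L = sf$L))
  pk <- pk[!is.na(pk$period), ]
  if (!is.null(period_range))
    pk <- pk[pk$period >= period_range[1] & pk$period <= period_range[2], ]
  if (nrow(pk) == 0) return(NA_real_)
  thr <- threshold_factor * stats::median(offorigin_peaks(sf)$S)
  best <- which.max(pk$S)
  if (pk$S[best] < thr || pk$S[best] == 0) return(NA_real_)
  pk$period[best]
}

#' Height of the strongest off-origin peak in a wavelength band
#'
#' Convenience for tracking superlattice order parameters: the maximal S
#' among off-origin waves whose Cartesian wavelength 2*pi/|k| (in lattice
#' constants) lies inside \code{lambda_range}, together with the detection
#' threshold used by [dominant_period()].
#'
#' @inheritParams dominant_period
#' @param lambda_range optional length-2 wavelength window in lattice
#'   constants.
#' @return list(height, threshold, lambda, m, n).
#' @export
peak_height <- function(sf, lambda_range = NULL, threshold_factor = 5) {
  pk <- offorigin_peaks(sf)
  thr <- threshold_factor * stats::median(pk$S)
  if (!is.null(lambda_range))
    pk <- pk[pk$lambda >= lambda_range[1] & pk$lambda <= lambda_range[2], ]
  if (nrow(pk) == 0)
    return(list(height = 0, threshold = thr, lambda = NA_real_,
                m = NA_integer_, n = NA_integer_))
  best <- which.max(pk$S)
  list(height = pk$S[best], threshold = thr, lambda = pk$lambda[best],
       m = pk$m[best], n = pk$n[best])
}

#' Hexagonal cluster-superlattice order parameter
#'
#' Order parameter for the flower-cluster (c7-type) phases: the height of the
#' six-fold-coherent superlattice Bragg peak of one species' cluster field.
#' The field keeps only particles belonging to connected clusters of at most
#' \code{max_cluster} sites (the compact aggregates; a percolating stripe or
#' bubble network does not contribute), its squared Fourier transform is
#' normalized by the species' total particle count (so the peak measures the
#' fraction of the species carrying superlattice order), the candidate
#' wavevectors are restricted to wavelengths 2*pi/|k| in
#' \code{lambda_range} (the cluster-superlattice band: flowers cannot sit
#' closer than sqrt(19) lattice constants, i.e. wavelengths >= ~3.8), and the
#' peak height at k is the minimum of S over the six 60-degree rotations of k
#' (a hexagonal superlattice puts coherent intensity on all six; stripe order
#' does not).  The detection threshold is \code{threshold_factor} times the
#' median off-origin intensity of the species' full spectrum.
#'
#' @param config a \code{lattice_config}.
#' @param species species carrying the cluster order (default 2).
#' @param max_cluster largest cluster size counted as a compact aggregate.
#' @param lambda_range superlattice wavelength band in lattice constants.
#' @param threshold_factor detection threshold relative to the median
#'   off-origin intensity of the species' full spectrum.
#' @return list(height, threshold, ratio, lambda, n_cluster_particles).
#'   Order is considered detected when \code{ratio >= 1}.
#' @export
superlattice_order <- function(config, species = 2, max_cluster = 9,
                               lambda_range = c(3.5, 7),
                               threshold_factor = 5) {
  g <- config$geometry
  n_total <- sum(config$occ == as.integer(species))
  cs <- cluster_stats(config, species)
  keep <- integer(0)
  if (cs$n_clusters > 0) {
    sizes <- tabulate(cs$membership[cs$membership > 0])
    keep <- which(cs$membership %in% which(sizes <= max_cluster))
  }
  occ <- integer(g$n)
  occ[keep] <- as.integer(species)
  sf_cluster <- per_species_spectrum(new_configuration(g, occ), species)
  # renormalize to the species' full particle count
  if (length(keep) > 0 && n_total > 0)
    sf_cluster$S <- sf_cluster$S * (length(keep) / n_total)
  sf_full <- per_species_spectrum(config, species)
  thr <- threshold_factor * stats::median(offorigin_peaks(sf_full)$S)
  po <- offorigin_peaks(sf_cluster)
  bb <- po[po$lambda >= lambda_range[1] & po$lambda <= lambda_range[2], ]
  if (nrow(bb) == 0 || n_total == 0)
    return(list(height = 0, threshold = thr, ratio = 0, lambda = NA_real_,
                n_cluster_particles = length(keep)))
  L <- g$L
  getS <- function(m, n) sf_cluster$S[cbind((m %% L) + 1, (n %% L) + 1)]
  h6 <- rep(Inf, nrow(bb))
  m <- bb$m; n <- bb$n
  for (j in 1:6) {
    h6 <- pmin(h6, getS(m, n))
    tmp <- m - n; n <- m; m <- tmp  # 60-degree rotation of reciprocal indices
  }
  i <- which.max(h6)
  list(height = h6[i], threshold = thr,
       ratio = if (thr > 0) h6[i] / thr else ifelse(h6[i] > 0, Inf, 0),
       lambda = bb$lambda[i], n_cluster_particles = length(keep))
}

# --- clusters ---------------------------------------------------------------

#' Cluster statistics under nearest-neighbour adjacency
#'
#' Connected components of the sites occupied by \code{species} (or by any
#' particle when species is NULL), connected through nearest-neighbour bonds.
#'
#' @param config a \code{lattice_config}.
#' @param species 1, 2 or NULL (any particle).
#' @return a list with \code{n_clusters}, \code{sizes} (decreasing),
#'   \code{membership} (0 for non-member sites) and
#'   \code{largest_fraction} (largest cluster size / species particle count).
#' @export
cluster_stats <- function(config, species = NULL) {
  occ <- config$occ
  g <- config$geometry
  keep <- if (is.null(species)) occ > 0L else occ == as.integer(species)
  idx <- which(keep)
  membership <- integer(g$n)
  if (length(idx) == 0)
    return(list(n_clusters = 0L, sizes = integer(0),
                membership = membership, largest_fraction = NA_real_))
  # union-find over nearest-neighbour bonds among kept sites
  parent <- seq_len(g$n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (j in 1:6) {
    nb <- g$nn[idx, j]
    ok <- keep[nb]
    for (k in which(ok)) {
      ra <- find(idx[k]); rb <- find(nb[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(idx, find, 1L)
  comp <- match(roots, unique(roots))
  membership[idx] <- comp
  sizes <- sort(tabulate(comp), decreasing = TRUE)
  list(n_clusters = length(sizes), sizes = sizes, membership = membership,
       largest_fraction = sizes[1] / length(idx))
}

#' Count seven-particle hexagonal 'flower' clusters
#'
#' A flower is a connected cluster of exactly 7 particles of one species
#' whose internal bond census is 12 nearest-neighbour pairs and 3
#' third-neighbour pairs (a centre with its full hexagon of neighbours).
#'
#' @param config a \code{lattice_config}.
#' @param species 1, 2, or NULL to count flowers of either species.
#' @return number of flower clusters.
#' @export
count_flowers <- function(config, species = NULL) {
  species_list <- if (is.null(species)) 1:2 else species
  total <- 0L
  for (sp in species_list) {
    cs <- cluster_stats(config, sp)
    if (cs$n_clusters == 0) next
    sizes_by_comp <- tabulate(cs$membership[cs$membership > 0])
    for (comp in which(sizes_by_comp == 7L)) {
      sites <- which(cs$membership == comp)
      bonds <- pair_census(config$geometry, sites)
      if (bonds["nn"] == 12 && bonds["third"] == 3) total <- total + 1L
    }
  }
  total
}

# count internal nn/third pairs among a set of sites
pair_census <- function(geometry, sites) {
  inset <- logical(geometry$n)
  inset[sites] <- TRUE
  n_nn <- sum(inset[geometry$nn[sites, ]]) / 2
  n_th <- sum(inset[geometry$third[sites, ]]) / 2
  c(nn = n_nn, third = n_th)
}

# --- motif classification ---------------------------------------------------

# apply one of the 12 lattice point-group operations to a configuration
transform_config <- function(config, op) {
  g <- config$geometry
  L <- g$L
  q <- g$coords[, "q"]; r <- g$coords[, "r"]
  for (i in seq_len(op$rot)) {  # 60-degree rotation: (q, r) -> (-r, q + r)
    tmp <- -r
    r <- q + r
    q <- tmp
  }
  if (op$refl) { tmp <- q; q <- r; r <- tmp }
  occ_new <- integer(g$n)
  occ_new[(q %% L) + L * (r %% L) + 1L] <- config$occ
  new_configuration(g, occ_new)
}

point_group_ops <- function() {
  ops <- list()
  for (rot in 0:5) for (refl in c(FALSE, TRUE))
    ops[[length(ops) + 1L]] <- list(rot = rot, refl = refl)
  ops
}

# per-site local environments of the occupied sites: own species and the
# like/unlike counts on the two interacting shells.  Rotation- and
# translation-invariant by construction.
env_vectors <- function(config, sites = NULL) {
  g <- config$geometry
  occ <- config$occ
  if (is.null(sites)) sites <- which(occ > 0L)
  sites <- sites[occ[sites] > 0L]
  if (!length(sites)) return(NULL)
  s <- occ[sites]
  nnocc <- matrix(occ[g$nn[sites, , drop = FALSE]], length(sites), 6)
  thocc <- matrix(occ[g$third[sites, , drop = FALSE]], length(sites), 6)
  cbind(sp = s,
        lk_nn = rowSums(nnocc == s), ul_nn = rowSums(nnocc != s & nnocc > 0L),
        lk_th = rowSums(thocc == s), ul_th = rowSums(thocc != s & thocc > 0L))
}

env_census <- function(v) {
  key <- apply(v, 1, paste, collapse = ",")
  tab <- table(key)
  list(envs = do.call(rbind, lapply(strsplit(names(tab), ","), as.numeric)),
       freq = as.numeric(tab) / sum(tab))
}

# frequency-weighted soft coverage of census `ca` by census `cb`: each
# environment of `ca` contributes max(0, 1 - d/3) with d its L1 distance to
# the nearest same-species environment of `cb`
env_soft_cover <- function(ca, cb) {
  d <- vapply(seq_len(nrow(ca$envs)), function(i) {
    dv <- abs(sweep(cb$envs[, -1, drop = FALSE], 2, ca$envs[i, -1], "-"))
    min(rowSums(dv) + (cb$envs[, 1] != ca$envs[i, 1]) * 1e6)
  }, 0)
  sum(ca$freq * pmax(0, 1 - d / 3))
}

# smallest commensurate L >= 5 for tiling a pattern
commensurate_L <- function(pattern, L_min = 5) {
  L <- max(pattern$w * pattern$h, L_min)
  while (L %% pattern$h != 0 || L %% pattern$w != 0 ||
         (pattern$shear * (L / pattern$h)) %% pattern$w != 0) L <- L + 1
  L
}

#' Classify the dominant ordered motif of a configuration
#'
#' Heuristic motif classification against the pattern library.  The default
#' method is a local-environment census: every occupied site is summarized by
#' its species and the like/unlike occupation counts of its two interacting
#' shells (a rotation- and translation-invariant shape census), the censuses
#' of the configuration and of each ideally tiled library pattern are
#' compared by symmetric soft overlap (environments match within an L1 count
#' distance of up to 3, with linearly decreasing weight), and patterns are
#' ranked by the overlap.  The \code{"correlation"} method instead matches
#' the configuration directly against the tiled pattern over all unit-cell
#' translations and the 12 lattice point-group orientations, scoring the
#' fraction of agreeing sites among sites occupied in either field; it is
#' exact for ideal single-domain states but brittle for sprawling
#' multi-orientation domains.
#'
#' @param config a \code{lattice_config}.
#' @param library pattern library (occupied patterns only are scored).
#' @param region \code{"largest_cluster"} (sites of the largest any-species
#'   connected cluster), \code{"domains"} (all clusters larger than 9 sites,
#'   i.e. excluding dispersed compact aggregates) or \code{"all"}.
#' @param method \code{"environment"} (default) or \code{"correlation"}.
#' @param params a \code{model_params} (used if library is NULL).
#' @return a data.frame of labels and scores, sorted decreasing; the top row
#'   is the classification, its score the confidence (reported, never
#'   silently asserted).
#' @export
classify_motifs <- function(config, library = NULL,
                            region = c("largest_cluster", "domains", "all"),
                            method = c("environment", "correlation"),
                            params = model_params()) {
  region <- match.arg(region)
  method <- match.arg(method)
  if (is.null(library)) library <- pattern_library(params)
  library <- Filter(function(p) p$n1 + p$n2 > 0, library)
  g <- config$geometry

  sites <- which(config$occ > 0L)
  if (region != "all" && length(sites)) {
    cs <- cluster_stats(config, NULL)
    sizes <- tabulate(cs$membership[cs$membership > 0])
    keep <- if (region == "largest_cluster") which.max(sizes)
    else which(sizes > 9)
    sites <- which(cs$membership %in% keep)
  }

  if (method == "environment") {
    v <- env_vectors(config, sites)
    if (is.null(v)) {
      out <- data.frame(label = vapply(library, `[[`, "", "label"), score = 0)
      return(out)
    }
    cc <- env_census(v)
    scores <- vapply(library, function(p) {
      tc <- env_census(env_vectors(tile_pattern(p, build_geometry(commensurate_L(p)))))
      0.5 * env_soft_cover(cc, tc) + 0.5 * env_soft_cover(tc, cc)
    }, 0)
  } else {
    mask <- logical(g$n)
    mask[sites] <- TRUE
    for (k in 1:2) mask <- mask | apply(matrix(mask[g$nn], g$n, 6), 1, any)
    ops <- point_group_ops()
    variants <- lapply(ops, function(op) transform_config(config, op))
    masks <- lapply(ops, function(op)
      transform_config(new_configuration(g, as.integer(mask)), op)$occ > 0L)
    q <- g$coords[, "q"]; r <- g$coords[, "r"]
    scores <- vapply(library, function(p) {
      best <- 0
      for (vi in seq_along(variants)) {
        occ <- variants[[vi]]$occ
        mk <- masks[[vi]]
        for (dq in 0:(p$w - 1)) for (dr in 0:(p$h - 1)) {
          pat <- motif_at(p, q - dq, r - dr)
          rel <- mk & (occ > 0L | pat > 0L)
          denom <- sum(rel)
          if (denom == 0) next
          sc <- sum(occ[rel] == pat[rel]) / denom
          if (sc > best) best <- sc
        }
      }
      best
    }, 0)
  }
  out <- data.frame(label = vapply(library, `[[`, "", "label"),
                    score = scores, row.names = NULL)
  out[order(-out$score), ]
}
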