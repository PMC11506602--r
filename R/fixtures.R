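#' @title Deterministic test-configuration generators
#' @description Generators for the configurations used throughout the test
#'   suite and examples: tiled library patterns, isolated motifs, exact-count
#'   random mixtures and defected patterns.  All output is deterministic for
#'   a fixed specification and seed.
#' @name fixtures
NULL

#' Specify a fixture
#'
#' @param kind one of \code{"pattern-tile"}, \code{"isolated-motif"},
#'   \code{"random"}, \code{"defected-pattern"}.
#' @param label pattern label (pattern-tile / defected-pattern kinds).
#' @param motif motif name for isolated-motif: \code{"flower"},
#'   \code{"rhomb"}, \code{"dimer"} or \code{"single"}.
#' @param L lattice linear size.
#' @param species species of an isolated motif (default 1).
#' @param c1,c2 target concentrations for the random kind; exact counts
#'   \code{round(ci*L^2)} are placed by shuffling a fixed multiset.
#' @param defect_rate Bernoulli rate at which occupied sites of a defected
#'   pattern are emptied.
#' @param seed integer seed.
#' @return an object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(kind, label = NULL, motif = NULL, L = 12, species = 1,
                         c1 = 0.05, c2 = 0.05, defect_rate = 0.05, seed = 1) {
  kind <- match.arg(kind, c("pattern-tile", "isolated-motif", "random",
                            "defected-pattern"))
  structure(list(kind = kind, label = label, motif = motif, L = as.integer(L),
                 species = as.integer(species), c1 = c1, c2 = c2,
                 defect_rate = defect_rate, seed = seed),
            class = "fixture_spec")
}

# axial offsets of the isolated motifs
motif_offsets <- function(name) {
  switch(name,
         flower = rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                        c(1, -1), c(-1, 1)),
         rhomb = rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 1)),
         dimer = rbind(c(0, 0), c(1, 0)),
         single = rbind(c(0, 0)),
         stop("unknown motif '", name, "'"))
}

#' Build a fixture configuration
#'
#' @param spec a \code{fixture_spec}.
#' @param params a \code{model_params} (for pattern lookups).
#' @return a \code{lattice_config}.
#' @examples
#' cfg <- make_fixture(fixture_spec("isolated-motif", motif = "flower", L = 12))
#' total_energy(cfg)  # -12 + 3*J
#' @export
make_fixture <- function(spec, params = model_params()) {
  g <- build_geometry(spec$L)
  switch(spec$kind,
    "pattern-tile" = {
      lib <- pattern_library(params)
      if (!spec$label %in% names(lib)) stop("unknown pattern '", spec$label, "'")
      tile_pattern(lib[[spec$label]], g)
    },
    "isolated-motif" = {
      off <- motif_offsets(spec$motif)
      ctr <- floor(spec$L / 2)
      occ <- integer(g$n)
      occ[site_index(spec$L, ctr + off[, 1], ctr + off[, 2])] <- spec$species
      new_configuration(g, occ)
    },
    "random" = {
      N1 <- round(spec$c1 * g$n)
      N2 <- round(spec$c2 * g$n)
      if (N1 + N2 > g$n) stop("requested concentrations overfill the lattice")
      occ <- with_seed(spec$seed,
                       sample(c(rep(1L, N1), rep(2L, N2),
                                rep(0L, g$n - N1 - N2))))
      new_configuration(g, occ)
    },
    "defected-pattern" = {
      lib <- pattern_library(params)
      if (!spec$label %in% names(lib)) stop("unknown pattern '", spec$label, "'")
      cfg <- tile_pattern(lib[[spec$label]], g)
      flips <- with_seed(spec$seed,
                         stats::runif(g$n) < spec$defect_rate)
      cfg$occ[flips] <- 0L
      cfg
    })
}
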