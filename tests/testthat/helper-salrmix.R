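# shared objects for the suite
params_default <- model_params()       # J = 3/4
lib_default <- pattern_library(params_default)

# brute-force shells by minimal-image Euclidean distance (independent oracle
# for the neighbour tables)
brute_shells <- function(L) {
  g <- build_geometry(L)
  pos <- site_positions(g)
  # periodic images: lattice vectors L*a1, L*a2
  shifts <- expand.grid(i = -1:1, j = -1:1)
  img <- function(p) {
    cbind(p[, 1] + shifts$i * L + shifts$j * L / 2,
          p[, 2] + shifts$j * L * sqrt(3) / 2)
  }
  nn <- vector("list", g$n); third <- vector("list", g$n)
  for (x in seq_len(g$n)) {
    d2min <- rep(Inf, g$n)
    for (k in seq_len(nrow(shifts))) {
      dx <- pos[, 1] - (pos[x, 1] + shifts$i[k] * L + shifts$j[k] * L / 2)
      dy <- pos[, 2] - (pos[x, 2] + shifts$j[k] * L * sqrt(3) / 2)
      d2min <- pmin(d2min, dx^2 + dy^2)
    }
    nn[[x]] <- which(abs(d2min - 1) < 1e-9)
    third[[x]] <- which(abs(d2min - 4) < 1e-9)
  }
  list(nn = nn, third = third)
}

# energy-class chi-square helper: observed counts vs exact probabilities
chisq_stat <- function(obs, p) {
  n <- sum(obs)
  keep <- n * p >= 5
  sum((obs[keep] - n * p[keep])^2 / (n * p[keep]))
}
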