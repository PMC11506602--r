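#' @title Snapshot and observable file formats
#' @description Plain-text, line-oriented, versioned formats: snapshots list
#'   one occupied site per line as \code{q r species} (0-based axial
#'   coordinates, sorted by (q, r) for byte-stable output) under a commented
#'   metadata header; observables are written as CSV with a commented
#'   metadata preamble echoing the full run parameters and seed.
#' @name cli_io
NULL

SNAPSHOT_FORMAT <- "salrmix-snapshot 1"

#' Write a configuration snapshot
#'
#' @param config a \code{lattice_config}.
#' @param metadata named list/vector of scalar metadata (J, T_star, mu1, ...);
#'   \code{L} is always recorded.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_snapshot <- function(config, metadata = list(), path) {
  g <- config$geometry
  meta <- c(list(L = g$L), metadata)
  lines <- c(paste0("# ", SNAPSHOT_FORMAT),
             paste0("# ", names(meta), "=",
                    vapply(meta, function(v) format(v, digits = 15), "")),
             "# q r species")
  idx <- which(config$occ != 0L)
  if (length(idx)) {
    q <- g$coords[idx, "q"]
    r <- g$coords[idx, "r"]
    o <- order(q, r)
    lines <- c(lines, paste(q[o], r[o], config$occ[idx][o]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration snapshot
#'
#' Exact inverse of [write_snapshot()]; malformed input (unknown version,
#' out-of-range coordinates, duplicate sites, truncated records) raises a
#' parse error naming the offending line.
#'
#' @param path file path.
#' @return a list with \code{config} (a \code{lattice_config}) and
#'   \code{metadata} (named character vector).
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !identical(lines[1], paste0("# ", SNAPSHOT_FORMAT)))
    stop("line 1: not a '", SNAPSHOT_FORMAT, "' file")
  is_meta <- startsWith(lines, "#")
  body_start <- match(FALSE, is_meta, nomatch = length(lines) + 1L)
  meta_lines <- grep("^# [^ ]+=", lines[seq_len(body_start - 1L)], value = TRUE)
  kv <- sub("^# ", "", meta_lines)
  metadata <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  if (!"L" %in% names(metadata)) stop("header does not declare L")
  L <- as.integer(metadata[["L"]])
  g <- build_geometry(L)
  occ <- integer(g$n)
  if (body_start <= length(lines)) {
    for (i in body_start:length(lines)) {
      if (lines[i] == "") next
      f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
      if (length(f) != 3 || anyNA(suppressWarnings(as.integer(f))))
        stop("line ", i, ": expected 'q r species'")
      f <- as.integer(f)
      if (f[1] < 0 || f[1] >= L || f[2] < 0 || f[2] >= L)
        stop("line ", i, ": coordinate out of range for L = ", L)
      if (!f[3] %in% 1:2)
        stop("line ", i, ": species must be 1 or 2")
      s <- f[1] + L * f[2] + 1L
      if (occ[s] != 0L) stop("line ", i, ": duplicate site (", f[1], ",", f[2], ")")
      occ[s] <- f[3]
    }
  }
  list(config = new_configuration(g, occ), metadata = metadata)
}

#' Write an isotherm (or any observable table) as CSV with metadata preamble
#'
#' @param df a data.frame.
#' @param metadata named list echoed as commented \code{key=value} lines.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_observables_csv <- function(df, metadata = list(), path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# salrmix-observables 1",
               paste0("# ", names(metadata), "=",
                      vapply(metadata, function(v) format(v, digits = 15), ""))),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read an observables CSV written by [write_observables_csv()]
#'
#' @param path file path.
#' @return a list with \code{data} (data.frame) and \code{metadata}.
#' @export
read_observables_csv <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  kv <- sub("^# ", "", lines[is_meta][-1])
  kv <- kv[grepl("=", kv)]
  metadata <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  list(data = df, metadata = metadata)
}
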