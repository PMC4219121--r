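#' Load a probe-to-gene annotation map
#'
#' Reads a headerless two-column tab-separated file, `probe_id<TAB>entrez_id`,
#' with one line per (probe, gene) pair; a probe hybridizing k genes appears
#' on k lines. Gene lists are deduplicated per probe.
#'
#' @param path Path to the map file.
#'
#' @return A named list (class `survpool_probe_map`): probe id -> character
#'   vector of Entrez gene ids.
#' @export
load_probe_map <- function(path) {
  df <- readr::read_tsv(
    path,
    col_names = c("probe_id", "entrez_id"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (any(is.na(df$probe_id) | df$probe_id == "")) {
    abort(sprintf("'%s': empty probe id at line %d.", path, which(is.na(df$probe_id) | df$probe_id == "")[1L]))
  }
  entries <- lapply(split(df$entrez_id, df$probe_id), function(g) unique(g[!is.na(g) & g != ""]))
  probe_map(entries)
}

#' Construct a probe-to-gene map from a named list
#'
#' @param entries Named list: probe id -> character vector of Entrez gene ids
#'   (possibly empty).
#'
#' @return An object of class `survpool_probe_map`.
#' @export
probe_map <- function(entries) {
  if (is.null(names(entries)) && length(entries) > 0L) {
    abort("`entries` must be a named list keyed by probe id.")
  }
  if (anyDuplicated(names(entries))) {
    abort(sprintf("Duplicate probe id '%s' in map.", names(entries)[duplicated(names(entries))][1L]))
  }
  entries <- lapply(entries, function(g) unique(as.character(g)))
  structure(entries, class = "survpool_probe_map")
}

#' Drop probes mapping to zero or multiple genes
#'
#' Probes that map to more than one Entrez gene are ambiguous at the gene
#' level and are filtered out before collapsing; probes with no gene are
#' dropped as unannotated. Removal counts are reported via a message.
#'
#' @param map A `survpool_probe_map`.
#'
#' @return A `survpool_probe_map` in which every probe maps to exactly one gene.
#' @export
filter_multimapping <- function(map) {
  if (!inherits(map, "survpool_probe_map")) map <- probe_map(map)
  k <- lengths(map)
  n_multi <- sum(k > 1L)
  n_none <- sum(k == 0L)
  if (n_multi + n_none > 0L) {
    inform(sprintf(
      "Filtered %d multi-mapping and %d unannotated probe(s); %d single-gene probe(s) kept.",
      n_multi, n_none, sum(k == 1L)
    ))
  }
  probe_map(unclass(map)[k == 1L])
}

#' Collapse a probe-level matrix to Entrez genes
#'
#' Rows are re-keyed from probes to Entrez gene ids using a (single-gene)
#' probe map; where several probes measure the same gene their values are
#' averaged arithmetically per sample on the log scale, ignoring missing
#' values. Probes absent from the map are dropped.
#'
#' @param expr Probe-level numeric matrix (probes x samples).
#' @param map A `survpool_probe_map`, already passed through
#'   [filter_multimapping()] (enforced).
#'
#' @return A numeric matrix keyed by Entrez gene id.
#' @export
collapse_to_genes <- function(expr, map) {
  stopifnot_expression_matrix(expr)
  if (!inherits(map, "survpool_probe_map")) map <- probe_map(map)
  if (any(lengths(map) != 1L)) {
    abort("`map` contains multi-mapping or unannotated probes; run filter_multimapping() first.")
  }
  probes <- intersect(rownames(expr), names(map))
  if (length(probes) == 0L) {
    abort("No overlap between expression matrix rows and the probe map.")
  }
  vals <- expr[probes, , drop = FALSE]
  genes <- vapply(unclass(map)[probes], identity, character(1L))
  obs <- !is.na(vals)
  vals0 <- vals
  vals0[!obs] <- 0
  sums <- rowsum(vals0, genes)
  counts <- rowsum(obs + 0, genes)
  out <- sums / counts
  out[counts == 0] <- NA_real_
  stopifnot_expression_matrix(out, "collapsed")
  out
}

#' Quantile normalize an expression matrix
#'
#' Makes every column share the same empirical distribution: the reference
#' is the row-wise mean of the sorted columns, and each column's values are
#' replaced by the reference values at their rank positions. Ties within a
#' column receive the mean of the reference values spanning their tied
#' ranks. Missing entries are excluded from ranking (ranks interpolated on
#' the quantile scale) and restored as missing.
#'
#' @param expr Numeric matrix (features x samples).
#'
#' @return The normalized matrix; single-column input is returned unchanged
#'   with a warning.
#' @export
quantile_normalize <- function(expr) {
  stopifnot_expression_matrix(expr)
  n <- nrow(expr)
  p <- ncol(expr)
  if (p == 1L) {
    warn("quantile_normalize(): single-column matrix returned unchanged.")
    return(expr)
  }
  if (n == 1L) {
    out <- expr
    out[1L, ] <- mean(expr[1L, ], na.rm = TRUE)
    out[is.na(expr)] <- NA_real_
    return(out)
  }
  grid_n <- seq(0, 1, length.out = n)
  sorted <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    v <- sort(expr[, j])
    m <- length(v)
    if (m < 2L) {
      abort(sprintf("quantile_normalize(): column %d has fewer than 2 non-missing values.", j))
    }
    sorted[, j] <- if (m == n) v else approx(seq(0, 1, length.out = m), v, xout = grid_n)$y
  }
  ref <- rowMeans(sorted)
  out <- expr
  for (j in seq_len(p)) {
    idx <- which(!is.na(expr[, j]))
    v <- expr[idx, j]
    m <- length(v)
    refj <- if (m == n) ref else approx(grid_n, ref, xout = seq(0, 1, length.out = m))$y
    first <- rank(v, ties.method = "min")
    last <- rank(v, ties.method = "max")
    cs <- c(0, cumsum(sort(refj)))
    out[idx, j] <- (cs[last + 1L] - cs[first]) / (last - first + 1L)
  }
  out
}
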