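#' Load a miRNA-to-host-gene map
#'
#' Reads a headerless tab-separated file,
#' `mirna<TAB>entrez_id[<TAB>status]`, mapping each (typically intronic)
#' miRNA to the Entrez id of its host gene. The optional third column is
#' the surrogacy vetting status (`correlated`, `not_correlated`,
#' `unknown`); it defaults to `unknown`.
#'
#' @param path Path to the map file.
#'
#' @return A tibble (class `survpool_mirna_map`) with columns `mirna`,
#'   `host_gene`, `status`.
#' @export
load_mirna_host_map <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  mirna <- character(length(fields))
  host <- character(length(fields))
  status <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 2L) abort(sprintf("'%s': line %d has fewer than 2 fields.", path, i))
    mirna[i] <- trimws(f[1L])
    host[i] <- trimws(f[2L])
    status[i] <- if (length(f) >= 3L && nzchar(trimws(f[3L]))) trimws(f[3L]) else "unknown"
    if (!grepl("^[0-9]+$", host[i])) {
      abort(sprintf("'%s': malformed Entrez id '%s' at line %d.", path, host[i], i))
    }
    if (!status[i] %in% c("correlated", "not_correlated", "unknown")) {
      abort(sprintf("'%s': unknown vetting status '%s' at line %d.", path, status[i], i))
    }
  }
  if (anyDuplicated(mirna)) {
    at <- which(duplicated(mirna))[1L]
    abort(sprintf("'%s': duplicate miRNA '%s' at line %d.", path, mirna[at], at))
  }
  structure(
    tibble(mirna = mirna, host_gene = host, status = status),
    class = c("survpool_mirna_map", class(tibble()))
  )
}

#' Query a miRNA through its host gene
#'
#' A miRNA not measured directly on the arrays is queried via its host
#' gene's expression as a surrogate. The result is numerically identical to
#' [pooled_query()] on the host gene; it additionally carries the miRNA
#' name, host gene, vetting status, and a caution flag whenever the
#' surrogacy has not been vetted as `correlated`.
#'
#' @param comp A `survpool_compendium`.
#' @param mirna miRNA name (miRBase-style).
#' @param map A `survpool_mirna_map` from [load_mirna_host_map()].
#' @param spec A `survpool_query`; its `genes` field is replaced by the
#'   host gene. Defaults to a median-cutoff OS query.
#'
#' @return A `survpool_result` with extra fields `mirna`, `host_gene`,
#'   `vetting_status`, `caution`.
#' @export
mirna_query <- function(comp, mirna, map, spec = NULL) {
  if (!inherits(map, "survpool_mirna_map")) abort("`map` must come from load_mirna_host_map().")
  hit <- match(mirna, map$mirna)
  if (is.na(hit)) {
    d <- adist(mirna, map$mirna, ignore.case = TRUE)
    near <- map$mirna[order(d)][seq_len(min(3L, nrow(map)))]
    abort(sprintf(
      "miRNA '%s' is not in the host-gene map. Nearest names: %s.",
      mirna, paste(near, collapse = ", ")
    ))
  }
  host <- map$host_gene[hit]
  status <- map$status[hit]
  if (is.null(spec)) {
    spec <- query_spec(host)
  } else {
    spec$genes <- host
  }
  res <- pooled_query(comp, spec)
  res$mirna <- mirna
  res$host_gene <- host
  res$vetting_status <- status
  res$caution <- status != "correlated"
  if (res$caution) {
    inform(sprintf(
      "miRNA '%s': host-gene surrogacy is '%s'; interpret with caution.",
      mirna, status
    ))
  }
  res
}

#' Vet miRNA host-gene surrogates against direct miRNA measurements
#'
#' For every mapped miRNA present in both matrices, correlates the host
#' gene's expression with the directly measured miRNA expression over the
#' shared samples (Spearman by default, robust across platform scales),
#' adjusts the correlation p-values across all vetted pairs by
#' Benjamini-Hochberg, and labels a pair `correlated` when the adjusted p
#' falls below `alpha` with a positive correlation (a negative correlation
#' would invalidate the surrogate's direction).
#'
#' @param host_expr Gene-level expression matrix (Entrez ids x samples).
#' @param mirna_expr Direct miRNA expression matrix (miRNA names x samples).
#' @param map A `survpool_mirna_map`.
#' @param alpha Adjusted-p threshold for `correlated` (default 0.05).
#' @param method `"spearman"` (default) or `"pearson"`.
#'
#' @return A tibble (class `survpool_vetting`) with columns `mirna`,
#'   `host_gene`, `correlation`, `p_raw`, `p_adjusted`, `status`, and
#'   attribute `fraction_correlated`.
#' @export
vet_surrogates <- function(host_expr, mirna_expr, map, alpha = 0.05,
                           method = c("spearman", "pearson")) {
  method <- rlang::arg_match(method)
  stopifnot_expression_matrix(host_expr, "host_expr")
  stopifnot_expression_matrix(mirna_expr, "mirna_expr")
  if (!inherits(map, "survpool_mirna_map")) abort("`map` must come from load_mirna_host_map().")
  shared <- intersect(colnames(host_expr), colnames(mirna_expr))
  if (length(shared) < 10L) {
    abort(sprintf("Only %d shared sample(s); at least 10 required for vetting.", length(shared)))
  }
  pairs <- map[map$mirna %in% rownames(mirna_expr) & map$host_gene %in% rownames(host_expr), ]
  if (nrow(pairs) == 0L) abort("No mapped miRNA is present in both matrices.")
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    h <- host_expr[pairs$host_gene[i], shared]
    m <- mirna_expr[pairs$mirna[i], shared]
    ok <- !is.na(h) & !is.na(m)
    ct <- suppressWarnings(cor.test(h[ok], m[ok], method = method))
    tibble(
      mirna = pairs$mirna[i], host_gene = pairs$host_gene[i],
      correlation = unname(ct$estimate), p_raw = ct$p.value
    )
  })
  res$p_adjusted <- bh_adjust(res$p_raw)
  res$status <- ifelse(res$p_adjusted < alpha & res$correlation > 0,
                       "correlated", "not_correlated")
  frac <- mean(res$status == "correlated")
  structure(
    res,
    fraction_correlated = frac,
    class = c("survpool_vetting", class(res))
  )
}

#' @export
print.survpool_vetting <- function(x, ...) {
  cat(sprintf(
    "<survpool_vetting> %d pair(s); %.1f%% vetted as correlated\n",
    nrow(x), 100 * attr(x, "fraction_correlated")
  ))
  NextMethod()
}
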