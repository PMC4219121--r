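#' Tidy a pooled survival result
#'
#' One row for the high-versus-low group term, in broom's column
#' conventions.
#'
#' @param x A `survpool_result`.
#' @param exponentiate Report the estimate and confidence bounds on the
#'   hazard-ratio scale (default `TRUE`) rather than the log scale.
#' @param ... Unused.
#'
#' @return A one-row tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy survpool_result
#' @export
tidy.survpool_result <- function(x, exponentiate = TRUE, ...) {
  est <- if (exponentiate) x$hr else x$beta
  lo <- if (exponentiate) x$hr_ci_low else log(x$hr_ci_low)
  hi <- if (exponentiate) x$hr_ci_high else log(x$hr_ci_high)
  tibble(
    term = "group_high",
    estimate = est,
    std.error = x$se,
    statistic = if (is.finite(x$se)) x$beta / x$se else NA_real_,
    p.value = x$wald_p,
    conf.low = lo,
    conf.high = hi
  )
}

#' Model-level summary of a pooled survival result
#'
#' @param x A `survpool_result`.
#' @param ... Unused.
#'
#' @return A one-row tibble: pooled sample counts, event count, number of
#'   contributing datasets, hazard ratio and log-rank test.
#' @method glance survpool_result
#' @export
glance.survpool_result <- function(x, ...) {
  tibble(
    genes = paste(x$genes, collapse = "+"),
    endpoint = x$endpoint,
    cutoff = x$cutoff_method,
    n = x$n, n_high = x$n_high, n_low = x$n_low, n_events = x$n_events,
    n_datasets = nrow(x$datasets),
    hr = x$hr, hr_ci_low = x$hr_ci_low, hr_ci_high = x$hr_ci_high,
    logrank_chisq = x$logrank_chisq, logrank_p = x$logrank_p,
    flagged = x$flagged
  )
}

#' Export a pooled survival result as a JSON record
#'
#' @param x A `survpool_result`.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  if (!inherits(x, "survpool_result")) abort("`x` must be a survpool_result.")
  rec <- list(
    genes = x$genes, endpoint = x$endpoint, cutoff = x$cutoff_method,
    extremes_only = x$extremes_only,
    hr = x$hr, hr_ci_low = x$hr_ci_low, hr_ci_high = x$hr_ci_high,
    logrank_p = x$logrank_p, wald_p = x$wald_p,
    n = x$n, n_high = x$n_high, n_low = x$n_low, n_events = x$n_events,
    datasets = lapply(seq_len(nrow(x$datasets)), function(i) {
      list(
        dataset_id = x$datasets$dataset_id[i], n = x$datasets$n[i],
        n_high = x$datasets$n_high[i], n_low = x$datasets$n_low[i]
      )
    })
  )
  if (!is.null(x$mirna)) {
    rec$mirna <- x$mirna
    rec$host_gene <- x$host_gene
    rec$vetting_status <- x$vetting_status
    rec$caution <- x$caution
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a screen table as tab-separated text
#'
#' Columns mirror the screen's reporting layout: gene, hazard ratio, raw
#' and adjusted p-values, pooled sample count, concordance index and its
#' empirical permutation p-value.
#'
#' @param x A `survpool_screen` tibble.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, na = "NA", progress = FALSE)
  invisible(path)
}
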