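#' Kaplan-Meier product-limit estimate
#'
#' @param times Positive follow-up times (months).
#' @param events Event indicators (1 = event, 0 = censored).
#'
#' @return A tibble with one row per distinct event time: `time`, `n_risk`,
#'   `n_event`, `survival`. With no events the tibble has zero rows (the
#'   estimated survival function is identically 1).
#' @export
km_estimate <- function(times, events) {
  check_surv_input(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1, conf.type = "none")
  keep <- fit$n.event > 0
  tibble(
    time = fit$time[keep],
    n_risk = as.integer(fit$n.risk[keep]),
    n_event = as.integer(fit$n.event[keep]),
    survival = fit$surv[keep]
  )
}

check_surv_input <- function(times, events) {
  if (length(times) == 0L) abort("Empty survival input.")
  if (length(times) != length(events)) abort("`times` and `events` must have equal length.")
  if (any(is.na(times)) || any(is.na(events))) abort("Survival input contains missing values.")
  if (any(times <= 0) || any(!is.finite(times))) abort("Times must be finite and positive.")
  if (!all(events %in% c(0, 1))) abort("Events must be coded 0/1.")
  invisible(NULL)
}

#' Two-group log-rank test
#'
#' @param data Data frame with columns `time`, `event` and `group`
#'   (`"high"`/`"low"`).
#'
#' @return A list with `chisq`, `df` (always 1) and `p` (two-sided, from the
#'   chi-square distribution with 1 df).
#' @export
logrank_test <- function(data) {
  check_group_data(data)
  if (sum(data$event) < 1) abort("Log-rank test requires at least one event.")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = data)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, df = 1L, p = pchisq(chisq, df = 1L, lower.tail = FALSE))
}

check_group_data <- function(data) {
  if (!all(c("time", "event", "group") %in% names(data))) {
    abort("`data` must have columns time, event, group.")
  }
  check_surv_input(data$time, data$event)
  for (g in c("high", "low")) {
    if (!any(data$group == g)) abort(sprintf("Group '%s' is empty.", g))
  }
  invisible(NULL)
}

# Efron partial-likelihood pieces for a single binary covariate
# (x = 1 for the high group), optionally summed over strata. Returns the
# log partial likelihood, score U and information I at `beta`.
efron_pieces <- function(beta, strata_data) {
  r <- exp(beta)
  ll <- 0
  U <- 0
  I <- 0
  for (sd in strata_data) {
    A <- sd$n0R + r * sd$n1R # sum of exp(beta*x) over the risk set
    B <- sd$d0 + r * sd$d1 # ... over the deaths at this time
    den <- A[sd$j] - sd$frac * B[sd$j]
    num <- r * (sd$n1R[sd$j] - sd$frac * sd$d1[sd$j])
    m <- num / den
    ll <- ll + beta * sum(sd$d1) - sum(log(den))
    U <- U + sum(sd$d1) - sum(m)
    I <- I + sum(m - m^2)
  }
  list(ll = ll, U = U, I = I)
}

prepare_strata <- function(time, event, x) {
  o <- order(time)
  t <- time[o]
  e <- event[o]
  xx <- x[o]
  # counts per distinct time, ascending
  agg <- rowsum(cbind(d = e, d1 = e * xx), group = t)
  ut <- sort(unique(t))
  ev <- agg[, "d"] > 0
  if (!any(ev)) return(NULL)
  d <- agg[ev, "d"]
  d1 <- agg[ev, "d1"]
  ev_t <- ut[ev]
  first_idx <- match(ev_t, t)
  n <- length(t)
  suffix_high <- rev(cumsum(rev(xx)))
  n1R <- suffix_high[first_idx]
  nR <- n - first_idx + 1
  # expand the Efron inner sum: event time j repeated d_j times, l = 0..d_j-1
  j <- rep(seq_along(ev_t), d)
  frac <- (sequence(d) - 1) / rep(d, d)
  list(
    d0 = d - d1, d1 = d1, n1R = n1R, n0R = nR - n1R,
    j = j, frac = frac
  )
}

#' Cox hazard ratio for a binary high/low grouping
#'
#' Maximizes the Efron-tie-corrected partial likelihood for the single
#' group coefficient by Newton-Raphson (tolerance 1e-9 on the step, at most
#' 50 iterations) and reports `hr = exp(beta)` with a 95% Wald confidence
#' interval. With `stratified = TRUE` each dataset keeps its own baseline
#' hazard (score and information are summed over strata). A monotone
#' likelihood (complete separation of event orderings) is flagged rather
#' than raised: the estimate diverges and the confidence interval is
#' reported as infinite.
#'
#' @param data Data frame with columns `time`, `event`, `group` and (if
#'   `stratified`) `dataset_id`.
#' @param stratified Logical; stratify the baseline hazard by dataset.
#'
#' @return A list: `hr`, `hr_ci_low`, `hr_ci_high`, `beta`, `se`, `wald_p`,
#'   `flagged`, `converged`, `iterations`.
#' @export
cox_binary <- function(data, stratified = FALSE) {
  check_group_data(data)
  if (sum(data$event) < 2) abort("Cox estimation requires at least two events.")
  x <- as.numeric(data$group == "high")
  if (stratified) {
    if (!"dataset_id" %in% names(data)) abort("Stratified Cox requires a dataset_id column.")
    parts <- split(seq_len(nrow(data)), data$dataset_id)
  } else {
    parts <- list(seq_len(nrow(data)))
  }
  strata_data <- purrr::compact(lapply(parts, function(idx) {
    prepare_strata(data$time[idx], data$event[idx], x[idx])
  }))
  if (length(strata_data) == 0L) abort("No events available for Cox estimation.")

  beta <- 0
  flagged <- FALSE
  converged <- FALSE
  iter <- 0L
  pieces <- efron_pieces(beta, strata_data)
  while (iter < 50L) {
    iter <- iter + 1L
    if (pieces$I <= 0) {
      flagged <- TRUE
      break
    }
    step <- pieces$U / pieces$I
    # step-halving to keep the log partial likelihood non-decreasing
    new_beta <- beta + step
    new_pieces <- efron_pieces(new_beta, strata_data)
    h <- 0L
    while (is.na(new_pieces$ll) || new_pieces$ll < pieces$ll - 1e-12) {
      h <- h + 1L
      if (h > 30L) break
      step <- step / 2
      new_beta <- beta + step
      new_pieces <- efron_pieces(new_beta, strata_data)
    }
    beta <- new_beta
    pieces <- new_pieces
    if (abs(beta) > 15) {
      flagged <- TRUE
      break
    }
    if (abs(step) < 1e-9) {
      converged <- TRUE
      break
    }
  }
  if (flagged) {
    hr <- exp(beta)
    return(list(
      hr = hr, hr_ci_low = 0, hr_ci_high = Inf, beta = beta, se = Inf,
      wald_p = NA_real_, flagged = TRUE, converged = FALSE, iterations = iter
    ))
  }
  se <- 1 / sqrt(pieces$I)
  z <- qnorm(0.975)
  list(
    hr = exp(beta),
    hr_ci_low = exp(beta - z * se),
    hr_ci_high = exp(beta + z * se),
    beta = beta, se = se,
    wald_p = 2 * pnorm(-abs(beta / se)),
    flagged = FALSE, converged = converged, iterations = iter
  )
}

#' Specify a pooled survival query
#'
#' A query specification fully determines a pooled analysis: the gene list
#' (one gene, or several combined as all-high-versus-rest), the per-dataset
#' cutoff method, the survival endpoint, and optional clinical filters.
#'
#' @param genes Character vector of Entrez gene ids (length >= 1).
#' @param cutoff Cutoff method, see [compute_cutoff()].
#' @param extremes_only Logical; see [assign_groups()].
#' @param endpoint `"OS"` or `"DFS"`.
#' @param filters A `survpool_filter` from [clinical_filter()].
#' @param stratified Logical; dataset-stratified Cox baseline (sensitivity
#'   option; the default pools all samples into a single Cox model).
#'
#' @return An object of class `survpool_query`.
#' @export
query_spec <- function(genes, cutoff = "median", extremes_only = FALSE,
                       endpoint = c("OS", "DFS"), filters = clinical_filter(),
                       stratified = FALSE) {
  if (!is.character(genes) || length(genes) < 1L) abort("`genes` must be >= 1 gene id.")
  structure(
    list(
      genes = genes,
      cutoff = rlang::arg_match(cutoff, cutoff_methods()),
      extremes_only = isTRUE(extremes_only),
      endpoint = rlang::arg_match(endpoint),
      filters = filters,
      stratified = isTRUE(stratified)
    ),
    class = "survpool_query"
  )
}

# Per-cohort stage of a pooled query: clinical filter -> endpoint
# restriction -> per-gene cutoffs/assignment -> (optional) all-high
# combination. Returns NULL when the cohort contributes nothing.
cohort_contribution <- function(cohort, spec) {
  co <- filter_samples(cohort, spec$filters)
  if (n_samples(co) == 0L) return(NULL)
  tcol <- if (spec$endpoint == "OS") "os_time" else "dfs_time"
  ecol <- if (spec$endpoint == "OS") "os_event" else "dfs_event"
  usable <- !is.na(co$clinical[[tcol]]) & !is.na(co$clinical[[ecol]]) &
    co$clinical[[tcol]] > 0
  if (!any(usable)) return(NULL)
  out <- co
  out$expression <- co$expression[, usable, drop = FALSE]
  out$clinical <- co$clinical[usable, , drop = FALSE]
  assignments <- lapply(spec$genes, function(g) {
    assign_groups(out, g, method = spec$cutoff, extremes_only = spec$extremes_only)
  })
  if (any(vapply(assignments, nrow, integer(1L)) == 0L)) return(NULL)
  asg <- if (length(assignments) == 1L) assignments[[1L]] else combine_all_high(assignments)
  keep <- asg$group %in% c("high", "low")
  if (!any(keep)) return(NULL)
  idx <- match(asg$sample_id[keep], out$clinical$sample_id)
  list(
    samples = tibble(
      sample_id = asg$sample_id[keep],
      dataset_id = cohort$dataset_id,
      time = out$clinical[[tcol]][idx],
      event = out$clinical[[ecol]][idx],
      group = asg$group[keep]
    ),
    cutoffs = attr(asg, "cutoffs")
  )
}

#' Run a pooled high-versus-low survival query over a compendium
#'
#' The engine behind every query: each cohort is clinically filtered,
#' restricted to samples with the chosen endpoint, and dichotomized at its
#' own cutoff (per dataset, so platform-specific expression scales never
#' mix); the labelled samples are then pooled and analysed jointly with
#' Kaplan-Meier curves per group, a log-rank test, and a Cox hazard ratio
#' (high versus low, Efron ties).
#'
#' @param comp A `survpool_compendium`.
#' @param spec A `survpool_query` from [query_spec()].
#'
#' @return An object of class `survpool_result`; see [tidy.survpool_result()]
#'   and [autoplot.survpool_result()].
#' @export
pooled_query <- function(comp, spec) {
  if (!inherits(comp, "survpool_compendium")) abort("`comp` must be a survpool_compendium.")
  if (!inherits(spec, "survpool_query")) abort("`spec` must come from query_spec().")
  contribs <- purrr::compact(lapply(comp$cohorts, cohort_contribution, spec = spec))
  if (length(contribs) == 0L) {
    abort(sprintf(
      "No cohort contributes samples for gene(s) %s with endpoint %s under the given filters.",
      paste(spec$genes, collapse = "+"), spec$endpoint
    ))
  }
  pooled <- bind_rows(lapply(contribs, `[[`, "samples"))
  if (length(unique(pooled$group)) < 2L) {
    abort("Pooled data contain a single expression group; no comparison possible.")
  }
  lr <- logrank_test(pooled)
  cx <- cox_binary(pooled, stratified = spec$stratified)
  km <- bind_rows(lapply(c("high", "low"), function(g) {
    sub <- pooled[pooled$group == g, ]
    mutate(km_estimate(sub$time, sub$event), group = g, .before = 1L)
  }))
  per_dataset <- tibble(
    dataset_id = unname(vapply(contribs, function(x) x$samples$dataset_id[1L], character(1L))),
    n = unname(vapply(contribs, function(x) nrow(x$samples), integer(1L))),
    n_high = unname(vapply(contribs, function(x) sum(x$samples$group == "high"), integer(1L))),
    n_low = unname(vapply(contribs, function(x) sum(x$samples$group == "low"), integer(1L))),
    cutoff = unname(lapply(contribs, `[[`, "cutoffs"))
  )
  structure(
    list(
      genes = spec$genes,
      endpoint = spec$endpoint,
      cutoff_method = spec$cutoff,
      extremes_only = spec$extremes_only,
      stratified = spec$stratified,
      hr = cx$hr, hr_ci_low = cx$hr_ci_low, hr_ci_high = cx$hr_ci_high,
      beta = cx$beta, se = cx$se, wald_p = cx$wald_p, flagged = cx$flagged,
      logrank_chisq = lr$chisq, logrank_p = lr$p,
      n = nrow(pooled),
      n_high = sum(pooled$group == "high"),
      n_low = sum(pooled$group == "low"),
      n_events = sum(pooled$event),
      km = km,
      datasets = per_dataset,
      samples = pooled
    ),
    class = "survpool_result"
  )
}

#' @export
print.survpool_result <- function(x, ...) {
  cat(sprintf(
    "<survpool_result> %s, %s, %s cutoff%s\n",
    paste(x$genes, collapse = "+"), x$endpoint, x$cutoff_method,
    if (x$extremes_only) " (extremes only)" else ""
  ))
  if (!is.null(x$mirna)) {
    cat(sprintf(
      "  miRNA %s via host gene %s (vetting: %s)%s\n",
      x$mirna, x$host_gene, x$vetting_status,
      if (isTRUE(x$caution)) " - CAUTION: surrogacy not vetted as correlated" else ""
    ))
  }
  cat(sprintf(
    "  HR (high vs low) = %.3f [%.3f, %.3f], log-rank p = %.3g\n",
    x$hr, x$hr_ci_low, x$hr_ci_high, x$logrank_p
  ))
  cat(sprintf(
    "  n = %d (%d high / %d low), %d events, %d dataset(s)\n",
    x$n, x$n_high, x$n_low, x$n_events, nrow(x$datasets)
  ))
  invisible(x)
}
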