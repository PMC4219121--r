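#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector, returned in input order.
#'
#' @param pvalues Numeric vector with all values in `[0, 1]`.
#'
#' @return Adjusted p-values (same length and order).
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) abort("`pvalues` must be numeric.")
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

# Harrell concordance counts over usable pairs. A pair (i, j) is usable when
# sample i has an observed event and either t_i < t_j, or t_i == t_j with j
# censored (the event is then known to precede j's survival). Pairs tied on
# time with both events are not usable. Concordant: the event-bearing,
# shorter-surviving sample has the higher risk; risk ties count 1/2.
concordance_counts <- function(risk, times, events) {
  n <- length(risk)
  if (length(times) != n || length(events) != n) abort("Input lengths differ.")
  if (any(is.na(risk)) || any(is.na(times)) || any(is.na(events))) {
    abort("Concordance inputs must not contain missing values.")
  }
  t_i <- matrix(times, n, n)
  t_j <- matrix(times, n, n, byrow = TRUE)
  e_i <- matrix(events == 1, n, n)
  e_j <- matrix(events == 1, n, n, byrow = TRUE)
  usable <- e_i & (t_i < t_j | (t_i == t_j & !e_j))
  diag(usable) <- FALSE
  r_i <- matrix(risk, n, n)
  r_j <- matrix(risk, n, n, byrow = TRUE)
  concordant <- sum(usable & (r_i > r_j))
  tied <- sum(usable & (r_i == r_j))
  list(concordant = concordant, tied = tied, usable = sum(usable))
}

#' Harrell's concordance index
#'
#' Fraction of usable (orderable under censoring) sample pairs in which the
#' higher risk score goes with the shorter survival; tied risks count 1/2.
#' A value of 0.5 corresponds to random classification and 1 to perfect
#' discrimination.
#'
#' @param risk Numeric risk scores (higher = predicted worse outcome).
#' @param times Follow-up times.
#' @param events Event indicators (1/0).
#'
#' @return The concordance index in `[0, 1]`, with attribute `n_pairs`
#'   (number of usable pairs).
#' @export
concordance_index <- function(risk, times, events) {
  if (length(risk) < 2L) abort("Concordance requires at least 2 samples.")
  if (sum(events) < 1) abort("Concordance requires at least one event.")
  cc <- concordance_counts(risk, times, events)
  if (cc$usable == 0L) abort("No usable pairs for concordance.")
  structure((cc$concordant + 0.5 * cc$tied) / cc$usable, n_pairs = cc$usable)
}

# Per-dataset concordance combined as the usable-pair-weighted average.
# Expression scales are platform specific, so raw intensities are never
# compared across datasets; only within-dataset orderings contribute.
combined_concordance <- function(parts) {
  usable <- sum(vapply(parts, function(p) p$usable, numeric(1L)))
  if (usable == 0) return(NA_real_)
  conc <- sum(vapply(parts, function(p) p$concordant + 0.5 * p$tied, numeric(1L)))
  structure(conc / usable, n_pairs = usable)
}

#' Permutation-based empirical p-value for a concordance index
#'
#' Shuffles the survival information (time and event jointly) against the
#' risk scores `n_perm` times, recomputes the concordance index for each
#' shuffle, and reports the fraction of shuffles with a concordance greater
#' than or equal to the observed one. An observed fraction of zero is best
#' reported as `< 1/n_perm`; the add-one estimate `(r + 1) / (n_perm + 1)`
#' is attached as attribute `p_add_one`.
#'
#' @param c_true Observed concordance index.
#' @param risk,times,events As in [concordance_index()].
#' @param n_perm Number of shuffles (default 10000).
#' @param seed Mandatory RNG seed; the caller's RNG state is untouched.
#'
#' @return Empirical p-value `r / n_perm` with attributes `p_add_one`,
#'   `n_ge` and `n_perm`.
#' @export
empirical_p <- function(c_true, risk, times, events, n_perm = 10000, seed) {
  if (missing(seed)) abort("`seed` is required for empirical_p().")
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  n <- length(risk)
  with_seed(seed, {
    r_i <- matrix(risk, n, n)
    r_j <- matrix(risk, n, n, byrow = TRUE)
    gt <- r_i > r_j
    eq <- r_i == r_j
    diag(eq) <- FALSE
    count <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      pt <- times[perm]
      pe <- events[perm]
      t_i <- matrix(pt, n, n)
      t_j <- matrix(pt, n, n, byrow = TRUE)
      e_i <- matrix(pe == 1, n, n)
      e_j <- matrix(pe == 1, n, n, byrow = TRUE)
      usable <- e_i & (t_i < t_j | (t_i == t_j & !e_j))
      diag(usable) <- FALSE
      nu <- sum(usable)
      if (nu == 0L) next
      cb <- (sum(usable & gt) + 0.5 * sum(usable & eq)) / nu
      if (cb >= c_true - 1e-12) count <- count + 1L
    }
    structure(
      count / n_perm,
      p_add_one = (count + 1) / (n_perm + 1),
      n_ge = count, n_perm = n_perm
    )
  })
}

# Fast pooled log-rank chi-square via per-event-time hypergeometric
# tabulation on a pre-sorted pooled dataset; avoids a model-frame round
# trip per gene in the transcriptome-wide screen.
logrank_chisq_fast <- function(time, event, x) {
  st <- prepare_strata(time, event, x)
  if (is.null(st)) return(NA_real_)
  d <- st$d0 + st$d1
  nR <- st$n0R + st$n1R
  E1 <- d * st$n1R / nR
  V <- ifelse(nR > 1, d * (st$n1R / nR) * (st$n0R / nR) * (nR - d) / (nR - 1), 0)
  Vs <- sum(V)
  if (Vs <= 0) return(NA_real_)
  (sum(st$d1 - E1))^2 / Vs
}

#' Transcriptome-wide prognostic screen
#'
#' Runs the pooled high-versus-low analysis for every gene in the
#' compendium's gene universe, collects the hazard ratio and log-rank
#' p-value per gene, adjusts p-values across all tested genes by
#' Benjamini-Hochberg, and (optionally) computes a concordance index per
#' gene from its continuous expression. The concordance is computed within
#' each dataset and combined as the usable-pair-weighted average; for genes
#' with HR < 1 the risk orientation is flipped (risk = negated expression)
#' so that discrimination is reported orientation-free, with the direction
#' recorded. Genes for which the pooled analysis is impossible (absent,
#' single group, fewer than two events) are skipped and recorded in the
#' `skipped` attribute.
#'
#' @param comp A `survpool_compendium`.
#' @param endpoint `"OS"` or `"DFS"`.
#' @param cutoff Cutoff method, see [compute_cutoff()].
#' @param extremes_only Logical; see [assign_groups()].
#' @param p_source P-value entering the BH adjustment: `"logrank"`
#'   (default) or `"wald"`.
#' @param compute_c Logical; compute concordance indices (default `TRUE`).
#' @param c_mode `"per_dataset"` (default; platform-safe weighted
#'   combination) or `"pooled_rank"` (single concordance on pooled
#'   within-dataset ranks).
#' @param n_perm Number of survival shuffles for the empirical concordance
#'   p-value; 0 (default) skips it. Per-gene shuffle streams are derived
#'   from `seed` and a hash of the gene id, so results do not depend on
#'   screen order.
#' @param seed RNG seed, required when `n_perm > 0`.
#'
#' @return A tibble (class `survpool_screen`) with one row per tested gene:
#'   `gene`, `hr`, `hr_ci_low`, `hr_ci_high`, `logrank_p_raw`, `p_adjusted`,
#'   `n`, `c_index`, `c_direction`, `c_index_p_empirical`.
#' @export
screen_all_genes <- function(comp, endpoint = c("OS", "DFS"), cutoff = "median",
                             extremes_only = FALSE,
                             p_source = c("logrank", "wald"),
                             compute_c = TRUE,
                             c_mode = c("per_dataset", "pooled_rank"),
                             n_perm = 0, seed = NULL) {
  if (!inherits(comp, "survpool_compendium")) abort("`comp` must be a survpool_compendium.")
  endpoint <- rlang::arg_match(endpoint)
  cutoff <- rlang::arg_match(cutoff, cutoff_methods())
  p_source <- rlang::arg_match(p_source)
  c_mode <- rlang::arg_match(c_mode)
  if (n_perm > 0 && is.null(seed)) abort("`seed` is required when n_perm > 0.")

  tcol <- if (endpoint == "OS") "os_time" else "dfs_time"
  ecol <- if (endpoint == "OS") "os_event" else "dfs_event"
  # Pre-extract per-cohort survival data once; per gene only the grouping
  # changes.
  cohort_data <- purrr::compact(lapply(comp$cohorts, function(co) {
    usable <- !is.na(co$clinical[[tcol]]) & !is.na(co$clinical[[ecol]]) &
      co$clinical[[tcol]] > 0
    if (!any(usable)) return(NULL)
    list(
      dataset_id = co$dataset_id,
      expr = co$expression[, usable, drop = FALSE],
      time = co$clinical[[tcol]][usable],
      event = co$clinical[[ecol]][usable]
    )
  }))
  if (length(cohort_data) == 0L) {
    abort(sprintf("No cohort carries endpoint %s.", endpoint))
  }

  genes <- comp$gene_universe
  rows <- vector("list", length(genes))
  skipped <- character()
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    time <- numeric()
    event <- numeric()
    x <- numeric()
    c_parts <- list()
    risk_pooled <- numeric()
    for (cd in cohort_data) {
      if (!g %in% rownames(cd$expr)) next
      v <- cd$expr[g, ]
      cut <- suppressWarnings(compute_cutoff(v, cutoff))
      if (is.na(cut)) next
      if (extremes_only && cutoff %in% c("upper_quartile", "lower_quartile")) {
        q1 <- compute_cutoff(v, "lower_quartile")
        q3 <- compute_cutoff(v, "upper_quartile")
        grp <- ifelse(is.na(v), NA, ifelse(v > q3, 1, ifelse(v < q1, 0, NA)))
      } else if (cutoff == "lower_quartile") {
        grp <- ifelse(is.na(v), NA, as.numeric(v >= cut))
      } else {
        grp <- ifelse(is.na(v), NA, as.numeric(v > cut))
      }
      keep <- !is.na(grp)
      if (!any(keep)) next
      time <- c(time, cd$time[keep])
      event <- c(event, cd$event[keep])
      x <- c(x, grp[keep])
      if (compute_c) {
        ok <- !is.na(v)
        if (sum(ok) >= 2L && sum(cd$event[ok]) >= 1) {
          if (c_mode == "per_dataset") {
            c_parts[[length(c_parts) + 1L]] <-
              concordance_counts(v[ok], cd$time[ok], cd$event[ok])
          } else {
            risk_pooled <- c(risk_pooled, rank(v[ok]) / (sum(ok) + 1))
          }
        }
      }
    }
    if (length(time) == 0L || length(unique(x)) < 2L || sum(event) < 2) {
      skipped <- c(skipped, g)
      next
    }
    dat <- tibble(time = time, event = event, group = ifelse(x == 1, "high", "low"))
    chisq <- logrank_chisq_fast(time, event, x)
    if (is.na(chisq)) {
      skipped <- c(skipped, g)
      next
    }
    cx <- cox_binary(dat)
    if (cx$flagged) {
      skipped <- c(skipped, g)
      next
    }
    lr_p <- pchisq(chisq, df = 1L, lower.tail = FALSE)
    rows[[gi]] <- tibble(
      gene = g,
      hr = cx$hr, hr_ci_low = cx$hr_ci_low, hr_ci_high = cx$hr_ci_high,
      logrank_p_raw = lr_p, wald_p = cx$wald_p,
      n = length(time),
      c_index = NA_real_, c_direction = NA_character_,
      c_index_p_empirical = NA_real_,
      .gi = gi
    )
    if (compute_c) {
      cidx <- if (c_mode == "per_dataset") {
        combined_concordance(c_parts)
      } else if (length(risk_pooled) >= 2L) {
        tryCatch(as.numeric(concordance_index(risk_pooled, time, event)), error = function(e) NA_real_)
      } else {
        NA_real_
      }
      cidx <- as.numeric(cidx)
      if (!is.na(cidx)) {
        flip <- cx$hr < 1
        rows[[gi]]$c_index <- if (flip) 1 - cidx else cidx
        rows[[gi]]$c_direction <- if (flip) "protective" else "deleterious"
      }
    }
  }
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out) == 0L) {
    out <- tibble(
      gene = character(), hr = numeric(), hr_ci_low = numeric(),
      hr_ci_high = numeric(), logrank_p_raw = numeric(), wald_p = numeric(),
      n = integer(), c_index = numeric(), c_direction = character(),
      c_index_p_empirical = numeric(), .gi = integer()
    )
  }
  raw <- if (p_source == "logrank") out$logrank_p_raw else out$wald_p
  out$p_adjusted <- if (nrow(out) > 0L) bh_adjust(raw) else numeric()
  if (n_perm > 0 && nrow(out) > 0L) {
    for (k in seq_len(nrow(out))) {
      g <- out$gene[k]
      per <- screen_gene_permutation(
        comp, g, cohort_data, hr = out$hr[k], c_mode = c_mode,
        n_perm = n_perm, seed = derive_seed(seed, id_hash(g))
      )
      out$c_index_p_empirical[k] <- per
    }
  }
  out$.gi <- NULL
  out <- select(
    out, "gene", "hr", "hr_ci_low", "hr_ci_high", "logrank_p_raw",
    "wald_p", "p_adjusted", "n", "c_index", "c_direction",
    "c_index_p_empirical"
  )
  if (length(skipped) > 0L) {
    inform(sprintf("Screen skipped %d gene(s) with no analysable pooled data.", length(skipped)))
  }
  structure(out, skipped = skipped, endpoint = endpoint,
            cutoff_method = cutoff, p_source = p_source,
            class = c("survpool_screen", class(out)))
}

# Orientation-aware permutation p for one gene's combined concordance.
# Shuffles survival within each dataset (platform scales never mix) and
# recombines, mirroring the observed statistic's construction.
screen_gene_permutation <- function(comp, gene, cohort_data, hr, c_mode, n_perm, seed) {
  parts <- list()
  for (cd in cohort_data) {
    if (!gene %in% rownames(cd$expr)) next
    v <- cd$expr[gene, ]
    ok <- !is.na(v)
    if (sum(ok) < 2L || sum(cd$event[ok]) < 1) next
    risk <- if (hr < 1) -v[ok] else v[ok]
    parts[[length(parts) + 1L]] <- list(risk = risk, time = cd$time[ok], event = cd$event[ok])
  }
  if (length(parts) == 0L) return(NA_real_)
  obs <- combined_concordance(lapply(parts, function(p) {
    concordance_counts(p$risk, p$time, p$event)
  }))
  if (is.na(obs)) return(NA_real_)
  with_seed(seed, {
    count <- 0L
    for (b in seq_len(n_perm)) {
      cc <- lapply(parts, function(p) {
        perm <- sample.int(length(p$time))
        concordance_counts(p$risk, p$time[perm], p$event[perm])
      })
      cb <- combined_concordance(cc)
      if (!is.na(cb) && cb >= obs - 1e-12) count <- count + 1L
    }
    as.numeric(count / n_perm)
  })
}

#' Rank screen rows by hazard-ratio extremity
#'
#' Keeps BH-significant rows (`p_adjusted < alpha`) and orders them by
#' descending `|log(hr)|`, so a protective HR of 1/h ranks level with a
#' deleterious HR of h. With `k` given, returns the top-k rows in each
#' direction separately.
#'
#' @param rows A `survpool_screen` tibble.
#' @param alpha Significance threshold on the adjusted p-value (default
#'   0.05).
#' @param k Optional; return the `k` most extreme rows per direction.
#'
#' @return The ranked tibble, or (with `k`) a list with elements
#'   `top_high` (HR > 1) and `top_low` (HR < 1).
#' @export
rank_by_hr <- function(rows, alpha = 0.05, k = NULL) {
  if (!"p_adjusted" %in% names(rows)) abort("`rows` must carry a p_adjusted column.")
  sig <- rows[!is.na(rows$p_adjusted) & rows$p_adjusted < alpha, , drop = FALSE]
  sig <- sig[order(-abs(log(sig$hr))), , drop = FALSE]
  if (is.null(k)) return(sig)
  list(
    top_high = head(sig[sig$hr > 1, , drop = FALSE], k),
    top_low = head(sig[sig$hr < 1, , drop = FALSE], k)
  )
}
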