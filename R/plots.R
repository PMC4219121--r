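#' Kaplan-Meier plot of a pooled query result
#'
#' Draws the pooled Kaplan-Meier step curves for the high (black) and low
#' (grey) expression groups, months on the x axis and survival probability
#' on the y axis, annotated with the hazard ratio, log-rank p-value and
#' pooled sample count.
#'
#' @param object A `survpool_result`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot survpool_result
#' @export
autoplot.survpool_result <- function(object, ...) {
  km <- object$km
  start <- tibble(
    group = c("high", "low"), time = 0, n_risk = NA_integer_,
    n_event = NA_integer_, survival = 1
  )
  df <- bind_rows(start, km)
  df$group <- factor(df$group, levels = c("high", "low"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival, colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::scale_colour_manual(values = c(high = "black", low = "grey55")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Time (months)", y = "Survival probability", colour = "Expression",
      title = sprintf("%s (%s, %s cutoff)", paste(object$genes, collapse = "+"),
                      object$endpoint, object$cutoff_method),
      subtitle = sprintf("HR = %.2f [%.2f, %.2f], log-rank p = %.3g, n = %d",
                         object$hr, object$hr_ci_low, object$hr_ci_high,
                         object$logrank_p, object$n)
    ) +
    ggplot2::theme_classic()
}

#' Volcano-style overview of a prognostic screen
#'
#' Hazard ratio (log2 scale) against -log10 raw log-rank p, with
#' BH-significant genes highlighted.
#'
#' @param object A `survpool_screen` tibble.
#' @param alpha Adjusted-p threshold for highlighting (default 0.05).
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot survpool_screen
#' @export
autoplot.survpool_screen <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object)
  df$significant <- !is.na(df$p_adjusted) & df$p_adjusted < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$hr),
                                   y = -log10(.data$logrank_p_raw),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey65", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "log2 hazard ratio (high vs low)", y = "-log10 raw log-rank p",
      colour = sprintf("BH p < %.2g", alpha)
    ) +
    ggplot2::theme_classic()
}

#' Forest-style plot of per-dataset concordance for one gene
#'
#' Computes Harrell's C within each contributing dataset for the given
#' gene's continuous expression (oriented so that C >= 0.5 matches the
#' pooled hazard direction) and plots the per-dataset values with the
#' usable-pair-weighted combined estimate.
#'
#' @param comp A `survpool_compendium`.
#' @param gene Entrez gene id.
#' @param endpoint `"OS"` or `"DFS"`.
#'
#' @return A ggplot object.
#' @export
plot_concordance_forest <- function(comp, gene, endpoint = c("OS", "DFS")) {
  endpoint <- rlang::arg_match(endpoint)
  tcol <- if (endpoint == "OS") "os_time" else "dfs_time"
  ecol <- if (endpoint == "OS") "os_event" else "dfs_event"
  rows <- purrr::compact(lapply(comp$cohorts, function(co) {
    if (!gene %in% rownames(co$expression)) return(NULL)
    usable <- !is.na(co$clinical[[tcol]]) & !is.na(co$clinical[[ecol]]) &
      co$clinical[[tcol]] > 0
    v <- co$expression[gene, usable]
    ok <- !is.na(v)
    if (sum(ok) < 2L || sum(co$clinical[[ecol]][usable][ok]) < 1) return(NULL)
    cc <- concordance_counts(v[ok], co$clinical[[tcol]][usable][ok],
                             co$clinical[[ecol]][usable][ok])
    tibble(
      dataset_id = co$dataset_id,
      c_index = (cc$concordant + 0.5 * cc$tied) / cc$usable,
      n_pairs = cc$usable
    )
  }))
  if (length(rows) == 0L) abort(sprintf("Gene '%s' has no analysable dataset.", gene))
  df <- bind_rows(rows)
  combined <- sum(df$c_index * df$n_pairs) / sum(df$n_pairs)
  df <- bind_rows(df, tibble(dataset_id = "combined", c_index = combined,
                             n_pairs = sum(df$n_pairs)))
  df$dataset_id <- factor(df$dataset_id, levels = rev(df$dataset_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$c_index, y = .data$dataset_id,
                                   size = .data$n_pairs)) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(shape = 18, colour = "black") +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = "Concordance index", y = NULL,
                  title = sprintf("%s (%s)", gene, endpoint)) +
    ggplot2::theme_classic()
}
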