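cutoff_methods <- function() c("median", "upper_quartile", "lower_quartile")

#' Compute a dichotomization cutoff
#'
#' Returns the median, 75th or 25th percentile of the non-missing values,
#' using the linear-interpolation percentile definition (type 7). With fewer
#' than two non-missing values the dataset cannot be dichotomized for this
#' gene: `NA` is returned with a warning and the dataset is skipped upstream.
#'
#' @param values Numeric vector of expression values (one dataset, one gene).
#' @param method One of `"median"`, `"upper_quartile"`, `"lower_quartile"`.
#'
#' @return A single numeric cutoff, or `NA` if undefined.
#' @export
#'
#' @examples
#' compute_cutoff(c(1, 2, 3, 4), "median") # 2.5
#' compute_cutoff(c(1, 2, 3, 4), "upper_quartile") # 3.25
compute_cutoff <- function(values, method = "median") {
  method <- rlang::arg_match(method, cutoff_methods())
  v <- values[!is.na(values)]
  if (length(v) < 2L) {
    warn(sprintf("compute_cutoff(): only %d non-missing value(s); dataset skipped.", length(v)))
    return(NA_real_)
  }
  prob <- switch(method, median = 0.5, upper_quartile = 0.75, lower_quartile = 0.25)
  unname(quantile(v, probs = prob, type = 7, names = FALSE))
}

#' Assign samples of one cohort to high/low expression groups
#'
#' Dichotomizes a cohort on one gene at a per-dataset cutoff. Under the
#' median cutoff, samples strictly above the cutoff are `high` and all other
#' measured samples are `low` (ties at the cutoff go to `low`, keeping the
#' high group strictly above it). Under `upper_quartile`, `high` means
#' strictly above Q3 (the rest `low`); under `lower_quartile`, `low` means
#' strictly below Q1 (the rest `high`). With `extremes_only = TRUE`, the two
#' quartile modes instead compare the top quarter (`> Q3`) against the
#' bottom quarter (`< Q1`) and exclude the middle. Samples with missing
#' expression are always `excluded`.
#'
#' @param cohort A `survpool_cohort`.
#' @param gene Entrez gene id.
#' @param method Cutoff method, see [compute_cutoff()].
#' @param extremes_only Logical; quartile modes compare extremes only.
#'
#' @return A `survpool_assignment`: a tibble with columns `sample_id`,
#'   `value`, `group` plus attributes `gene`, `method`, `cutoffs` (named
#'   per-dataset cutoff values).
#' @export
assign_groups <- function(cohort, gene, method = "median", extremes_only = FALSE) {
  if (!inherits(cohort, "survpool_cohort")) abort("`cohort` must be a survpool_cohort.")
  method <- rlang::arg_match(method, cutoff_methods())
  empty <- new_assignment(
    tibble(sample_id = character(), value = numeric(), group = character()),
    gene, method, extremes_only, cutoffs = setNames(numeric(), character())
  )
  if (!is_string(gene) || !gene %in% rownames(cohort$expression)) {
    inform(sprintf("Dataset '%s': gene '%s' absent; contributes no samples.", cohort$dataset_id, gene))
    return(empty)
  }
  v <- cohort$expression[gene, ]
  if (extremes_only && method %in% c("upper_quartile", "lower_quartile")) {
    q1 <- compute_cutoff(v, "lower_quartile")
    q3 <- compute_cutoff(v, "upper_quartile")
    if (is.na(q1) || is.na(q3)) return(empty)
    group <- rep("excluded", length(v))
    group[!is.na(v) & v > q3] <- "high"
    group[!is.na(v) & v < q1] <- "low"
    cut <- if (method == "upper_quartile") q3 else q1
  } else {
    cut <- compute_cutoff(v, method)
    if (is.na(cut)) return(empty)
    group <- rep("excluded", length(v))
    if (method == "lower_quartile") {
      group[!is.na(v) & v < cut] <- "low"
      group[!is.na(v) & v >= cut] <- "high"
    } else {
      group[!is.na(v) & v > cut] <- "high"
      group[!is.na(v) & v <= cut] <- "low"
    }
  }
  new_assignment(
    tibble(sample_id = colnames(cohort$expression), value = unname(v), group = group),
    gene, method, extremes_only,
    cutoffs = setNames(cut, cohort$dataset_id)
  )
}

new_assignment <- function(tbl, gene, method, extremes_only, cutoffs) {
  structure(
    tbl,
    gene = gene, method = method, extremes_only = extremes_only, cutoffs = cutoffs,
    class = c("survpool_assignment", class(tbl))
  )
}

#' Combine several single-gene assignments into an all-high query
#'
#' Implements the multi-gene combination query: a sample is `high` only if
#' it is high in every input assignment, `excluded` if it is excluded in any
#' of them (missing expression for any gene), and `low` otherwise ("the
#' rest").
#'
#' @param assignments List of `survpool_assignment` objects over the same
#'   sample universe.
#'
#' @return A combined `survpool_assignment` whose gene descriptor joins the
#'   input genes with `"+"`.
#' @export
combine_all_high <- function(assignments) {
  if (!is.list(assignments) || length(assignments) < 2L) {
    abort("`assignments` must be a list of at least two assignments.")
  }
  ids <- assignments[[1L]]$sample_id
  for (a in assignments[-1L]) {
    if (!setequal(a$sample_id, ids)) {
      abort("Assignments cover different sample universes; cannot combine.")
    }
  }
  mat <- vapply(
    assignments,
    function(a) a$group[match(ids, a$sample_id)],
    character(length(ids))
  )
  mat <- matrix(mat, nrow = length(ids))
  group <- rep("low", length(ids))
  group[apply(mat == "high", 1L, all)] <- "high"
  group[apply(mat == "excluded", 1L, any)] <- "excluded"
  genes <- vapply(assignments, function(a) attr(a, "gene"), character(1L))
  cutoffs <- lapply(assignments, attr, "cutoffs")
  names(cutoffs) <- genes
  new_assignment(
    tibble(sample_id = ids, value = NA_real_, group = group),
    gene = paste(genes, collapse = "+"),
    method = attr(assignments[[1L]], "method"),
    extremes_only = attr(assignments[[1L]], "extremes_only"),
    cutoffs = cutoffs
  )
}

#' Construct a clinical filter
#'
#' All arguments are optional constraints; an empty filter is a no-op.
#' Samples with a missing value for any constrained field are dropped.
#'
#' @param age_min,age_max Closed age interval in years.
#' @param figo_stage Numeric subset of `1:4`.
#' @param grade Numeric subset of `1:3`.
#' @param histology Subset of `c("serous", "endometrioid", "other")`.
#' @param residual_tumour,platinum,taxane,neoadjuvant,chemotherapy `"yes"`
#'   or `"no"`.
#'
#' @return An object of class `survpool_filter`.
#' @export
clinical_filter <- function(age_min = NULL, age_max = NULL, figo_stage = NULL,
                            grade = NULL, histology = NULL, residual_tumour = NULL,
                            platinum = NULL, taxane = NULL, neoadjuvant = NULL,
                            chemotherapy = NULL) {
  flt <- list(
    age_min = age_min, age_max = age_max, figo_stage = figo_stage, grade = grade,
    histology = histology, residual_tumour = residual_tumour, platinum = platinum,
    taxane = taxane, neoadjuvant = neoadjuvant, chemotherapy = chemotherapy
  )
  structure(flt[!vapply(flt, is.null, logical(1L))], class = "survpool_filter")
}

is_empty_filter <- function(filter) length(filter) == 0L

#' Restrict a cohort to samples satisfying a clinical filter
#'
#' Keeps samples satisfying every stated constraint; samples missing a value
#' for a constrained field are dropped. Filtering happens before cutoff
#' computation, so dichotomization cutoffs are defined on the selected
#' population. A filter that removes all samples yields an empty cohort
#' (logged), which simply contributes nothing to a pooled query.
#'
#' @param cohort A `survpool_cohort`.
#' @param filter A `survpool_filter`; the empty filter returns the cohort
#'   unchanged.
#'
#' @return The filtered `survpool_cohort`.
#' @export
filter_samples <- function(cohort, filter = clinical_filter()) {
  if (!inherits(cohort, "survpool_cohort")) abort("`cohort` must be a survpool_cohort.")
  if (!inherits(filter, "survpool_filter")) abort("`filter` must come from clinical_filter().")
  if (is_empty_filter(filter)) return(cohort)
  clin <- cohort$clinical
  keep <- rep(TRUE, nrow(clin))
  constrain <- function(keep, col, ok) keep & !is.na(col) & ok
  if (!is.null(filter$age_min)) keep <- constrain(keep, clin$age, clin$age >= filter$age_min)
  if (!is.null(filter$age_max)) keep <- constrain(keep, clin$age, clin$age <= filter$age_max)
  for (fld in c("figo_stage", "grade", "histology", "residual_tumour",
                "platinum", "taxane", "neoadjuvant", "chemotherapy")) {
    if (!is.null(filter[[fld]])) {
      keep <- constrain(keep, clin[[fld]], clin[[fld]] %in% filter[[fld]])
    }
  }
  if (!any(keep)) {
    inform(sprintf("Dataset '%s': clinical filter removed all samples.", cohort$dataset_id))
  }
  out <- cohort
  out$expression <- cohort$expression[, keep, drop = FALSE]
  out$clinical <- clin[keep, , drop = FALSE]
  out
}
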