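#' Read a tab-separated expression matrix
#'
#' Reads a feature-by-sample expression matrix from tab-separated text. The
#' first column holds feature identifiers (probe or Entrez gene ids), the
#' header row holds sample identifiers, and remaining cells are log-scale
#' intensities. Empty cells and `NA` become missing values.
#'
#' @param path Path to a tab-separated text file.
#'
#' @return A numeric matrix with feature rownames and sample colnames.
#' @export
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("feature_id\ts1\ts2", "p1\t1.0\t2.0", "p2\t3.0\t4.0"), tf)
#' read_expression_matrix(tf)
read_expression_matrix <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, name_repair = "minimal"
  )
  if (ncol(df) < 2L) {
    abort(sprintf("'%s': expected a feature-id column plus at least one sample column.", path))
  }
  feature_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(feature_ids)) {
    dup <- feature_ids[duplicated(feature_ids)][1L]
    abort(sprintf("'%s': duplicate feature id '%s'.", path, dup))
  }
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1L]
    abort(sprintf("'%s': duplicate sample id '%s'.", path, dup))
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  missing <- is.na(raw) | raw == "" | raw == "NA"
  values <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- !missing & is.na(values)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "'%s': non-numeric value '%s' at data row %d (feature '%s'), column '%s'.",
      path, raw[idx[1L], idx[2L]], idx[1L], feature_ids[idx[1L]], sample_ids[idx[2L]]
    ))
  }
  values[missing] <- NA_real_
  dimnames(values) <- list(feature_ids, sample_ids)
  stopifnot_expression_matrix(values, "values")
  values
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression_matrix()]; numeric values round-trip exactly.
#'
#' @param expr Numeric matrix with feature rownames and sample colnames.
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot_expression_matrix(expr)
  df <- as_tibble(expr, rownames = "feature_id")
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

clinical_columns <- function() {
  c(
    "sample_id", "os_time", "os_event", "dfs_time", "dfs_event", "age",
    "figo_stage", "grade", "histology", "residual_tumour",
    "platinum", "taxane", "neoadjuvant", "chemotherapy"
  )
}

parse_numeric_field <- function(x, field, rows, nonneg = FALSE, fatal_negative = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & x != "" & x != "NA" & is.na(out)
  if (any(bad)) {
    warn(sprintf(
      "Column '%s': %d unparseable value(s) (e.g. '%s' at row %d) set to missing.",
      field, sum(bad), x[bad][1L], rows[bad][1L]
    ))
  }
  if (fatal_negative && any(out < 0, na.rm = TRUE)) {
    r <- rows[which(out < 0)][1L]
    abort(sprintf("Column '%s': negative time at row %d.", field, r))
  }
  out
}

parse_event_field <- function(x, field, rows) {
  key <- tolower(trimws(x))
  out <- rep(NA_real_, length(x))
  out[key %in% c("1", "yes", "true", "event", "dead", "relapse")] <- 1
  out[key %in% c("0", "no", "false", "censored", "alive")] <- 0
  bad <- !is.na(key) & key != "" & key != "na" & is.na(out)
  if (any(bad)) {
    warn(sprintf(
      "Column '%s': %d unmappable event value(s) (e.g. '%s' at row %d) set to missing.",
      field, sum(bad), x[bad][1L], rows[bad][1L]
    ))
  }
  out
}

# FIGO stage: Roman (I-IV) or Arabic (1-4); substage suffixes (e.g. IIIc, 3b)
# truncate to the major stage.
parse_stage_field <- function(x, rows) {
  key <- toupper(gsub("[[:space:]]", "", x))
  key <- sub("^STAGE", "", key)
  out <- rep(NA_real_, length(x))
  out[grepl("^IV", key)] <- 4
  out[grepl("^III", key)] <- 3
  out[grepl("^II($|[^I])", key)] <- 2
  out[grepl("^I($|[^IV])", key)] <- 1
  arab <- grepl("^[1-4]", key)
  out[arab] <- as.numeric(substr(key[arab], 1L, 1L))
  bad <- !is.na(key) & key != "" & key != "NA" & is.na(out)
  if (any(bad)) {
    warn(sprintf(
      "Column 'figo_stage': %d unmappable value(s) (e.g. '%s' at row %d) set to missing.",
      sum(bad), x[bad][1L], rows[bad][1L]
    ))
  }
  out
}

parse_grade_field <- function(x, rows) {
  key <- toupper(gsub("[[:space:]]", "", x))
  key <- sub("^G(RADE)?", "", key)
  out <- rep(NA_real_, length(x))
  ok <- grepl("^[1-3]", key)
  out[ok] <- as.numeric(substr(key[ok], 1L, 1L))
  bad <- !is.na(key) & key != "" & key != "NA" & !ok
  if (any(bad)) {
    warn(sprintf(
      "Column 'grade': %d unmappable value(s) (e.g. '%s' at row %d) set to missing.",
      sum(bad), x[bad][1L], rows[bad][1L]
    ))
  }
  out
}

# Histology collapses to the controlled vocabulary {serous, endometrioid,
# other}; any recognisable but unlisted subtype (clear cell, mucinous, ...)
# maps to "other".
parse_histology_field <- function(x) {
  key <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  known <- !is.na(key) & key != "" & key != "na"
  out[known] <- "other"
  out[known & grepl("^ser", key)] <- "serous"
  out[known & grepl("^end", key)] <- "endometrioid"
  out
}

parse_yesno_field <- function(x, field, rows) {
  key <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[key %in% c("yes", "y", "1", "true")] <- "yes"
  out[key %in% c("no", "n", "0", "false")] <- "no"
  bad <- !is.na(key) & key != "" & key != "na" & is.na(out)
  if (any(bad)) {
    warn(sprintf(
      "Column '%s': %d unmappable value(s) (e.g. '%s' at row %d) set to missing.",
      field, sum(bad), x[bad][1L], rows[bad][1L]
    ))
  }
  out
}

#' Read and harmonize a clinical table
#'
#' Reads a tab-separated clinical table (one row per sample) and maps its
#' columns onto the controlled vocabulary used throughout the package:
#' survival endpoints in months, FIGO stage 1-4 (Roman numerals accepted,
#' substages truncated), grade 1-3, histology in `{serous, endometrioid,
#' other}`, and yes/no treatment flags. Unrecognized columns are ignored with
#' a warning and unmappable values degrade to missing rather than erroring,
#' so one ambiguous record never blocks integration of a whole dataset. An
#' event indicator whose matching time is missing is itself set to missing.
#'
#' @param path Path to a tab-separated text file with a header row.
#'
#' @return A tibble with the columns of `clinical_columns()`; unrecognized
#'   input columns are dropped.
#' @export
read_clinical_table <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, name_repair = "minimal"
  )
  names(df) <- tolower(trimws(names(df)))
  if (!"sample_id" %in% names(df)) {
    abort(sprintf("'%s': required column 'sample_id' is missing.", path))
  }
  unknown <- setdiff(names(df), clinical_columns())
  if (length(unknown) > 0L) {
    warn(sprintf("'%s': ignoring unrecognized column(s): %s.", path, paste(unknown, collapse = ", ")))
  }
  n <- nrow(df)
  rows <- seq_len(n)
  col <- function(name) if (name %in% names(df)) df[[name]] else rep(NA_character_, n)

  sample_id <- trimws(col("sample_id"))
  if (anyDuplicated(sample_id)) {
    dup <- sample_id[duplicated(sample_id)][1L]
    abort(sprintf("'%s': duplicate sample_id '%s'.", path, dup))
  }
  out <- tibble(
    sample_id = sample_id,
    os_time = parse_numeric_field(col("os_time"), "os_time", rows, fatal_negative = TRUE),
    os_event = parse_event_field(col("os_event"), "os_event", rows),
    dfs_time = parse_numeric_field(col("dfs_time"), "dfs_time", rows, fatal_negative = TRUE),
    dfs_event = parse_event_field(col("dfs_event"), "dfs_event", rows),
    age = parse_numeric_field(col("age"), "age", rows),
    figo_stage = parse_stage_field(col("figo_stage"), rows),
    grade = parse_grade_field(col("grade"), rows),
    histology = parse_histology_field(col("histology")),
    residual_tumour = parse_yesno_field(col("residual_tumour"), "residual_tumour", rows),
    platinum = parse_yesno_field(col("platinum"), "platinum", rows),
    taxane = parse_yesno_field(col("taxane"), "taxane", rows),
    neoadjuvant = parse_yesno_field(col("neoadjuvant"), "neoadjuvant", rows),
    chemotherapy = parse_yesno_field(col("chemotherapy"), "chemotherapy", rows)
  )
  # Event indicators are only meaningful alongside a time.
  for (ep in c("os", "dfs")) {
    tcol <- paste0(ep, "_time")
    ecol <- paste0(ep, "_event")
    orphan <- !is.na(out[[ecol]]) & is.na(out[[tcol]])
    if (any(orphan)) {
      warn(sprintf(
        "Column '%s': %d indicator(s) without a matching time set to missing.",
        ecol, sum(orphan)
      ))
      out[[ecol]][orphan] <- NA_real_
    }
  }
  out
}

#' Write a clinical table as tab-separated text
#'
#' @param clinical A tibble in the layout returned by [read_clinical_table()].
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  readr::write_tsv(clinical, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Assemble one cohort from an expression matrix and a clinical table
#'
#' Aligns a gene-centred expression matrix with its clinical table on the
#' intersection of sample ids (keeping the expression matrix's order) and
#' enforces the minimum-cohort-size inclusion rule. Cohorts below
#' `min_patients` samples are rejected; pass a smaller `min_patients` to
#' override (e.g. for small test fixtures).
#'
#' @param dataset_id Unique dataset identifier.
#' @param platform Array platform label.
#' @param expr Numeric matrix, Entrez gene ids x sample ids.
#' @param clinical Tibble in the layout of [read_clinical_table()].
#' @param min_patients Minimum number of aligned samples (default 50).
#'
#' @return An object of class `survpool_cohort`.
#' @export
assemble_cohort <- function(dataset_id, platform, expr, clinical, min_patients = 50) {
  if (!is_string(dataset_id)) abort("`dataset_id` must be a single string.")
  if (!is_string(platform)) abort("`platform` must be a single string.")
  stopifnot_expression_matrix(expr)
  if (!is.data.frame(clinical) || !"sample_id" %in% names(clinical)) {
    abort("`clinical` must be a data frame with a 'sample_id' column.")
  }
  if (anyDuplicated(clinical$sample_id)) {
    abort(sprintf("Dataset '%s': duplicate sample_id in clinical table.", dataset_id))
  }
  shared <- colnames(expr)[colnames(expr) %in% clinical$sample_id]
  if (length(shared) == 0L) {
    abort(sprintf("Dataset '%s': expression and clinical tables share no sample ids.", dataset_id))
  }
  if (length(shared) < min_patients) {
    abort(sprintf(
      "Dataset '%s' rejected: %d aligned sample(s), fewer than min_patients = %d.",
      dataset_id, length(shared), min_patients
    ))
  }
  clin <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  missing_cols <- setdiff(clinical_columns(), names(clin))
  for (mc in missing_cols) clin[[mc]] <- if (mc %in% c("histology", "residual_tumour", "platinum", "taxane", "neoadjuvant", "chemotherapy")) NA_character_ else NA_real_
  clin <- clin[, clinical_columns()]
  if (all(is.na(clin$os_time)) && all(is.na(clin$dfs_time))) {
    abort(sprintf("Dataset '%s': no sample has an OS or DFS time.", dataset_id))
  }
  structure(
    list(
      dataset_id = dataset_id,
      platform = platform,
      expression = expr[, shared, drop = FALSE],
      clinical = as_tibble(clin)
    ),
    class = "survpool_cohort"
  )
}

#' @export
print.survpool_cohort <- function(x, ...) {
  cat(sprintf(
    "<survpool_cohort> %s (%s): %d genes x %d samples; OS %d, DFS %d\n",
    x$dataset_id, x$platform, nrow(x$expression), ncol(x$expression),
    sum(!is.na(x$clinical$os_time)), sum(!is.na(x$clinical$dfs_time))
  ))
  invisible(x)
}

n_samples <- function(cohort) ncol(cohort$expression)

#' Assemble a compendium from a list of cohorts
#'
#' @param cohorts List of `survpool_cohort` objects with unique dataset ids.
#'
#' @return An object of class `survpool_compendium` whose `gene_universe` is
#'   the union of the cohorts' Entrez gene ids.
#' @export
assemble_compendium <- function(cohorts) {
  if (!is.list(cohorts) || length(cohorts) == 0L) {
    abort("`cohorts` must be a non-empty list of cohorts.")
  }
  ok <- vapply(cohorts, inherits, logical(1L), what = "survpool_cohort")
  if (!all(ok)) abort("All elements of `cohorts` must be `survpool_cohort` objects.")
  ids <- vapply(cohorts, function(x) x$dataset_id, character(1L))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate dataset_id: '%s'.", ids[duplicated(ids)][1L]))
  }
  names(cohorts) <- ids
  structure(
    list(
      cohorts = cohorts,
      gene_universe = Reduce(union, lapply(cohorts, function(x) rownames(x$expression)))
    ),
    class = "survpool_compendium"
  )
}

#' @export
print.survpool_compendium <- function(x, ...) {
  ns <- vapply(x$cohorts, n_samples, integer(1L))
  cat(sprintf(
    "<survpool_compendium> %d dataset(s), %d samples, %d genes in universe\n",
    length(x$cohorts), sum(ns), length(x$gene_universe)
  ))
  for (co in x$cohorts) {
    cat(sprintf("  - %s (%s): %d samples\n", co$dataset_id, co$platform, n_samples(co)))
  }
  invisible(x)
}
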