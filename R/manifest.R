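#' Build a compendium from a manifest file
#'
#' A manifest (YAML or JSON) lists the datasets of a compendium, one entry
#' per dataset under a top-level `datasets` key:
#'
#' ```yaml
#' datasets:
#'   - id: DS1
#'     platform: CHIP-A
#'     expression: DS1_expression.tsv
#'     clinical: DS1_clinical.tsv
#'     probe_map: DS1_probemap.tsv   # optional; omit for gene-level matrices
#'     time_unit: months             # days | months | years
#'     quantile_normalize: false
#' ```
#'
#' Relative paths resolve against the manifest's directory. For each
#' dataset the expression matrix is read, optionally quantile normalized
#' (within the dataset only, never across datasets) and collapsed to Entrez
#' genes through its probe map; survival times are converted to months
#' (days / 30.44, years x 12); and the cohort is assembled subject to the
#' minimum-size rule.
#'
#' @param path Manifest file path.
#' @param min_patients Minimum cohort size (default 50); pass 1 to keep
#'   every dataset.
#'
#' @return A `survpool_compendium`.
#' @export
read_compendium <- function(path, min_patients = 50) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$datasets) || length(cfg$datasets) == 0L) {
    abort(sprintf("'%s': manifest has no `datasets` entries.", path))
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  cohorts <- lapply(cfg$datasets, function(ds) {
    for (fld in c("id", "platform", "expression", "clinical")) {
      if (is.null(ds[[fld]])) abort(sprintf("Manifest dataset entry lacks '%s'.", fld))
    }
    expr <- read_expression_matrix(resolve(ds$expression))
    if (!is.null(ds$probe_map)) {
      pm <- filter_multimapping(load_probe_map(resolve(ds$probe_map)))
      if (isTRUE(ds$quantile_normalize)) expr <- quantile_normalize(expr)
      expr <- collapse_to_genes(expr, pm)
    } else if (isTRUE(ds$quantile_normalize)) {
      expr <- quantile_normalize(expr)
    }
    clin <- read_clinical_table(resolve(ds$clinical))
    unit <- ds$time_unit %||% "months"
    clin <- convert_time_unit(clin, unit)
    assemble_cohort(ds$id, ds$platform, expr, clin, min_patients = min_patients)
  })
  assemble_compendium(cohorts)
}

# Survival times are stored in months throughout.
convert_time_unit <- function(clinical, unit) {
  unit <- rlang::arg_match(unit, c("months", "days", "years"))
  f <- switch(unit, months = 1, days = 1 / 30.44, years = 12)
  clinical$os_time <- clinical$os_time * f
  clinical$dfs_time <- clinical$dfs_time * f
  clinical
}

#' Write a compendium to disk as per-dataset files plus a manifest
#'
#' Writes each cohort's gene-level expression matrix and clinical table as
#' tab-separated text and a `manifest.yaml` tying them together; the
#' output is directly loadable with [read_compendium()].
#'
#' @param comp A `survpool_compendium`.
#' @param dir Output directory (created if needed).
#'
#' @return The manifest path, invisibly.
#' @export
write_compendium <- function(comp, dir) {
  if (!inherits(comp, "survpool_compendium")) abort("`comp` must be a survpool_compendium.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(comp$cohorts, function(co) {
    efile <- paste0(co$dataset_id, "_expression.tsv")
    cfile <- paste0(co$dataset_id, "_clinical.tsv")
    write_expression_matrix(co$expression, file.path(dir, efile))
    write_clinical_table(co$clinical, file.path(dir, cfile))
    list(
      id = co$dataset_id, platform = co$platform,
      expression = efile, clinical = cfile, time_unit = "months"
    )
  })
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(datasets = unname(entries)), manifest)
  invisible(manifest)
}
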