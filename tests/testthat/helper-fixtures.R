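# In-code fixtures: tiny cohorts and compendia built deterministically.

make_expr <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

make_clinical <- function(sample_ids, os_time = NULL, os_event = NULL,
                          dfs_time = NULL, dfs_event = NULL, ...) {
  n <- length(sample_ids)
  def <- function(x, fallback) if (is.null(x)) rep(fallback, n) else x
  extra <- list(...)
  out <- tibble::tibble(
    sample_id = sample_ids,
    os_time = def(os_time, NA_real_),
    os_event = def(os_event, NA_real_),
    dfs_time = def(dfs_time, NA_real_),
    dfs_event = def(dfs_event, NA_real_),
    age = rep(NA_real_, n), figo_stage = rep(NA_real_, n),
    grade = rep(NA_real_, n), histology = rep(NA_character_, n),
    residual_tumour = rep(NA_character_, n), platinum = rep(NA_character_, n),
    taxane = rep(NA_character_, n), neoadjuvant = rep(NA_character_, n),
    chemotherapy = rep(NA_character_, n)
  )
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

make_cohort <- function(dataset_id, expr, clinical = NULL) {
  if (is.null(clinical)) {
    n <- ncol(expr)
    clinical <- make_clinical(colnames(expr),
                              os_time = seq_len(n) * 3,
                              os_event = rep(c(1, 0), length.out = n))
  }
  assemble_cohort(dataset_id, "TESTCHIP", expr, clinical, min_patients = 1)
}

# A small seeded cohort with continuous expression and exponential survival.
random_cohort <- function(dataset_id, n = 40, genes = c("g1", "g2"), seed = 1) {
  withr::with_seed(seed, {
    samples <- sprintf("%s_s%02d", dataset_id, seq_len(n))
    expr <- matrix(rnorm(length(genes) * n), length(genes), n,
                   dimnames = list(genes, samples))
    clin <- make_clinical(samples,
                          os_time = rexp(n, 1 / 40),
                          os_event = rbinom(n, 1, 0.7),
                          dfs_time = rexp(n, 1 / 30),
                          dfs_event = rbinom(n, 1, 0.7))
    assemble_cohort(dataset_id, "TESTCHIP", expr, clin, min_patients = 1)
  })
}
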