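test_that("expression matrices read with ids preserved and missing cells as NA", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "feature_id\ts1\ts2",
    "p1\t1.0\t2.0",
    "p2\t3.0\t",
    "p3\t5.0\tNA"
  ), tf)
  m <- read_expression_matrix(tf)
  expect_identical(rownames(m), c("p1", "p2", "p3"))
  expect_identical(colnames(m), c("s1", "s2"))
  expect_equal(m["p1", ], c(s1 = 1, s2 = 2))
  expect_true(is.na(m["p2", "s2"]))
  expect_true(is.na(m["p3", "s2"]))
})

test_that("expression reader rejects duplicates and locates non-numeric cells", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1", "p1\t1.0", "p1\t2.0"), tf)
  expect_error(read_expression_matrix(tf), "duplicate feature id 'p1'")

  writeLines(c("feature_id\ts1\ts1", "p1\t1.0\t2.0"), tf)
  expect_error(read_expression_matrix(tf), "duplicate sample id 's1'")

  writeLines(c("feature_id\ts1\ts2", "p1\t1.0\t2.0", "p2\tbad\t4.0"), tf)
  expect_error(read_expression_matrix(tf), "non-numeric value 'bad' at data row 2.*column 's1'")
})

test_that("expression write/read round-trips generated matrices exactly", {
  withr::local_seed(42)
  m <- matrix(rnorm(60), 12, 5,
              dimnames = list(sprintf("p%02d", 1:12), sprintf("s%d", 1:5)))
  m[sample(length(m), 7)] <- NA
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, tf)
  expect_identical(read_expression_matrix(tf), m)
})

test_that("clinical vocabulary mapping handles stages, histology and orphan events", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("sample_id", "os_time", "os_event", "figo_stage", "grade", "histology", "platinum", sep = "\t"),
    paste("s1", "47", "1", "III", "2", "Serous", "Yes", sep = "\t"),
    paste("s2", "20", "0", "IIIc", "G3", "clear cell", "0", sep = "\t"),
    paste("s3", "", "1", "4", "1", "end", "maybe", sep = "\t"),
    paste("s4", "12", "", "IV", "", "ser", "", sep = "\t")
  ), tf)
  expect_warning(expect_warning(clin <- read_clinical_table(tf), "platinum"), "os_event")
  expect_equal(clin$os_time, c(47, 20, NA, 12))
  expect_equal(clin$figo_stage, c(3, 3, 4, 4))
  expect_equal(clin$grade, c(2, 3, 1, NA))
  expect_equal(clin$histology, c("serous", "other", "endometrioid", "serous"))
  expect_equal(clin$platinum, c("yes", "no", NA, NA))
  # event present without a time is coerced to missing
  expect_true(is.na(clin$os_event[3]))
  expect_equal(clin$os_event[c(1, 2, 4)], c(1, 0, NA))
})

test_that("clinical reader fails on missing sample_id, negative times, duplicates", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient\tos_time", "s1\t10"), tf)
  expect_error(suppressWarnings(read_clinical_table(tf)), "sample_id")

  writeLines(c("sample_id\tos_time", "s1\t-3"), tf)
  expect_error(read_clinical_table(tf), "negative time at row 1")

  writeLines(c("sample_id\tos_time", "s1\t3", "s1\t4"), tf)
  expect_error(read_clinical_table(tf), "duplicate sample_id")
})

test_that("unrecognized clinical columns are ignored with a warning", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tos_time\tos_event\tshoe_size", "s1\t10\t1\t42"), tf)
  expect_warning(clin <- read_clinical_table(tf), "shoe_size")
  expect_false("shoe_size" %in% names(clin))
})

test_that("cohort assembly aligns on the sample intersection in expression order", {
  expr <- make_expr(c(1, 2, 3), "g1", c("s1", "s2", "s3"))
  clin <- make_clinical(c("s2", "s3", "s4"), os_time = c(5, 6, 7), os_event = c(1, 0, 1))
  co <- assemble_cohort("A", "chip", expr, clin, min_patients = 2)
  expect_identical(colnames(co$expression), c("s2", "s3"))
  expect_identical(co$clinical$sample_id, c("s2", "s3"))
  # never more samples than either input
  expect_lte(ncol(co$expression), ncol(expr))
  expect_lte(ncol(co$expression), nrow(clin))
})

test_that("minimum-cohort-size rule rejects below threshold and can be overridden", {
  withr::local_seed(7)
  n <- 49
  samples <- sprintf("s%02d", seq_len(n))
  expr <- matrix(rnorm(n), 1, n, dimnames = list("g1", samples))
  clin <- make_clinical(samples, os_time = rexp(n, 0.02), os_event = rbinom(n, 1, 0.7))
  expect_error(assemble_cohort("A", "chip", expr, clin), "49.*min_patients = 50")
  expect_s3_class(assemble_cohort("A", "chip", expr, clin, min_patients = 1), "survpool_cohort")
})

test_that("assembly errors on empty intersection and endpoint-free cohorts", {
  expr <- make_expr(c(1, 2), "g1", c("s1", "s2"))
  clin <- make_clinical(c("t1", "t2"), os_time = c(1, 2), os_event = c(1, 1))
  expect_error(assemble_cohort("A", "chip", expr, clin, min_patients = 1), "no sample ids")
  clin2 <- make_clinical(c("s1", "s2"))
  expect_error(assemble_cohort("A", "chip", expr, clin2, min_patients = 1), "OS or DFS")
})

test_that("cohort assembly is idempotent on already-aligned inputs", {
  co <- random_cohort("A", n = 12)
  co2 <- assemble_cohort(co$dataset_id, co$platform, co$expression, co$clinical,
                         min_patients = 1)
  expect_identical(co2$expression, co$expression)
  expect_identical(co2$clinical, co$clinical)
})

test_that("compendium assembly unions gene universes and rejects duplicate ids", {
  a <- make_cohort("A", make_expr(c(1, 2, 3, 4), c("g1", "g2"), c("s1", "s2")))
  b <- make_cohort("B", make_expr(c(1, 2, 3, 4), c("g2", "g3"), c("t1", "t2")))
  comp <- assemble_compendium(list(a, b))
  expect_setequal(comp$gene_universe, c("g1", "g2", "g3"))
  single <- assemble_compendium(list(a))
  expect_identical(single$gene_universe, c("g1", "g2"))
  expect_error(assemble_compendium(list(a, a)), "Duplicate dataset_id")
})

test_that("a written compendium reloads through the manifest identically", {
  cfg <- sim_config(n_datasets = 2, n_samples = 25, n_genes = 12, seed = 303)
  dir <- withr::local_tempdir()
  sim <- suppressMessages(simulate_compendium(cfg, dir = dir))
  reloaded <- suppressMessages(suppressWarnings(read_compendium(sim$manifest, min_patients = 1)))
  expect_identical(names(reloaded$cohorts), names(sim$compendium$cohorts))
  for (id in names(reloaded$cohorts)) {
    expect_equal(reloaded$cohorts[[id]]$expression,
                 sim$compendium$cohorts[[id]]$expression)
    expect_equal(as.data.frame(reloaded$cohorts[[id]]$clinical),
                 as.data.frame(sim$compendium$cohorts[[id]]$clinical))
  }
})

test_that("declared time units convert to months", {
  clin <- make_clinical("s1", os_time = 365.28, os_event = 1, dfs_time = 2, dfs_event = 0)
  days <- survpool:::convert_time_unit(clin, "days")
  expect_equal(days$os_time, 365.28 / 30.44)
  years <- survpool:::convert_time_unit(clin, "years")
  expect_equal(years$dfs_time, 24)
  months <- survpool:::convert_time_unit(clin, "months")
  expect_equal(months$os_time, 365.28)
})
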