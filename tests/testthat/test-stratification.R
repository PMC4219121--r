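test_that("cutoffs use the linear-interpolation percentile definition", {
  expect_equal(compute_cutoff(c(1, 2, 3, 4), "median"), 2.5)
  expect_equal(compute_cutoff(c(1, 2, 3, 4), "upper_quartile"), 3.25)
  expect_equal(compute_cutoff(c(1, 2, 3, 4), "lower_quartile"), 1.75)
  expect_equal(compute_cutoff(c(5, 5, 5, 5), "median"), 5)
  expect_equal(compute_cutoff(c(NA, 1, 2, NA), "median"), 1.5)
  expect_warning(out <- compute_cutoff(c(1, NA), "median"), "skipped")
  expect_true(is.na(out))
})

test_that("median dichotomization sends ties and constants to low, missing to excluded", {
  co <- make_cohort("A", make_expr(c(1, 2, 3, 4), "g1", paste0("s", 1:4)))
  a <- assign_groups(co, "g1", "median")
  expect_equal(a$group, c("low", "low", "high", "high"))
  expect_equal(unname(attr(a, "cutoffs")), 2.5)

  co2 <- make_cohort("A", make_expr(c(1, 2, 2, 3), "g1", paste0("s", 1:4)))
  a2 <- assign_groups(co2, "g1", "median")
  expect_equal(a2$group, c("low", "low", "low", "high"))

  co3 <- make_cohort("A", make_expr(rep(7, 4), "g1", paste0("s", 1:4)))
  expect_true(all(assign_groups(co3, "g1")$group == "low"))

  co4 <- make_cohort("A", make_expr(c(1, NA, 3, 4), "g1", paste0("s", 1:4)))
  a4 <- assign_groups(co4, "g1")
  expect_equal(a4$group[2], "excluded")
})

test_that("quartile modes split all samples by default and extremes with the modifier", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8)
  co <- make_cohort("A", make_expr(vals, "g1", paste0("s", 1:8)))
  up <- assign_groups(co, "g1", "upper_quartile")
  q3 <- compute_cutoff(vals, "upper_quartile")
  expect_equal(up$group, ifelse(vals > q3, "high", "low"))

  lo <- assign_groups(co, "g1", "lower_quartile")
  q1 <- compute_cutoff(vals, "lower_quartile")
  expect_equal(lo$group, ifelse(vals < q1, "low", "high"))

  ext <- assign_groups(co, "g1", "upper_quartile", extremes_only = TRUE)
  expect_equal(ext$group, ifelse(vals > q3, "high", ifelse(vals < q1, "low", "excluded")))
})

test_that("a cohort missing the gene contributes no samples", {
  co <- make_cohort("A", make_expr(c(1, 2), "g1", c("s1", "s2")))
  a <- suppressMessages(assign_groups(co, "g999"))
  expect_equal(nrow(a), 0L)
})

test_that("all-high combination intersects high sets and propagates exclusions", {
  co <- make_cohort("A", make_expr(c(1, 2, 3, 4,
                                     4, 3, 2, 1), c("g1", "g2"), paste0("s", 1:4)))
  a <- assign_groups(co, "g1")
  b <- assign_groups(co, "g2")
  ab <- combine_all_high(list(a, b))
  expect_true(all(ab$group == "low")) # opposite orderings: nobody high in both

  # worked example: A high={s1,s2}, B high={s2,s3} -> combined high={s2}
  co2 <- make_cohort("A", make_expr(c(4, 3, 1, 2,
                                      1, 4, 3, 2), c("g1", "g2"), paste0("s", 1:4)))
  a2 <- assign_groups(co2, "g1")
  b2 <- assign_groups(co2, "g2")
  expect_setequal(a2$sample_id[a2$group == "high"], c("s1", "s2"))
  expect_setequal(b2$sample_id[b2$group == "high"], c("s2", "s3"))
  comb <- combine_all_high(list(a2, b2))
  expect_identical(comb$sample_id[comb$group == "high"], "s2")
  expect_setequal(comb$sample_id[comb$group == "low"], c("s1", "s3", "s4"))

  # combining identical assignments reproduces the input grouping
  same <- combine_all_high(list(a2, a2))
  expect_equal(same$group, a2$group)
})

test_that("three-way combination matches the set-intersection oracle", {
  withr::local_seed(12)
  for (rep in 1:5) {
    co <- random_cohort(sprintf("C%d", rep), n = 30, genes = c("g1", "g2", "g3"), seed = rep)
    asg <- lapply(c("g1", "g2", "g3"), function(g) assign_groups(co, g))
    comb <- combine_all_high(asg)
    high_sets <- lapply(asg, function(a) a$sample_id[a$group == "high"])
    oracle_high <- Reduce(intersect, high_sets)
    expect_setequal(comb$sample_id[comb$group == "high"], oracle_high)
    # combined high set is contained in every input high set
    for (h in high_sets) expect_true(all(comb$sample_id[comb$group == "high"] %in% h))
  }
  expect_error(combine_all_high(list(
    assign_groups(random_cohort("X", n = 10, seed = 1), "g1"),
    assign_groups(random_cohort("Y", n = 10, seed = 2), "g1")
  )), "sample universes")
})

test_that("clinical filters drop constrained-missing samples and compose", {
  co <- make_cohort("A", make_expr(c(1, 2, 3), "g1", paste0("s", 1:3)),
                    make_clinical(paste0("s", 1:3),
                                  os_time = c(10, 20, 30), os_event = c(1, 1, 0),
                                  grade = c(1, 3, NA),
                                  platinum = c("yes", "yes", "no"),
                                  figo_stage = c(3, 4, 3)))
  f <- filter_samples(co, clinical_filter(grade = 3))
  expect_identical(f$clinical$sample_id, "s2")

  expect_identical(filter_samples(co, clinical_filter()), co)

  both <- filter_samples(co, clinical_filter(platinum = "yes", figo_stage = c(3, 4)))
  seq1 <- filter_samples(filter_samples(co, clinical_filter(platinum = "yes")),
                         clinical_filter(figo_stage = c(3, 4)))
  expect_identical(both$clinical, seq1$clinical)
  expect_identical(both$expression, seq1$expression)

  expect_message(none <- filter_samples(co, clinical_filter(grade = 2)), "removed all")
  expect_equal(ncol(none$expression), 0L)
})

test_that("dichotomization depends only on ranks and on the cohort's own data", {
  withr::local_seed(77)
  transforms <- list(exp, function(x) x^3, function(x) 2 * x + 1, atan)
  for (rep in 1:4) {
    co <- random_cohort(sprintf("A%d", rep), n = 25 + rep, seed = 100 + rep)
    for (method in c("median", "upper_quartile", "lower_quartile")) {
      base <- assign_groups(co, "g1", method)
      for (tr in transforms) {
        co_t <- co
        co_t$expression["g1", ] <- tr(co$expression["g1", ])
        expect_equal(assign_groups(co_t, "g1", method)$group, base$group)
      }
    }
  }
  # rescaling one cohort never changes another cohort's assignments
  a <- random_cohort("A", n = 20, seed = 5)
  b <- random_cohort("B", n = 20, seed = 6)
  before <- assign_groups(b, "g1")
  a$expression <- a$expression * 100 + 5
  expect_identical(assign_groups(b, "g1")$group, before$group)
})

test_that("median splits are balanced up to cutoff ties", {
  withr::local_seed(21)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    vals <- if (rep %% 2 == 0) rnorm(n) else sample(1:5, n, replace = TRUE)
    co <- make_cohort("A", make_expr(vals, "g1", sprintf("s%03d", 1:n)))
    a <- assign_groups(co, "g1")
    cut <- attr(a, "cutoffs")[[1]]
    ties <- sum(vals == cut)
    # strictly-above and strictly-below counts differ only by cutoff ties
    expect_lte(abs(sum(vals > cut) - sum(vals < cut)), ties)
    if (ties == 0 && n %% 2 == 0) {
      expect_equal(sum(a$group == "high"), sum(a$group == "low"))
    }
  }
})
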