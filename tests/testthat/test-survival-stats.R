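test_that("Kaplan-Meier handles censored-only and all-event inputs", {
  expect_equal(nrow(km_estimate(c(5, 10), c(0, 0))), 0L) # S(t) = 1 everywhere

  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3L, 2L, 1L))

  expect_error(km_estimate(numeric(), numeric()), "Empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "positive")
})

test_that("Kaplan-Meier matches the hand tabulation on random censored instances", {
  withr::local_seed(401)
  for (rep in 1:25) {
    inst <- random_surv_instance(sample(5:40, 1), tie = rep %% 2 == 0)
    km <- km_estimate(inst$time, inst$event)
    ora <- oracle_km(inst$time, inst$event)
    expect_equal(km$time, ora$time)
    expect_equal(km$survival, ora$survival, tolerance = 1e-10)
  }
})

test_that("Kaplan-Meier probabilities are invariant to time rescaling", {
  withr::local_seed(402)
  inst <- random_surv_instance(30)
  km1 <- km_estimate(inst$time, inst$event)
  km2 <- km_estimate(inst$time * 3.7, inst$event)
  expect_equal(km2$time, km1$time * 3.7)
  expect_equal(km2$survival, km1$survival)
})

test_that("log-rank test is null on identical groups and errors on empty ones", {
  base <- tibble::tibble(time = c(3, 6, 9, 12), event = c(1, 0, 1, 1))
  data <- dplyr::bind_rows(
    dplyr::mutate(base, group = "high"),
    dplyr::mutate(base, group = "low")
  )
  lr <- logrank_test(data)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  one <- dplyr::mutate(base, group = "high")
  expect_error(logrank_test(one), "Group 'low' is empty")
})

test_that("log-rank statistic matches the per-event-time tabulation oracle", {
  withr::local_seed(403)
  for (rep in 1:25) {
    inst <- random_surv_instance(sample(6:40, 1), tie = rep %% 2 == 0)
    data <- tibble::tibble(
      time = inst$time, event = inst$event,
      group = ifelse(inst$x == 1, "high", "low")
    )
    lr <- logrank_test(data)
    expect_equal(lr$chisq, oracle_logrank_chisq(inst$time, inst$event, inst$x),
                 tolerance = 1e-8)
    # internal fast path used by the screen agrees with the canonical test
    expect_equal(survpool:::logrank_chisq_fast(inst$time, inst$event, inst$x),
                 lr$chisq, tolerance = 1e-8)
    # invariant under group-label exchange
    flipped <- dplyr::mutate(data, group = ifelse(group == "high", "low", "high"))
    expect_equal(logrank_test(flipped)$p, lr$p, tolerance = 1e-12)
  }
})

test_that("Cox estimates match the written-out Efron partial-likelihood oracle", {
  withr::local_seed(404)
  done <- 0
  while (done < 25) {
    inst <- random_surv_instance(sample(8:40, 1), tie = done %% 2 == 0)
    beta_oracle <- oracle_cox_beta(inst$time, inst$event, inst$x)
    if (is.na(beta_oracle) || abs(beta_oracle) > 5) next
    data <- tibble::tibble(
      time = inst$time, event = inst$event,
      group = ifelse(inst$x == 1, "high", "low")
    )
    fit <- cox_binary(data)
    expect_false(fit$flagged)
    expect_equal(fit$beta, beta_oracle, tolerance = 1e-8)
    done <- done + 1
  }
})

test_that("Cox estimates agree with the survival package on beta, SE and CI", {
  withr::local_seed(405)
  done <- 0
  while (done < 10) {
    inst <- random_surv_instance(sample(30:60, 1), tie = done %% 2 == 0, cens = 0.2)
    data <- tibble::tibble(
      time = inst$time, event = inst$event,
      group = ifelse(inst$x == 1, "high", "low"),
      dataset_id = rep(c("A", "B"), length.out = length(inst$time))
    )
    fit <- cox_binary(data)
    fits <- cox_binary(data, stratified = TRUE)
    if (fit$flagged || fits$flagged || abs(fit$beta) > 3 || abs(fits$beta) > 3) next
    ref <- survival::coxph(
      survival::Surv(time, event) ~ I(group == "high"),
      data = data, ties = "efron",
      control = survival::coxph.control(eps = 1e-10, iter.max = 50)
    )
    expect_equal(fit$beta, unname(ref$coefficients), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(ref$var[1, 1])), tolerance = 1e-6)
    expect_equal(log(c(fit$hr_ci_low, fit$hr_ci_high)),
                 unname(stats::confint(ref)[1, ]), tolerance = 1e-6)

    refs <- survival::coxph(
      survival::Surv(time, event) ~ I(group == "high") + survival::strata(dataset_id),
      data = data, ties = "efron",
      control = survival::coxph.control(eps = 1e-10, iter.max = 50)
    )
    expect_equal(fits$beta, unname(refs$coefficients), tolerance = 1e-6)
    done <- done + 1
  }
})

test_that("Cox symmetry: exchanging groups inverts the hazard ratio", {
  withr::local_seed(406)
  inst <- random_surv_instance(40)
  data <- tibble::tibble(
    time = inst$time, event = inst$event,
    group = ifelse(inst$x == 1, "high", "low")
  )
  fit <- cox_binary(data)
  flipped <- dplyr::mutate(data, group = ifelse(group == "high", "low", "high"))
  fit2 <- cox_binary(flipped)
  expect_equal(fit$hr * fit2$hr, 1, tolerance = 1e-9)
  expect_equal(fit2$hr_ci_low, 1 / fit$hr_ci_high, tolerance = 1e-9)
  expect_equal(fit2$hr_ci_high, 1 / fit$hr_ci_low, tolerance = 1e-9)
})

test_that("Cox is null-centred when groups carry no signal", {
  withr::local_seed(407)
  n <- 4000
  data <- tibble::tibble(
    time = rexp(n, 1 / 40),
    event = rbinom(n, 1, 0.7),
    group = sample(c("high", "low"), n, replace = TRUE)
  )
  fit <- cox_binary(data)
  expect_lt(abs(fit$beta), 3 / sqrt(sum(data$event) / 4)) # ~3 SE of the null
})

test_that("monotone likelihoods are flagged with an infinite CI, not a crash", {
  # every high-group event precedes every low-group observation
  data <- tibble::tibble(
    time = c(1, 2, 3, 10, 11, 12),
    event = c(1, 1, 1, 1, 1, 1),
    group = c("high", "high", "high", "low", "low", "low")
  )
  fit <- cox_binary(data)
  expect_true(fit$flagged)
  expect_equal(fit$hr_ci_low, 0)
  expect_equal(fit$hr_ci_high, Inf)
})

test_that("a pooled query on a single-contributor compendium equals the lone cohort", {
  a <- random_cohort("A", n = 40, genes = c("g1", "g2"), seed = 31)
  b <- random_cohort("B", n = 40, genes = "g9", seed = 32)
  spec <- query_spec("g1")
  both <- suppressMessages(pooled_query(assemble_compendium(list(a, b)), spec))
  alone <- pooled_query(assemble_compendium(list(a)), spec)
  expect_equal(both$hr, alone$hr)
  expect_equal(both$logrank_p, alone$logrank_p)
  expect_equal(both$n, alone$n)
  expect_identical(both$datasets$dataset_id, "A")
})

test_that("pooled queries are deterministic and respect endpoint availability", {
  a <- random_cohort("A", n = 40, seed = 41)
  b <- random_cohort("B", n = 40, seed = 42)
  comp <- assemble_compendium(list(a, b))
  r1 <- pooled_query(comp, query_spec("g1", endpoint = "DFS"))
  r2 <- pooled_query(comp, query_spec("g1", endpoint = "DFS"))
  expect_identical(r1[setdiff(names(r1), "samples")], r2[setdiff(names(r2), "samples")])
  expect_identical(r1$samples, r2$samples)

  # samples lacking the endpoint drop out per query
  b2 <- b
  b2$clinical$dfs_time <- NA_real_
  b2$clinical$dfs_event <- NA_real_
  comp2 <- assemble_compendium(list(a, b2))
  r3 <- pooled_query(comp2, query_spec("g1", endpoint = "DFS"))
  expect_identical(r3$datasets$dataset_id, "A")
})

test_that("pooling replicate cohorts keeps the HR and shrinks the CI", {
  a <- random_cohort("A", n = 60, seed = 51)
  a2 <- a
  a2$dataset_id <- "A2"
  a3 <- a
  a3$dataset_id <- "A3"
  one <- pooled_query(assemble_compendium(list(a)), query_spec("g1"))
  three <- pooled_query(assemble_compendium(list(a, a2, a3)), query_spec("g1"))
  # replication creates cross-copy time ties, so the Efron correction moves
  # the estimate a whisker; the point estimate stays put up to that effect
  expect_lt(abs(log(three$hr) - log(one$hr)), 0.02)
  width <- function(r) log(r$hr_ci_high) - log(r$hr_ci_low)
  expect_lt(width(three), width(one))
})

test_that("pooled queries fail informatively when nothing contributes", {
  a <- random_cohort("A", n = 20, seed = 61)
  comp <- assemble_compendium(list(a))
  expect_error(suppressMessages(pooled_query(comp, query_spec("absent_gene"))),
               "No cohort contributes")
  const <- a
  const$expression["g1", ] <- 1 # constant gene: everyone low
  expect_error(pooled_query(assemble_compendium(list(const)), query_spec("g1")),
               "single expression group")
})

test_that("multi-gene queries run the all-high combination within each cohort", {
  a <- random_cohort("A", n = 50, genes = c("g1", "g2"), seed = 71)
  comp <- assemble_compendium(list(a))
  res <- pooled_query(comp, query_spec(c("g1", "g2")))
  a1 <- assign_groups(a, "g1")
  a2 <- assign_groups(a, "g2")
  comb <- combine_all_high(list(a1, a2))
  expect_equal(res$n_high, sum(comb$group == "high"))
  expect_identical(sort(res$samples$sample_id[res$samples$group == "high"]),
                   sort(comb$sample_id[comb$group == "high"]))
})
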