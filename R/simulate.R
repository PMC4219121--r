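#' Configure a synthetic compendium
#'
#' The generator emulates the structure of a multi-platform expression
#' compendium with survival follow-up: several datasets with disjoint probe
#' vocabularies but overlapping Entrez gene content, dataset-specific
#' location and scale, duplicate and multi-mapping probes, missing values,
#' exponential-type survival with effects planted on the dichotomized scale
#' (group membership above/below the dataset median multiplies the hazard),
#' independent exponential censoring hitting the target rate exactly in
#' expectation, and partially missing clinical covariates.
#'
#' @param n_datasets Number of datasets (default 5).
#' @param n_samples Samples per dataset; scalar or vector of length
#'   `n_datasets` (default 200).
#' @param n_genes Size of the simulated gene universe (default 100).
#' @param gene_coverage Fraction of the universe covered per dataset
#'   (default 0.9); planted genes are always covered.
#' @param probes_per_gene Candidate probe counts per gene (default `1:3`).
#' @param multimap_fraction Fraction of additional probes mapping to two
#'   genes, to exercise the multi-mapping filter (default 0.05).
#' @param probe_noise_sd Probe-level measurement noise SD on the log scale
#'   (default 0.25).
#' @param location_shift_sd SD of the dataset-specific location shift
#'   (default 2).
#' @param scale_range Range of the dataset-specific scale factor (default
#'   `c(0.6, 1.6)`).
#' @param missing_rate Fraction of probe-level entries set missing
#'   (default 0.02).
#' @param planted_effects Named numeric vector of per-gene log hazard
#'   ratios (high versus low dichotomized group). Unnamed vectors are
#'   assigned to the first genes of the universe.
#' @param censoring_rate Target censoring fraction (default 0.3; must be
#'   <= 0.95).
#' @param baseline_mean Baseline mean survival in months for the low group
#'   (default 40).
#' @param clinical_missing_rate Missingness applied to clinical covariates
#'   (default 0.15).
#' @param seed Mandatory RNG seed.
#'
#' @return An object of class `survpool_sim_config`.
#' @export
sim_config <- function(n_datasets = 5, n_samples = 200, n_genes = 100,
                       gene_coverage = 0.9, probes_per_gene = 1:3,
                       multimap_fraction = 0.05, probe_noise_sd = 0.25,
                       location_shift_sd = 2, scale_range = c(0.6, 1.6),
                       missing_rate = 0.02, planted_effects = numeric(),
                       censoring_rate = 0.3, baseline_mean = 40,
                       clinical_missing_rate = 0.15, seed) {
  if (missing(seed)) abort("`seed` is mandatory in sim_config().")
  if (censoring_rate > 0.95) abort("Infeasible censoring target: must be <= 0.95.")
  if (censoring_rate < 0) abort("`censoring_rate` must be non-negative.")
  if (length(planted_effects) > n_genes) abort("More planted effects than genes.")
  probs <- c(gene_coverage, multimap_fraction, missing_rate, clinical_missing_rate)
  if (any(probs < 0 | probs > 1)) abort("Fractions must lie in [0, 1].")
  genes <- sprintf("%d", 100000 + seq_len(n_genes))
  if (length(planted_effects) > 0L) {
    if (is.null(names(planted_effects))) {
      names(planted_effects) <- genes[seq_along(planted_effects)]
    }
    if (!all(names(planted_effects) %in% genes)) {
      abort("Planted effect names must be gene ids of the simulated universe.")
    }
  }
  structure(
    list(
      n_datasets = n_datasets,
      n_samples = rep_len(n_samples, n_datasets),
      n_genes = n_genes, genes = genes, gene_coverage = gene_coverage,
      probes_per_gene = probes_per_gene, multimap_fraction = multimap_fraction,
      probe_noise_sd = probe_noise_sd, location_shift_sd = location_shift_sd,
      scale_range = scale_range, missing_rate = missing_rate,
      planted_effects = planted_effects, censoring_rate = censoring_rate,
      baseline_mean = baseline_mean,
      clinical_missing_rate = clinical_missing_rate,
      seed = as.integer(seed)
    ),
    class = "survpool_sim_config"
  )
}

#' Ground-truth table of a simulation configuration
#'
#' A deterministic function of the configuration alone (independent of the
#' random draws): the planted per-gene log hazard ratios.
#'
#' @param cfg A `survpool_sim_config`.
#'
#' @return A tibble with columns `gene` and `log_hr`.
#' @export
truth_table <- function(cfg) {
  if (!inherits(cfg, "survpool_sim_config")) abort("`cfg` must come from sim_config().")
  tibble(
    gene = names(cfg$planted_effects) %0% character(),
    log_hr = unname(cfg$planted_effects)
  )
}

# Draw survival under the planted dichotomized-effect model. Censoring with
# per-sample rate h * r / (1 - r) makes P(censored) = r exactly.
draw_survival <- function(hazard, censoring_rate) {
  n <- length(hazard)
  t_event <- rexp(n, rate = hazard)
  if (censoring_rate > 0) {
    t_cens <- rexp(n, rate = hazard * censoring_rate / (1 - censoring_rate))
  } else {
    t_cens <- rep(Inf, n)
  }
  list(time = pmin(t_event, t_cens), event = as.numeric(t_event <= t_cens))
}

simulate_clinical <- function(sample_ids, surv_os, surv_dfs, cfg) {
  n <- length(sample_ids)
  miss <- function(x) {
    x[runif(n) < cfg$clinical_missing_rate] <- NA
    x
  }
  tibble(
    sample_id = sample_ids,
    os_time = surv_os$time, os_event = surv_os$event,
    dfs_time = surv_dfs$time, dfs_event = surv_dfs$event,
    age = miss(round(rnorm(n, 60, 11))),
    figo_stage = miss(sample(1:4, n, replace = TRUE, prob = c(0.08, 0.08, 0.64, 0.20))),
    grade = miss(sample(1:3, n, replace = TRUE, prob = c(0.10, 0.35, 0.55))),
    histology = miss(sample(c("serous", "endometrioid", "other"), n,
                            replace = TRUE, prob = c(0.80, 0.10, 0.10))),
    residual_tumour = miss(sample(c("yes", "no"), n, replace = TRUE, prob = c(0.55, 0.45))),
    platinum = miss(sample(c("yes", "no"), n, replace = TRUE, prob = c(0.80, 0.20))),
    taxane = miss(sample(c("yes", "no"), n, replace = TRUE, prob = c(0.60, 0.40))),
    neoadjuvant = miss(sample(c("yes", "no"), n, replace = TRUE, prob = c(0.15, 0.85))),
    chemotherapy = miss(sample(c("yes", "no"), n, replace = TRUE, prob = c(0.85, 0.15)))
  )
}

#' Simulate a multi-platform compendium with known ground truth
#'
#' Generates `cfg$n_datasets` datasets according to the configuration (see
#' [sim_config()]) and assembles them into a compendium. Each dataset gets
#' its own probe vocabulary, probe multiplicities, location/scale profile
#' and missing-data mask; the planted hazard effects act on the
#' dichotomized (above/below the dataset median of the collapsed gene
#' value) groups, so the generator's truth is in exactly the units the
#' analysis estimates. With three or more datasets, the second dataset
#' carries only OS and the third only DFS, exercising endpoint-missingness
#' paths. When `dir` is given, probe-level matrices, probe maps, clinical
#' tables, a manifest and the truth table are also written to disk in the
#' package's text formats; the same seed yields byte-identical files.
#'
#' @param cfg A `survpool_sim_config`.
#' @param dir Optional output directory.
#'
#' @return A list (class `survpool_simulation`) with elements `compendium`
#'   (a `survpool_compendium` built from the collapsed matrices exactly as
#'   the reader pipeline would), `truth` (see [truth_table()]),
#'   `planted_cutoffs` (per dataset, the median cutoffs used when planting),
#'   and `manifest` (path, or `NULL`).
#' @export
simulate_compendium <- function(cfg, dir = NULL) {
  if (!inherits(cfg, "survpool_sim_config")) abort("`cfg` must come from sim_config().")
  with_seed(cfg$seed, {
    planted_genes <- names(cfg$planted_effects) %0% character()
    cohorts <- vector("list", cfg$n_datasets)
    planted_cutoffs <- list()
    files <- list()
    for (d in seq_len(cfg$n_datasets)) {
      ds_id <- sprintf("SIM%02d", d)
      n <- cfg$n_samples[[d]]
      sample_ids <- sprintf("%s_S%04d", ds_id, seq_len(n))
      n_cov <- max(length(planted_genes), round(cfg$gene_coverage * cfg$n_genes))
      others <- setdiff(cfg$genes, planted_genes)
      covered <- c(planted_genes,
                   sample(others, min(length(others), n_cov - length(planted_genes))))
      covered <- cfg$genes[cfg$genes %in% covered] # universe order
      latent <- matrix(rnorm(length(covered) * n), length(covered), n,
                       dimnames = list(covered, sample_ids))
      shift <- rnorm(1, 0, cfg$location_shift_sd)
      scale <- runif(1, cfg$scale_range[1L], cfg$scale_range[2L])
      k <- sample(cfg$probes_per_gene, length(covered), replace = TRUE)
      gene_of_probe <- rep(covered, k)
      n_probe <- length(gene_of_probe)
      probe_vals <- shift + scale * latent[gene_of_probe, , drop = FALSE] +
        matrix(rnorm(n_probe * n, 0, cfg$probe_noise_sd), n_probe, n)
      map_probes <- as.list(gene_of_probe)
      # ambiguous probes hybridizing two genes, to exercise the filter
      n_mm <- round(cfg$multimap_fraction * n_probe)
      if (n_mm > 0L && length(covered) >= 2L) {
        mm_vals <- matrix(NA_real_, n_mm, n)
        mm_map <- vector("list", n_mm)
        for (i in seq_len(n_mm)) {
          pair <- sample(covered, 2L)
          mm_vals[i, ] <- shift + scale * colMeans(latent[pair, , drop = FALSE]) +
            rnorm(n, 0, cfg$probe_noise_sd)
          mm_map[[i]] <- pair
        }
        probe_vals <- rbind(probe_vals, mm_vals)
        map_probes <- c(map_probes, mm_map)
      }
      probe_ids <- sprintf("%s_P%05d", ds_id, seq_len(nrow(probe_vals)))
      dimnames(probe_vals) <- list(probe_ids, sample_ids)
      names(map_probes) <- probe_ids
      if (cfg$missing_rate > 0) {
        mask <- matrix(runif(length(probe_vals)) < cfg$missing_rate,
                       nrow(probe_vals), ncol(probe_vals))
        probe_vals[mask] <- NA_real_
      }
      pmap <- probe_map(map_probes)
      gene_expr <- collapse_to_genes(probe_vals, suppressMessages(filter_multimapping(pmap)))

      # hazards act on the dichotomized groups the analysis will recover
      log_haz <- rep(0, n)
      cuts <- setNames(numeric(length(planted_genes)), planted_genes)
      for (g in planted_genes) {
        v <- gene_expr[g, ]
        cut <- suppressWarnings(compute_cutoff(v, "median"))
        cuts[[g]] <- cut
        hi <- !is.na(v) & v > cut
        log_haz <- log_haz + cfg$planted_effects[[g]] * hi
      }
      planted_cutoffs[[ds_id]] <- cuts
      hazard <- exp(log_haz) / cfg$baseline_mean
      surv_os <- draw_survival(hazard, cfg$censoring_rate)
      surv_dfs <- draw_survival(hazard, cfg$censoring_rate)
      clin <- simulate_clinical(sample_ids, surv_os, surv_dfs, cfg)
      if (cfg$n_datasets >= 3L && d == 2L) {
        clin$dfs_time <- NA_real_
        clin$dfs_event <- NA_real_
      }
      if (cfg$n_datasets >= 3L && d == 3L) {
        clin$os_time <- NA_real_
        clin$os_event <- NA_real_
      }
      platform <- sprintf("SIMCHIP-%d", (d - 1L) %% 7L + 1L)
      cohorts[[d]] <- assemble_cohort(ds_id, platform, gene_expr, clin, min_patients = 1)
      files[[d]] <- list(id = ds_id, platform = platform, probe_vals = probe_vals,
                         map = pmap, clin = clin)
    }
    comp <- assemble_compendium(cohorts)
    manifest <- NULL
    if (!is.null(dir)) {
      manifest <- write_simulation_files(files, truth_table(cfg), dir)
    }
    structure(
      list(
        compendium = comp,
        truth = truth_table(cfg),
        planted_cutoffs = planted_cutoffs,
        manifest = manifest
      ),
      class = "survpool_simulation"
    )
  })
}

write_simulation_files <- function(files, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(files, function(f) {
    efile <- paste0(f$id, "_expression.tsv")
    cfile <- paste0(f$id, "_clinical.tsv")
    mfile <- paste0(f$id, "_probemap.tsv")
    write_expression_matrix(f$probe_vals, file.path(dir, efile))
    write_clinical_table(f$clin, file.path(dir, cfile))
    long <- tibble(
      probe_id = rep(names(f$map), lengths(f$map)),
      entrez_id = unlist(unname(unclass(f$map)))
    )
    readr::write_tsv(long, file.path(dir, mfile), col_names = FALSE, progress = FALSE)
    list(
      id = f$id, platform = f$platform,
      expression = efile, clinical = cfile, probe_map = mfile,
      time_unit = "months"
    )
  })
  readr::write_tsv(truth, file.path(dir, "truth_table.tsv"), progress = FALSE)
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(datasets = unname(entries)), manifest)
  manifest
}

#' Simulate matched host-gene and miRNA expression matrices
#'
#' Generates a matched pair of matrices over the same samples in which a
#' chosen fraction of (host gene, miRNA) pairs share a latent expression
#' factor (co-expressed, as intronic miRNAs transcribed with their host)
#' while the remainder are independent noise. Used to validate
#' [vet_surrogates()] against a known co-expression fraction.
#'
#' @param n_pairs Number of miRNA/host pairs (default 100).
#' @param n_samples Number of shared samples (default 200).
#' @param shared_fraction Fraction of pairs sharing a latent factor
#'   (default 0.6); the count is rounded.
#' @param noise_sd Noise SD around the shared factor (default 1; with a
#'   unit-variance factor this gives a true correlation of 0.5).
#' @param seed Mandatory RNG seed.
#'
#' @return A list: `host_expr`, `mirna_expr`, `map` (a
#'   `survpool_mirna_map` with status `unknown`), and `truth` (tibble with
#'   `mirna` and logical `shared`).
#' @export
simulate_matched_mirna <- function(n_pairs = 100, n_samples = 200,
                                   shared_fraction = 0.6, noise_sd = 1, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  if (shared_fraction < 0 || shared_fraction > 1) abort("`shared_fraction` must be in [0, 1].")
  with_seed(seed, {
    samples <- sprintf("T_S%04d", seq_len(n_samples))
    mirnas <- sprintf("hsa-mir-sim-%03d", seq_len(n_pairs))
    hosts <- sprintf("%d", 900000 + seq_len(n_pairs))
    n_shared <- round(shared_fraction * n_pairs)
    host_expr <- matrix(NA_real_, n_pairs, n_samples, dimnames = list(hosts, samples))
    mirna_expr <- matrix(NA_real_, n_pairs, n_samples, dimnames = list(mirnas, samples))
    for (i in seq_len(n_pairs)) {
      if (i <= n_shared) {
        f <- rnorm(n_samples)
        host_expr[i, ] <- f + rnorm(n_samples, 0, noise_sd)
        mirna_expr[i, ] <- f + rnorm(n_samples, 0, noise_sd)
      } else {
        host_expr[i, ] <- rnorm(n_samples)
        mirna_expr[i, ] <- rnorm(n_samples)
      }
    }
    map <- structure(
      tibble(mirna = mirnas, host_gene = hosts, status = "unknown"),
      class = c("survpool_mirna_map", class(tibble()))
    )
    list(
      host_expr = host_expr, mirna_expr = mirna_expr, map = map,
      truth = tibble(mirna = mirnas, shared = seq_len(n_pairs) <= n_shared)
    )
  })
}
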