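---
title: "Pooled multi-cohort survival meta-analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled multi-cohort survival meta-analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Expression microarray cohorts of the same disease — here the motivating
case is ovarian cancer, where compendia of a dozen or more cohorts across
several array platforms exist — cannot be pooled on the raw intensity
scale: platforms differ in probe chemistry, dynamic range and location, so
a value of 7.2 on one chip has no relation to 7.2 on another. `survpool`
implements the simple, robust alternative used by gene-centred prognostic
meta-analysis tools: map every platform to a shared Entrez gene namespace,
dichotomize each gene **within each dataset** at that dataset's own median
(or quartile) of the gene's expression, and only then pool the resulting
high/low labels across datasets for a single survival analysis. Because
the labels are per-dataset ranks, any dataset-specific monotone distortion
of the intensity scale — a location shift, a scale change, compression at
the top of the dynamic range — leaves the analysis untouched. The same
property makes the method sensitive to presence/absence expression
changes: a gene moving from undetected to weakly expressed still changes
quartile within its dataset even though its absolute signal stays low.

## Pipeline

For each dataset the inputs are a probe-level (or gene-level) log-scale
expression matrix, a probe-to-Entrez map, and a clinical table with
overall-survival (OS) and/or disease-free-survival (DFS) follow-up in
months plus standard covariates (age, FIGO stage, grade, histology,
residual tumour, treatment flags).

1. **Gene centering.** Probes mapping to zero or to multiple Entrez genes
   are dropped (`filter_multimapping()`); where several probes remain for
   one gene their values are averaged per sample, arithmetically on the
   log scale, ignoring missing entries (`collapse_to_genes()`). Averaging
   on the log scale reflects that the upstream normalizations
   (GCRMA-style single-channel calls, loess-normalized two-channel
   ratios) already produce log-scale values. Optional quantile
   normalization (`quantile_normalize()`) is applied per dataset and
   never across datasets: cross-dataset effects are entirely handled by
   the per-dataset dichotomization, so normalizing across cohorts would
   add an assumption without buying anything. Normalization runs at the
   probe level, before collapsing; the order is a documented assumption
   of this implementation.
2. **Cohort assembly.** Expression and clinical tables align on their
   shared sample ids, in expression order; datasets below 50 aligned
   patients are rejected by default (`min_patients` overrides, e.g. for
   fixtures). Survival times are stored in months; manifests may declare
   per-dataset units (`days` are divided by 30.44, `years` multiplied
   by 12).
3. **Stratification.** `compute_cutoff()` uses the linear-interpolation
   (type 7) percentile definition — the default of the statistical
   environment this class of tools is built in. A sample is `high` when
   its value is strictly above the cutoff; values exactly at the cutoff
   go to `low`, which keeps the high group strictly above the cutoff and
   resolves the tie case the strict greater-than/less-than wording leaves
   open. Under the quartile cutoffs the default reading keeps all
   samples (above Q3 versus the rest, or below Q1 versus the rest); the
   alternative reading — top quarter versus bottom quarter, middle
   excluded — is available as `extremes_only = TRUE` because the
   published description is ambiguous between the two.
4. **Clinical filtering** happens *before* cutoff computation: a query on,
   say, platinum-treated stage III/IV patients defines its high/low
   groups on that selected population. Samples missing a constrained
   covariate are dropped by the filter; samples missing the chosen
   endpoint are dropped per query (a sample may carry OS but not DFS).
5. **Pooled analysis** (`pooled_query()`): the labelled samples from all
   contributing datasets are pooled for Kaplan-Meier curves per group, a
   two-group log-rank test (p two-sided from the chi-square with 1 df),
   and a Cox proportional-hazards fit of the single high-versus-low
   indicator with Efron tie handling, reported as a hazard ratio with a
   95% Wald interval. Multi-gene queries combine per-gene assignments
   within each cohort as *all-high versus the rest* before pooling.

## Statistical engine

Kaplan-Meier estimation and the log-rank test delegate to the standard
`survival` package (`survfit`, `survdiff`); both are nevertheless covered
by independent hand-tabulation oracles in the test suite. The Cox fit for
the single binary covariate is implemented in the package itself: the
Efron-corrected partial likelihood for a two-group comparison reduces to
closed-form sums over event times, and a Newton-Raphson iteration with
analytic score and information (convergence tolerance 1e-9 on the step,
at most 50 iterations, step-halving to keep the likelihood
non-decreasing) is both transparent and fast enough to run tens of
thousands of times in a screen. The fit is cross-checked in the tests
against `survival::coxph` and against direct maximization of the
written-out partial likelihood. A monotone likelihood (complete
separation of event orderings) is detected by divergence of the estimate
(|beta| > 15) and returned as a flagged result with an infinite
confidence interval rather than an error, since a screen must survive
degenerate genes. The pooled Cox is unstratified by default — the pooled
analysis is a single global fit — with a dataset-stratified baseline
available (`stratified = TRUE`) as a sensitivity analysis; for the
stratified fit, score and information simply sum over datasets.

## Transcriptome-wide screen

`screen_all_genes()` runs the pooled analysis for every gene in the
compendium's universe, skipping (and recording) genes with no analysable
pooled data, adjusts the per-gene p-values with Benjamini-Hochberg across
all tested genes, and ranks the significant rows by effect extremity,
`|log HR|`, so a protective hazard ratio of 1/h ranks level with a
deleterious one of h. BH is applied to the log-rank p-values by default;
the Wald p-values are available via `p_source = "wald"` since the
published description does not say which entered the adjustment.

**Concordance index.** Harrell's C is the probability that, of a usable
pair, the sample with the higher risk score fails earlier. A pair is
usable when the earlier observation is an event (or ties a censored time);
pairs tied on time with both events are excluded (Harrell's original
rule) and tied risks count 1/2. Expression intensities are not comparable
across platforms, so the per-gene C is computed within each dataset from
the gene's *continuous* expression and combined across datasets as the
usable-pair-weighted average; a pooled-within-dataset-rank mode exists as
an option (`c_mode = "pooled_rank"`). Whether the original tool used
continuous or dichotomized expression is unstated; continuous is the
default here because a C-index of a median split cannot exceed modest
values and the published per-gene values (~0.6) match continuous scoring.
For genes whose hazard ratio is below 1 the risk orientation is flipped
(risk = negated expression) so that discrimination is reported
orientation-free with an explicit direction flag — published tables
report C ≈ 0.6 for protective and deleterious genes alike. The empirical
p-value shuffles the survival information (time and event jointly,
within each dataset) `n_perm` times — 10,000 in the published protocol —
and counts shuffles with C at least the observed value; a count of zero
is reported as 0 with the add-one estimate (r+1)/(n_perm+1) attached,
matching the "< 1/n_perm" convention. Per-gene shuffle streams are
derived from the master seed and a hash of the gene id, so a gene's
p-value does not depend on which other genes were screened or in what
order.

## miRNA host-gene surrogacy

Intronic miRNAs co-transcribed with their host genes can be queried
through the host's array signal. `mirna_query()` delegates exactly to the
host gene's pooled query — the numbers are identical by construction —
and annotates the result with the miRNA, host gene, vetting status and a
caution flag whenever surrogacy has not been vetted as correlated.
`vet_surrogates()` performs that vetting on matched host/miRNA matrices:
Spearman correlation per mapped pair over shared samples (rank-based, so
platform scales and monotone distortions are immaterial; Pearson by
flag), BH adjustment across all vetted pairs, and `correlated` status for
adjusted p < 0.05 with positive correlation — a negative correlation
would invalidate the surrogate's direction even if significant.

## Synthetic compendium

Because the real compendium is external data, every claim the package
makes about itself is validated on a seeded generator
(`simulate_compendium()`) that emulates the structure that matters:

- several datasets with disjoint probe vocabularies, 1-3 probes per gene,
  ~5% additional two-gene (multi-mapping) probes, per-dataset location
  shifts (SD 2 log units) and scale factors (0.6-1.6), 2% missing
  entries, and ~90% gene coverage per dataset;
- exponential survival (baseline mean 40 months, the order of magnitude
  of published ovarian-cancer cohort means) with planted effects acting
  on the *dichotomized* group — a sample above its dataset's median for a
  planted gene multiplies its hazard by exp(beta) — so the generator's
  truth is in exactly the units the pipeline estimates;
- independent exponential censoring with per-sample rate h·r/(1-r),
  which hits the target censoring fraction r exactly in expectation
  (default 30%, typical of these cohorts);
- clinical covariates drawn from marginals resembling a high-grade
  serous-dominated case mix (80% serous, ~84% stage III/IV), with 15%
  missingness;
- with three or more datasets, the second dataset is OS-only and the
  third DFS-only, exercising the endpoint-missingness paths the real
  compendium's availability pattern forces.

The generator does **not** attempt microarray noise physics (probe
sequence or GC effects), batch artefacts beyond location/scale, dependent
censoring, or correlated expression between genes. Passing tests
therefore demonstrate correctness of the statistical machinery and
robustness to the distortions the method claims to absorb — not that any
particular real-data hazard ratio is right.

## Validation experiments and their sizes

The test suite runs five simulation experiments, sized to finish in a few
minutes on one CPU while keeping Monte-Carlo error well inside each
acceptance band:

- **Analytic anchors.** A risk score that reverse-orders 100 distinct
  uncensored times gives C = 1 exactly; the mean C of 1,000 random risk
  vectors on a fixed censored dataset (n = 100, 30% censoring) lies
  within 0.5 ± 0.02.
- **Oracle equivalence.** On 50 random instances (n ≤ 40, with and
  without time ties) KM, log-rank, Cox and C match the brute-force
  oracles to 1e-8.
- **Parameter recovery.** 100 replicates of a 5 × 200-sample compendium
  with one planted twofold dichotomized effect and 30% censoring: the
  true HR of 2 falls inside the reported 95% CI in at least 90
  replicates (nominal coverage 95%).
- **Null calibration.** 20 all-null runs of 200 genes over 600 pooled OS
  samples: 5% ± 1.5% of the 4,000 raw log-rank p-values fall below 0.05,
  and at most 1 run in 20 shows any BH-adjusted p < 0.05. Under the
  global null BH rejects somewhere with probability close to 0.05 per
  run (Simes), so this is a sharp check by construction.
- **Screen recovery.** 20 compendia of 7 × 200 samples (~1,190 pooled OS
  samples), 1,000 genes, ten planted effects. Ten coexisting
  proportional-hazards effects attenuate each other's *marginal*
  single-gene hazard ratios — the non-collapsibility of the HR acts like
  a frailty shared by every per-gene fit — so the conditional planted
  magnitudes are set to 2.8-fold (five deleterious, five protective),
  which yields realized marginal dichotomized effects of roughly 1.5- to
  1.75-fold, at or above the 1.5-fold detectability floor this
  experiment targets; a conditional 1.5-fold effect would shrink to
  ~1.2-fold marginally and be undetectable at any sample size. All ten
  planted genes must appear in the top 20 by |log HR| among
  BH-significant rows in at least 18 of 20 seeds.
- **Surrogate vetting.** 20 matched host/miRNA sets (100 pairs × 200
  samples) with exactly 60% of pairs sharing a unit-variance latent
  factor under unit noise (true correlation 0.5): the estimated
  correlated fraction stays within ±7 percentage points of 60%.

## Numerical and degenerate-input conventions

- Percentiles: type 7 (linear interpolation) everywhere.
- Cutoff ties go to `low`; constant genes put every sample in `low` and
  the query errors cleanly on the resulting single group.
- Fewer than two non-missing values in a dataset: that dataset is
  skipped for that gene, with a warning.
- Quantile normalization: ties receive the mean of the reference values
  at their tied rank positions; missing entries are excluded from
  ranking via interpolation on the quantile scale and restored as
  missing; a single-column matrix is returned unchanged with a warning.
- Newton-Raphson: start at beta = 0, tolerance 1e-9 on the step, max 50
  iterations, step-halving on likelihood decrease, |beta| > 15 flags a
  monotone likelihood.
- All randomness (permutation p-values, the generator) flows through
  explicit seeds; internal RNG use never perturbs the caller's stream.

## Known limitations

- The pooled Cox fits a single binary covariate; clinical heterogeneity
  is handled by filtering, never by covariate adjustment, mirroring the
  method it implements.
- Marginal per-gene hazard ratios are attenuated when many true effects
  coexist (see above); a screening tool inherits this by design.
- The miRNA module infers expression from host genes; the vetting module
  quantifies but cannot remove the resulting uncertainty for
  non-co-expressed pairs.
- No proportional-hazards diagnostics, time-varying effects, or
  multivariable models are provided; they are out of scope for this
  method.
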