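---
title: "Methods: from differentiation omics to a prognostic methylation signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from differentiation omics to a prognostic methylation signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocdsig)
```

`ocdsig` turns a staged ovarian cancer stem-cell (OCSC) differentiation
methylome/transcriptome into a prognostic promoter-methylation signature.
This vignette is the package's own account of the underlying model: what
each stage computes, which conventions were pinned down where several
readings were defensible, what the synthetic-data generator does and does
not emulate, and where the method's limits are.

## 1. The differentiation model and phase contrasts

The substrate is a pair of gene-by-stage matrices over six stages: two
spheroid stem/progenitor stages (SR1, SR2) and four adherent differentiated
progenies (AD1–AD4). Methylation is a promoter-window beta fraction in
[0, 1]; expression is a positive array intensity. Differentiation is
summarized by three *phase contrasts*, each comparing a baseline group of
stages against a more differentiated comparison group:

| phase | baseline  | comparison | interpretation              |
|-------|-----------|------------|-----------------------------|
| A     | SR1       | SR2        | within the spheroid state   |
| B     | SR1, SR2  | AD1, AD2   | spheroid to early adherent  |
| C     | AD1, AD2  | AD3, AD4   | early to late adherent      |

Group summaries are unweighted arithmetic means of stage values (phase B's
baseline pools SR1 and SR2 with equal weight, since the spheroid stages are
presented as one biological group). Single-stage groups are allowed: the
design has one sample per stage, so contrasts are thresholded point
contrasts, not variance-based tests.

Per gene and phase we compute the beta difference `delta_beta`
(comparison minus baseline; negative = hypomethylation along
differentiation) and the linear-scale fold change (ratio of group means).
A gene is differentially methylated (DMR) at `|delta_beta| >= 0.10` and
differentially expressed (DEG) at fold change `>= 1.5` or `<= 1/1.5`. Both
thresholds are *closed*: boundary values are flagged. Because group means
are floating-point quantities, the comparisons carry an absolute guard of
1e-9 so that an exactly-10-percentage-point change (e.g. 0.50 vs 0.40,
which base R represents as 0.09999999999999998) is flagged as intended.

Candidates are the discordant pairs only — hypomethylated with higher
expression (`hypo_up`) or hypermethylated with lower expression
(`hyper_down`) — matching the biological expectation that promoter
methylation represses transcription. Concordant pairs and single-omic hits
are dropped. A gene may be a candidate in more than one phase; the pooled
candidate list therefore counts distinct (gene, phase) pairs. Whether a
recurring gene should be deduplicated across phases is genuinely open; we
count pairs because the per-phase tallies are the quantities the selection
is anchored to.

Two small genomic utilities support the upstream bookkeeping: the promoter
window is defined as 1 kb either side of the TSS (2 kb total, symmetric, so
strand does not alter it), in 0-based half-open coordinates clipped at 0;
and capture samples are retained when uniquely mapped reads are at least
40% of mapped reads (inclusive threshold).

## 2. The recurrent risk score

The RRS asks whether a gene's methylation level is *recurrently* associated
with progression-free survival (PFS), rather than significant under one
arbitrary dichotomization. For one gene in one cohort:

* **Cutoff grid** — five sample quantiles of the analyzed patients' values:
  25%, 33.3%, 50%, 66.7%, 75%. Quantiles use linear interpolation between
  order statistics (R type 7), pinned for reproducibility.
* **Endpoints** — PFS at 1.5 years, 3 years, and overall. The finite
  horizons are implemented as administrative censoring (times beyond the
  horizon become censored at it). A landmark-binary reading of the
  endpoints would also have been defensible; administrative censoring keeps
  the full time axis and the log-rank machinery uniform across endpoints.
* **Vote** — patients at or below the cutoff are `low` (ties go low, a
  declared deterministic rule), and the two arms are compared by the
  two-group log-rank test. With two-sided p below `alpha` (default 0.05,
  exposed as a parameter), the condition votes +1 if the *low* arm has the
  excess of observed over expected events, −1 if the *high* arm does;
  otherwise 0. The direction is read post hoc from the O−E sign; a
  one-sided formulation would differ only in the effective per-condition
  level.

The RRS is the sum over the fixed 5 × 3 grid: an integer in [−15, 15].
Degenerate conditions — an empty arm (all values on one side of a tied
cutoff) or no events after endpoint restriction — vote 0 rather than
erroring, so the grid total is defined for every gene.

No multiple-testing correction is applied inside the grid or across genes
by default; the grid's 15 conditions are heavily correlated, and the
de facto error control is the requirement that the score replicate in two
independent cohorts. (A Benjamini–Hochberg option across genes exists for
sensitivity analyses.) The concordance rule is the stricter of the two
plausible readings: selection requires `RRS > 1` in both cohorts (or
`< −1` in both), i.e. |total| ≥ 2 twice; the laxer "same nonzero sign in
both" reading is available via `rule = "sign"`.

## 3. Signature, risk groups and survival evaluation

Selected genes become a signature: each entry is a gene, a risk direction
(positive RRS totals mean low values are unfavourable →
`low_value_at_risk`), and a dichotomization cutoff. Which cutoff to carry
into the signature is not determined by the selection itself; the default
takes the gene's grid cutoff with the smallest overall-endpoint log-rank
p-value in a reference cohort, with the median as a configurable fallback.

A patient's *genes at risk* is the count of signature genes on their
unfavourable side (ties at the cutoff count as at risk for low-value-risk
genes, consistent with the global ties-go-low rule). Groups are 0–1, 2, and
≥3 genes at risk — adding a gene at risk can never demote a patient.
Evaluation uses standard machinery, deliberately delegated to the
`survival` package rather than re-derived: Kaplan–Meier product-limit
curves (censoring ties processed after events), the k-sample log-rank test,
and Cox proportional-hazards fits with Efron tie handling and Wald 95% CIs.
Reference levels mirror the clinical table layout: risk group "0–1", Early
stage, grade G1, Optimal debulking. Separation or event-free levels are
flagged non-estimable rather than reported with meaningless CIs. The test
suite cross-checks this machinery against independent brute-force oracles
(per-event-time 2×2 hypergeometric tables for the log-rank statistic; the
product-limit definition for KM), so the package's use of `survival` is
verified, not assumed.

Survival probabilities at a horizon (e.g. 60 months) are read off the KM
step function right-continuously: the value at the largest event time not
exceeding the horizon, 1 if no event has occurred by then.

## 4. Immune context

As in-package surrogates for external infiltration tooling, the package
correlates a gene's values with per-patient immune scores (CTL, M1, M2,
Tfh, CAF) — Pearson by default for expression/score pairs, Spearman as the
guard for bounded betas — and compares survival across the four joint
gene-high/low × infiltrate-high/low strata. Strata are cut at medians by
default (the external tools' internal cutpoints are not public), ties going
low; empty strata are reported with n = 0 and excluded from the log-rank
test with the degrees of freedom reduced. The "worst" stratum is the one
with the lowest KM survival at the evaluation horizon (default 60 months).

## 5. The synthetic-data generator

The generator exists so that every downstream stage has inputs with known
ground truth. It emulates structure, not biology:

* **Stage omics.** Null genes are flat at a uniform(0.3, 0.7) baseline beta
  and a log-normal expression baseline, with per-sample Gaussian noise
  (`noise_sd_beta`, default 0.01 on the beta scale; `noise_sd_log_expr`,
  default 0.05 on the log scale). Planted genes change by
  `planted_delta_beta` (default 0.25) and `planted_fc` (default 2.0).
  Genes planted in phases B and C change as a persistent step at the
  phase's first comparison stage — methylation acquired during
  differentiation persists in the progeny. A phase-A change (SR1 vs SR2,
  both spheroid) is planted at SR2 with the adherent stages settling at the
  SR1/SR2 average; this makes the phase-B contrast cancel exactly, so each
  planted gene registers in exactly one phase for any effect size. The
  configuration validator enforces a null-calibration guard: the noise SD
  must keep a null gene's probability of crossing the 0.10 DMR threshold
  below 1e-6 (worst case is the 1-vs-1 phase-A contrast), so planted-count
  recovery is exact rather than approximate. Default effect sizes are
  chosen for clean separation between planted and null genes, not to mimic
  any measured effect-size distribution, which is unreported for the
  original candidates.
* **Survival cohorts.** Betas are uniform(0.2, 0.8) per patient and gene,
  keeping all five quantile cutoffs distinct and the dichotomizations
  non-degenerate. Event times follow an exponential proportional-hazards
  model: the baseline rate (default 0.04/month, i.e. a median PFS of about
  17 months, typical of advanced EOC) is multiplied by each risk gene's
  hazard ratio for patients on its risk side of the cohort median — below
  for hypomethylation-risk genes, mirroring the screen's orientation.
  Censoring is an independent exponential (default 0.01/month) plus an
  administrative horizon (default 120 months); the event flag is 1 iff the
  event time is smallest. Exponential hazards are the simplest model
  consistent with Cox evaluation: closed-form, fast, and HR-recoverable.
  Clinical covariates (stage, grade, debulk) are drawn from configurable
  category probabilities and are hazard-linked only when `covariate_hr` is
  set — off by default so signature-recovery tests are unconfounded;
  multivariate-adjustment tests switch it on.
* **Immune profiles.** Scores are standard normal; planted links rebuild a
  score as `sign * 0.5 * z(gene) + sqrt(0.75) * noise`, giving an expected
  Pearson correlation of ±0.5. A separate single-cohort generator raises
  the hazard multiplicatively in the joint gene-high/cell-high stratum for
  the joint-strata analysis.

Determinism: a configuration (including its seed) fully determines all
output; different generator stages use decorrelated sub-streams of the one
seed, and the caller's RNG state is restored afterwards.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: probe-level microarray artefacts and
normalization, read-level sequencing noise, beta-value distributional shape
(real promoter betas are bimodal, not uniform), inter-gene correlation
(each gene is independent), non-proportional or time-varying hazards,
informative censoring, and cohort heterogeneity beyond independent
resampling of the same configuration.

## 6. Test problem sizes

The property suites run at sizes chosen to make their statistical
assertions sharp while keeping the suite quick to run: null calibration of
the dual-cohort concordance over 200 replicate cohort pairs of 100 patients
(selection rate required below 10%); planted-effect recovery (HR 2.5,
300 patients per cohort) over 50 replicates requiring concordant totals of
at least +2 in 90%; Cox log-HR recovery within 10% at 2000 patients; and
joint-stratum identification (hazard multiplier 3, 400 patients) over 50
replicates at 90%. The integration reconstruction plants the published
per-phase candidate counts (95/32/3 hypomethylated-up, 184/1/21
hypermethylated-down) among 6000 genes and requires the pooled count of
336 exactly.

## 7. Known limitations

* The RRS's 15 conditions are strongly dependent (nested cutoffs, nested
  endpoints); the score is a robustness heuristic, not a calibrated test
  statistic, and its null distribution is wider than naive binomial
  intuition suggests — hence the dual-cohort requirement.
* Administrative-censoring endpoints and post-hoc-signed two-sided log-rank
  tests are pinned conventions; alternatives (landmark analyses, one-sided
  tests) would change individual votes, though rarely concordant selection.
* The signature cutoff is chosen by overall-endpoint fit in a reference
  cohort, which is mildly optimistic in that cohort; evaluation should use
  the other cohort, as in the worked example.
* Clinical covariates enter the Cox models as fixed categories; no
  time-dependent covariates, competing risks, or imputation of missing
  signature genes (complete-case grouping only).
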