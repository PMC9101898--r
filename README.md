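# ocdsig

Prognostic DNA-methylation gene signatures from cancer stem-cell
differentiation omics.

## The problem

Epithelial ovarian cancer (EOC) is usually diagnosed late and relapses
often; markers that stratify progression risk are scarce. One route to such
markers starts from the biology of ovarian cancer stem cells (OCSCs): genes
that become epigenetically reprogrammed while OCSCs differentiate are
candidates for clinically relevant methylation changes. `ocdsig` implements
that analytic chain as a tested, reusable R pipeline:

1. **Omics integration.** Given promoter methylation (beta fractions over a
   2 kb window centred on the TSS) and expression intensities for six
   differentiation stages — spheroid stem stages SR1, SR2 and adherent
   progenies AD1–AD4 — three phase contrasts are evaluated
   (A: SR1 vs SR2; B: SR1+SR2 vs AD1+AD2; C: AD1+AD2 vs AD3+AD4).
   A gene is a *candidate* in a phase when its group-mean beta changes by
   ≥ 10 percentage points, its expression changes ≥ 1.5-fold, and the two
   changes are discordant (hypomethylated-with-upregulation or
   hypermethylated-with-downregulation).
2. **Recurrent risk score (RRS).** For each candidate gene and each of two
   independent survival cohorts, patients are dichotomized at five quantile
   cutoffs (25%, 33.3%, 50%, 66.7%, 75%) and compared by the log-rank test
   at three progression-free-survival endpoints (18 months, 36 months,
   overall) — 15 conditions. A condition votes +1 when the low-methylation
   arm has significantly inferior survival, −1 when the high arm does, 0
   otherwise:

   RRS = Σ over the 5 × 3 grid of sign(condition), RRS ∈ [−15, 15].

   Genes with RRS > 1 in both cohorts (or < −1 in both) are selected.
3. **Signature stratification.** Selected genes form a signature; each
   patient is coded by the number of genes on their unfavourable side
   ("genes at risk") and grouped 0–1 / 2 / ≥3. Separation is evaluated by
   Kaplan–Meier curves, the k-sample log-rank test, and univariate /
   multivariate Cox proportional-hazards models (crude and adjusted HRs
   with Wald 95% CIs).
4. **Immune context.** Gene values are correlated with immune-infiltration
   scores (CTL, M1, M2, Tfh, CAF), and survival is compared across the four
   joint gene-high/low × infiltrate-high/low strata.

A synthetic-data module simulates all required inputs — stage omics with
planted phase-specific changes, paired survival cohorts with planted
proportional-hazards effects under an exponential model, and immune
profiles with planted correlations — so every stage of the pipeline is
testable without any download.

## Worked example

Simulate two 300-patient cohorts with five planted hypomethylation-risk
genes, screen by dual-cohort RRS, derive a signature, and evaluate it on
the second cohort:

```r
library(ocdsig)

cfg <- sim_config(
  seed = 101, n_genes = 50, n_patients_per_cohort = 300,
  risk_genes = data.frame(
    gene = sprintf("gene_%05d", 1:5),
    direction = "hypo",
    hazard_ratio = c(2.5, 2.2, 2.0, 1.8, 1.8)
  )
)
cohorts <- simulate_survival_cohorts(cfg)

screen <- rrs_screen(cohorts$cohort_a, cohorts$cohort_b,
                     genes = sprintf("gene_%05d", 1:6))
screen
#>         gene total_a total_b            verdict
#> 1 gene_00001       9      15 selected_hypo_risk
#> 2 gene_00002      12       9 selected_hypo_risk
#> 3 gene_00003      12      10 selected_hypo_risk
#> 4 gene_00004      15      15 selected_hypo_risk
#> 5 gene_00005      15      12 selected_hypo_risk
#> 6 gene_00006       0       0       not_selected
```

All five planted genes reach strongly positive vote totals in both cohorts
(low methylation recurrently associated with inferior survival); the null
gene scores 0. Build the signature and stratify:

```r
spec <- derive_signature_from_rrs(screen, cohorts$cohort_a)
risk <- code_risk(cohorts$cohort_b, spec)
table(risk$group)
#> 0-1   2 >=3
#>  93 100 107

m <- match(risk$patient_id, cohorts$cohort_b$data$patient_id)
multi_group_logrank(cohorts$cohort_b$data$time_months[m],
                    cohorts$cohort_b$data$event[m], risk$group)$p
#> [1] 1.85e-14

cox_univariate(cohorts$cohort_b, "risk_group", risk = risk)
#>         term level   hr ci_low ci_high        p reference estimable
#> 1 risk_group   0-1 1.00     NA      NA       NA      TRUE      TRUE
#> 2 risk_group     2 1.93   1.40    2.65 4.84e-05     FALSE      TRUE
#> 3 risk_group   >=3 3.56   2.57    4.94 2.59e-14     FALSE      TRUE
```

Patients with ≥3 genes at risk progress 3.6 times faster than those with
0–1; 12-month progression-free survival falls from 28.6% (0–1) through
9.7% (2) to 0% (≥3).

A thin command-line front end over the same functions ships at
`inst/cli/ocdsig.R` (subcommands `simulate`, `integrate`, `rrs`,
`signature`, `immune`; all I/O is headered TSV).

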