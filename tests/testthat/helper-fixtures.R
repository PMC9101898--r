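# Shared small fixtures, all generated in code.

# zero-noise stage omics with 2 hypo-up + 1 hyper-down genes planted in phase A
fixture_planted_A <- function(seed = 42) {
  sim_config(
    seed = seed, n_genes = 100,
    planted_per_phase = list(A = c(2, 1), B = c(0, 0), C = c(0, 0)),
    noise_sd_beta = 0, noise_sd_log_expr = 0
  )
}

# a tiny hand-built stage omics: one gene per scenario, exact group means
fixture_manual_omics <- function() {
  stages <- c("SR1", "SR2", "AD1", "AD2", "AD3", "AD4")
  beta <- rbind(
    flat = rep(0.5, 6),
    hypoA = c(0.50, 0.35, 0.35, 0.35, 0.35, 0.35),
    subthr = c(0.50, 0.41, 0.41, 0.41, 0.41, 0.41)
  )
  expr <- rbind(
    flat = rep(10, 6),
    hypoA = c(10, 15, 15, 15, 15, 15),
    subthr = c(10, 10, 10, 10, 10, 10)
  )
  colnames(beta) <- colnames(expr) <- stages
  stage_omics(beta, expr)
}

# small two-cohort simulation with one planted hypomethylation-risk gene
fixture_risky_cohorts <- function(seed = 11, hr = 2.5, n = 300, n_genes = 3) {
  cfg <- sim_config(
    seed = seed, n_genes = n_genes, n_patients_per_cohort = n,
    risk_genes = data.frame(gene = "gene_00001", direction = "hypo",
                            hazard_ratio = hr)
  )
  simulate_survival_cohorts(cfg)
}

# deterministic toy cohort from explicit vectors
toy_cohort <- function(time, event, values, cohort_id = "toy") {
  survival_cohort(
    data.frame(
      patient_id = sprintf("p%02d", seq_along(time)),
      time_months = time, event = event, g1 = values,
      stringsAsFactors = FALSE
    ),
    genes = "g1", cohort_id = cohort_id
  )
}
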