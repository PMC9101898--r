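#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator: planted
#' phase-specific methylation/expression changes for the stage-omics
#' matrices, planted proportional-hazards methylation--survival effects for
#' the paired survival cohorts, and planted gene--immune-score links.
#'
#' Planted effect genes are carved out of the gene pool sequentially, so the
#' per-phase and per-class sets are pairwise disjoint by construction.
#'
#' @param seed integer seed; identical configurations give identical output.
#' @param n_genes number of genes simulated.
#' @param planted_per_phase named list over phases `A`, `B`, `C`; each entry
#'   a length-2 vector `c(hypo_up, hyper_down)` counting genes planted as
#'   hypomethylated-with-upregulation and hypermethylated-with-downregulation
#'   in that phase's contrast.
#' @param planted_delta_beta magnitude of the planted group-mean beta change
#'   (fraction, in (0, 1\]).
#' @param planted_fc planted expression fold change (must exceed the 1.5-fold
#'   selection threshold).
#' @param noise_sd_beta per-sample Gaussian noise SD on betas. Must be small
#'   enough that a null gene crosses the 10-percentage-point differential
#'   methylation threshold with probability below 1e-6.
#' @param noise_sd_log_expr per-sample Gaussian noise SD on log expression.
#' @param n_patients_per_cohort patients per simulated survival cohort.
#' @param risk_genes data.frame with columns `gene`, `direction`
#'   (`"hypo"`: hazard raised when the patient's beta is below the cohort
#'   median; `"hyper"`: above), `hazard_ratio`.
#' @param baseline_hazard baseline event rate, events per month.
#' @param censor_rate independent exponential censoring rate, events per month.
#' @param max_follow_up administrative censoring horizon in months (>= 60).
#' @param covariate_probs named list of category probabilities for `stage`,
#'   `grade`, `debulk`.
#' @param covariate_hr optional named list of per-level hazard ratios, e.g.
#'   `list(stage = c(Late = 3.5))`; off (all 1) by default so that signature
#'   recovery tests are unconfounded.
#' @param immune_link data.frame with columns `gene`, `cell_type`
#'   (one of CTL, M1, M2, Tfh, CAF), `sign` (+1/-1): planted correlation
#'   between the gene's cohort values and that immune score.
#' @param immune_joint_hazard optional data.frame with columns `gene`,
#'   `cell_type`, `hazard_multiplier`: extra hazard applied to patients in
#'   the gene-high & cell-high joint stratum (used by
#'   [simulate_joint_immune_cohort()]).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 500L,
                       planted_per_phase = list(A = c(0L, 0L),
                                                B = c(0L, 0L),
                                                C = c(0L, 0L)),
                       planted_delta_beta = 0.25,
                       planted_fc = 2.0,
                       noise_sd_beta = 0.01,
                       noise_sd_log_expr = 0.05,
                       n_patients_per_cohort = 300L,
                       risk_genes = NULL,
                       baseline_hazard = 0.04,
                       censor_rate = 0.01,
                       max_follow_up = 120,
                       covariate_probs = list(
                         stage = c(Early = 0.25, Late = 0.75),
                         grade = c(G1 = 0.10, G2 = 0.30, G3 = 0.60),
                         debulk = c(Optimal = 0.60, Suboptimal = 0.40)
                       ),
                       covariate_hr = NULL,
                       immune_link = NULL,
                       immune_joint_hazard = NULL) {
  seed <- as.integer(seed)
  n_genes <- as.integer(n_genes)
  if (is.na(seed)) stopf("seed must be an integer")
  if (n_genes < 1L) stopf("n_genes must be positive")

  phases <- c("A", "B", "C")
  if (!all(phases %in% names(planted_per_phase))) {
    stopf("planted_per_phase must name phases A, B and C")
  }
  counts <- lapply(planted_per_phase[phases], function(x) {
    x <- as.integer(x)
    if (length(x) != 2L || anyNA(x) || any(x < 0L)) {
      stopf("each planted_per_phase entry must be c(hypo_up, hyper_down) >= 0")
    }
    x
  })
  if (sum(unlist(counts)) > n_genes) {
    stopf("planted gene counts (%d) exceed n_genes (%d)",
          sum(unlist(counts)), n_genes)
  }

  if (planted_delta_beta <= 0 || planted_delta_beta > 1) {
    stopf("planted_delta_beta must lie in (0, 1]")
  }
  if (planted_fc <= 1.5) stopf("planted_fc must exceed 1.5")
  if (noise_sd_beta < 0 || noise_sd_log_expr < 0) {
    stopf("noise SDs must be nonnegative")
  }
  # null-gene false-DMR guard: worst case is a 1-vs-1 stage contrast, where
  # the group-mean delta of a null gene is N(0, sqrt(2) * noise_sd_beta)
  if (noise_sd_beta > 0) {
    p_cross <- 2 * stats::pnorm(-0.10, sd = sqrt(2) * noise_sd_beta)
    if (p_cross > 1e-6) {
      stopf("noise_sd_beta = %g lets null genes cross the 0.10 DMR threshold with probability %.2g > 1e-6",
            noise_sd_beta, p_cross)
    }
  }

  n_patients_per_cohort <- as.integer(n_patients_per_cohort)
  if (n_patients_per_cohort < 1L) stopf("n_patients_per_cohort must be positive")
  if (baseline_hazard <= 0 || censor_rate <= 0) {
    stopf("baseline_hazard and censor_rate must be strictly positive")
  }
  if (max_follow_up < 60) stopf("max_follow_up must be at least 60 months")

  if (!is.null(risk_genes)) {
    risk_genes <- as.data.frame(risk_genes)
    need <- c("gene", "direction", "hazard_ratio")
    if (!all(need %in% names(risk_genes))) {
      stopf("risk_genes needs columns: %s", paste(need, collapse = ", "))
    }
    if (!all(risk_genes$direction %in% c("hypo", "hyper"))) {
      stopf("risk_genes$direction must be 'hypo' or 'hyper'")
    }
    if (any(risk_genes$hazard_ratio <= 0)) {
      stopf("hazard ratios must be positive")
    }
    if (anyDuplicated(risk_genes$gene)) stopf("risk_genes must be unique")
  }

  for (nm in c("stage", "grade", "debulk")) {
    p <- covariate_probs[[nm]]
    if (is.null(p) || is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stopf("covariate_probs$%s must be named probabilities summing to 1", nm)
    }
  }

  if (!is.null(immune_link)) {
    immune_link <- as.data.frame(immune_link)
    need <- c("gene", "cell_type", "sign")
    if (!all(need %in% names(immune_link))) {
      stopf("immune_link needs columns: %s", paste(need, collapse = ", "))
    }
    bad <- setdiff(immune_link$cell_type, immune_cell_types())
    if (length(bad)) {
      stopf("unknown immune cell type(s): %s", paste(bad, collapse = ", "))
    }
    if (!all(immune_link$sign %in% c(-1, 1))) {
      stopf("immune_link$sign must be +1 or -1")
    }
  }

  if (!is.null(immune_joint_hazard)) {
    immune_joint_hazard <- as.data.frame(immune_joint_hazard)
    need <- c("gene", "cell_type", "hazard_multiplier")
    if (!all(need %in% names(immune_joint_hazard))) {
      stopf("immune_joint_hazard needs columns: %s", paste(need, collapse = ", "))
    }
    bad <- setdiff(immune_joint_hazard$cell_type, immune_cell_types())
    if (length(bad)) {
      stopf("unknown immune cell type(s): %s", paste(bad, collapse = ", "))
    }
    if (any(immune_joint_hazard$hazard_multiplier <= 0)) {
      stopf("hazard multipliers must be positive")
    }
  }

  structure(
    list(
      seed = seed,
      n_genes = n_genes,
      planted_per_phase = counts,
      planted_delta_beta = planted_delta_beta,
      planted_fc = planted_fc,
      noise_sd_beta = noise_sd_beta,
      noise_sd_log_expr = noise_sd_log_expr,
      n_patients_per_cohort = n_patients_per_cohort,
      risk_genes = risk_genes,
      baseline_hazard = baseline_hazard,
      censor_rate = censor_rate,
      max_follow_up = max_follow_up,
      covariate_probs = covariate_probs,
      covariate_hr = covariate_hr,
      immune_link = immune_link,
      immune_joint_hazard = immune_joint_hazard
    ),
    class = "sim_config"
  )
}

#' Immune cell types known to the simulator and immune-context analyses
#' @return character vector of score labels.
#' @export
immune_cell_types <- function() c("CTL", "M1", "M2", "Tfh", "CAF")

# stage labels and the per-phase changepoint column index: a change planted
# for phase B or C appears from that stage onward (epigenetic marks acquired
# during differentiation persist in the progeny stages). A phase A change
# (SR1 vs SR2) is planted at SR2, and the adherent stages settle at the
# SR1/SR2 average so the phase B contrast (which pools SR1+SR2 as its
# baseline) cancels exactly for any effect size.
.STAGES <- c("SR1", "SR2", "AD1", "AD2", "AD3", "AD4")
.PHASE_CHANGEPOINT <- c(A = 2L, B = 3L, C = 5L)

#' Simulate stage-omics matrices with planted phase-specific changes
#'
#' Generates gene-by-stage methylation and expression matrices over SR1,
#' SR2, AD1--AD4. Genes planted in phase B or C change as a persistent step
#' at that phase's changepoint stage: a hypo-up gene's beta drops by
#' `planted_delta_beta` and its expression rises `planted_fc`-fold from that
#' stage onward; hyper-down genes are mirror-imaged. Genes planted in phase
#' A change at SR2 and then settle at the SR1/SR2 average in the adherent
#' stages, so each planted gene registers in exactly one phase contrast.
#' Null genes are flat apart from per-sample noise, so their group-mean
#' contrasts stay well inside the 10-percentage-point / 1.5-fold selection
#' thresholds.
#'
#' @param config a [sim_config()].
#' @return list with elements `omics` (a [stage_omics()]) and `truth`
#'   (planted ground truth: `candidates` data.frame with columns `gene`,
#'   `phase`, `class`, and `risk_genes` as configured).
#' @export
simulate_stage_omics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(seed_stream(config$seed, 1L), {
    n <- config$n_genes
    genes <- sprintf("gene_%05d", seq_len(n))

    # carve disjoint planted sets off the front of the gene list
    truth <- data.frame(gene = character(), phase = character(),
                        class = character(), stringsAsFactors = FALSE)
    cursor <- 0L
    for (phase in c("A", "B", "C")) {
      k <- config$planted_per_phase[[phase]]
      for (cls in c("hypo_up", "hyper_down")) {
        nk <- if (cls == "hypo_up") k[[1L]] else k[[2L]]
        if (nk > 0L) {
          idx <- cursor + seq_len(nk)
          truth <- rbind(truth, data.frame(
            gene = genes[idx], phase = phase, class = cls,
            stringsAsFactors = FALSE
          ))
          cursor <- cursor + nk
        }
      }
    }

    base_beta <- stats::runif(n, 0.30, 0.70)
    base_expr <- exp(stats::rnorm(n, mean = log(100), sd = 0.5))

    beta <- matrix(base_beta, nrow = n, ncol = 6,
                   dimnames = list(genes, .STAGES))
    expr <- matrix(base_expr, nrow = n, ncol = 6,
                   dimnames = list(genes, .STAGES))

    if (nrow(truth)) {
      for (i in seq_len(nrow(truth))) {
        g <- truth$gene[i]
        sgn <- if (truth$class[i] == "hypo_up") -1 else 1
        fc <- if (truth$class[i] == "hypo_up") config$planted_fc else
          1 / config$planted_fc
        if (truth$phase[i] == "A") {
          beta[g, 2L] <- beta[g, 2L] + sgn * config$planted_delta_beta
          expr[g, 2L] <- expr[g, 2L] * fc
          # adherent stages hold the SR1/SR2 mean: phase B contrast cancels
          beta[g, 3:6] <- beta[g, 3:6] + sgn * config$planted_delta_beta / 2
          expr[g, 3:6] <- expr[g, 3:6] * (1 + fc) / 2
        } else {
          cols <- .PHASE_CHANGEPOINT[[truth$phase[i]]]:6L
          beta[g, cols] <- beta[g, cols] + sgn * config$planted_delta_beta
          expr[g, cols] <- expr[g, cols] * fc
        }
      }
    }

    if (config$noise_sd_beta > 0) {
      beta <- beta + stats::rnorm(length(beta), sd = config$noise_sd_beta)
    }
    if (config$noise_sd_log_expr > 0) {
      expr <- expr * exp(stats::rnorm(length(expr),
                                      sd = config$noise_sd_log_expr))
    }
    beta <- pmin(pmax(beta, 0), 1)

    list(
      omics = stage_omics(beta, expr),
      truth = list(candidates = truth, risk_genes = config$risk_genes)
    )
  })
}

# draw clinical covariates for n patients
.draw_covariates <- function(n, probs) {
  data.frame(
    stage = sample(names(probs$stage), n, replace = TRUE, prob = probs$stage),
    grade = sample(names(probs$grade), n, replace = TRUE, prob = probs$grade),
    debulk = sample(names(probs$debulk), n, replace = TRUE, prob = probs$debulk),
    stringsAsFactors = FALSE
  )
}

# one simulated cohort under the exponential proportional-hazards model
.simulate_one_cohort <- function(config, cohort_id, genes) {
  n <- config$n_patients_per_cohort
  betas <- matrix(stats::runif(n * length(genes), 0.20, 0.80),
                  nrow = n, dimnames = list(NULL, genes))

  covar <- .draw_covariates(n, config$covariate_probs)

  log_rate <- rep(log(config$baseline_hazard), n)
  if (!is.null(config$risk_genes)) {
    for (i in seq_len(nrow(config$risk_genes))) {
      g <- config$risk_genes$gene[i]
      med <- stats::median(betas[, g])
      at_risk <- if (config$risk_genes$direction[i] == "hypo") {
        betas[, g] < med
      } else {
        betas[, g] > med
      }
      log_rate <- log_rate + at_risk * log(config$risk_genes$hazard_ratio[i])
    }
  }
  if (!is.null(config$covariate_hr)) {
    for (nm in names(config$covariate_hr)) {
      hrs <- config$covariate_hr[[nm]]
      for (lvl in names(hrs)) {
        log_rate <- log_rate + (covar[[nm]] == lvl) * log(hrs[[lvl]])
      }
    }
  }

  t_event <- stats::rexp(n, rate = exp(log_rate))
  t_cens <- stats::rexp(n, rate = config$censor_rate)
  obs <- pmin(t_event, t_cens, config$max_follow_up)
  event <- as.integer(t_event <= t_cens & t_event <= config$max_follow_up)

  data <- data.frame(
    patient_id = sprintf("%s_p%04d", cohort_id, seq_len(n)),
    time_months = obs,
    event = event,
    covar,
    stringsAsFactors = FALSE
  )
  data <- cbind(data, as.data.frame(betas))
  survival_cohort(data, genes, cohort_id = cohort_id)
}

#' Simulate two independent survival cohorts with planted hazard effects
#'
#' Each patient receives a beta value per gene (uniform on (0.2, 0.8), which
#' keeps all five quantile cutoffs non-degenerate), clinical covariates, and
#' an event time from an exponential proportional-hazards model: each
#' configured risk gene multiplies the hazard by its `hazard_ratio` for
#' patients on its risk side of the cohort median (below for direction
#' `"hypo"`, above for `"hyper"`). Observed time is the minimum of the event
#' time, an independent exponential censoring time and the administrative
#' horizon `max_follow_up`; the event flag is 1 iff the event time is the
#' smallest of the three. The two cohorts share the configuration but are
#' independent draws, emulating discovery/validation databases.
#'
#' @param config a [sim_config()].
#' @return list with `cohort_a`, `cohort_b` (each a [survival_cohort()]) and
#'   `truth` (the planted risk-gene table).
#' @export
simulate_survival_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sprintf("gene_%05d", seq_len(config$n_genes))
  if (!is.null(config$risk_genes) &&
      !all(config$risk_genes$gene %in% genes)) {
    stopf("risk_genes reference genes outside the simulated gene set")
  }
  cohort_a <- with_local_seed(seed_stream(config$seed, 2L),
                              .simulate_one_cohort(config, "A", genes))
  cohort_b <- with_local_seed(seed_stream(config$seed, 3L),
                              .simulate_one_cohort(config, "B", genes))
  list(cohort_a = cohort_a, cohort_b = cohort_b,
       truth = list(risk_genes = config$risk_genes))
}

#' Simulate per-patient immune infiltration scores
#'
#' Draws one standard-normal score per patient for each of CTL, M1, M2, Tfh
#' and CAF. For every `(gene, cell_type, sign)` entry of
#' `config$immune_link`, the score is rebuilt as a mixture of the gene's
#' standardized cohort values and independent noise so that the planted
#' Pearson correlation is `sign * 0.5` in expectation (comfortably past the
#' |r| >= 0.3 recovery bar).
#'
#' @param cohort a [survival_cohort()] providing the patients and gene values.
#' @param config a [sim_config()].
#' @return data.frame with `patient_id` and one column per cell type.
#' @export
simulate_immune_profiles <- function(cohort, config) {
  stopifnot(inherits(cohort, "survival_cohort"), inherits(config, "sim_config"))
  n <- cohort_size(cohort)
  if (n == 0L) stopf("cohort is empty")
  with_local_seed(seed_stream(config$seed, 4L), {
    cells <- immune_cell_types()
    scores <- matrix(stats::rnorm(n * length(cells)), nrow = n,
                     dimnames = list(NULL, cells))
    link <- config$immune_link
    if (!is.null(link)) {
      r0 <- 0.5
      for (i in seq_len(nrow(link))) {
        g <- link$gene[i]
        v <- cohort_values(cohort, g)
        if (stats::sd(v) == 0) {
          stopf("gene '%s' has constant values; planted immune link is degenerate", g)
        }
        z <- as.numeric(scale(v))
        scores[, link$cell_type[i]] <-
          link$sign[i] * r0 * z + sqrt(1 - r0^2) * stats::rnorm(n)
      }
    }
    data.frame(patient_id = cohort$data$patient_id, scores,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a cohort whose hazard is raised in one joint gene/immune stratum
#'
#' Builds a single cohort together with immune scores in which patients who
#' are jointly above the median for a chosen gene and a chosen immune cell
#' score have their hazard multiplied, emulating an unfavourable
#' gene-high/infiltrate-high stratum. The first row of
#' `config$immune_joint_hazard` defines the stratum and multiplier.
#'
#' @param config a [sim_config()] with a non-null `immune_joint_hazard`.
#' @return list with `cohort` (a [survival_cohort()]) and `immune`
#'   (the immune-score data.frame).
#' @export
simulate_joint_immune_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$immune_joint_hazard)) {
    stopf("config$immune_joint_hazard must be set")
  }
  spec <- config$immune_joint_hazard[1L, ]
  genes <- sprintf("gene_%05d", seq_len(config$n_genes))
  if (!spec$gene %in% genes) {
    stopf("immune_joint_hazard references a gene outside the simulated set")
  }
  with_local_seed(seed_stream(config$seed, 5L), {
    n <- config$n_patients_per_cohort
    vals <- matrix(stats::runif(n * length(genes), 0.20, 0.80),
                   nrow = n, dimnames = list(NULL, genes))
    cells <- immune_cell_types()
    scores <- matrix(stats::rnorm(n * length(cells)), nrow = n,
                     dimnames = list(NULL, cells))

    g <- vals[, spec$gene]
    s <- scores[, spec$cell_type]
    joint_high <- g > stats::median(g) & s > stats::median(s)

    rate <- config$baseline_hazard * spec$hazard_multiplier^joint_high
    t_event <- stats::rexp(n, rate = rate)
    t_cens <- stats::rexp(n, rate = config$censor_rate)
    obs <- pmin(t_event, t_cens, config$max_follow_up)
    event <- as.integer(t_event <= t_cens & t_event <= config$max_follow_up)

    covar <- .draw_covariates(n, config$covariate_probs)
    data <- data.frame(
      patient_id = sprintf("J_p%04d", seq_len(n)),
      time_months = obs,
      event = event,
      covar,
      stringsAsFactors = FALSE
    )
    data <- cbind(data, as.data.frame(vals))
    list(
      cohort = survival_cohort(data, genes, cohort_id = "J"),
      immune = data.frame(patient_id = data$patient_id, scores,
                          stringsAsFactors = FALSE)
    )
  })
}
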