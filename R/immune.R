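#' Correlate a gene's molecular values with an immune infiltration score
#'
#' Pearson (default) or Spearman correlation with a two-sided test, on
#' complete pairs. Positive r means higher gene values accompany higher
#' infiltration scores. Pearson suits expression/score pairs; the rank
#' option guards bounded methylation betas.
#'
#' @param values per-patient gene values (methylation beta or expression).
#' @param scores per-patient immune scores, same length/order.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r`, `p`, `n`, `method`.
#' @export
correlate_gene_infiltrate <- function(values, scores,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(values) != length(scores)) {
    stopf("values and scores must have equal length")
  }
  keep <- is.finite(values) & is.finite(scores)
  values <- values[keep]
  scores <- scores[keep]
  if (length(values) < 3L) {
    stopf("at least 3 complete pairs required (got %d)", length(values))
  }
  if (stats::sd(values) == 0 || stats::sd(scores) == 0) {
    stopf("correlation is undefined for a constant input")
  }
  ct <- suppressWarnings(
    stats::cor.test(values, scores, method = method, exact = FALSE)
  )
  list(r = unname(ct$estimate), p = ct$p.value, n = length(values),
       method = method)
}

#' Survival across joint gene-by-immune-cell strata
#'
#' Dichotomizes patients by a gene's values and by one immune cell score
#' (at their medians by default; values at or below a cutoff go to `low`),
#' forming four joint strata: gene_low/cell_low, gene_low/cell_high,
#' gene_high/cell_low, gene_high/cell_high. Returns each stratum's
#' Kaplan-Meier curve, the multi-group log-rank test over the non-empty
#' strata (degrees of freedom reduced accordingly), and the stratum with
#' the lowest 60-month survival.
#'
#' @param cohort a [survival_cohort()].
#' @param immune immune-score data.frame (`patient_id` plus score columns)
#'   as produced by [simulate_immune_profiles()].
#' @param gene gene identifier in the cohort.
#' @param cell_type immune score column, one of [immune_cell_types()].
#' @param gene_cutoff,cell_cutoff dichotomization thresholds (default:
#'   medians of the analyzed patients).
#' @param eval_time horizon (months) at which strata are ranked (default 60).
#' @return list with `strata` (per-stratum n, events, survival at
#'   `eval_time`), `curves` (named list of [km_estimate()] results; `NULL`
#'   for empty strata), `logrank` (test over non-empty strata) and
#'   `worst_stratum`.
#' @export
joint_strata_survival <- function(cohort, immune, gene, cell_type,
                                  gene_cutoff = NULL, cell_cutoff = NULL,
                                  eval_time = 60) {
  stopifnot(inherits(cohort, "survival_cohort"))
  if (!cell_type %in% names(immune)) {
    stopf("unknown cell type '%s' (immune table has: %s)", cell_type,
          paste(setdiff(names(immune), "patient_id"), collapse = ", "))
  }
  m <- match(cohort$data$patient_id, immune$patient_id)
  if (anyNA(m)) stopf("immune profile missing for %d patient(s)", sum(is.na(m)))

  values <- cohort_values(cohort, gene)
  scores <- immune[[cell_type]][m]
  time <- cohort$data$time_months
  event <- cohort$data$event
  keep <- is.finite(values) & is.finite(scores)
  values <- values[keep]; scores <- scores[keep]
  time <- time[keep]; event <- event[keep]
  if (!length(time) || sum(event) == 0) {
    stopf("joint strata analysis needs at least one patient and one event")
  }

  gene_cutoff <- gene_cutoff %||% stats::median(values)
  cell_cutoff <- cell_cutoff %||% stats::median(scores)
  gl <- dichotomize(values, gene_cutoff)
  cl <- dichotomize(scores, cell_cutoff)
  stratum <- paste0("gene_", gl, "/cell_", cl)
  all_strata <- as.vector(outer(c("gene_low", "gene_high"),
                                c("cell_low", "cell_high"), paste, sep = "/"))

  curves <- stats::setNames(vector("list", 4L), all_strata)
  surv60 <- stats::setNames(rep(NA_real_, 4L), all_strata)
  n_strat <- stats::setNames(integer(4L), all_strata)
  ev_strat <- stats::setNames(integer(4L), all_strata)
  for (st in all_strata) {
    sel <- stratum == st
    n_strat[st] <- sum(sel)
    ev_strat[st] <- sum(event[sel])
    if (any(sel)) {
      curves[[st]] <- km_estimate(time[sel], event[sel])
      surv60[st] <- survival_at(curves[[st]], eval_time)
    }
  }

  non_empty <- names(n_strat)[n_strat > 0]
  logrank <- if (length(non_empty) >= 2L) {
    multi_group_logrank(time, event, stratum)
  } else {
    list(statistic = 0, df = 0L, p = 1, degenerate = TRUE)
  }

  ranked <- surv60[!is.na(surv60)]
  worst <- names(ranked)[which.min(ranked)]

  list(
    strata = data.frame(
      stratum = all_strata, n = as.integer(n_strat),
      events = as.integer(ev_strat),
      survival_at_eval = unname(surv60),
      stringsAsFactors = FALSE
    ),
    curves = curves,
    logrank = logrank,
    worst_stratum = worst
  )
}
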