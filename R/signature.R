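#' The five signature genes
#'
#' Gene symbols of the five-gene prognostic promoter-methylation signature
#' derived from the ovarian cancer stem-cell differentiation screen.
#'
#' @return character vector of five gene symbols.
#' @export
signature_genes <- function() {
  c("GNPDA1", "GPD1", "GRASP", "HOXC11", "MSLN")
}

#' Construct a signature specification
#'
#' A signature is a set of genes, each with a risk direction (whether low or
#' high values are unfavourable) and a dichotomization cutoff.
#'
#' @param gene character vector of unique gene identifiers.
#' @param risk_direction `"low_value_at_risk"` or `"high_value_at_risk"`,
#'   recycled.
#' @param cutoff numeric per-gene dichotomization threshold, recycled.
#' @return data.frame of class `signature_spec` with columns `gene`,
#'   `risk_direction`, `cutoff`.
#' @export
signature_spec <- function(gene, risk_direction, cutoff) {
  if (anyDuplicated(gene)) stopf("signature genes must be unique")
  if (!all(risk_direction %in% c("low_value_at_risk", "high_value_at_risk"))) {
    stopf("risk_direction must be 'low_value_at_risk' or 'high_value_at_risk'")
  }
  out <- data.frame(
    gene = gene,
    risk_direction = rep_len(risk_direction, length(gene)),
    cutoff = rep_len(cutoff, length(gene)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("signature_spec", "data.frame")
  out
}

#' Risk-group labels used throughout
#' @return character vector `c("0-1", "2", ">=3")`.
#' @export
risk_group_levels <- function() c("0-1", "2", ">=3")

.risk_group_of <- function(n_risk) {
  ifelse(n_risk <= 1, "0-1", ifelse(n_risk == 2, "2", ">=3"))
}

#' Code patients by count of signature genes at risk
#'
#' Each signature gene contributes one unfavourable "binomial code" when the
#' patient's value falls on its risk side of the cutoff: at or below the
#' cutoff for `low_value_at_risk` genes (ties count as at risk), strictly
#' above for `high_value_at_risk`. Patients are grouped by the count:
#' 0--1 genes at risk, exactly 2, or 3 and more. Patients missing any
#' signature gene are excluded (complete-case) with a warning.
#'
#' @param cohort a [survival_cohort()].
#' @param spec a [signature_spec()].
#' @return data.frame with columns `patient_id`, `n_risk`, `group` (factor
#'   with levels `"0-1"`, `"2"`, `">=3"`).
#' @export
code_risk <- function(cohort, spec) {
  stopifnot(inherits(cohort, "survival_cohort"),
            inherits(spec, "signature_spec"))
  missing_genes <- setdiff(spec$gene, cohort$genes)
  if (length(missing_genes)) {
    stopf("signature gene(s) absent from cohort: %s",
          paste(missing_genes, collapse = ", "))
  }
  vals <- as.matrix(cohort$data[, spec$gene, drop = FALSE])
  complete <- stats::complete.cases(vals)
  if (!all(complete)) {
    warning(sprintf("%d patient(s) excluded: missing signature gene values",
                    sum(!complete)), call. = FALSE)
  }
  vals <- vals[complete, , drop = FALSE]
  at_risk <- vapply(seq_len(nrow(spec)), function(j) {
    if (spec$risk_direction[j] == "low_value_at_risk") {
      vals[, j] <= spec$cutoff[j]
    } else {
      vals[, j] > spec$cutoff[j]
    }
  }, logical(nrow(vals)))
  if (is.null(dim(at_risk))) at_risk <- matrix(at_risk, nrow = 1L)
  n_risk <- as.integer(rowSums(at_risk))
  data.frame(
    patient_id = cohort$data$patient_id[complete],
    n_risk = n_risk,
    group = factor(.risk_group_of(n_risk), levels = risk_group_levels()),
    stringsAsFactors = FALSE
  )
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit estimator via [survival::survfit()];
#' censoring tied with an event time is processed after the event (standard
#' convention). The returned curve is tabulated at the distinct event times.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @return object of class `km_curve`: list with `event_times`, `survival`,
#'   `at_risk` (all aligned), and `n`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stopf("empty survival input")
  if (any(time <= 0)) stopf("times must be strictly positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  structure(
    list(
      event_times = fit$time[keep],
      survival = fit$surv[keep],
      at_risk = fit$n.risk[keep],
      n = length(time)
    ),
    class = "km_curve"
  )
}

#' Survival probability at a time point
#'
#' Evaluates the right-continuous Kaplan-Meier step function: the survival
#' at the largest event time not exceeding `t`, or 1 when no event has
#' occurred by `t`.
#'
#' @param curve a [km_estimate()] result.
#' @param t evaluation time in months (> 0; default 60).
#' @return survival probability in \[0, 1\].
#' @export
survival_at <- function(curve, t = 60) {
  stopifnot(inherits(curve, "km_curve"))
  if (!(t > 0)) stopf("t must be positive")
  idx <- which(curve$event_times <= t)
  if (!length(idx)) return(1)
  curve$survival[max(idx)]
}

#' k-sample log-rank test
#'
#' Generalization of the two-group log-rank statistic to two or more
#' labelled groups (chi-square, k-1 df); reduces to [logrank_test()]'s
#' statistic when k = 2. All-censored pooled data gives a degenerate null
#' result (p = 1).
#'
#' @param time,event follow-up and 0/1 event indicators.
#' @param group group labels (>= 2 non-empty groups for a test).
#' @return list with `statistic`, `df`, `p`, `degenerate`.
#' @export
multi_group_logrank <- function(time, event, group) {
  group <- as.character(group)
  keep <- !is.na(group)
  time <- time[keep]; event <- event[keep]; group <- group[keep]
  k <- length(unique(group))
  if (k < 2L) stopf("at least two non-empty groups required")
  if (sum(event) == 0) {
    return(list(statistic = 0, df = k - 1L, p = 1, degenerate = TRUE))
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- unname(fit$chisq)
  df <- length(fit$n) - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE),
       degenerate = FALSE)
}

# reference levels for the clinical covariates (first level = reference)
.COVARIATE_LEVELS <- list(
  risk_group = c("0-1", "2", ">=3"),
  stage = c("Early", "Late"),
  grade = c("G1", "G2", "G3"),
  debulk = c("Optimal", "Suboptimal")
)

# assemble the analysis frame shared by the Cox fits
.cox_frame <- function(cohort, risk = NULL) {
  df <- data.frame(
    time = cohort$data$time_months,
    event = cohort$data$event,
    stringsAsFactors = FALSE
  )
  for (nm in c("stage", "grade", "debulk")) {
    if (nm %in% names(cohort$data)) {
      df[[nm]] <- factor(cohort$data[[nm]], levels = .COVARIATE_LEVELS[[nm]])
    }
  }
  if (!is.null(risk)) {
    m <- match(cohort$data$patient_id, risk$patient_id)
    df$risk_group <- factor(as.character(risk$group[m]),
                            levels = .COVARIATE_LEVELS$risk_group)
  }
  df
}

# tidy one coxph fit into per-level hazard-ratio rows, reference rows included
.cox_tidy <- function(fit, df, terms) {
  s <- summary(fit)
  coefs <- s$coefficients
  ci <- s$conf.int
  out <- list()
  for (tm in terms) {
    levs <- levels(df[[tm]])
    present <- levs[levs %in% unique(as.character(df[[tm]]))]
    for (lvl in present) {
      if (lvl == present[1L]) {
        out[[length(out) + 1L]] <- data.frame(
          term = tm, level = lvl, hr = 1, ci_low = NA_real_,
          ci_high = NA_real_, p = NA_real_, reference = TRUE,
          estimable = TRUE, stringsAsFactors = FALSE
        )
        next
      }
      rn <- paste0(tm, lvl)
      if (!rn %in% rownames(coefs)) next
      se <- coefs[rn, "se(coef)"]
      estimable <- is.finite(se) && se < 1e3
      out[[length(out) + 1L]] <- data.frame(
        term = tm, level = lvl,
        hr = unname(ci[rn, "exp(coef)"]),
        ci_low = unname(ci[rn, "lower .95"]),
        ci_high = unname(ci[rn, "upper .95"]),
        p = unname(coefs[rn, "Pr(>|z|)"]),
        reference = FALSE, estimable = estimable,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Univariate Cox proportional-hazards analysis
#'
#' Fits one proportional-hazards model for a single characteristic (risk
#' group, stage, grade or debulk status) and reports the crude hazard ratio
#' with Wald 95\% CI and p-value for each non-reference level. Reference
#' levels (risk group "0-1", Early stage, grade G1, Optimal debulk) are
#' reported with HR fixed at 1. Ties are handled by the Efron
#' approximation. Levels with an inflated standard error (separation, or a
#' level without events) are flagged non-estimable.
#'
#' @param cohort a [survival_cohort()].
#' @param term one of `"risk_group"`, `"stage"`, `"grade"`, `"debulk"`.
#' @param risk risk assignments from [code_risk()]; required when
#'   `term = "risk_group"`.
#' @return data.frame with columns `term`, `level`, `hr`, `ci_low`,
#'   `ci_high`, `p`, `reference`, `estimable`.
#' @export
cox_univariate <- function(cohort,
                           term = c("risk_group", "stage", "grade", "debulk"),
                           risk = NULL) {
  term <- match.arg(term)
  if (term == "risk_group" && is.null(risk)) {
    stopf("risk assignments are required for term 'risk_group'")
  }
  df <- .cox_frame(cohort, risk = risk)
  if (!term %in% names(df)) stopf("covariate '%s' absent from cohort", term)
  df <- df[!is.na(df[[term]]), , drop = FALSE]
  if (nlevels(droplevels(df[[term]])) < 2L) {
    stopf("term '%s' has fewer than 2 observed levels", term)
  }
  fit <- survival::coxph(
    stats::as.formula(paste0("survival::Surv(time, event) ~ ", term)),
    data = df, ties = "efron"
  )
  .cox_tidy(fit, df, term)
}

#' Multivariate Cox proportional-hazards analysis
#'
#' Single joint fit adjusting the signature risk group for stage, grade and
#' debulk status; reports adjusted hazard ratios per non-reference level.
#' Warns when the event count is below 10 per estimated parameter.
#'
#' @param cohort a [survival_cohort()].
#' @param risk risk assignments from [code_risk()].
#' @return data.frame as in [cox_univariate()], one block per covariate.
#' @export
cox_multivariate <- function(cohort, risk) {
  df <- .cox_frame(cohort, risk = risk)
  terms <- c("risk_group", "stage", "grade", "debulk")
  absent <- setdiff(terms, names(df))
  if (length(absent)) {
    stopf("covariate(s) absent from cohort: %s", paste(absent, collapse = ", "))
  }
  df <- df[stats::complete.cases(df[, terms]), , drop = FALSE]
  n_par <- sum(vapply(terms, function(tm) {
    nlevels(droplevels(df[[tm]])) - 1L
  }, integer(1)))
  if (sum(df$event) < 10 * n_par) {
    warning(sprintf("only %d events for %d parameters (< 10 per parameter)",
                    sum(df$event), n_par), call. = FALSE)
  }
  fit <- survival::coxph(
    survival::Surv(time, event) ~ risk_group + stage + grade + debulk,
    data = df, ties = "efron"
  )
  .cox_tidy(fit, df, terms)
}

#' Derive a signature specification from RRS selections
#'
#' Bridges the dual-cohort screen to a usable signature: every selected gene
#' becomes a signature entry whose risk direction follows the RRS sign
#' (positive totals mean low values are unfavourable, hence
#' `low_value_at_risk`) and whose cutoff is the grid threshold achieving the
#' smallest overall-endpoint log-rank p-value in the reference cohort
#' (`cutoff = "median"` falls back to the gene's median).
#'
#' @param screen output of [rrs_screen()] (or a compatible data.frame with
#'   columns `gene`, `verdict`).
#' @param cohort the [survival_cohort()] on which cutoffs are placed.
#' @param cutoff `"best_grid"` (default) or `"median"`.
#' @return a [signature_spec()].
#' @export
derive_signature_from_rrs <- function(screen, cohort,
                                      cutoff = c("best_grid", "median")) {
  cutoff <- match.arg(cutoff)
  selected <- screen[screen$verdict != "not_selected", , drop = FALSE]
  if (!nrow(selected)) stopf("no genes were selected by the RRS screen")

  dirs <- ifelse(selected$verdict == "selected_hypo_risk",
                 "low_value_at_risk", "high_value_at_risk")
  cuts <- vapply(seq_len(nrow(selected)), function(i) {
    g <- selected$gene[i]
    values <- cohort_values(cohort, g)
    values <- values[is.finite(values)]
    if (cutoff == "median") return(stats::median(values))
    grid <- quantile_cutoffs(values)
    time <- cohort$data$time_months[is.finite(cohort_values(cohort, g))]
    event <- cohort$data$event[is.finite(cohort_values(cohort, g))]
    ps <- vapply(grid, function(th) {
      logrank_test(time, event, dichotomize(values, th))$p
    }, numeric(1))
    unname(grid[[which.min(ps)]])
  }, numeric(1))

  signature_spec(selected$gene, dirs, cuts)
}
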