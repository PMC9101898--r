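#' Quantile cutoff grid for one gene
#'
#' The five dichotomization thresholds used by the recurrent risk score:
#' low quartile (25\%), low tertile (33.3\%), median (50\%), high tertile
#' (66.7\%) and high quartile (75\%) of the analyzed patients' values,
#' computed as linear-interpolation sample quantiles.
#'
#' @param values numeric vector of molecular values (>= 10 finite values).
#' @return named numeric vector of five non-decreasing thresholds
#'   (`q25`, `q33`, `q50`, `q67`, `q75`), with attribute `degenerate` set to
#'   `TRUE` when all thresholds coincide.
#' @export
quantile_cutoffs <- function(values) {
  if (any(!is.finite(values))) stopf("values must all be finite")
  if (length(values) < 10L) {
    stopf("at least 10 values required to place quantile cutoffs (got %d)",
          length(values))
  }
  probs <- c(0.25, 1 / 3, 0.5, 2 / 3, 0.75)
  q <- stats::quantile(values, probs = probs, type = 7, names = FALSE)
  names(q) <- c("q25", "q33", "q50", "q67", "q75")
  attr(q, "degenerate") <- (max(q) - min(q)) == 0
  q
}

#' Dichotomize values at a threshold
#'
#' Values at or below the threshold are labelled `low`, values above it
#' `high` (declared tie rule: ties go low).
#'
#' @param values numeric vector.
#' @param threshold finite cutoff.
#' @return character vector of `"low"` / `"high"` labels.
#' @export
dichotomize <- function(values, threshold) {
  if (!is.finite(threshold)) stopf("threshold must be finite")
  ifelse(values <= threshold, "low", "high")
}

#' The three progression-free-survival endpoints
#'
#' 1.5-year and 3-year endpoints are implemented as administrative
#' censoring at 18 and 36 months; `overall` applies no horizon.
#'
#' @return data.frame with columns `endpoint_id` and `horizon_months`.
#' @export
endpoint_specs <- function() {
  data.frame(
    endpoint_id = c("18m", "36m", "overall"),
    horizon_months = c(18, 36, Inf),
    stringsAsFactors = FALSE
  )
}

#' Administratively censor follow-up at a horizon
#'
#' Observations with time beyond the horizon are truncated to the horizon
#' and marked censored; all others are unchanged. An infinite horizon is the
#' identity.
#'
#' @param time positive follow-up times (months).
#' @param event 0/1 event indicators.
#' @param horizon censoring horizon in months (> 0, may be `Inf`).
#' @return list with truncated `time` and `event` vectors.
#' @export
restrict_endpoint <- function(time, event, horizon) {
  if (!(horizon > 0)) stopf("horizon must be positive")
  beyond <- time > horizon
  list(
    time = pmin(time, horizon),
    event = ifelse(beyond, 0L, as.integer(event))
  )
}

#' Two-group log-rank test with inferior-group direction
#'
#' Standard two-sample log-rank chi-square (1 df) with the hypergeometric
#' variance at tied event times, via [survival::survdiff()]. The inferior
#' group is the one with more observed than expected events. Degenerate
#' inputs (an empty arm, or no events in the pooled data) return a
#' flagged null result (statistic 0, p = 1, inferior `"none"`) rather than
#' erroring, so that vote grids stay fully defined.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param group two-level grouping (`"low"` / `"high"` labels).
#' @return list with `statistic`, `p`, `inferior_group`, `degenerate`.
#' @export
logrank_test <- function(time, event, group) {
  if (length(time) == 0L) stopf("empty survival input")
  group <- as.character(group)
  levs <- unique(group)
  if (length(levs) < 2L || sum(event) == 0) {
    return(list(statistic = 0, p = 1, inferior_group = "none",
                degenerate = TRUE))
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- unname(fit$chisq)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  oe <- fit$obs - fit$exp
  grp_names <- sub("^group=", "", names(fit$n))
  inferior <- if (all(abs(oe) < 1e-12)) "none" else grp_names[which.max(oe)]
  list(statistic = stat, p = p, inferior_group = inferior, degenerate = FALSE)
}

#' Score one cutoff-by-endpoint condition
#'
#' Applies the vote rule of the recurrent risk score: +1 when the low-value
#' group has significantly inferior survival, -1 when the high-value group
#' does, 0 otherwise (including degenerate splits).
#'
#' @param time,event endpoint-restricted follow-up.
#' @param labels `"low"`/`"high"` patient labels from [dichotomize()].
#' @param alpha significance level for a condition (default 0.05).
#' @return list with `logrank_p`, `inferior_group`, `vote`.
#' @export
score_condition <- function(time, event, labels, alpha = 0.05) {
  lr <- logrank_test(time, event, labels)
  vote <- 0L
  if (!lr$degenerate && lr$p < alpha) {
    if (lr$inferior_group == "low") vote <- 1L
    if (lr$inferior_group == "high") vote <- -1L
  }
  list(logrank_p = lr$p, inferior_group = lr$inferior_group, vote = vote)
}

#' Recurrent risk score for one gene in one cohort
#'
#' Enumerates the full 5 x 3 condition grid -- five quantile cutoffs
#' (ascending) by three PFS endpoints (18 months, 36 months, overall) -- and
#' sums the 15 signed votes. A positive total means low values of the gene
#' recurrently associate with inferior survival.
#'
#' @param cohort a [survival_cohort()].
#' @param gene gene identifier.
#' @param alpha per-condition significance level (default 0.05).
#' @return object of class `rrs_result`: list with `gene`, `cohort_id`,
#'   `votes` (15-row data.frame with `cutoff_id`, `endpoint_id`,
#'   `threshold`, `logrank_p`, `inferior_group`, `vote`) and `total`.
#' @export
compute_rrs <- function(cohort, gene, alpha = 0.05) {
  stopifnot(inherits(cohort, "survival_cohort"))
  values <- cohort_values(cohort, gene)
  keep <- is.finite(values) & is.finite(cohort$data$time_months)
  values <- values[keep]
  time <- cohort$data$time_months[keep]
  event <- cohort$data$event[keep]
  if (length(values) < 10L) {
    stopf("fewer than 10 analyzable patients for gene '%s'", gene)
  }

  cutoffs <- quantile_cutoffs(values)
  eps <- endpoint_specs()
  rows <- vector("list", length(cutoffs) * nrow(eps))
  k <- 0L
  for (ci in seq_along(cutoffs)) {
    labels <- dichotomize(values, cutoffs[[ci]])
    for (ei in seq_len(nrow(eps))) {
      restricted <- restrict_endpoint(time, event, eps$horizon_months[ei])
      sc <- score_condition(restricted$time, restricted$event, labels,
                            alpha = alpha)
      k <- k + 1L
      rows[[k]] <- data.frame(
        cutoff_id = names(cutoffs)[ci],
        endpoint_id = eps$endpoint_id[ei],
        threshold = unname(cutoffs[[ci]]),
        logrank_p = sc$logrank_p,
        inferior_group = sc$inferior_group,
        vote = sc$vote,
        stringsAsFactors = FALSE
      )
    }
  }
  votes <- do.call(rbind, rows)
  structure(
    list(gene = gene, cohort_id = cohort$cohort_id, votes = votes,
         total = sum(votes$vote)),
    class = "rrs_result"
  )
}

#' @export
print.rrs_result <- function(x, ...) {
  cat(sprintf("<rrs_result> gene %s, cohort %s: total %+d (of 15 conditions)\n",
              x$gene, x$cohort_id, x$total))
  invisible(x)
}

#' Dual-cohort concordance selection
#'
#' A gene is selected as hypomethylation-at-risk when its RRS total exceeds
#' 1 (i.e. is at least +2) in both cohorts, and as hypermethylation-at-risk
#' when both totals are below -1. Rule `"sign"` relaxes this to totals of
#' matching nonzero sign in both cohorts.
#'
#' @param rrs_a,rrs_b `rrs_result` objects for the same gene in two cohorts.
#' @param rule `"strict"` (|total| >= 2 in both, default) or `"sign"`.
#' @return one of `"selected_hypo_risk"`, `"selected_hyper_risk"`,
#'   `"not_selected"`.
#' @export
select_concordant <- function(rrs_a, rrs_b, rule = c("strict", "sign")) {
  rule <- match.arg(rule)
  if (!identical(rrs_a$gene, rrs_b$gene)) {
    stopf("RRS results refer to different genes ('%s' vs '%s')",
          rrs_a$gene, rrs_b$gene)
  }
  lo <- if (rule == "strict") 1 else 0
  if (rrs_a$total > lo && rrs_b$total > lo) return("selected_hypo_risk")
  if (rrs_a$total < -lo && rrs_b$total < -lo) return("selected_hyper_risk")
  "not_selected"
}

#' Screen genes by dual-cohort recurrent risk score
#'
#' Computes the RRS for every requested gene in both cohorts and applies
#' the concordance rule. Optionally adjusts the per-condition log-rank
#' p-values across genes by Benjamini-Hochberg before voting (off by
#' default; the dual-cohort concordance requirement is the de facto error
#' control).
#'
#' @param cohort_a,cohort_b two independent [survival_cohort()]s.
#' @param genes genes to screen (default: all genes shared by both cohorts).
#' @param alpha per-condition significance level.
#' @param rule concordance rule, see [select_concordant()].
#' @param adjust `"none"` (default) or `"BH"`: correction of condition
#'   p-values across genes within each cohort/condition.
#' @return data.frame with one row per gene: `gene`, `total_a`, `total_b`,
#'   `verdict`.
#' @export
rrs_screen <- function(cohort_a, cohort_b, genes = NULL, alpha = 0.05,
                       rule = c("strict", "sign"), adjust = c("none", "BH")) {
  rule <- match.arg(rule)
  adjust <- match.arg(adjust)
  genes <- genes %||% intersect(cohort_a$genes, cohort_b$genes)
  res_a <- lapply(genes, function(g) compute_rrs(cohort_a, g, alpha = alpha))
  res_b <- lapply(genes, function(g) compute_rrs(cohort_b, g, alpha = alpha))

  if (adjust == "BH") {
    res_a <- .rrs_bh_revote(res_a, alpha)
    res_b <- .rrs_bh_revote(res_b, alpha)
  }

  data.frame(
    gene = genes,
    total_a = vapply(res_a, `[[`, integer(1), "total"),
    total_b = vapply(res_b, `[[`, integer(1), "total"),
    verdict = mapply(function(a, b) select_concordant(a, b, rule = rule),
                     res_a, res_b),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# re-vote after BH adjustment of each condition's p-values across genes
.rrs_bh_revote <- function(res, alpha) {
  pmat <- vapply(res, function(r) r$votes$logrank_p, numeric(15L))
  padj <- t(apply(pmat, 1L, stats::p.adjust, method = "BH"))
  lapply(seq_along(res), function(i) {
    r <- res[[i]]
    r$votes$logrank_p <- padj[, i]
    sig <- r$votes$logrank_p < alpha
    r$votes$vote <- ifelse(!sig, 0L,
                           ifelse(r$votes$inferior_group == "low", 1L,
                                  ifelse(r$votes$inferior_group == "high",
                                         -1L, 0L)))
    r$total <- sum(r$votes$vote)
    r
  })
}
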