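#' Stage omics container
#'
#' Bundles a gene-by-stage promoter methylation matrix (beta fractions in
#' \[0, 1\]) and a gene-by-stage expression intensity matrix (strictly
#' positive) over the six differentiation stages: two spheroid stem-cell
#' stages (SR1, SR2) and four adherent differentiated stages (AD1--AD4).
#'
#' @param methylation numeric matrix, genes as rows, stages as columns,
#'   values in \[0, 1\].
#' @param expression numeric matrix with identical dimnames, values > 0.
#' @return An object of class `stage_omics` with elements `genes`, `stages`,
#'   `methylation` and `expression`.
#' @export
stage_omics <- function(methylation, expression) {
  if (!is.matrix(methylation) || !is.matrix(expression)) {
    stopf("methylation and expression must be matrices")
  }
  if (!identical(dim(methylation), dim(expression)) ||
      !identical(dimnames(methylation), dimnames(expression))) {
    stopf("methylation and expression matrices must share dimnames")
  }
  if (is.null(rownames(methylation)) || is.null(colnames(methylation))) {
    stopf("matrices must carry gene rownames and stage colnames")
  }
  if (anyNA(methylation) || anyNA(expression)) {
    stopf("omics matrices must not contain missing values")
  }
  if (min(methylation) < 0 || max(methylation) > 1) {
    stopf("methylation betas must lie in [0, 1]")
  }
  if (min(expression) <= 0) {
    stopf("expression intensities must be strictly positive")
  }
  structure(
    list(
      genes = rownames(methylation),
      stages = colnames(methylation),
      methylation = methylation,
      expression = expression
    ),
    class = "stage_omics"
  )
}

#' @export
print.stage_omics <- function(x, ...) {
  cat(sprintf(
    "<stage_omics> %d genes x %d stages (%s)\n",
    length(x$genes), length(x$stages), paste(x$stages, collapse = ", ")
  ))
  invisible(x)
}

#' Survival cohort container
#'
#' A cohort of patients with progression-free survival follow-up and
#' per-gene molecular values (typically promoter methylation betas).
#'
#' @param data data.frame with columns `patient_id`, `time_months` (> 0),
#'   `event` (0/1), clinical covariates `stage`, `grade`, `debulk`, plus one
#'   numeric column per gene.
#' @param genes character vector naming the gene columns of `data`.
#' @param cohort_id label for the cohort (e.g. `"A"`).
#' @return An object of class `survival_cohort`.
#' @export
survival_cohort <- function(data, genes, cohort_id = "cohort") {
  required <- c("patient_id", "time_months", "event")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stopf("cohort data lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!all(genes %in% names(data))) {
    stopf("gene column(s) absent from cohort data: %s",
          paste(setdiff(genes, names(data)), collapse = ", "))
  }
  if (any(data$time_months <= 0, na.rm = TRUE)) {
    stopf("survival times must be strictly positive")
  }
  if (!all(data$event %in% c(0, 1))) {
    stopf("event indicator must be 0 or 1")
  }
  structure(
    list(cohort_id = cohort_id, data = data, genes = genes),
    class = "survival_cohort"
  )
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf(
    "<survival_cohort '%s'> %d patients, %d genes, %d events\n",
    x$cohort_id, nrow(x$data), length(x$genes), sum(x$data$event)
  ))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort a `survival_cohort`.
#' @return integer patient count.
#' @export
cohort_size <- function(cohort) nrow(cohort$data)

#' Extract one gene's molecular values from a cohort
#' @param cohort a `survival_cohort`.
#' @param gene gene identifier (must be one of `cohort$genes`).
#' @return numeric vector, one value per patient (may contain `NA`).
#' @export
cohort_values <- function(cohort, gene) {
  if (!gene %in% cohort$genes) {
    stopf("gene '%s' not present in cohort '%s'", gene, cohort$cohort_id)
  }
  cohort$data[[gene]]
}
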