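# All tables are plain tab-separated text with a header row; missing values
# are written as empty fields.

#' Read stage omics from two delimited matrices
#'
#' @param meth_file,expr_file TSV files, genes as rows (first column), the
#'   six stage labels as column headers.
#' @return a [stage_omics()].
#' @export
read_stage_omics <- function(meth_file, expr_file) {
  read_mat <- function(f) {
    df <- utils::read.delim(f, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m
  }
  stage_omics(read_mat(meth_file), read_mat(expr_file))
}

#' Write stage omics as two delimited matrices
#' @param omics a [stage_omics()].
#' @param meth_file,expr_file output TSV paths.
#' @return invisibly, the omics object.
#' @export
write_stage_omics <- function(omics, meth_file, expr_file) {
  wr <- function(m, f) {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  }
  wr(omics$methylation, meth_file)
  wr(omics$expression, expr_file)
  invisible(omics)
}

#' Read a survival cohort table
#'
#' Expects columns `patient_id, time_months, event, stage, grade, debulk`
#' followed by one numeric column per gene; empty fields are missing values.
#'
#' @param file TSV path.
#' @param cohort_id label for the cohort.
#' @return a [survival_cohort()].
#' @export
read_survival_cohort <- function(file, cohort_id = "cohort") {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")
  clinical <- c("patient_id", "time_months", "event", "stage", "grade", "debulk")
  genes <- setdiff(names(df), clinical)
  survival_cohort(df, genes, cohort_id = cohort_id)
}

#' Write a survival cohort table
#' @param cohort a [survival_cohort()].
#' @param file output TSV path.
#' @return invisibly, the cohort.
#' @export
write_survival_cohort <- function(cohort, file) {
  utils::write.table(cohort$data, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(cohort)
}

#' Read an immune-score table
#' @param file TSV path with `patient_id` plus one column per cell type.
#' @return data.frame.
#' @export
read_immune_profiles <- function(file) {
  utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = "")
}

#' Write an immune-score table
#' @param immune data.frame from [simulate_immune_profiles()].
#' @param file output TSV path.
#' @return invisibly, the table.
#' @export
write_immune_profiles <- function(immune, file) {
  utils::write.table(immune, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(immune)
}
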