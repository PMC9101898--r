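#' Promoter window around a transcription start site
#'
#' Defines the 2 kb promoter region used for promoter methylation levels:
#' 1 kb upstream and 1 kb downstream of the TSS. The span is symmetric, so
#' strand is recorded but does not alter the window. Coordinates are 0-based
#' half-open (BED convention); windows are clipped at coordinate 0, in which
#' case they are narrower than 2000 bp.
#'
#' @param tss 0-based TSS coordinate(s), >= 0.
#' @param chrom chromosome label(s), recycled to the length of `tss`.
#' @param strand strand label(s) among `"+"`, `"-"`, `"."`.
#' @param flank bases added on each side (default 1000).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' make_promoter_window(5000, "chr1", "+")  # [4000, 6000)
#' @export
make_promoter_window <- function(tss, chrom = "chr1", strand = ".",
                                 flank = 1000L) {
  if (any(!is.finite(tss)) || any(tss < 0)) {
    stopf("tss coordinates must be nonnegative")
  }
  if (!all(strand %in% c("+", "-", "."))) {
    stopf("strand must be one of '+', '-', '.'")
  }
  data.frame(
    chrom = rep_len(as.character(chrom), length(tss)),
    start = pmax(0, tss - flank),
    end = tss + flank,
    strand = rep_len(as.character(strand), length(tss)),
    stringsAsFactors = FALSE
  )
}

#' Sample QC by uniquely-mapped read fraction
#'
#' Retains capture-sequencing samples whose uniquely mapped reads make up at
#' least 40\% of total mapped reads; the threshold is inclusive.
#'
#' @param sample_stats data.frame with columns `sample_id` and
#'   `uniquely_mapped_fraction` (values in \[0, 1\]).
#' @param min_fraction inclusive retention threshold (default 0.40).
#' @return character vector of retained sample ids, input order preserved.
#' @export
qc_filter_samples <- function(sample_stats, min_fraction = 0.40) {
  need <- c("sample_id", "uniquely_mapped_fraction")
  if (!all(need %in% names(sample_stats))) {
    stopf("sample_stats needs columns: %s", paste(need, collapse = ", "))
  }
  f <- sample_stats$uniquely_mapped_fraction
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    stopf("uniquely_mapped_fraction must lie in [0, 1]")
  }
  sample_stats$sample_id[f >= min_fraction]
}

#' The three differentiation phase contrasts
#'
#' Phase A compares the two spheroid stem-cell stages (SR1 vs SR2); phase B
#' compares spheroids against early adherent progeny (SR1+SR2 vs AD1+AD2);
#' phase C compares early against late adherent progeny (AD1+AD2 vs
#' AD3+AD4). The comparison group is always the more differentiated one.
#'
#' @return named list of contrasts, each with `phase_id`,
#'   `baseline_stages`, `comparison_stages`.
#' @export
phase_contrasts <- function() {
  list(
    A = list(phase_id = "A", baseline_stages = "SR1",
             comparison_stages = "SR2"),
    B = list(phase_id = "B", baseline_stages = c("SR1", "SR2"),
             comparison_stages = c("AD1", "AD2")),
    C = list(phase_id = "C", baseline_stages = c("AD1", "AD2"),
             comparison_stages = c("AD3", "AD4"))
  )
}

#' Differential methylation / expression contrast for one phase
#'
#' For each gene, computes the group-mean beta difference
#' (comparison minus baseline; negative = hypomethylation along
#' differentiation) and the linear-scale expression fold change (ratio of
#' group means). Flags differentially methylated genes at an absolute
#' group-mean beta change of at least 10 percentage points and
#' differentially expressed genes at a fold change of at least 1.5 in
#' either direction; both thresholds are closed (boundary values flagged).
#'
#' @param omics a [stage_omics()].
#' @param contrast one element of [phase_contrasts()].
#' @param genes genes to evaluate (default: all).
#' @param delta_threshold DMR threshold on |delta beta| (default 0.10).
#' @param fc_threshold DEG threshold on fold change (default 1.5).
#' @return data.frame with columns `gene`, `phase`, `delta_beta`,
#'   `fold_change`, `dmr_flag`, `dmr_direction`, `deg_flag`, `deg_direction`.
#' @export
compute_contrast <- function(omics, contrast, genes = NULL,
                             delta_threshold = 0.10, fc_threshold = 1.5) {
  stopifnot(inherits(omics, "stage_omics"))
  stages <- c(contrast$baseline_stages, contrast$comparison_stages)
  missing_stages <- setdiff(stages, omics$stages)
  if (length(missing_stages)) {
    stopf("stage(s) absent from omics: %s", paste(missing_stages, collapse = ", "))
  }
  genes <- genes %||% omics$genes
  missing_genes <- setdiff(genes, omics$genes)
  if (length(missing_genes)) {
    stopf("unknown gene(s): %s", paste(utils::head(missing_genes, 5), collapse = ", "))
  }

  bmean <- function(m, cols) rowMeans(m[genes, cols, drop = FALSE])
  delta <- bmean(omics$methylation, contrast$comparison_stages) -
    bmean(omics$methylation, contrast$baseline_stages)
  fc <- bmean(omics$expression, contrast$comparison_stages) /
    bmean(omics$expression, contrast$baseline_stages)

  eps <- .THRESH_EPS
  dmr <- abs(delta) >= delta_threshold - eps
  dmr_dir <- ifelse(!dmr, "none", ifelse(delta < 0, "hypo", "hyper"))
  up <- fc >= fc_threshold - eps
  down <- fc <= 1 / fc_threshold + eps
  deg <- up | down
  deg_dir <- ifelse(up, "up", ifelse(down, "down", "none"))

  data.frame(
    gene = genes,
    phase = contrast$phase_id,
    delta_beta = unname(delta),
    fold_change = unname(fc),
    dmr_flag = unname(dmr),
    dmr_direction = unname(dmr_dir),
    deg_flag = unname(deg),
    deg_direction = unname(deg_dir),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Negative-correlation candidate selection
#'
#' Keeps only genes whose methylation and expression changed discordantly:
#' hypomethylated with up-regulation (`hypo_up`) or hypermethylated with
#' down-regulation (`hyper_down`). Concordant pairs and single-omic hits
#' (DMR without DEG, or vice versa) are excluded.
#'
#' @param results contrast table(s) from [compute_contrast()], row-bound.
#' @return data.frame with columns `gene`, `phase`, `class`, sorted by
#'   phase, class, gene.
#' @export
select_candidates <- function(results) {
  hypo_up <- results$dmr_direction == "hypo" & results$deg_direction == "up"
  hyper_down <- results$dmr_direction == "hyper" & results$deg_direction == "down"
  out <- data.frame(
    gene = results$gene[hypo_up | hyper_down],
    phase = results$phase[hypo_up | hyper_down],
    class = ifelse(hypo_up[hypo_up | hyper_down], "hypo_up", "hyper_down"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$phase, out$class, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full three-phase integration pipeline
#'
#' Applies the A/B/C phase contrasts to the stage omics, selects
#' negative-correlation candidates in each phase, and pools them. A gene may
#' recur across phases; the pooled list therefore counts distinct
#' (gene, phase) pairs.
#'
#' @inheritParams compute_contrast
#' @return list with `contrasts` (per-phase contrast tables), `candidates`
#'   (per-phase candidate tables), `pooled` (row-bound candidates) and
#'   `counts` (per-phase/class candidate counts with pooled total).
#' @export
run_all_phases <- function(omics, delta_threshold = 0.10, fc_threshold = 1.5) {
  stopifnot(inherits(omics, "stage_omics"))
  missing_stages <- setdiff(.STAGES, omics$stages)
  if (length(missing_stages)) {
    stopf("omics must contain all six stages; missing: %s",
          paste(missing_stages, collapse = ", "))
  }
  contrasts <- phase_contrasts()
  results <- lapply(contrasts, function(ct) {
    compute_contrast(omics, ct,
                     delta_threshold = delta_threshold,
                     fc_threshold = fc_threshold)
  })
  candidates <- lapply(results, select_candidates)
  pooled <- do.call(rbind, c(candidates, list(make.row.names = FALSE)))

  counts <- do.call(rbind, lapply(names(candidates), function(ph) {
    data.frame(
      phase = ph,
      hypo_up = sum(candidates[[ph]]$class == "hypo_up"),
      hyper_down = sum(candidates[[ph]]$class == "hyper_down"),
      stringsAsFactors = FALSE
    )
  }))
  counts$total <- counts$hypo_up + counts$hyper_down

  list(
    contrasts = results,
    candidates = candidates,
    pooled = pooled,
    counts = counts,
    n_pooled = nrow(pooled)
  )
}
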