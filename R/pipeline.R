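#' Run the full prognostic pipeline on one merged cohort
#'
#' Chains the pipeline stages: scaling normalization to a common
#' shared-probe mean, duplicate-sample removal (earliest dataset retained),
#' five-parameter QC exclusion, receptor surrogate calls and St Gallen
#' subtype assignment, signature scoring, the quartile-bounded minimum-p
#' cutoff scan, and the paired multivariate Cox panel. Counts removed at
#' each filtering step are reported in `accounting`.
#'
#' @param expression Raw merged [expr_matrix()].
#' @param clinical Clinical data.frame covering the matrix's samples.
#' @param qc QC metrics data.frame, or `NULL` to skip QC exclusion.
#' @param signature A [signature_def()].
#' @param target_mean Scaling normalization target (default 1000).
#' @param dataset_priority Dataset labels in publication order for
#'   duplicate resolution; default order of appearance.
#' @param er_cutoff,her2_cutoff Receptor call cutoffs.
#' @param qc_z,qc_exclude_min_failures QC band width and exclusion
#'   threshold, see [qc_filter()].
#' @param p_source,ties Passed to [cutoff_scan()].
#' @return List with `matrix` (normalized, filtered), `clinical` (filtered,
#'   with receptor calls, subtype and `score` merged in), `scores`, `scan`
#'   ([cutoff_scan()] result), `paired` (the [paired_cox_panel()] table),
#'   `duplicates_removed`, `qc_result`, and `accounting` (data.frame of
#'   per-stage sample counts).
#' @export
run_pipeline <- function(expression, clinical, qc, signature,
                         target_mean = 1000, dataset_priority = NULL,
                         er_cutoff = 500, her2_cutoff = 4800,
                         qc_z = 1.96, qc_exclude_min_failures = 3L,
                         p_source = "cox", ties = "efron") {
  stopifnot(inherits(expression, "expr_matrix"))
  n0 <- ncol(expression$values)
  norm <- scale_normalize(expression, target_mean = target_mean)
  if (is.null(dataset_priority)) dataset_priority <- unique(norm$dataset)
  dedup <- remove_duplicates(norm, priority = dataset_priority)
  mat <- dedup$matrix
  n1 <- ncol(mat$values)

  qc_result <- NULL
  if (!is.null(qc)) {
    qc_in <- qc[qc$sample_id %in% sample_ids(mat), , drop = FALSE]
    qc_result <- qc_filter(qc_in, z = qc_z,
                           exclude_min_failures = qc_exclude_min_failures)
    keep <- setdiff(sample_ids(mat), qc_result$excluded)
    mat <- subset_samples(mat, keep)
  }
  n2 <- ncol(mat$values)

  cl <- clinical[match(sample_ids(mat), clinical$sample_id), , drop = FALSE]
  if (anyNA(cl$sample_id)) {
    stop("clinical table is missing samples present in the matrix",
         call. = FALSE)
  }
  er <- call_er(mat, cutoff = er_cutoff)
  her2 <- call_her2(mat, cutoff = her2_cutoff)
  cl$er_status <- unname(er)
  cl$her2_status <- unname(her2)
  cl$subtype <- suppressWarnings(unname(assign_subtype(er, her2)))
  scores <- score_signature(mat, signature)
  cl$score <- unname(scores)

  scan <- cutoff_scan(scores, cl$rfs_months, cl$event,
                      p_source = p_source, ties = ties)
  group <- as.integer(scores > scan$selected_cutoff)
  paired <- paired_cox_panel(group, cl)

  accounting <- data.frame(
    stage = c("input", "after_duplicate_removal", "after_qc_exclusion"),
    n_samples = c(n0, n1, n2),
    n_removed = c(0L, n0 - n1, n1 - n2)
  )
  list(matrix = mat, clinical = cl, scores = scores, scan = scan,
       paired = paired, duplicates_removed = dedup$removed,
       qc_result = qc_result, accounting = accounting)
}
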