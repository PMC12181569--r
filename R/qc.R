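#' Read a per-sample array QC metrics table
#'
#' The five Affymetrix QC parameters: background signal, raw Q (noise),
#' percentage of present calls, detection of the bioB spike-in, and the
#' GAPDH/ACTB 3'-to-5' degradation ratio.
#'
#' @param path Path to a TSV file with header columns `sample_id`,
#'   `background_signal`, `raw_q`, `percent_present`, `biob_detected`
#'   (TRUE/FALSE or 1/0), `ratio_3to5`.
#' @return Data.frame of QC metrics, one row per sample.
#' @export
read_qc <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  required <- c("sample_id", "background_signal", "raw_q", "percent_present",
                "biob_detected", "ratio_3to5")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("QC table missing metric column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$biob_detected <- as.logical(df$biob_detected)
  for (col in c("background_signal", "raw_q", "percent_present", "ratio_3to5")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (any(df$percent_present < 0 | df$percent_present > 100, na.rm = TRUE)) {
    stop("percent_present must lie in [0, 100]", call. = FALSE)
  }
  if (any(df$ratio_3to5 <= 0, na.rm = TRUE)) {
    stop("ratio_3to5 must be positive", call. = FALSE)
  }
  df[required]
}

#' Write a QC metrics table as TSV
#'
#' @param qc QC data.frame as returned by [read_qc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc <- function(qc, path) {
  utils::write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Five-parameter array quality-control filter
#'
#' For each continuous metric (background signal, raw Q, percent present
#' calls, 3'-to-5' ratio), a sample passes when its value lies within a
#' normal-theory 95% band, `mean +/- z * SD`, computed across all samples in
#' the batch; the bioB spike passes when detected. A sample's status follows
#' from its failure count: `0` failed metrics -> `pass`, between 1 and
#' `exclude_min_failures - 1` -> `flagged` (kept, but reported), `>=
#' exclude_min_failures` -> `excluded`. The default exclusion threshold of 3
#' treats isolated metric excursions as warnings and removes only samples
#' failing most of the panel; set `exclude_min_failures = 1` for the strict
#' any-failure rule.
#'
#' @param qc QC metrics data.frame (see [read_qc()]); needs >= 3 samples so
#'   the band has a spread estimate.
#' @param z Band half-width in standard deviations (default `1.96`, the
#'   normal 95% band).
#' @param exclude_min_failures Minimum number of failed metrics for
#'   exclusion (default 3).
#' @return A list with `status` (data.frame: `sample_id`, one logical
#'   `pass_*` column per metric, `n_failed`, `status`), and the id vectors
#'   `passed`, `flagged`, `excluded` partitioning the samples.
#' @export
qc_filter <- function(qc, z = 1.96, exclude_min_failures = 3L) {
  if (nrow(qc) < 3L) stop("QC banding needs at least 3 samples", call. = FALSE)
  cont <- c("background_signal", "raw_q", "percent_present", "ratio_3to5")
  miss <- setdiff(c("sample_id", cont, "biob_detected"), names(qc))
  if (length(miss)) {
    stop("QC table missing metric column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  status <- data.frame(sample_id = qc$sample_id, stringsAsFactors = FALSE)
  for (col in cont) {
    m <- mean(qc[[col]]); s <- stats::sd(qc[[col]])
    status[[paste0("pass_", col)]] <- abs(qc[[col]] - m) <= z * s
  }
  status$pass_biob <- qc$biob_detected
  passcols <- grep("^pass_", names(status))
  status$n_failed <- rowSums(!status[passcols])
  status$status <- ifelse(status$n_failed == 0L, "pass",
                          ifelse(status$n_failed >= exclude_min_failures,
                                 "excluded", "flagged"))
  list(status = status,
       passed = status$sample_id[status$status == "pass"],
       flagged = status$sample_id[status$status == "flagged"],
       excluded = status$sample_id[status$status == "excluded"])
}
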