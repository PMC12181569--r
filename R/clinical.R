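#' Read a per-sample clinical table
#'
#' The clinical carrier is a CSV with a named header. `sample_id`,
#' `rfs_months` (relapse-free survival follow-up, months) and `event`
#' (binary relapse indicator) are required; the covariates `er_status`,
#' `her2_status`, `node_status` (`"positive"`/`"negative"`), `size_cm`,
#' `age_years` and `subtype` are optional. Missing values (empty string or
#' `"NA"`) are preserved as `NA` — nothing is imputed.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with one row per sample and the canonical column
#'   set; status columns are character (`"positive"`/`"negative"`/`NA`),
#'   `subtype` one of `"basal"`, `"luminal_a"`, `"luminal_b"`,
#'   `"her2_enriched"` or `NA`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        colClasses = "character", na.strings = c("", "NA"))
  required <- c("sample_id", "rfs_months", "event")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("clinical table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(sample_id = df$sample_id, stringsAsFactors = FALSE)
  out$rfs_months <- as.numeric(df$rfs_months)
  if (anyNA(out$rfs_months)) stop("rfs_months must be numeric and present", call. = FALSE)
  if (any(out$rfs_months < 0)) stop("rfs_months must be non-negative", call. = FALSE)
  ev <- df$event
  if (!all(ev %in% c("0", "1", "0.0", "1.0", "TRUE", "FALSE"))) {
    stop("event must code to {0,1}", call. = FALSE)
  }
  out$event <- as.integer(ev %in% c("1", "1.0", "TRUE"))
  status_cols <- c("er_status", "her2_status", "node_status")
  for (col in status_cols) {
    v <- if (col %in% names(df)) tolower(df[[col]]) else rep(NA_character_, nrow(df))
    bad <- !is.na(v) & !v %in% c("positive", "negative")
    if (any(bad)) stop(col, " must be positive/negative or missing", call. = FALSE)
    out[[col]] <- v
  }
  out$size_cm <- if ("size_cm" %in% names(df)) as.numeric(df$size_cm) else NA_real_
  out$age_years <- if ("age_years" %in% names(df)) as.numeric(df$age_years) else NA_real_
  for (col in c("size_cm", "age_years")) {
    if (any(!is.na(out[[col]]) & out[[col]] <= 0)) {
      stop(col, " must be positive where present", call. = FALSE)
    }
  }
  sub <- if ("subtype" %in% names(df)) tolower(df$subtype) else rep(NA_character_, nrow(df))
  valid_sub <- c("basal", "luminal_a", "luminal_b", "her2_enriched")
  if (any(!is.na(sub) & !sub %in% valid_sub)) {
    stop("subtype must be one of ", paste(valid_sub, collapse = ", "), call. = FALSE)
  }
  out$subtype <- sub
  if (anyDuplicated(out$sample_id)) stop("duplicate sample_id in clinical table", call. = FALSE)
  out
}

#' Write a clinical table as CSV
#'
#' Missing values are written as `"NA"`.
#'
#' @param clinical Clinical data.frame as returned by [read_clinical()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' Expand a cohort-characteristic count table into per-patient records
#'
#' Utility for worked-example arithmetic on published cohort summaries: given
#' counts of patients per category (events, receptor status, nodal status),
#' builds a clinical data.frame of that many rows so that
#' [summarize_cohort()] can recompute the printed percentages. Categories are
#' filled independently (the joint distribution is not reconstructed), which
#' is sufficient for marginal counts and percentages.
#'
#' @param n_total Total number of patients.
#' @param n_events Number with a relapse event.
#' @param n_er_pos,n_er_neg ER-positive / ER-negative counts (remainder `NA`).
#' @param n_her2_pos,n_her2_neg HER2 counts (remainder `NA`).
#' @param n_node_pos,n_node_neg Nodal status counts (remainder `NA`).
#' @return A clinical data.frame with `n_total` rows (RFS time set to 1 and
#'   sizes/ages to `NA`; only the categorical marginals are meaningful).
#' @export
cohort_from_counts <- function(n_total, n_events,
                               n_er_pos = 0, n_er_neg = 0,
                               n_her2_pos = 0, n_her2_neg = 0,
                               n_node_pos = 0, n_node_neg = 0) {
  fill <- function(n_pos, n_neg) {
    if (n_pos + n_neg > n_total) stop("category counts exceed n_total", call. = FALSE)
    c(rep("positive", n_pos), rep("negative", n_neg),
      rep(NA_character_, n_total - n_pos - n_neg))
  }
  data.frame(
    sample_id = sprintf("P%04d", seq_len(n_total)),
    rfs_months = 1,
    event = rep(c(1L, 0L), c(n_events, n_total - n_events)),
    er_status = fill(n_er_pos, n_er_neg),
    her2_status = fill(n_her2_pos, n_her2_neg),
    node_status = fill(n_node_pos, n_node_neg),
    size_cm = NA_real_, age_years = NA_real_, subtype = NA_character_,
    stringsAsFactors = FALSE
  )
}
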