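#' Construct a validated expression matrix
#'
#' The central container of the pipeline: a probe-by-sample matrix of linear
#' MAS5-scale intensities together with per-sample dataset/platform
#' provenance and the designated cross-platform shared probe set (the
#' analogue of the 22,277-probe GPL96/GPL570/GPL571 overlap; any size is
#' accepted for synthetic data).
#'
#' @param values Numeric matrix, probes in rows and samples in columns, with
#'   unique row and column names. Intensities must be finite and
#'   non-negative.
#' @param dataset Character vector of dataset labels, one per sample
#'   (recycled if length 1).
#' @param platform Character vector of platform labels, one per sample
#'   (recycled if length 1).
#' @param shared_probes Character vector of probe IDs designated as the
#'   cross-platform overlap used for scaling normalization and duplicate
#'   detection. Defaults to all probes.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `dataset`, `platform` (both named by sample) and `shared_probes`.
#' @seealso [read_expression()], [scale_normalize()]
#' @export
expr_matrix <- function(values, dataset, platform = "GPL570",
                        shared_probes = rownames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (probes x samples)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have probe rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate probe IDs in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample IDs in expression matrix", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("expression intensities must be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("expression intensities must be non-negative", call. = FALSE)
  }
  n <- ncol(values)
  dataset <- rep_len(as.character(dataset), n)
  platform <- rep_len(as.character(platform), n)
  names(dataset) <- names(platform) <- colnames(values)
  shared_probes <- as.character(shared_probes)
  if (!all(shared_probes %in% rownames(values))) {
    stop("`shared_probes` must be a subset of the probe IDs", call. = FALSE)
  }
  structure(
    list(values = values, dataset = dataset, platform = platform,
         shared_probes = shared_probes),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "expr_matrix: %d probes x %d samples (%d shared probes, %d dataset(s): %s)\n",
    nrow(x$values), ncol(x$values), length(x$shared_probes),
    length(unique(x$dataset)), paste(unique(x$dataset), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

probe_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read a tab-delimited expression matrix
#'
#' Expects probe IDs in the first column and a header row of sample IDs; the
#' body must be numeric, finite and non-negative (linear MAS5 intensities).
#'
#' @param path Path to a TSV file.
#' @param dataset Dataset label applied to every sample in the file.
#' @param platform Platform label applied to every sample in the file.
#' @param shared_probes Optional probe subset designated as the
#'   cross-platform overlap; defaults to all probes in the file.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, dataset = "dataset1", platform = "GPL570",
                            shared_probes = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expression file needs a probe column and >=1 sample", call. = FALSE)
  header <- scan(path, what = character(), nlines = 1L, sep = "\t",
                 quiet = TRUE)
  if (anyDuplicated(header[-1L])) {
    stop("duplicate sample IDs in expression file header", call. = FALSE)
  }
  probes <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, colnames(body)))
  if (anyNA(vals)) stop("non-numeric intensity values in ", path, call. = FALSE)
  rownames(vals) <- probes
  if (is.null(shared_probes)) shared_probes <- probes
  expr_matrix(vals, dataset = dataset, platform = platform,
              shared_probes = shared_probes)
}

#' Write an expression matrix as TSV
#'
#' Writes probe IDs in the first column (`probe_id`) followed by one column
#' per sample, at full double precision so a read/write round trip is
#' lossless.
#'
#' @param x An [expr_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(probe_id = probe_ids(x),
                   format(x$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge expression matrices over their common probe set
#'
#' Concatenates samples of several matrices, restricted to the probes present
#' in every input (order taken from the first matrix); the merged shared
#' probe set is the intersection of the inputs' shared sets. Sample IDs must
#' be globally unique.
#'
#' @param matrices List of [expr_matrix()] objects.
#' @return A single merged [expr_matrix()].
#' @export
merge_expression <- function(matrices) {
  stopifnot(length(matrices) >= 1L, all(vapply(matrices, inherits, TRUE, "expr_matrix")))
  if (length(matrices) == 1L) return(matrices[[1L]])
  common <- Reduce(intersect, lapply(matrices, probe_ids))
  if (length(common) == 0L) stop("matrices share no probes", call. = FALSE)
  shared <- Reduce(intersect, lapply(matrices, function(m) m$shared_probes))
  shared <- intersect(common, shared)
  if (length(shared) == 0L) stop("matrices share no shared_probes", call. = FALSE)
  vals <- do.call(cbind, lapply(matrices, function(m) m$values[common, , drop = FALSE]))
  expr_matrix(vals,
              dataset = unlist(lapply(matrices, `[[`, "dataset"), use.names = FALSE),
              platform = unlist(lapply(matrices, `[[`, "platform"), use.names = FALSE),
              shared_probes = shared)
}

#' Subset an expression matrix by sample
#'
#' @param x An [expr_matrix()].
#' @param samples Character vector of sample IDs to keep, in the given order.
#' @return An [expr_matrix()] restricted to `samples`.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "expr_matrix"))
  missing <- setdiff(samples, sample_ids(x))
  if (length(missing)) {
    stop("unknown sample IDs: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  expr_matrix(x$values[, samples, drop = FALSE],
              dataset = x$dataset[samples], platform = x$platform[samples],
              shared_probes = x$shared_probes)
}
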