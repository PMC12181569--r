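#' Secondary scaling normalization to a common shared-probe mean
#'
#' Mitigates between-dataset scale (batch) differences after MAS5: each
#' sample is multiplied by one factor `f = target_mean / mean(shared-probe
#' intensities)` so that afterwards the mean over the shared probe set
#' equals `target_mean` exactly for every array. The factor is computed on
#' the shared (cross-platform) probes only but applied to all probes, so
#' platform-specific probes stay on the same within-sample scale.
#' Within-sample probe ratios are preserved exactly and the operation is
#' idempotent.
#'
#' @param x An [expr_matrix()] with a non-empty `shared_probes` set.
#' @param target_mean Target shared-probe mean per array (default 1000).
#' @return The normalized [expr_matrix()].
#' @export
scale_normalize <- function(x, target_mean = 1000) {
  stopifnot(inherits(x, "expr_matrix"), target_mean > 0)
  if (length(x$shared_probes) == 0L) {
    stop("shared_probes is empty; nothing to normalize against", call. = FALSE)
  }
  means <- colMeans(x$values[x$shared_probes, , drop = FALSE])
  bad <- means <= 0
  if (any(bad)) {
    stop("cannot normalize sample(s) with zero shared-probe mean: ",
         paste(names(means)[bad], collapse = ", "), call. = FALSE)
  }
  x$values <- sweep(x$values, 2L, target_mean / means, `*`)
  x
}

#' Remove duplicate samples across merged datasets
#'
#' Two samples are duplicates when their expression vectors over the shared
#' probe set are identical after rounding to `precision` significant figures
#' (identical normalized values, as produced when the same array was
#' deposited in more than one repository dataset). Within a duplicate group
#' the sample from the earliest dataset in `priority` survives; ties within
#' one dataset keep the first sample in column order, so permuting samples
#' within a dataset never changes which dataset's copy survives.
#'
#' @param x A merged [expr_matrix()] (typically after [scale_normalize()],
#'   so copies deposited at different raw scales compare equal).
#' @param priority Character vector of dataset labels in publication order
#'   (first = earliest, retained). Defaults to order of first appearance in
#'   `x`.
#' @param precision Significant figures used when comparing intensities
#'   (default 4), guarding against serialization noise.
#' @return List with `matrix` (the deduplicated [expr_matrix()]) and
#'   `removed`, a data.frame pairing each `removed_id` with its surviving
#'   `retained_id`.
#' @export
remove_duplicates <- function(x, priority = unique(x$dataset), precision = 4L) {
  stopifnot(inherits(x, "expr_matrix"))
  extra <- setdiff(unique(x$dataset), priority)
  if (length(extra)) {
    stop("datasets missing from `priority`: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  shared <- x$values[x$shared_probes, , drop = FALSE]
  keys <- apply(signif(shared, precision), 2L, paste, collapse = ",")
  rank <- match(x$dataset, priority)
  ids <- sample_ids(x)
  retained <- character(0)
  removed_id <- retained_id <- character(0)
  for (grp in split(seq_along(ids), keys)) {
    # survivor: earliest-priority dataset, then first column within it
    survivor <- grp[order(rank[grp], grp)][1L]
    retained <- c(retained, ids[survivor])
    losers <- setdiff(grp, survivor)
    removed_id <- c(removed_id, ids[losers])
    retained_id <- c(retained_id, rep(ids[survivor], length(losers)))
  }
  keep <- sort(match(retained, ids))
  list(
    matrix = subset_samples(x, ids[keep]),
    removed = data.frame(removed_id = removed_id, retained_id = retained_id,
                         stringsAsFactors = FALSE)
  )
}
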