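#' Expression-surrogate estrogen-receptor call
#'
#' Classifies each sample as ER positive or negative from the intensity of
#' the ESR1 probe set `205225_at` at the established linear-scale cutoff of
#' 500. Samples exactly at the cutoff call positive (the `>=` convention;
#' configurable only through `cutoff`).
#'
#' @param x A scale-normalized [expr_matrix()].
#' @param probe Probe-set ID carrying the receptor transcript.
#' @param cutoff Linear intensity cutoff.
#' @return Named character vector per sample: `"positive"` / `"negative"`.
#' @export
call_er <- function(x, probe = "205225_at", cutoff = 500) {
  call_receptor(x, probe, cutoff)
}

#' Expression-surrogate HER2 (ERBB2) call
#'
#' As [call_er()], using probe set `216836_s_at` at cutoff 4800.
#'
#' @inheritParams call_er
#' @return Named character vector per sample: `"positive"` / `"negative"`.
#' @export
call_her2 <- function(x, probe = "216836_s_at", cutoff = 4800) {
  call_receptor(x, probe, cutoff)
}

call_receptor <- function(x, probe, cutoff) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!probe %in% probe_ids(x)) {
    stop("receptor probe ", probe, " not present in matrix", call. = FALSE)
  }
  v <- x$values[probe, ]
  ifelse(v >= cutoff, "positive", "negative")
}

#' St Gallen surrogate subtype from receptor calls
#'
#' Maps expression-surrogate receptor status to the St Gallen surrogate
#' intrinsic subtypes: ER-/HER2- is basal-like, ER-/HER2+ is HER2-enriched,
#' ER+/HER2+ is luminal B. ER+/HER2- tumors split on a proliferation
#' criterion (high -> luminal B, low -> luminal A); when no proliferation
#' input is available they default to luminal A and a warning is issued,
#' since the luminal A/B boundary is then not identified.
#'
#' @param er,her2 Character vectors of `"positive"`/`"negative"` (or `NA`).
#' @param proliferation_high Optional logical vector (e.g. an MKI67 probe
#'   dichotomized at a caller-chosen cutoff).
#' @return Character vector of subtypes (`"basal"`, `"luminal_a"`,
#'   `"luminal_b"`, `"her2_enriched"`); `NA` where a receptor call is
#'   unknown.
#' @export
assign_subtype <- function(er, her2, proliferation_high = NULL) {
  stopifnot(length(er) == length(her2))
  if (is.null(proliferation_high)) {
    if (any(er %in% "positive" & her2 %in% "negative")) {
      warning("no proliferation input: ER+/HER2- tumors assigned luminal_a; ",
              "the luminal A/B split is not identified", call. = FALSE)
    }
    proliferation_high <- rep(FALSE, length(er))
  }
  stopifnot(length(proliferation_high) == length(er))
  out <- rep(NA_character_, length(er))
  known <- !is.na(er) & !is.na(her2)
  erp <- er == "positive"; h2p <- her2 == "positive"
  out[known & !erp & !h2p] <- "basal"
  out[known & !erp & h2p] <- "her2_enriched"
  out[known & erp & h2p] <- "luminal_b"
  lumsplit <- known & erp & !h2p
  out[lumsplit] <- ifelse(proliferation_high[lumsplit] %in% TRUE,
                          "luminal_b", "luminal_a")
  if (!is.null(names(er))) names(out) <- names(er)
  out
}

#' Mean-expression signature score
#'
#' Scores each sample as the unweighted mean over the signature's genes of
#' that gene's value, where a gene's value is the mean of its available
#' probes. Genes with no probe present in the matrix are excluded from the
#' mean and reported in the `missing_genes` attribute, never silently
#' dropped. Scores are degree-1 homogeneous in intensity, so they should be
#' computed on the scale-normalized matrix.
#'
#' @param x An [expr_matrix()] (after [scale_normalize()]).
#' @param sig A [signature_def()].
#' @return Named numeric vector of per-sample scores; attributes
#'   `missing_genes` (genes with no available probe) and `genes_used`.
#' @export
score_signature <- function(x, sig) {
  stopifnot(inherits(x, "expr_matrix"), inherits(sig, "signature_def"))
  avail <- lapply(sig$probes_of, intersect, probe_ids(x))
  usable <- lengths(avail) > 0L
  if (!any(usable)) {
    stop("no signature gene has a probe in the matrix; missing probes: ",
         paste(unlist(sig$probes_of), collapse = ", "), call. = FALSE)
  }
  gene_vals <- vapply(avail[usable], function(p) {
    colMeans(x$values[p, , drop = FALSE])
  }, numeric(ncol(x$values)))
  if (ncol(x$values) == 1L) gene_vals <- matrix(gene_vals, nrow = 1L)
  score <- rowMeans(gene_vals)
  names(score) <- sample_ids(x)
  attr(score, "missing_genes") <- names(avail)[!usable]
  attr(score, "genes_used") <- names(avail)[usable]
  score
}
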