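#' Construct a gene-signature definition
#'
#' A signature is a named set of genes, each mapped to one or more probe-set
#' IDs on the array platform. Scoring averages probes within a gene, then
#' genes within the signature (see [score_signature()]).
#'
#' @param name Signature name (e.g. `"SenMayo"`).
#' @param gene Character vector of gene symbols, one entry per (gene, probe)
#'   pair.
#' @param probe Character vector of probe-set IDs, parallel to `gene`.
#' @return An object of class `signature_def`: list with `name` and
#'   `probes_of`, a named list mapping each gene to its probe IDs. Duplicate
#'   (gene, probe) pairs are collapsed; gene and probe order are normalized
#'   (sorted) so the definition is order-invariant.
#' @export
signature_def <- function(name, gene, probe) {
  gene <- as.character(gene)
  probe <- as.character(probe)
  if (length(gene) != length(probe) || length(gene) == 0L) {
    stop("`gene` and `probe` must be non-empty parallel vectors", call. = FALSE)
  }
  keep <- !duplicated(paste0(gene, "\r", probe))
  gene <- gene[keep]; probe <- probe[keep]
  probes_of <- lapply(split(probe, gene), function(p) sort(unique(p)))
  probes_of <- probes_of[sort(names(probes_of))]
  structure(list(name = name, probes_of = probes_of), class = "signature_def")
}

#' @export
print.signature_def <- function(x, ...) {
  cat(sprintf("signature '%s': %d genes, %d probes\n", x$name,
              length(x$probes_of), length(unlist(x$probes_of))))
  invisible(x)
}

#' Read a signature definition from TSV
#'
#' Expects a two-column TSV with header columns `gene` and `probe`; extra
#' columns are ignored. Duplicated rows collapse to one mapping and row
#' order does not affect the result.
#'
#' @param path Path to the TSV file.
#' @param name Signature name; defaults to the file name without extension.
#' @return A [signature_def()].
#' @export
read_signature <- function(path, name = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("signature file is empty", call. = FALSE)
  if (!all(c("gene", "probe") %in% names(df))) {
    stop("signature file needs `gene` and `probe` columns", call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  signature_def(name, df$gene, df$probe)
}

#' Write a signature definition as TSV
#'
#' @param sig A [signature_def()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "signature_def"))
  df <- data.frame(
    gene = rep(names(sig$probes_of), lengths(sig$probes_of)),
    probe = unlist(sig$probes_of, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
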