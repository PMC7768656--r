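## Preprocessing chain: quantile normalization (RNA-seq raw counts),
## log2 transform, low-expression filtering, probe-to-gene collapsing.
## Canonical RNA-seq order: raw -> quantileNormalize -> log2Transform ->
## filterLowExpression; microarray log intensities skip the first two.

#' Log2-transform an expression matrix
#'
#' Transforms each cell `x` to `log2(x + offset)`. The default offset of
#' 1 is the usual pseudo-count for count-like data; pass `offset = 0`
#' for strictly positive intensity data.
#'
#' @param se SummarizedExperiment on the raw scale.
#' @param offset Pseudo-count added before the logarithm.
#' @return The transformed SummarizedExperiment with
#'   `metadata()$scale == "log2"`.
#' @export
log2Transform <- function(se, offset = 1) {
  if (identical(S4Vectors::metadata(se)$scale, "log2"))
    stopf("matrix is already on the log2 scale")
  m <- SummarizedExperiment::assay(se, "expr")
  bad <- rowSums(m + offset <= 0) > 0
  if (any(bad))
    stopf("log2 undefined (value + offset <= 0) for gene(s): %s",
          paste(utils::head(rownames(m)[bad], 5), collapse = ", "))
  SummarizedExperiment::assay(se, "expr") <- log2(m + offset)
  S4Vectors::metadata(se)$scale <- "log2"
  se
}

#' Filter genes with widespread low expression
#'
#' Removes genes for which strictly more than `max_fraction` of samples
#' fall below `threshold` on the log2 scale (default: more than 25% of
#' samples below 1). Retained rows are untouched.
#'
#' @param se SummarizedExperiment on the log2 scale.
#' @param threshold Low-expression cutoff on the log2 scale.
#' @param max_fraction Largest tolerated fraction of low samples.
#' @return The filtered SummarizedExperiment;
#'   `metadata()$n_low_removed` records the removed-gene count.
#' @export
filterLowExpression <- function(se, threshold = 1, max_fraction = 0.25) {
  if (!identical(S4Vectors::metadata(se)$scale, "log2"))
    stopf("filterLowExpression expects a log2-scale matrix")
  m <- SummarizedExperiment::assay(se, "expr")
  frac_low <- rowMeans(m < threshold)
  keep <- frac_low <= max_fraction          # strict "more than" removes
  if (!any(keep))
    stopf("all genes removed; review the low-expression threshold (%g)",
          threshold)
  removed <- sum(!keep)
  message(sprintf("filterLowExpression: %d gene(s) removed", removed))
  out <- se[keep, ]
  S4Vectors::metadata(out)$n_low_removed <- removed
  out
}

#' Quantile-normalize samples
#'
#' Forces every sample (column) to share a common empirical
#' distribution: the k-th smallest value in each sample is replaced by
#' the mean of the k-th smallest values across samples, with ties
#' receiving the mean of the reference values they span
#' (via [limma::normalizeQuantiles()]). Idempotent and rank-preserving
#' within samples.
#'
#' @param se SummarizedExperiment with at least two samples.
#' @return The normalized SummarizedExperiment.
#' @export
quantileNormalize <- function(se) {
  m <- SummarizedExperiment::assay(se, "expr")
  if (ncol(m) < 2) {
    warnf("quantileNormalize: single-sample matrix returned unchanged")
    return(se)
  }
  SummarizedExperiment::assay(se, "expr") <-
    limma::normalizeQuantiles(m, ties = TRUE)
  se
}

#' Read a probe-to-gene map
#'
#' Two-column delimited text `probe_id  gene_symbol` (many-to-one).
#'
#' @param path Path to the map file.
#' @return A named character vector: names = probe ids, values = gene
#'   symbols.
#' @export
readProbeMap <- function(path) {
  if (!file.exists(path)) stopf("probe map not found: %s", path)
  delim <- detectDelim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("probe map needs two columns")
  probes <- as.character(df[[1]]); genes <- as.character(df[[2]])
  if (anyDuplicated(probes))
    stopf("duplicated probe id(s): %s",
          paste(unique(probes[duplicated(probes)]), collapse = ", "))
  if (any(!nzchar(genes))) stopf("empty gene symbol in probe map")
  stats::setNames(genes, probes)
}

#' Collapse probes to gene symbols
#'
#' Replaces the probe rows mapping to one gene symbol by their
#' arithmetic per-sample mean. Probes absent from the map are dropped
#' (count reported).
#'
#' @param se SummarizedExperiment whose rows are probes.
#' @param map Named character vector from [readProbeMap()].
#' @return A SummarizedExperiment with one row per mapped gene symbol.
#' @export
collapseProbes <- function(se, map) {
  if (length(map) == 0) stopf("empty probe map")
  m <- SummarizedExperiment::assay(se, "expr")
  mapped <- rownames(m) %in% names(map)
  if (sum(!mapped) > 0)
    message(sprintf("collapseProbes: %d unmapped probe(s) dropped",
                    sum(!mapped)))
  if (!any(mapped)) stopf("no probes present in the map")
  m <- m[mapped, , drop = FALSE]
  sym <- map[rownames(m)]
  collapsed <- rowsum(m, group = sym, reorder = TRUE) /
    as.vector(table(sym)[sort(unique(sym))])
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = collapsed))
  S4Vectors::metadata(out) <- S4Vectors::metadata(se)
  out
}
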