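## Box-Cox normality sweep and tumor-purity association analyses.

#' Box-Cox power transform
#'
#' `(x^lambda - 1) / lambda`, with the analytic limit `log(x)` at
#' `lambda = 0`. Strictly increasing in `x` for every `lambda`, so
#' within-gene sample ranks are preserved.
#'
#' @param x Positive numeric vector.
#' @param lambda Power parameter.
#' @return Transformed vector.
#' @export
boxCoxTransform <- function(x, lambda) {
  if (any(x <= 0)) stopf("Box-Cox requires strictly positive values")
  if (lambda == 0) log(x) else (x^lambda - 1) / lambda
}

#' Box-Cox normality sweep
#'
#' For each `lambda` on the grid, transforms every gene and counts how
#' many genes pass a Shapiro-Wilk normality test at level `alpha`; the
#' count on the untransformed data is reported alongside. Genes with
#' any non-positive value lie outside the transform's domain and are
#' skipped (their number is reported).
#'
#' @param se SummarizedExperiment.
#' @param lambdas Numeric grid (default the integers -10..10).
#' @param alpha Normality level (default 0.01).
#' @return A list of class `"boxcox_sweep"`: `table` (data.frame
#'   `lambda`, `n_normal_genes`), `untransformed_count`, `n_tested`,
#'   `n_skipped`.
#' @export
boxCoxSweep <- function(se, lambdas = -10:10, alpha = 0.01) {
  if (length(lambdas) == 0) stopf("empty lambda grid")
  m <- SummarizedExperiment::assay(se, "expr")
  pos <- rowSums(m <= 0) == 0
  n_skipped <- sum(!pos)
  if (n_skipped > 0)
    message(sprintf("boxCoxSweep: %d gene(s) with non-positive values skipped",
                    n_skipped))
  m <- m[pos, , drop = FALSE]
  if (nrow(m) == 0) stopf("no genes with strictly positive values")
  shapiro_ok <- function(v) {
    p <- tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
    !is.na(p) && p > alpha
  }
  untransformed <- sum(apply(m, 1, shapiro_ok))
  counts <- vapply(lambdas, function(l) {
    sum(apply(m, 1, function(v) shapiro_ok(boxCoxTransform(v, l))))
  }, 0L)
  structure(list(
    table = data.frame(lambda = lambdas, n_normal_genes = counts),
    untransformed_count = untransformed,
    n_tested = nrow(m), n_skipped = n_skipped
  ), class = "boxcox_sweep")
}

#' Per-gene correlation with tumor purity
#'
#' Correlates every gene's expression with the pathologist purity
#' estimate across the samples where purity is available, adjusts the
#' p-values with Benjamini-Hochberg, and flags genes whose adjusted p
#' falls below `alpha_adj`.
#'
#' @param se Aligned cohort whose `colData` carries a `purity` column.
#' @param method `"spearman"` (default, robust to non-Normal shapes) or
#'   `"pearson"`.
#' @param alpha_adj Adjusted-p cutoff (default 0.001).
#' @return A data.frame `gene_id`, `cor`, `p`, `p_adj`, `significant`.
#' @export
purityScan <- function(se, method = c("spearman", "pearson"),
                       alpha_adj = 0.001) {
  method <- match.arg(method)
  cd <- SummarizedExperiment::colData(se)
  if (!"purity" %in% colnames(cd)) stopf("cohort has no purity column")
  purity <- cd$purity
  has <- !is.na(purity)
  if (sum(has) < 10) stopf("purity available for fewer than 10 samples")
  if (stats::sd(purity[has]) == 0) stopf("constant purity values")
  m <- SummarizedExperiment::assay(se, "expr")[, has, drop = FALSE]
  pv <- purity[has]
  res <- t(apply(m, 1, function(x) {
    ct <- suppressWarnings(stats::cor.test(x, pv, method = method,
                                           exact = FALSE))
    c(ct$estimate, ct$p.value)
  }))
  p_adj <- stats::p.adjust(res[, 2], method = "BH")
  data.frame(gene_id = rownames(m), cor = unname(res[, 1]),
             p = unname(res[, 2]), p_adj = p_adj,
             significant = p_adj < alpha_adj,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Association between Normal shape and purity influence
#'
#' Cross-tabulates genes as Normal vs non-Normal (by their shape call)
#' against purity-significant vs not, and tests the association with a
#' two-sided Fisher exact test (hypergeometric; conditional-MLE odds
#' ratio). Genes called `UNKNOWN` carry no shape verdict and are
#' excluded.
#'
#' @param calls A [ShapeCalls-class] object.
#' @param purity_flags Logical vector named by gene id (the
#'   `significant` column of [purityScan()]).
#' @return A list of class `"purity_association"`: `table` (2x2),
#'   `odds_ratio`, `p`.
#' @export
purityAssociation <- function(calls, purity_flags) {
  fam <- geneFamilies(calls)
  fam <- fam[fam != "UNKNOWN"]
  common <- intersect(names(fam), names(purity_flags))
  if (length(common) == 0) stopf("no genes shared between calls and flags")
  is_normal <- factor(fam[common] == "NORMAL", levels = c(TRUE, FALSE),
                      labels = c("Normal", "non-Normal"))
  is_sig <- factor(purity_flags[common], levels = c(TRUE, FALSE),
                   labels = c("purity-significant", "not"))
  tab <- table(is_normal, is_sig)
  if (any(rowSums(tab) == 0))
    stopf("need at least one gene in each classification arm")
  ft <- stats::fisher.test(tab)
  structure(list(table = tab, odds_ratio = unname(ft$estimate),
                 p = ft$p.value),
            class = "purity_association")
}

#' @export
print.purity_association <- function(x, ...) {
  print(x$table)
  cat(sprintf("Fisher exact: odds ratio %.4g, p = %.4g\n",
              x$odds_ratio, x$p))
  invisible(x)
}
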