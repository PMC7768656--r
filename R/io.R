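## Cohort input/output: expression matrices, clinical tables, alignment.
## Expression lives in a SummarizedExperiment (assay "expr"); the scale
## ("raw" or "log2") is tracked in metadata(se)$scale. Clinical data is a
## DataFrame keyed by sample id and, after alignCohort(), sits in colData.

detectDelim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

#' Read a genes-by-samples expression matrix
#'
#' Expects delimited text (tab or comma, auto-detected) with gene
#' identifiers in the first column and a header row of sample
#' identifiers. Duplicated identifiers, non-numeric cells and missing
#' values are hard errors; imputation is deliberately not offered.
#'
#' @param path Path to the matrix file.
#' @param scale Scale of the stored values: `"raw"` (linear counts or
#'   intensities) or `"log2"`.
#' @return A [SummarizedExperiment::SummarizedExperiment] with a single
#'   assay `"expr"`; `metadata()$scale` records the scale.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), f)
#' se <- readExpressionMatrix(f, scale = "raw")
#' dim(se)
#' @export
readExpressionMatrix <- function(path, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  delim <- detectDelim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2) stopf("expression file needs a gene-id column and >= 1 sample")
  gene_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g) > 0)
    stopf("duplicated gene id(s): %s", paste(unique(dup_g), collapse = ", "))
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s) > 0)
    stopf("duplicated sample id(s): %s", paste(unique(dup_s), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stopf("non-numeric or missing value \"%s\" at gene \"%s\", sample \"%s\"",
          vals[i, j], gene_ids[i], sample_ids[j])
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = num))
  S4Vectors::metadata(se)$scale <- scale
  se
}

#' Write an expression matrix as TSV
#'
#' Full-precision tab-separated output; a round trip through
#' [readExpressionMatrix()] reproduces finite doubles bit-exactly.
#'
#' @param se SummarizedExperiment with an `"expr"` assay.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(se, path) {
  m <- SummarizedExperiment::assay(se, "expr")
  df <- data.frame(gene_id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical survival table
#'
#' Delimited text with header `sample_id`, `time_days`, `event` and an
#' optional `purity` column (percent, 0-100). Rows with missing survival
#' time are dropped and their number reported via a message, matching
#' the source methodology of omitting missing survival times.
#'
#' @param path Path to the clinical file.
#' @return A [S4Vectors::DataFrame] with rownames = sample ids and
#'   columns `time_days`, `event`, and `purity` when supplied;
#'   `metadata()$n_dropped` records how many rows were dropped.
#' @export
readClinical <- function(path) {
  if (!file.exists(path)) stopf("clinical file not found: %s", path)
  delim <- detectDelim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_days", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stopf("clinical file lacks column(s): %s", paste(miss, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0)
    stopf("duplicated sample id(s): %s", paste(unique(dup), collapse = ", "))
  drop <- is.na(df$time_days)
  n_dropped <- sum(drop)
  if (n_dropped > 0) {
    message(sprintf("readClinical: %d row(s) with missing survival time dropped",
                    n_dropped))
    df <- df[!drop, , drop = FALSE]
  }
  if (any(df$time_days < 0)) {
    bad <- df$sample_id[df$time_days < 0][1]
    stopf("negative survival time for sample \"%s\"", bad)
  }
  if (!all(df$event %in% c(0, 1))) {
    bad <- df$sample_id[!df$event %in% c(0, 1)][1]
    stopf("event indicator outside {0,1} for sample \"%s\"", bad)
  }
  out <- S4Vectors::DataFrame(time_days = as.numeric(df$time_days),
                              event = as.integer(df$event),
                              row.names = df$sample_id)
  if ("purity" %in% colnames(df)) {
    p <- as.numeric(df$purity)
    ok <- is.na(p) | (p >= 0 & p <= 100)
    if (!all(ok)) stopf("purity outside [0,100] for sample \"%s\"",
                        df$sample_id[!ok][1])
    out$purity <- p
  }
  S4Vectors::metadata(out)$n_dropped <- n_dropped
  out
}

#' Align an expression matrix with a clinical table
#'
#' Restricts both objects to the intersection of their sample ids and
#' installs the clinical columns in `colData`. Sample order follows the
#' expression matrix so downstream splits are deterministic. Applying
#' the function twice equals applying it once.
#'
#' @param se SummarizedExperiment from [readExpressionMatrix()].
#' @param clin DataFrame from [readClinical()].
#' @return A SummarizedExperiment restricted to the common samples with
#'   `time_days`, `event` (and `purity`) in `colData`.
#' @export
alignCohort <- function(se, clin) {
  common <- intersect(colnames(se), rownames(clin))
  if (length(common) == 0)
    stopf("no samples shared between expression and clinical data")
  common <- colnames(se)[colnames(se) %in% common]  # expression order
  out <- se[, common]
  cd <- clin[common, , drop = FALSE]
  for (nm in colnames(cd)) SummarizedExperiment::colData(out)[[nm]] <- cd[[nm]]
  message(sprintf("alignCohort: %d common sample(s)", length(common)))
  out
}

#' Extract the survival table of an aligned cohort
#'
#' @param se Aligned SummarizedExperiment (see [alignCohort()]).
#' @return A data.frame with `sample_id`, `time_days`, `event` and
#'   `purity` when present.
#' @export
survivalTable <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  if (!all(c("time_days", "event") %in% colnames(cd)))
    stopf("cohort carries no survival data; run alignCohort() first")
  out <- data.frame(sample_id = colnames(se),
                    time_days = cd$time_days,
                    event = cd$event,
                    stringsAsFactors = FALSE)
  if ("purity" %in% colnames(cd)) out$purity <- cd$purity
  out
}
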