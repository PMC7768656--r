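#' Analysis configuration
#'
#' Bundles the tunable parameters of the shape-classification and
#' survival pipeline. Defaults follow the published methodology where it
#' states a value: Shapiro/bootstrap-KS significance 0.01, log-rank
#' significance 0.05, bimodality-index cut 1.1, tenth-percentile tails,
#' 1000 survival-forest trees, 100 train/test repeats.
#'
#' @param alpha_fit Significance level for the goodness-of-fit stage
#'   (Shapiro-Wilk and bootstrap KS). Default 0.01.
#' @param alpha_survival Significance level for the log-rank test.
#'   Default 0.05.
#' @param bi_threshold Bimodality-index threshold above which a gene is
#'   called bimodal. Default 1.1.
#' @param tail_fraction Fraction of samples in each extreme tail when
#'   splitting patients. Default 0.10 (the tenth percentile).
#' @param n_bootstrap Parametric-bootstrap replicates for the KS tests.
#'   Default 200.
#' @param n_trees Trees in the random survival forest. Default 1000.
#' @param n_repeats Train/test repeats in the classifier comparison.
#'   Default 100.
#' @param n_selected_genes Genes selected per assumption arm (top-k).
#'   Default 100.
#' @param rng_seed Integer master seed for all randomized steps.
#' @param cauchy_scale Either `"half-iqr"` (scale = IQR/2, the
#'   statistically consistent Cauchy estimator, since the Cauchy
#'   quartiles sit at location +/- scale) or `"iqr"` (scale = IQR, the
#'   literal median/IQR convention). Default `"half-iqr"`.
#' @param log2_offset Pseudo-count added before log2 of count-like data.
#'   Default 1.
#' @param mode_split Either `"mixture"` (bimodal patient groups from the
#'   mixture responsibilities) or `"kmeans"` (2-means fallback).
#' @return A named list of class `"shape_config"`.
#' @examples
#' cfg <- shapeConfig(n_bootstrap = 99, rng_seed = 7)
#' cfg$alpha_fit
#' @export
shapeConfig <- function(alpha_fit = 0.01,
                        alpha_survival = 0.05,
                        bi_threshold = 1.1,
                        tail_fraction = 0.10,
                        n_bootstrap = 200L,
                        n_trees = 1000L,
                        n_repeats = 100L,
                        n_selected_genes = 100L,
                        rng_seed = 1L,
                        cauchy_scale = c("half-iqr", "iqr"),
                        log2_offset = 1,
                        mode_split = c("mixture", "kmeans")) {
  cauchy_scale <- match.arg(cauchy_scale)
  mode_split <- match.arg(mode_split)
  if (!(alpha_fit > 0 && alpha_fit < 1))
    stopf("alpha_fit must lie in (0, 1), got %g", alpha_fit)
  if (!(alpha_survival > 0 && alpha_survival < 1))
    stopf("alpha_survival must lie in (0, 1), got %g", alpha_survival)
  if (!(tail_fraction > 0 && tail_fraction < 0.5))
    stopf("tail_fraction must lie in (0, 0.5), got %g", tail_fraction)
  if (bi_threshold <= 0) stopf("bi_threshold must be positive")
  for (nm in c("n_bootstrap", "n_trees", "n_repeats", "n_selected_genes")) {
    v <- get(nm)
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != as.integer(v))
      stopf("%s must be a positive integer", nm)
  }
  structure(list(
    alpha_fit = alpha_fit, alpha_survival = alpha_survival,
    bi_threshold = bi_threshold, tail_fraction = tail_fraction,
    n_bootstrap = as.integer(n_bootstrap), n_trees = as.integer(n_trees),
    n_repeats = as.integer(n_repeats),
    n_selected_genes = as.integer(n_selected_genes),
    rng_seed = as.integer(rng_seed), cauchy_scale = cauchy_scale,
    log2_offset = log2_offset, mode_split = mode_split
  ), class = "shape_config")
}

#' Read a configuration file
#'
#' Accepts either a flat `key=value` text file or a JSON object whose
#' keys mirror [shapeConfig()] arguments. Unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return A `"shape_config"` list.
#' @export
readShapeConfig <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  txt <- readLines(path, warn = FALSE)
  joined <- trimws(paste(txt, collapse = "\n"))
  if (startsWith(joined, "{")) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stopf("jsonlite is required to read JSON configuration")
    vals <- jsonlite::fromJSON(joined)
  } else {
    lines <- trimws(txt)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- lengths(kv) != 2
    if (any(bad)) stopf("malformed config line: %s", lines[bad][1])
    vals <- lapply(kv, function(p) {
      v <- trimws(p[2])
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    })
    names(vals) <- vapply(kv, function(p) trimws(p[1]), "")
  }
  known <- names(formals(shapeConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(shapeConfig, vals)
}

#' @export
print.shape_config <- function(x, ...) {
  cat("Shape-analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-17s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
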