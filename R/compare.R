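## Classifier-comparison protocol: repeated 2/3-1/3 train/test splits;
## per repeat, gene selection under the SHAPE / SYMMETRIC / RANDOM
## assumptions (classification restricted to the training set), a
## random survival forest per arm, and misclassification scoring on the
## held-out third. All three arms share the partition within a repeat.

#' Select genes on a training cohort under one assumption
#'
#' `SHAPE`: classify the training genes, run the shape-aware prognostic
#' scan and keep the `k` smallest log-rank p-values. `SYMMETRIC`: the
#' same top-k from the two-tailed scan (no classification needed).
#' `RANDOM`: `k` genes drawn uniformly without replacement.
#'
#' @param train_se Aligned training cohort.
#' @param cfg A [shapeConfig()] list (`cfg$n_selected_genes` = k).
#' @param assumption `"SHAPE"`, `"SYMMETRIC"` or `"RANDOM"`.
#' @param seed Integer seed (bootstrap classification / random draw).
#' @return Character vector of selected gene ids.
#' @export
selectGenes <- function(train_se, cfg = shapeConfig(),
                        assumption = c("SHAPE", "SYMMETRIC", "RANDOM"),
                        seed = cfg$rng_seed) {
  assumption <- match.arg(assumption)
  genes <- rownames(train_se)
  k <- cfg$n_selected_genes
  if (assumption == "RANDOM")
    return(withLocalSeed(seed, sample(genes, min(k, length(genes)))))
  scan <- if (assumption == "SHAPE") {
    cfg_train <- cfg; cfg_train$rng_seed <- as.integer(seed)
    calls <- classifyMatrix(train_se, cfg_train)
    prognosticScan(train_se, calls, cfg, assumption = "SHAPE")
  } else {
    prognosticScan(train_se, NULL, cfg, assumption = "SYMMETRIC")
  }
  testable <- scan[!is.na(scan$p), , drop = FALSE]
  if (nrow(testable) < k)
    warnf("only %d testable gene(s) for k = %d; using all", nrow(testable), k)
  testable$gene_id[order(testable$p)][seq_len(min(k, nrow(testable)))]
}

#' Train a random survival forest and score risk
#'
#' Grows an ensemble of survival trees, each on a bootstrap resample
#' with log-rank splitting and random feature subsetting (via
#' [ranger::ranger()], single-threaded for seed reproducibility). The
#' risk score is the ensemble mortality: the per-sample cumulative
#' hazard summed over the event-time grid -- higher means worse
#' predicted survival.
#'
#' @param train_expr Samples-by-genes numeric matrix (training).
#' @param train_surv Training survival data.frame.
#' @param test_expr Samples-by-genes matrix (same columns, test).
#' @param n_trees Number of trees (one bootstrap resample each).
#' @param seed Integer seed.
#' @return A list with numeric vectors `test_risk` and `train_risk`
#'   (named by sample).
#' @export
fitPredictSurvivalForest <- function(train_expr, train_surv, test_expr,
                                     n_trees = 1000L, seed = 1L) {
  if (ncol(train_expr) < 2) stopf("survival forest needs >= 2 features")
  if (nrow(train_expr) < 10) stopf("survival forest needs >= 10 training samples")
  if (sum(train_surv$event) < 2) stopf("survival forest needs >= 2 training events")
  df <- data.frame(time = train_surv$time_days, status = train_surv$event,
                   train_expr, check.names = FALSE)
  fit <- ranger::ranger(
    survival::Surv(time, status) ~ ., data = df,
    num.trees = n_trees, splitrule = "logrank",
    seed = as.integer(seed), num.threads = 1L,
    respect.unordered.factors = "order")
  mortality <- function(newx) {
    chf <- stats::predict(fit,
      data = as.data.frame(newx, check.names = FALSE),
      num.threads = 1L)$chf
    stats::setNames(rowSums(chf), rownames(newx))
  }
  list(test_risk = mortality(test_expr), train_risk = mortality(train_expr))
}

#' Misclassification rate of predicted survival status
#'
#' Patients are labelled by the training-set median observed time
#' `T_med`: observed status is poor if death occurred at or before
#' `T_med`, good if the patient survived beyond it (event or
#' censored); patients censored at or before `T_med` carry no label and
#' leave the denominator. The predicted status is poor when the risk
#' score exceeds the median training risk. The rate is the fraction of
#' labelled test patients whose prediction disagrees.
#'
#' @param test_risk Named risk scores for the test samples.
#' @param train_risk Risk scores of the training samples (threshold).
#' @param test_surv,train_surv Survival data.frames.
#' @return A list: `rate`, `n_evaluable`, `n_errors`.
#' @export
misclassificationRate <- function(test_risk, train_risk,
                                  test_surv, train_surv) {
  t_med <- stats::median(train_surv$time_days)
  idx <- match(names(test_risk), test_surv$sample_id)
  if (anyNA(idx)) stopf("risk scores contain unknown samples")
  time <- test_surv$time_days[idx]; event <- test_surv$event[idx]
  observed_poor <- event == 1 & time <= t_med
  evaluable <- observed_poor | time > t_med
  if (!any(evaluable))
    stopf("no evaluable test samples (all censored before the median)")
  predicted_poor <- test_risk > stats::median(train_risk)
  errors <- sum(predicted_poor[evaluable] != observed_poor[evaluable])
  list(rate = errors / sum(evaluable), n_evaluable = sum(evaluable),
       n_errors = errors)
}

#' Run the full shape-vs-symmetric-vs-random comparison
#'
#' For each repeat a seeded 2/3-1/3 sample partition is drawn; each
#' assumption selects genes on the training portion only, trains a
#' survival forest and is scored on the test portion. All three arms
#' share the partition within a repeat (paired design). Per-repeat
#' failures are flagged (`NA` rate), not fatal.
#'
#' @param se Aligned cohort with >= 60 samples.
#' @param cfg A [shapeConfig()] list (`n_repeats`, `n_trees`,
#'   `n_selected_genes`, `rng_seed`).
#' @return A data.frame with one row per repeat x assumption:
#'   `repeat_index`, `assumption`, `k`, `rate`, `n_evaluable`,
#'   `partition_hash`; the selected gene sets are in
#'   `attr(, "selected")`.
#' @export
runComparison <- function(se, cfg = shapeConfig()) {
  n <- ncol(se)
  if (n < 60) stopf("the comparison protocol needs >= 60 samples")
  surv_all <- survivalTable(se)
  rows <- list(); selected <- list()
  for (r in seq_len(cfg$n_repeats)) {
    rep_seed <- geneSeed(sprintf("repeat-%d", r), cfg$rng_seed)
    train_idx <- withLocalSeed(rep_seed, sort(sample(n, floor(2 * n / 3))))
    phash <- geneSeed(paste(train_idx, collapse = ","), 0L)
    train_se <- se[, train_idx]
    test_se <- se[, -train_idx]
    train_surv <- survivalTable(train_se)
    test_surv <- survivalTable(test_se)
    for (a in c("SHAPE", "SYMMETRIC", "RANDOM")) {
      res <- tryCatch({
        sel <- selectGenes(train_se, cfg, assumption = a,
                           seed = rep_seed + match(a, c("SHAPE", "SYMMETRIC",
                                                        "RANDOM")))
        tr_x <- t(SummarizedExperiment::assay(train_se, "expr")[sel, ,
                                                                drop = FALSE])
        te_x <- t(SummarizedExperiment::assay(test_se, "expr")[sel, ,
                                                               drop = FALSE])
        rf <- fitPredictSurvivalForest(tr_x, train_surv, te_x,
                                       n_trees = cfg$n_trees,
                                       seed = rep_seed)
        mc <- misclassificationRate(rf$test_risk, rf$train_risk,
                                    test_surv, train_surv)
        list(sel = sel, rate = mc$rate, n_eval = mc$n_evaluable)
      }, error = function(e) {
        warnf("repeat %d, %s arm failed: %s", r, a, conditionMessage(e))
        list(sel = character(), rate = NA_real_, n_eval = NA_integer_)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_index = r, assumption = a,
        k = length(res$sel), rate = res$rate,
        n_evaluable = res$n_eval, partition_hash = phash,
        stringsAsFactors = FALSE)
      selected[[sprintf("%d.%s", r, a)]] <- res$sel
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "selected") <- selected
  out
}

#' Summarize a comparison run
#'
#' Counts the repeats where the shape arm's misclassification rate is
#' at most the symmetric arm's (`wins`, ties counted inside and also
#' reported separately), runs a paired Wilcoxon signed-rank test on the
#' per-repeat rate pairs, and reports notched-boxplot summaries
#' (median, quartiles, median +/- 1.58*IQR/sqrt(n)) per assumption.
#'
#' @param results Data.frame from [runComparison()].
#' @return A list of class `"comparison_summary"`: `n_repeats`, `wins`,
#'   `ties`, `losses`, `wilcoxon_p`, `mean_rates`, `boxplot_stats`.
#' @export
summarizeComparison <- function(results) {
  wide <- split(results, results$assumption)
  if (!all(c("SHAPE", "SYMMETRIC") %in% names(wide)))
    stopf("results must contain SHAPE and SYMMETRIC arms")
  sh <- wide$SHAPE[order(wide$SHAPE$repeat_index), ]
  sy <- wide$SYMMETRIC[order(wide$SYMMETRIC$repeat_index), ]
  if (!identical(sh$repeat_index, sy$repeat_index))
    stopf("mismatched repeat indices between arms")
  ok <- !is.na(sh$rate) & !is.na(sy$rate)
  a <- sh$rate[ok]; b <- sy$rate[ok]
  wins <- sum(a <= b); ties <- sum(a == b)
  diffs <- a - b
  wilcoxon_p <- if (all(diffs == 0)) 1 else
    suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
  boxstats <- lapply(wide, function(df) {
    x <- df$rate[!is.na(df$rate)]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    c(median = q[2], q1 = q[1], q3 = q[3],
      notch_lo = q[2] - 1.58 * iqr / sqrt(length(x)),
      notch_hi = q[2] + 1.58 * iqr / sqrt(length(x)))
  })
  structure(list(
    n_repeats = sum(ok), wins = wins, ties = ties,
    losses = sum(a > b), wilcoxon_p = wilcoxon_p,
    mean_rates = vapply(wide, function(df) mean(df$rate, na.rm = TRUE), 0),
    boxplot_stats = boxstats
  ), class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf("Shape vs symmetric over %d repeat(s)\n", x$n_repeats))
  cat(sprintf("  shape <= symmetric: %d (%d tie(s), %d loss(es))\n",
              x$wins, x$ties, x$losses))
  cat(sprintf("  paired Wilcoxon p = %.4g\n", x$wilcoxon_p))
  for (nm in names(x$mean_rates))
    cat(sprintf("  mean rate %-10s %.4f\n", nm, x$mean_rates[[nm]]))
  invisible(x)
}
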