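test_that("random gene selection is seed-deterministic", {
  fx <- fixtureCohort()
  cfg <- shapeConfig(n_selected_genes = 2)
  s1 <- selectGenes(fx$se, cfg, "RANDOM", seed = 4)
  s2 <- selectGenes(fx$se, cfg, "RANDOM", seed = 4)
  expect_identical(s1, s2)
  expect_length(s1, 2L)
})

test_that("shape selection recovers planted prognostic genes the symmetric scan misses", {
  ## cohort whose only prognostic gene is bimodal: the mode split sees
  ## it, the two-tailed split dilutes it
  fx <- fixtureCohort(n = 150, seed = 123, hr = 5)
  cfg <- shapeConfig(n_bootstrap = 99, n_selected_genes = 1, rng_seed = 6)
  sel_shape <- suppressWarnings(selectGenes(fx$se, cfg, "SHAPE", seed = 6))
  expect_identical(sel_shape, "planted")
})

test_that("survival forest risk scores are deterministic and track planted risk", {
  withr::with_seed(19, {
    n <- 200
    g <- rbinom(n, 1, 0.5)
    X <- cbind(f1 = rnorm(n, 3 * g, 1), f2 = rnorm(n))
    rownames(X) <- sprintf("s%03d", 1:n)
    haz <- 0.01 * ifelse(g == 1, 5, 1)
    t_ev <- rexp(n, haz); t_c <- rexp(n, 0.004)
    surv <- data.frame(sample_id = rownames(X),
                       time_days = pmin(t_ev, t_c),
                       event = as.integer(t_ev <= t_c))
  })
  tr <- 1:130; te <- 131:200
  rf <- fitPredictSurvivalForest(X[tr, ], surv[tr, ], X[te, ],
                                 n_trees = 200, seed = 2)
  rf2 <- fitPredictSurvivalForest(X[tr, ], surv[tr, ], X[te, ],
                                  n_trees = 200, seed = 2)
  expect_identical(rf$test_risk, rf2$test_risk)
  ## higher risk score in the high-hazard group
  expect_gt(cor(rf$test_risk, g[te], method = "spearman"), 0.5)
  ## permuting test samples permutes scores identically
  perm <- rev(seq_along(te))
  rf3 <- fitPredictSurvivalForest(X[tr, ], surv[tr, ], X[te, ][perm, ],
                                  n_trees = 200, seed = 2)
  expect_identical(rf3$test_risk, rf$test_risk[perm])
  expect_error(
    fitPredictSurvivalForest(X[tr, ], transform(surv[tr, ], event = 0L),
                             X[te, ], 50, 1), "events")
})

test_that("misclassification scoring handles perfect, flipped, and empty cases", {
  train_surv <- data.frame(sample_id = sprintf("tr%d", 1:10),
                           time_days = c(1:5, 100:104), event = 1L)
  ## T_med = 52.5; test: 3 poor (event before), 3 good (beyond)
  test_surv <- data.frame(sample_id = sprintf("te%d", 1:6),
                          time_days = c(5, 10, 20, 100, 110, 120),
                          event = c(1L, 1L, 1L, 0L, 1L, 0L))
  train_risk <- stats::setNames(1:10, train_surv$sample_id)
  perfect <- stats::setNames(c(10, 9, 8, 1, 2, 3), test_surv$sample_id)
  mc <- misclassificationRate(perfect, train_risk, test_surv, train_surv)
  expect_equal(mc$rate, 0); expect_equal(mc$n_evaluable, 6L)
  flipped <- stats::setNames(c(1, 2, 3, 10, 9, 8), test_surv$sample_id)
  expect_equal(
    misclassificationRate(flipped, train_risk, test_surv, train_surv)$rate, 1)
  ## censored before the median leaves the denominator
  test_cens <- transform(test_surv, event = 0L)
  test_cens$time_days <- c(5, 10, 20, 30, 40, 50)
  expect_error(
    misclassificationRate(perfect, train_risk, test_cens, train_surv),
    "evaluable")
})

test_that("the comparison protocol pairs arms within repeats and summarizes wins", {
  fx <- fixtureCohort(n = 90, seed = 31, hr = 5)
  cfg <- shapeConfig(n_bootstrap = 99, n_trees = 50, n_repeats = 3,
                     n_selected_genes = 2, rng_seed = 8)
  res <- suppressWarnings(runComparison(fx$se, cfg))
  expect_equal(nrow(res), 9L)    # 3 assumptions x 3 repeats
  expect_true(all(res$rate >= 0 & res$rate <= 1, na.rm = TRUE))
  ## identical partitions across arms within a repeat
  for (r in 1:3)
    expect_equal(length(unique(res$partition_hash[res$repeat_index == r])), 1L)
  ## full determinism under the same config
  res2 <- suppressWarnings(runComparison(fx$se, cfg))
  expect_equal(res, res2, ignore_attr = TRUE)

  sm <- summarizeComparison(res)
  expect_equal(sm$wins + sm$losses, sm$n_repeats)
  expect_lte(sm$ties, sm$wins)
})

test_that("summary statistics behave on constructed rate vectors", {
  mk <- function(shape, sym) {
    n <- length(shape)
    rbind(data.frame(repeat_index = 1:n, assumption = "SHAPE", k = 10,
                     rate = shape, n_evaluable = 30, partition_hash = 1:n),
          data.frame(repeat_index = 1:n, assumption = "SYMMETRIC", k = 10,
                     rate = sym, n_evaluable = 30, partition_hash = 1:n))
  }
  ## identical vectors: all wins are ties, Wilcoxon p = 1
  same <- mk(rep(0.3, 8), rep(0.3, 8))
  sm <- summarizeComparison(same)
  expect_equal(sm$wins, 8L); expect_equal(sm$ties, 8L)
  expect_equal(sm$wilcoxon_p, 1)

  ## uniform shift: shape better in all 20 repeats, p < 0.01
  withr::with_seed(3, r <- runif(20, 0.3, 0.5))
  shift <- mk(r - 0.1, r)
  sm2 <- summarizeComparison(shift)
  expect_equal(sm2$wins, 20L)
  expect_lt(sm2$wilcoxon_p, 0.01)

  ## swapping the arms maps wins -> n - wins + ties
  swapped <- mk(r, r - 0.1)
  sm3 <- summarizeComparison(swapped)
  expect_equal(sm3$wins, 20L - sm2$wins + sm2$ties)

  ## notched-boxplot summary: median +/- 1.58 IQR / sqrt(n)
  q <- quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(unname(sm2$boxplot_stats$SYMMETRIC["median"]), q[2])
  expect_equal(unname(sm2$boxplot_stats$SYMMETRIC["notch_hi"]),
               q[2] + 1.58 * (q[3] - q[1]) / sqrt(20))
})
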