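test_that("shape-aware splits obey the family rules and size invariants", {
  x <- stats::setNames(seq_len(100) + 0.5, sprintf("p%03d", 1:100))
  ## symmetric: both tails, |G1| = 2 * floor(0.1 * n)
  sp <- splitPatients(x, "NORMAL", tail_fraction = 0.10)
  expect_identical(sp$rule, "TWO_TAIL")
  expect_equal(sum(sp$group == "G1"), 20L)
  expect_true(all(names(which(sp$group == "G1")) %in%
                  names(x)[c(1:10, 91:100)]))

  ## right-skewed: upper tail only, |G1| = floor(0.1 * n)
  g <- stats::setNames(sort(rgamma(100, 2, 1)), names(x))
  spg <- splitPatients(g, "GAMMA")
  expect_identical(spg$rule, "ONE_TAIL_UPPER")
  expect_equal(sum(spg$group == "G1"), 10L)
  expect_true(all(g[spg$group == "G1"] > max(g[spg$group == "G2"])))

  ## left-skewed data uses the lower tail
  spl <- splitPatients(stats::setNames(-g, names(x)), "LOGNORMAL")
  expect_identical(spl$rule, "ONE_TAIL_LOWER")

  ## bimodal: groups recover the generating components beyond the midpoint
  withr::with_seed(13, {
    comp <- rbinom(100, 1, 0.5)
    xb <- stats::setNames(rnorm(100, 10 * comp, 1), names(x))
  })
  spb <- splitPatients(xb, "BIMODAL")
  expect_identical(spb$rule, "MODE")
  clear <- abs(xb - 5) > 0    # all samples; modes at 0 and 10 are far apart
  expect_equal(unname(spb$group[clear] == "G1"), comp[clear] == 1)

  expect_error(splitPatients(x, "UNKNOWN"), "UNKNOWN")
  expect_error(splitPatients(x[1:10], "NORMAL"), "n >= 20")
})

test_that("log-rank test matches the brute-force hypergeometric oracle", {
  ## toy fixture: all events, fully separated groups
  surv <- data.frame(sample_id = sprintf("s%d", 1:6),
                     time_days = c(1, 2, 3, 4, 5, 6),
                     event = rep(1L, 6))
  sp <- makeSplit(surv$sample_id, g1 = sprintf("s%d", 1:3))
  lr <- logrankTest(sp, surv)
  or <- logrankOracle(surv$time_days, surv$event,
                      ifelse(surv$sample_id %in% sprintf("s%d", 1:3), 1, 2))
  expect_equal(lr$statistic, or$statistic, tolerance = 1e-10)
  expect_equal(lr$p, or$p, tolerance = 1e-10)

  ## exhaustive small fixtures: every event/censor pattern at n = 6,
  ## alternating group labels, ties included
  time <- c(2, 2, 4, 5, 7, 9)
  grp <- c(1, 2, 1, 2, 1, 2)
  surv6 <- data.frame(sample_id = sprintf("t%d", 1:6), time_days = time,
                      event = 0L)
  sp6 <- makeSplit(surv6$sample_id, g1 = sprintf("t%d", c(1, 3, 5)))
  for (pattern in 1:63) {
    ev <- as.integer(intToBits(pattern)[1:6])
    if (sum(ev[grp == 1]) == 0 || sum(ev[grp == 2]) == 0) next
    surv6$event <- ev
    lr <- logrankTest(sp6, surv6)
    or <- logrankOracle(time, ev, grp)
    expect_equal(lr$statistic, or$statistic, tolerance = 1e-10)
    expect_equal(lr$p, or$p, tolerance = 1e-10)
  }

  ## identical survival in both groups -> statistic ~ 0; time-scale invariance
  survd <- data.frame(sample_id = sprintf("u%d", 1:8),
                      time_days = rep(c(1, 2, 3, 4), 2), event = rep(1L, 8))
  spd <- makeSplit(survd$sample_id, g1 = sprintf("u%d", 1:4))
  lrd <- logrankTest(spd, survd)
  expect_equal(lrd$statistic, 0, tolerance = 1e-12)
  expect_equal(lrd$p, 1, tolerance = 1e-10)
  survd2 <- survd; survd2$time_days <- survd$time_days * 2
  expect_equal(logrankTest(spd, survd2)$statistic, lrd$statistic)

  surv_none <- transform(survd, event = 0L)
  expect_error(logrankTest(spd, surv_none), "no events")
})

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  surv <- data.frame(sample_id = c("a", "b", "c"),
                     time_days = c(1, 2, 3), event = c(1L, 1L, 1L))
  km <- kmEstimate(surv)
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  all_cens <- transform(surv, event = 0L)
  expect_true(all(kmEstimate(all_cens)$surv == 1))

  ## censoring shrinks the risk set without a step
  s2 <- data.frame(sample_id = c("a", "b"), time_days = c(1, 2),
                   event = c(0L, 1L))
  km2 <- kmEstimate(s2)
  expect_equal(km2$surv[km2$time == 2], 0)  # risk set of 1 at t = 2

  ## at the largest event time with no censoring: empirical fraction
  withr::with_seed(17, {
    s3 <- data.frame(sample_id = sprintf("x%d", 1:40),
                     time_days = sample(1:100, 40), event = 1L)
  })
  km3 <- kmEstimate(s3)
  expect_equal(km3$surv[which.max(km3$time)], 0)
  tmid <- sort(s3$time_days)[20]
  expect_equal(km3$surv[km3$time == tmid], mean(s3$time_days > tmid))
})

test_that("the prognostic scan flags a planted gene and skips UNKNOWN", {
  fx <- fixtureCohort()
  cfg <- shapeConfig(n_bootstrap = 99, rng_seed = 5)
  calls <- classifyMatrix(fx$se, cfg)
  scan <- prognosticScan(fx$se, calls, cfg, assumption = "SHAPE")
  expect_equal(nrow(scan), 3L)
  planted <- scan[scan$gene_id == "planted", ]
  expect_identical(planted$family, "BIMODAL")
  expect_identical(planted$rule, "MODE")
  expect_true(planted$significant)
  expect_true(all(scan$significant == (scan$p < 0.05), na.rm = TRUE))

  ## symmetric assumption forces TWO_TAIL everywhere
  scan_sym <- prognosticScan(fx$se, NULL, cfg, assumption = "SYMMETRIC")
  expect_true(all(scan_sym$rule == "TWO_TAIL", na.rm = TRUE))
  ## for NORMAL genes the two assumptions coincide
  nid <- scan$gene_id[scan$family == "NORMAL"]
  expect_equal(scan$p[scan$gene_id %in% nid],
               scan_sym$p[scan_sym$gene_id %in% nid])
})

test_that("random label assignment is calibrated at the nominal level", {
  fx <- fixtureCohort(n = 100, seed = 77)
  surv <- survivalTable(fx$se)
  x <- SummarizedExperiment::assay(fx$se)["noise1", ]
  splits <- list(noise1 = splitPatients(x, "NORMAL"))
  null <- randomSplitNull(surv, splits, n_perm = 400, seed = 9)
  ## 99% binomial band around 0.05 with 400 draws
  band <- qbinom(c(0.005, 0.995), 400, 0.05) / 400
  expect_gte(null$rate, band[1]); expect_lte(null$rate, band[2])
  ## determinism
  null2 <- randomSplitNull(surv, splits, n_perm = 400, seed = 9)
  expect_identical(null$counts, null2$counts)
})
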