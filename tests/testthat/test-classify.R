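test_that("the mixture fit recovers well-separated components and the BI formula", {
  ## symmetric construction: two tight half-samples at 0 and 10
  x <- c(rnorm(100, 0, 0.5), rnorm(100, 10, 0.5))
  fit <- fitBimodalMixture(x)
  expect_lt(abs(fit$mu1 - 0), 0.2)
  expect_lt(abs(fit$mu2 - 10), 0.2)
  expect_lt(abs(fit$pi - 0.5), 0.05)
  expect_lte(fit$mu1, fit$mu2)
  ## BI invariant holds exactly
  expect_equal(fit$bi,
               sqrt(fit$pi * (1 - fit$pi)) * (fit$mu2 - fit$mu1) / fit$sigma)
  expect_true(all(fit$responsibilities >= 0 & fit$responsibilities <= 1))
  ## responsibilities separate the modes at the midpoint
  expect_true(all(fit$responsibilities[x > 5] > 0.5))
  expect_true(all(fit$responsibilities[x < 5] < 0.5))
  expect_error(fitBimodalMixture(rep(1, 50)), "variance")
})

test_that("BI is near truth for a 4-sigma mixture at large n", {
  x <- withr::with_seed(11, rnorm(10000, 4 * rbinom(10000, 1, 0.5), 1))
  bi <- fitBimodalMixture(x)$bi
  expect_gt(bi, 1.9); expect_lt(bi, 2.1)   # truth 0.5 * 4 = 2
})

test_that("the row-vectorized EM agrees with the single-gene mixture fit", {
  withr::with_seed(91, {
    X <- rbind(
      bim = rnorm(150, 5 * rbinom(150, 1, 0.4), 1),
      norm = rnorm(150, 3, 2),
      skew = rgamma(150, 1.5, 1),
      tight = c(rnorm(75, 0, 0.3), rnorm(75, 8, 0.3)))
  })
  em <- GeneShapes:::emFitMatrix(X)
  for (i in seq_len(nrow(X))) {
    single <- fitBimodalMixture(X[i, ])
    expect_equal(em$bi[[i]], single$bi, tolerance = 1e-6)
    expect_equal(em$pi[[i]], single$pi, tolerance = 1e-6)
    expect_equal(unname(em$responsibilities[i, ]),
                 unname(single$responsibilities), tolerance = 1e-6)
  }
})

test_that("Shapiro screening gates the log test on positivity", {
  withr::with_seed(21, {
    x <- exp(rnorm(500))
    p <- testNormalLognormal(x)
    expect_gt(p[["p_lognormal"]], 0.01)
    expect_lt(p[["p_normal"]], 0.01)
    xneg <- c(x[1:99], -1)
    expect_true(is.na(testNormalLognormal(xneg)[["p_lognormal"]]))
  })
  expect_error(testNormalLognormal(rnorm(2)), "n")
  expect_error(testNormalLognormal(rnorm(5001)), "subsample")
})

test_that("bootstrap KS p-values are bounded, deterministic, and powerful", {
  withr::with_seed(31, {
    x <- rgamma(150, 2, 1)
    p1 <- ksBootstrapP(x, "GAMMA", B = 99, seed = 7)
    p2 <- ksBootstrapP(x, "GAMMA", B = 99, seed = 7)
    expect_identical(p1, p2)
    expect_gte(p1, 1 / 100); expect_lte(p1, 1)
    ## Normal(5,1) data is overwhelmingly rejected as Pareto
    rej <- vapply(1:40, function(i)
      ksBootstrapP(rnorm(150, 5, 1), "PARETO", B = 99, seed = i), 0)
    expect_gte(mean(rej <= 0.05), 0.95)
  })
  expect_error(ksBootstrapP(c(-1, 1, 2), "GAMMA"), "positive")
  expect_error(ksBootstrapP(rnorm(30), "CAUCHY", B = 5), "19")
  ## estimator failure -> NA (constant data has zero IQR)
  expect_true(is.na(ksBootstrapP(rep(2, 30), "CAUCHY", B = 19, seed = 1)))
})

test_that("classifyGene follows the bimodality-first decision pipeline", {
  cfg <- shapeConfig(n_bootstrap = 99)
  ## clearly bimodal: BI = 0.5 * 10 = 5 >> 1.1, unimodal stage skipped
  x <- c(rnorm(150, 0, 0.5), rnorm(150, 5, 0.5))
  cl <- classifyGene(x, cfg, seed = 1)
  expect_identical(cl$family, "BIMODAL")
  expect_gt(cl$bi, 1.1)
  expect_true(all(is.na(cl$pvals)))
  expect_s3_class(cl$bimodal_fit, "bimodal_fit")

  ## Normal data with negative values can never be called
  ## Lognormal/Gamma/Pareto (positivity gate)
  withr::with_seed(41, {
    for (i in 1:10) {
      cl <- classifyGene(rnorm(100), cfg, seed = i)
      expect_false(cl$family %in% c("LOGNORMAL", "GAMMA", "PARETO"))
      expect_true(is.na(cl$pvals[["p_lognormal"]]))
      expect_true(is.na(cl$pvals[["p_gamma"]]))
    }
  })
  ## zero variance -> UNKNOWN with a warning
  expect_warning(cl0 <- classifyGene(rep(3, 50), cfg), "zero-variance")
  expect_identical(cl0$family, "UNKNOWN")
})

test_that("classifyMatrix partitions genes and is order-invariant", {
  withr::with_seed(51, {
    m <- rbind(
      gBim = c(rnorm(100, 0, 0.5), rnorm(100, 6, 0.5)),
      gNorm = rnorm(200, 10, 1),
      gGam = rgamma(200, 3, 1),
      gFlat = rep(1, 200))
    colnames(m) <- sprintf("s%03d", 1:200)
  })
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(expr = m))
  cfg <- shapeConfig(n_bootstrap = 99, rng_seed = 3)
  calls <- classifyMatrix(se, cfg)
  expect_s4_class(calls, "ShapeCalls")
  expect_equal(length(calls), 4L)
  fc <- familyCounts(calls)
  expect_equal(sum(fc$count), 4L)           # partition: one family per gene
  expect_equal(sum(fc$fraction), 1)
  expect_identical(unname(geneFamilies(calls)["gBim"]), "BIMODAL")
  expect_identical(unname(geneFamilies(calls)["gFlat"]), "UNKNOWN")

  ## permuting gene order permutes the calls identically (id-keyed seeds)
  perm <- c(3, 1, 4, 2)
  calls_p <- classifyMatrix(se[perm, ], cfg)
  t1 <- as.data.frame(calls); t2 <- as.data.frame(calls_p)
  expect_equal(t2[order(t2$gene_id), ], t1[order(t1$gene_id), ],
               ignore_attr = TRUE)

  ## TSV writer emits NA for untestable p-values
  f <- tempfile(fileext = ".tsv")
  writeCalls(calls, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 4L)
  expect_true(is.na(tab$p_normal[tab$gene_id == "gBim"]))
})
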