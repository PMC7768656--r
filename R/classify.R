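## Bimodality-first decision pipeline assigning each gene one of
## NORMAL, LOGNORMAL, CAUCHY, GAMMA, PARETO, BIMODAL, UNKNOWN.
## A gene is bimodal whenever its Bimodality Index exceeds the
## threshold; otherwise the five unimodal candidates are tested
## (Shapiro-Wilk for Normal/Lognormal, parametric-bootstrap KS for
## Cauchy/Gamma/Pareto) and the largest passing p-value wins.

#' Equal-variance two-component Gaussian mixture fit
#'
#' EM fit of `pi*N(mu2, sigma) + (1-pi)*N(mu1, sigma)` with a common
#' standard deviation, matching the mixture underlying the Bimodality
#' Index `BI = sqrt(pi*(1-pi)) * |mu2 - mu1| / sigma`. Initialization
#' splits the sample at the median (component means = half-sample
#' means); iteration stops when the log-likelihood improves by less
#' than 1e-8 or after 500 iterations. Components are ordered
#' `mu1 <= mu2`.
#'
#' @param x Numeric vector, n >= 10, non-constant.
#' @return A list of class `"bimodal_fit"` with elements `pi`, `mu1`,
#'   `mu2`, `sigma`, `bi`, `responsibilities` (posterior probability of
#'   the upper component, per sample) and `loglik`.
#' @examples
#' x <- c(rnorm(100), rnorm(100, 4))
#' fitBimodalMixture(x)$bi   # close to 2
#' @export
fitBimodalMixture <- function(x) {
  n <- length(x)
  if (n < 10) stopf("mixture fit needs n >= 10")
  if (stats::sd(x) == 0) stopf("zero-variance input")
  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (length(hi) == 0) { lo <- x[x < med]; hi <- x[x >= med] }
  mu1 <- mean(lo); mu2 <- mean(hi)
  sg <- stats::sd(x); pi2 <- length(hi) / n
  ll_old <- -Inf; ll <- ll_old
  for (it in seq_len(500L)) {
    d1 <- stats::dnorm(x, mu1, sg); d2 <- stats::dnorm(x, mu2, sg)
    num <- pi2 * d2
    den <- (1 - pi2) * d1 + num
    den[den <= 0] <- .Machine$double.xmin
    r <- num / den
    ll <- sum(log(den))
    if (it > 1 && ll - ll_old < 1e-8) break
    ll_old <- ll
    pi2 <- mean(r)
    s1 <- sum(1 - r); s2 <- sum(r)
    if (s1 > 0) mu1 <- sum((1 - r) * x) / s1
    if (s2 > 0) mu2 <- sum(r * x) / s2
    sg <- sqrt(sum((1 - r) * (x - mu1)^2 + r * (x - mu2)^2) / n)
    if (sg <= 0) sg <- .Machine$double.eps
  }
  if (mu1 > mu2) {
    tmp <- mu1; mu1 <- mu2; mu2 <- tmp
    pi2 <- 1 - pi2; r <- 1 - r
  }
  structure(list(
    pi = pi2, mu1 = mu1, mu2 = mu2, sigma = sg,
    bi = sqrt(pi2 * (1 - pi2)) * abs(mu2 - mu1) / sg,
    responsibilities = r, loglik = ll
  ), class = "bimodal_fit")
}

## Row-vectorized EM for the equal-variance two-component mixture: the
## same update rule, initialization and stopping rule as
## fitBimodalMixture(), run on every row of X at once with per-row
## convergence freezing. Returns per-row parameter vectors plus the
## responsibility matrix.
emFitMatrix <- function(X, tol = 1e-8, maxit = 500L) {
  G <- nrow(X); n <- ncol(X)
  med <- apply(X, 1, stats::median)
  L <- X <= med                      # lower half-sample membership
  allLow <- rowSums(!L) == 0
  if (any(allLow)) L[allLow, ] <- X[allLow, , drop = FALSE] < med[allLow]
  nlo <- rowSums(L); nhi <- n - nlo
  mu1 <- rowSums(X * L) / nlo
  mu2 <- rowSums(X * !L) / pmax(nhi, 1)
  rmean <- rowMeans(X)
  sg <- sqrt(rowSums((X - rmean)^2) / (n - 1))
  pi2 <- nhi / n
  resp <- matrix(NA_real_, G, n, dimnames = dimnames(X))
  ll_final <- rep(NA_real_, G)
  active <- sg > 0
  ll_old <- rep(-Inf, G)
  for (it in seq_len(maxit)) {
    if (!any(active)) break
    idx <- which(active)
    Xa <- X[idx, , drop = FALSE]
    d1 <- stats::dnorm(Xa, mu1[idx], sg[idx])
    d2 <- stats::dnorm(Xa, mu2[idx], sg[idx])
    num <- pi2[idx] * d2
    den <- (1 - pi2[idx]) * d1 + num
    den[den <= 0] <- .Machine$double.xmin
    r <- num / den
    ll <- rowSums(log(den))
    resp[idx, ] <- r
    ll_final[idx] <- ll
    done <- it > 1 & (ll - ll_old[idx] < tol)
    ll_old[idx] <- ll
    if (any(done)) active[idx[done]] <- FALSE
    upd <- idx[!done]
    if (length(upd) > 0) {
      ru <- r[!done, , drop = FALSE]
      Xu <- Xa[!done, , drop = FALSE]
      s2 <- rowSums(ru); s1 <- n - s2
      pi2[upd] <- s2 / n
      m1 <- ifelse(s1 > 0, rowSums((1 - ru) * Xu) / s1, mu1[upd])
      m2 <- ifelse(s2 > 0, rowSums(ru * Xu) / s2, mu2[upd])
      mu1[upd] <- m1; mu2[upd] <- m2
      sgu <- sqrt(rowSums((1 - ru) * (Xu - m1)^2 + ru * (Xu - m2)^2) / n)
      sg[upd] <- pmax(sgu, .Machine$double.eps)
    }
  }
  flip <- !is.na(mu1) & !is.na(mu2) & mu1 > mu2
  if (any(flip)) {
    tmp <- mu1[flip]; mu1[flip] <- mu2[flip]; mu2[flip] <- tmp
    pi2[flip] <- 1 - pi2[flip]
    resp[flip, ] <- 1 - resp[flip, , drop = FALSE]
  }
  list(pi = pi2, mu1 = mu1, mu2 = mu2, sigma = sg,
       bi = sqrt(pi2 * (1 - pi2)) * abs(mu2 - mu1) / sg,
       responsibilities = resp, loglik = ll_final)
}

#' Shapiro-Wilk screening for Normal and Lognormal shape
#'
#' `p_normal` is the Shapiro-Wilk p-value on the data; `p_lognormal`
#' the Shapiro-Wilk p-value on `log(x)`, reported only when every value
#' is strictly positive (`NA` otherwise, since the Lognormal is defined
#' on positive values).
#'
#' @param x Numeric vector with `3 <= length(x) <= 5000` (the validity
#'   range of the Shapiro-Wilk test; subsample larger cohorts first).
#' @return Named numeric vector `c(p_normal, p_lognormal)`.
#' @export
testNormalLognormal <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000)
    stopf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d); subsample larger cohorts with a seeded RNG", n)
  p_normal <- stats::shapiro.test(x)$p.value
  p_lognormal <- if (all(x > 0)) stats::shapiro.test(log(x))$p.value
                 else NA_real_
  c(p_normal = p_normal, p_lognormal = p_lognormal)
}

#' Lilliefors-style parametric-bootstrap KS p-value
#'
#' Estimates the family's parameters on `x`, computes the observed KS
#' statistic, then repeatedly draws samples of the same size from the
#' fitted law, re-estimates the parameters on each draw and recomputes
#' the statistic. The p-value uses the add-one estimator
#' `(1 + #\{D_b >= D_obs\}) / (B + 1)`, so it is never zero.
#'
#' @param x Numeric vector (strictly positive for Gamma/Pareto).
#' @param family `"CAUCHY"`, `"GAMMA"` or `"PARETO"`.
#' @param B Number of bootstrap replicates (>= 19).
#' @param seed Integer seed for the bootstrap draws.
#' @param cauchy_scale Cauchy scale convention, see [fitCauchyQuantile()].
#' @return The bootstrap p-value, or `NA` when the estimator fails on
#'   `x` (family not testable for this gene).
#' @export
ksBootstrapP <- function(x, family, B = 200L, seed = 1L,
                         cauchy_scale = "half-iqr") {
  family <- match.arg(family, c("CAUCHY", "GAMMA", "PARETO"))
  if (B < 19) stopf("B must be >= 19")
  if (family %in% c("GAMMA", "PARETO") && any(x <= 0))
    stopf("%s requires strictly positive values", family)
  fit <- tryCatch(switch(family,
      CAUCHY = fitCauchyQuantile(x, scale_mode = cauchy_scale),
      GAMMA  = fitGammaMLE(x),
      PARETO = fitParetoMLE(x)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  d_obs <- ksStatistic(x, fit)
  n <- length(x)
  d_boot <- withLocalSeed(seed, {
    X <- familyDrawMatrix(fit, n, B)
    par <- familyRefitColumns(X, family, scale_mode = cauchy_scale)
    ok <- is.finite(par[1, ]) & is.finite(par[2, ]) & par[2, ] > 0
    d <- rep(NA_real_, B)
    if (any(ok))
      d[ok] <- ksStatisticColumns(X[, ok, drop = FALSE], family,
                                  par[, ok, drop = FALSE])
    d
  })
  d_boot <- d_boot[is.finite(d_boot)]
  (1 + sum(d_boot >= d_obs)) / (length(d_boot) + 1)
}

#' Classify one gene's expression distribution
#'
#' The decision pipeline: (1) fit the two-component mixture; if the
#' Bimodality Index exceeds `cfg$bi_threshold` the gene is `BIMODAL`
#' and no further testing occurs. (2) Otherwise compute the candidate
#' p-values -- Shapiro-Wilk for Normal and (positivity permitting)
#' Lognormal, bootstrap KS for Cauchy and (positivity permitting)
#' Gamma and Pareto. Candidates with `p > cfg$alpha_fit` compete and
#' the largest p-value wins; exact ties break in the order Normal,
#' Lognormal, Cauchy, Gamma, Pareto. (3) If no candidate passes the
#' gene is `UNKNOWN`.
#'
#' @param x Numeric vector of one gene's expression (n >= 10).
#' @param cfg A [shapeConfig()] list.
#' @param seed Integer seed for the bootstrap and any subsampling.
#' @return A list of class `"distribution_call"`: `family`, `bi`,
#'   the five p-values, `winning_fit` (a `fit_params` or `NULL`) and
#'   `bimodal_fit` (for bimodal genes).
#' @export
classifyGene <- function(x, cfg = shapeConfig(), seed = cfg$rng_seed) {
  if (length(x) < 10) stopf("classification needs n >= 10")
  pvals <- c(p_normal = NA_real_, p_lognormal = NA_real_,
             p_cauchy = NA_real_, p_gamma = NA_real_, p_pareto = NA_real_)
  call0 <- function(family, bi, winning_fit = NULL, bimodal_fit = NULL)
    structure(list(family = family, bi = bi, pvals = pvals,
                   winning_fit = winning_fit, bimodal_fit = bimodal_fit),
              class = "distribution_call")
  if (stats::sd(x) == 0) {
    warnf("zero-variance gene classified as UNKNOWN")
    return(call0("UNKNOWN", NA_real_))
  }
  bfit <- fitBimodalMixture(x)
  if (bfit$bi > cfg$bi_threshold)
    return(call0("BIMODAL", bfit$bi, bimodal_fit = bfit))
  gof <- gofStage(x, cfg, seed)
  pvals <- gof$pvals
  call0(gof$family, bfit$bi, winning_fit = gof$winning_fit)
}

## Unimodal goodness-of-fit stage shared by classifyGene() and
## classifyMatrix(): candidate p-values, winner selection, winning fit.
gofStage <- function(x, cfg, seed) {
  pvals <- c(p_normal = NA_real_, p_lognormal = NA_real_,
             p_cauchy = NA_real_, p_gamma = NA_real_, p_pareto = NA_real_)
  xs <- if (length(x) > 5000)
    withLocalSeed(seed, sample(x, 5000L)) else x
  sw <- testNormalLognormal(xs)
  pvals["p_normal"] <- sw[["p_normal"]]
  pvals["p_lognormal"] <- sw[["p_lognormal"]]
  pvals["p_cauchy"] <- ksBootstrapP(x, "CAUCHY", B = cfg$n_bootstrap,
                                    seed = seed + 1L,
                                    cauchy_scale = cfg$cauchy_scale)
  if (all(x > 0)) {
    pvals["p_gamma"] <- ksBootstrapP(x, "GAMMA", B = cfg$n_bootstrap,
                                     seed = seed + 2L)
    pvals["p_pareto"] <- ksBootstrapP(x, "PARETO", B = cfg$n_bootstrap,
                                      seed = seed + 3L)
  }
  passing <- which(!is.na(pvals) & pvals > cfg$alpha_fit)
  if (length(passing) == 0)
    return(list(family = "UNKNOWN", pvals = pvals, winning_fit = NULL))
  ## which.max on the candidate order breaks exact ties as
  ## Normal > Lognormal > Cauchy > Gamma > Pareto
  win_idx <- passing[which.max(pvals[passing])]
  family <- c("NORMAL", "LOGNORMAL", "CAUCHY", "GAMMA", "PARETO")[win_idx]
  wfit <- tryCatch(switch(family,
      NORMAL    = newFitParams("NORMAL", c(mean(x), stats::sd(x))),
      LOGNORMAL = newFitParams("LOGNORMAL", c(mean(log(x)), stats::sd(log(x)))),
      CAUCHY    = fitCauchyQuantile(x, scale_mode = cfg$cauchy_scale),
      GAMMA     = fitGammaMLE(x),
      PARETO    = fitParetoMLE(x)),
    error = function(e) NULL)
  list(family = family, pvals = pvals, winning_fit = wfit)
}

#' Classify every gene of a cohort
#'
#' Runs [classifyGene()] on each row. Per-gene seeds are derived by
#' hashing the gene identifier together with `cfg$rng_seed`, so results
#' are reproducible and independent of gene order.
#'
#' @param se SummarizedExperiment with an `"expr"` assay.
#' @param cfg A [shapeConfig()] list.
#' @return A [ShapeCalls-class] object.
#' @export
classifyMatrix <- function(se, cfg = shapeConfig()) {
  m <- SummarizedExperiment::assay(se, "expr")
  if (nrow(m) == 0) stopf("empty expression matrix")
  if (ncol(m) < 10) stopf("classification needs n >= 10")
  ids <- rownames(m)
  ## bimodality stage for all genes at once (same EM as classifyGene)
  em <- emFitMatrix(m)
  rows <- vector("list", nrow(m))
  bimodal_fits <- list()
  for (i in seq_len(nrow(m))) {
    gid <- ids[i]
    bi <- em$bi[i]
    pvals <- c(p_normal = NA_real_, p_lognormal = NA_real_,
               p_cauchy = NA_real_, p_gamma = NA_real_, p_pareto = NA_real_)
    if (is.na(bi)) {                       # zero-variance gene
      family <- "UNKNOWN"
    } else if (bi > cfg$bi_threshold) {
      family <- "BIMODAL"
      bimodal_fits[[gid]] <- structure(list(
        pi = em$pi[i], mu1 = em$mu1[i], mu2 = em$mu2[i],
        sigma = em$sigma[i], bi = bi,
        responsibilities = em$responsibilities[i, ],
        loglik = em$loglik[i]), class = "bimodal_fit")
    } else {
      gof <- gofStage(m[i, ], cfg, seed = geneSeed(gid, cfg$rng_seed))
      family <- gof$family
      pvals <- gof$pvals
    }
    rows[[i]] <- data.frame(
      gene_id = gid, family = family, bi = bi,
      p_normal = pvals[["p_normal"]], p_lognormal = pvals[["p_lognormal"]],
      p_cauchy = pvals[["p_cauchy"]], p_gamma = pvals[["p_gamma"]],
      p_pareto = pvals[["p_pareto"]], stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- calls$gene_id
  ShapeCalls(calls = S4Vectors::DataFrame(calls),
             bimodalFits = bimodal_fits, config = cfg)
}

#' Write per-gene calls as TSV
#'
#' Columns `gene_id family bi p_normal p_lognormal p_cauchy p_gamma
#' p_pareto`; untestable p-values are written as `NA`.
#'
#' @param calls A [ShapeCalls-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCalls <- function(calls, path) {
  df <- as.data.frame(callTable(calls))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
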