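## Parametric machinery for the five unimodal candidate families:
## densities/CDFs, seeded samplers, estimators, and the exact
## Kolmogorov-Smirnov statistic. Parameterizations: Normal (mean, sd),
## Lognormal (log-mean, log-sd), Cauchy (location, scale), Gamma
## (shape, rate), Pareto (minimum x_m, tail index alpha).

FAMILIES <- c("NORMAL", "LOGNORMAL", "CAUCHY", "GAMMA", "PARETO",
              "BIMODAL", "UNKNOWN")

newFitParams <- function(family, params) {
  family <- match.arg(family, FAMILIES)
  if (family %in% c("BIMODAL", "UNKNOWN"))
    stopf("%s carries no distribution-fit parameters", family)
  params <- as.numeric(params)
  if (length(params) != 2) stopf("%s expects 2 parameters", family)
  ok <- switch(family,
    NORMAL = , LOGNORMAL = , CAUCHY = params[2] > 0,
    GAMMA = , PARETO = all(params > 0))
  if (!isTRUE(ok) || any(!is.finite(params)))
    stopf("invalid %s parameters (%s)", family,
          paste(signif(params, 6), collapse = ", "))
  structure(list(family = family, params = params), class = "fit_params")
}

#' @export
print.fit_params <- function(x, ...) {
  lab <- switch(x$family,
    NORMAL = c("mean", "sd"), LOGNORMAL = c("meanlog", "sdlog"),
    CAUCHY = c("location", "scale"), GAMMA = c("shape", "rate"),
    PARETO = c("minimum", "index"))
  cat(sprintf("%s(%s = %.6g, %s = %.6g)\n", x$family,
              lab[1], x$params[1], lab[2], x$params[2]))
  invisible(x)
}

## CDF of a fitted family, vectorized over q
familyCDF <- function(q, fit) {
  p <- fit$params
  switch(fit$family,
    NORMAL    = stats::pnorm(q, p[1], p[2]),
    LOGNORMAL = stats::plnorm(q, p[1], p[2]),
    CAUCHY    = stats::pcauchy(q, p[1], p[2]),
    GAMMA     = stats::pgamma(q, shape = p[1], rate = p[2]),
    PARETO    = ifelse(q < p[1], 0, 1 - (p[1] / q)^p[2]),
    stopf("no CDF for family %s", fit$family))
}

#' Maximum-likelihood Gamma fit
#'
#' Estimates (shape k, rate beta) by Newton iteration on the profile
#' score `log(k) - digamma(k) = log(mean x) - mean(log x)`, initialized
#' at the method-of-moments estimate, to relative tolerance 1e-10
#' (at most 100 iterations); the rate follows as `k / mean(x)`.
#'
#' @param x Positive numeric vector, `length(x) >= 3`, not all equal.
#' @return A `fit_params` object with family `"GAMMA"`.
#' @examples
#' fitGammaMLE(rgamma(500, shape = 2, rate = 1/3))
#' @export
fitGammaMLE <- function(x) {
  if (length(x) < 3) stopf("Gamma MLE needs n >= 3")
  if (any(x <= 0)) stopf("Gamma MLE requires strictly positive values")
  if (max(x) == min(x)) stopf("Gamma MLE undefined for constant data")
  m <- mean(x)
  s <- log(m) - mean(log(x))
  k <- gammaShapeNewton(s, m^2 / stats::var(x))
  newFitParams("GAMMA", c(k, k / m))
}

## Newton solve of log(k) - digamma(k) = s; vectorized over s/k0 so the
## parametric bootstrap can refit all resamples at once.
gammaShapeNewton <- function(s, k0, tol = 1e-10, maxit = 100L) {
  k <- pmax(k0, 1e-8)
  for (i in seq_len(maxit)) {
    f <- log(k) - digamma(k) - s
    step <- f / (1 / k - trigamma(k))
    k_new <- k - step
    k_new <- ifelse(k_new <= 0, k / 2, k_new)   # guard: stay positive
    done <- abs(k_new - k) < tol * pmax(k, 1)
    k <- k_new
    if (all(done)) break
  }
  k
}

#' Closed-form Pareto maximum-likelihood fit
#'
#' `x_m = min(x)` and tail index `alpha = n / sum(log(x / x_m))`.
#'
#' @param x Positive numeric vector with `min(x) < max(x)`, n >= 2.
#' @return A `fit_params` object with family `"PARETO"`.
#' @examples
#' fitParetoMLE(c(1, 2, 4))   # alpha = 1/log(2)
#' @export
fitParetoMLE <- function(x) {
  if (length(x) < 2) stopf("Pareto MLE needs n >= 2")
  if (any(x <= 0)) stopf("Pareto MLE requires strictly positive values")
  xm <- min(x)
  slog <- sum(log(x / xm))
  if (slog == 0) stopf("Pareto index undefined for constant data")
  newFitParams("PARETO", c(xm, length(x) / slog))
}

#' Quantile-based Cauchy fit
#'
#' Location = sample median; scale = IQR/2 by default (the Cauchy
#' quartiles sit at location +/- scale, so IQR = 2*scale), or the
#' literal IQR under `scale_mode = "iqr"`. Quantiles use linear
#' interpolation at plotting positions (k-1)/(n-1).
#'
#' @param x Numeric vector, n >= 4.
#' @param scale_mode `"half-iqr"` (default) or `"iqr"`.
#' @return A `fit_params` object with family `"CAUCHY"`.
#' @examples
#' fitCauchyQuantile(c(1, 2, 3, 4, 5))        # location 3, scale 1
#' fitCauchyQuantile(1:5, scale_mode = "iqr") # location 3, scale 2
#' @export
fitCauchyQuantile <- function(x, scale_mode = c("half-iqr", "iqr")) {
  scale_mode <- match.arg(scale_mode)
  if (length(x) < 4) stopf("Cauchy quantile fit needs n >= 4")
  q <- typedQuantile(x, c(0.25, 0.5, 0.75))
  iqr <- q[3] - q[1]
  if (iqr == 0) stopf("degenerate Cauchy scale (IQR = 0)")
  newFitParams("CAUCHY", c(q[2], if (scale_mode == "iqr") iqr else iqr / 2))
}

#' Exact Kolmogorov-Smirnov statistic against a fitted family
#'
#' `D = sup_t |F_n(t) - F(t)|`, evaluated exactly as the maximum of the
#' two one-sided discrepancies at every order statistic.
#'
#' @param x Numeric vector.
#' @param fit A `fit_params` object (any family with a CDF).
#' @return The KS statistic, a scalar in `[0, 1]`.
#' @export
ksStatistic <- function(x, fit) {
  n <- length(x)
  u <- familyCDF(sort(x), fit)
  max(seq_len(n) / n - u, u - (seq_len(n) - 1) / n)
}

#' Draw a seeded sample from a fitted family
#'
#' @param fit A `fit_params` object.
#' @param n Number of draws.
#' @param seed Integer seed; identical seeds give identical draws. The
#'   caller's RNG state is untouched.
#' @return Numeric vector of length `n`.
#' @export
sampleFamily <- function(fit, n, seed) {
  if (n < 1) stopf("n must be >= 1")
  p <- fit$params
  withLocalSeed(seed, switch(fit$family,
    NORMAL    = stats::rnorm(n, p[1], p[2]),
    LOGNORMAL = stats::rlnorm(n, p[1], p[2]),
    CAUCHY    = stats::rcauchy(n, p[1], p[2]),
    GAMMA     = stats::rgamma(n, shape = p[1], rate = p[2]),
    PARETO    = p[1] * stats::runif(n)^(-1 / p[2]),
    stopf("cannot sample family %s", fit$family)))
}

## --- vectorized internals used by the parametric bootstrap ---------

## sort every column of X with a single order() call
colSortMatrix <- function(X) {
  matrix(X[order(col(X), X)], nrow = nrow(X), ncol = ncol(X))
}

## per-column maximum via max.col on the transpose (C-level)
colMaxMatrix <- function(X) {
  tX <- t(X)
  tX[cbind(seq_len(nrow(tX)), max.col(tX, ties.method = "first"))]
}

## type-7 quantile of every column of an already column-sorted matrix
colQuantileSorted <- function(Xs, p) {
  n <- nrow(Xs)
  h <- (n - 1) * p + 1
  j <- floor(h); g <- h - j
  lo <- Xs[j, ]
  if (g == 0) lo else (1 - g) * lo + g * Xs[j + 1, ]
}

## Draw an n x B matrix from the fitted law (no seed handling here; the
## caller owns the RNG state).
familyDrawMatrix <- function(fit, n, B) {
  p <- fit$params
  matrix(switch(fit$family,
    CAUCHY = stats::rcauchy(n * B, p[1], p[2]),
    GAMMA  = stats::rgamma(n * B, shape = p[1], rate = p[2]),
    PARETO = p[1] * stats::runif(n * B)^(-1 / p[2]),
    stopf("no bootstrap sampler for family %s", fit$family)), nrow = n)
}

## Re-estimate parameters on every column; returns a 2 x B matrix.
## Columns where the estimator degenerates get NA.
familyRefitColumns <- function(X, family, scale_mode = "half-iqr") {
  n <- nrow(X)
  if (family == "GAMMA") {
    mns <- colMeans(X)
    s <- log(mns) - colMeans(log(X))
    k0 <- mns^2 / apply(X, 2, stats::var)
    k <- gammaShapeNewton(s, k0)
    rbind(k, k / mns)
  } else if (family == "PARETO") {
    xm <- colSortMatrix(X)[1, ]
    alpha <- n / (colSums(log(X)) - n * log(xm))
    rbind(xm, alpha)
  } else if (family == "CAUCHY") {
    Xs <- colSortMatrix(X)
    q1 <- colQuantileSorted(Xs, 0.25)
    q2 <- colQuantileSorted(Xs, 0.5)
    q3 <- colQuantileSorted(Xs, 0.75)
    iqr <- q3 - q1
    iqr[iqr == 0] <- NA
    rbind(q2, if (scale_mode == "iqr") iqr else iqr / 2)
  } else stopf("no column refit for family %s", family)
}

## KS statistic for every column of X against per-column parameters.
ksStatisticColumns <- function(X, family, par) {
  n <- nrow(X)
  Xs <- colSortMatrix(X)
  U <- switch(family,
    CAUCHY = stats::pcauchy(Xs, rep(par[1, ], each = n),
                            rep(par[2, ], each = n)),
    GAMMA  = stats::pgamma(Xs, shape = rep(par[1, ], each = n),
                           rate = rep(par[2, ], each = n)),
    PARETO = {
      xm <- rep(par[1, ], each = n); a <- rep(par[2, ], each = n)
      ifelse(Xs < xm, 0, 1 - (xm / Xs)^a)
    })
  U <- matrix(U, nrow = n)
  i <- seq_len(n)
  colMaxMatrix(pmax(i / n - U, U - (i - 1) / n))
}
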