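## Fixtures built in code: small TSVs and cohorts used across tests.

writeTempTSV <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

## 3 genes x 2 samples well-formed expression fixture
fixtureExprFile <- function() {
  writeTempTSV(c("gene\ts1\ts2",
                 "g1\t1.5\t2.25",
                 "g2\t3\t4",
                 "g3\t0.125\t8"))
}

fixtureClinicalFile <- function(purity = FALSE) {
  hdr <- if (purity) "sample_id\ttime_days\tevent\tpurity"
         else "sample_id\ttime_days\tevent"
  rows <- c("s1\t100\t1", "s2\t250\t0", "s3\t40\t1")
  if (purity) rows <- paste0(rows, c("\t80", "\t65", "\t90"))
  writeTempTSV(c(hdr, rows))
}

## small aligned cohort with a planted bimodal prognostic gene
fixtureCohort <- function(n = 120, seed = 42, hr = 4) {
  withr::with_seed(seed, {
    g <- rbinom(n, 1, 0.5)
    expr <- rbind(
      planted = rnorm(n, 5 * g, 1),
      noise1 = rnorm(n, 10, 1),
      noise2 = rgamma(n, 2, 1))
    colnames(expr) <- sprintf("P%03d", seq_len(n))
    haz <- 0.01 * ifelse(g == 1, hr, 1)
    t_ev <- rexp(n, haz)
    t_c <- rexp(n, haz * 0.3 / 0.7)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(expr = expr),
      colData = S4Vectors::DataFrame(
        time_days = pmin(t_ev, t_c),
        event = as.integer(t_ev <= t_c),
        row.names = colnames(expr)))
    S4Vectors::metadata(se)$scale <- "log2"
    list(se = se, group = g)
  })
}

## Brute-force two-group log-rank oracle: hypergeometric moments at
## each distinct event time. Independent of the survival package.
logrankOracle <- function(time, event, group) {
  stopifnot(all(group %in% c(1, 2)))
  evt <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in evt) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & group == 1)
    d_t <- sum(time == t & event == 1)
    d1_t <- sum(time == t & event == 1 & group == 1)
    O <- O + d1_t
    E <- E + d_t * n1_t / n_t
    if (n_t > 1)
      V <- V + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

## Fisher two-sided p by full enumeration over tables with fixed margins
fisherOracle <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(support, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## patient_split constructor for tests
makeSplit <- function(ids, g1) {
  structure(list(
    group = stats::setNames(
      factor(ifelse(ids %in% g1, "G1", "G2"), levels = c("G1", "G2")), ids),
    rule = "TWO_TAIL", cut_points = NA_real_), class = "patient_split")
}
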