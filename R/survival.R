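## Shape-aware patient splitting, log-rank testing, Kaplan-Meier
## estimation, the genome-wide prognostic scan and the
## random-assignment null. Splitting rules by family:
##   NORMAL/CAUCHY            -> TWO_TAIL  (both tenth-percentile tails)
##   LOGNORMAL/GAMMA/PARETO   -> ONE_TAIL on the long-tail side
##   BIMODAL                  -> MODE      (mixture-component membership)

#' Split patients by the shape of a gene's expression
#'
#' Symmetric families put both extreme tails in Group 1; skewed
#' families use only the long tail (side chosen by the sign of the
#' sample skewness); bimodal genes use membership of the upper mixture
#' component (posterior responsibility >= 0.5). Values falling exactly
#' on a quantile cut go to the non-extreme group, so extreme groups
#' never exceed their nominal size.
#'
#' @param x Named numeric vector of one gene's expression across
#'   samples (n >= 20).
#' @param family Family label (see [classifyGene()]); `UNKNOWN` is an
#'   error.
#' @param bifit `"bimodal_fit"` for `family = "BIMODAL"`; ignored
#'   otherwise. When `NULL` for a bimodal gene the mixture is refit.
#' @param tail_fraction Tail mass per side (default 0.10).
#' @param mode_split `"mixture"` (default) or `"kmeans"` (2-means
#'   fallback for the bimodal rule).
#' @return A list of class `"patient_split"`: `group` (factor
#'   `G1`/`G2` named by sample), `rule`, `cut_points`.
#' @export
splitPatients <- function(x, family, bifit = NULL, tail_fraction = 0.10,
                          mode_split = c("mixture", "kmeans")) {
  mode_split <- match.arg(mode_split)
  n <- length(x)
  if (n < 20) stopf("patient splitting needs n >= 20")
  if (family == "UNKNOWN")
    stopf("no splitting rule for UNKNOWN genes")
  if (family == "BIMODAL") {
    if (mode_split == "kmeans") {
      km <- stats::kmeans(x, centers = range(x), iter.max = 50L)
      upper <- which.max(km$centers)
      g1 <- km$cluster == upper
      cuts <- mean(km$centers)
    } else {
      if (is.null(bifit)) bifit <- fitBimodalMixture(x)
      g1 <- bifit$responsibilities >= 0.5
      cuts <- (bifit$mu1 + bifit$mu2) / 2
    }
    rule <- "MODE"
  } else if (family %in% c("NORMAL", "CAUCHY")) {
    q <- typedQuantile(x, c(tail_fraction, 1 - tail_fraction))
    g1 <- x < q[1] | x > q[2]
    cuts <- q
    rule <- "TWO_TAIL"
  } else if (family %in% c("LOGNORMAL", "GAMMA", "PARETO")) {
    if (sampleSkewness(x) > 0) {
      q <- typedQuantile(x, 1 - tail_fraction)
      g1 <- x > q
      rule <- "ONE_TAIL_UPPER"
    } else {
      q <- typedQuantile(x, tail_fraction)
      g1 <- x < q
      rule <- "ONE_TAIL_LOWER"
    }
    cuts <- q
  } else stopf("unknown family label: %s", family)
  if (!any(g1) || all(g1))
    stopf("degenerate split for rule %s (one group empty)", rule)
  structure(list(
    group = stats::setNames(factor(ifelse(g1, "G1", "G2"),
                                   levels = c("G1", "G2")), names(x)),
    rule = rule, cut_points = unname(cuts)
  ), class = "patient_split")
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of the survival experience of the two
#' groups of a [splitPatients()] partition: at each distinct event time
#' observed events are compared with their hypergeometric expectation;
#' the statistic `(sum O - sum E)^2 / sum V` is referred to a 1-df
#' chi-square (computed via [survival::survdiff()]).
#'
#' @param split A `"patient_split"`.
#' @param surv A data.frame with `sample_id`, `time_days`, `event`
#'   (see [survivalTable()]), covering all split samples.
#' @return A list of class `"logrank_result"`: `statistic`, `p`, `n1`,
#'   `n2`, `events1`, `events2`.
#' @export
logrankTest <- function(split, surv) {
  idx <- match(names(split$group), surv$sample_id)
  if (anyNA(idx)) stopf("split contains samples missing from the survival table")
  time <- surv$time_days[idx]; event <- surv$event[idx]
  if (sum(event) == 0) stopf("no events in either group")
  grp <- split$group
  ## survdiff's chisq needs an invertible variance; patterns whose
  ## log-rank variance is exactly zero (e.g. every event occurring with
  ## a single patient at risk) make it fail, so fall back to the direct
  ## hypergeometric-moment computation, where zero variance means zero
  ## statistic.
  stat <- tryCatch(
    unname(survival::survdiff(survival::Surv(time, event) ~ grp)$chisq),
    error = function(e) {
      g1 <- grp == "G1"
      O <- E <- V <- 0
      for (t in sort(unique(time[event == 1]))) {
        at <- time >= t
        nt <- sum(at); n1t <- sum(at & g1)
        dt <- sum(time == t & event == 1)
        O <- O + sum(time == t & event == 1 & g1)
        E <- E + dt * n1t / nt
        if (nt > 1)
          V <- V + dt * (n1t / nt) * (1 - n1t / nt) * (nt - dt) / (nt - 1)
      }
      if (V > 0) (O - E)^2 / V else 0
    })
  structure(list(
    statistic = stat,
    p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    n1 = sum(grp == "G1"), n2 = sum(grp == "G2"),
    events1 = sum(event[grp == "G1"]), events2 = sum(event[grp == "G2"])
  ), class = "logrank_result")
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator, overall or per group.
#'
#' @param surv Survival data.frame (see [logrankTest()]).
#' @param group Optional factor/character vector of group labels, named
#'   by or aligned with `surv$sample_id`.
#' @return A data.frame with columns `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` -- one row per distinct time within
#'   each group.
#' @export
kmEstimate <- function(surv, group = NULL) {
  if (is.null(group)) {
    fit <- survival::survfit(
      survival::Surv(surv$time_days, surv$event) ~ 1)
    groups <- rep("all", length(fit$time))
  } else {
    if (!is.null(names(group))) group <- group[surv$sample_id]
    g <- factor(group)
    fit <- survival::survfit(
      survival::Surv(surv$time_days, surv$event) ~ g)
    if (is.null(fit$strata)) groups <- rep(levels(g)[1], length(fit$time))
    else groups <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = groups, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor,
             surv = fit$surv, stringsAsFactors = FALSE)
}

#' Genome-wide prognostic scan
#'
#' Splits the patients gene by gene and log-rank-tests each split.
#' Under the `SHAPE` assumption every gene uses the rule of its
#' assigned family; under `SYMMETRIC` every gene uses the two-tailed
#' rule regardless of family. `UNKNOWN` genes are skipped, as are genes
#' whose split degenerates (both recorded with `NA` p-values).
#'
#' @param se Aligned cohort (see [alignCohort()]).
#' @param calls A [ShapeCalls-class] object for the same genes, or
#'   `NULL` under `SYMMETRIC` (no classification needed).
#' @param cfg A [shapeConfig()] list.
#' @param assumption `"SHAPE"` or `"SYMMETRIC"`.
#' @return A data.frame `gene_id`, `family`, `rule`, `n1`, `n2`,
#'   `chisq`, `p`, `significant` (p < `cfg$alpha_survival`).
#' @export
prognosticScan <- function(se, calls = NULL, cfg = shapeConfig(),
                           assumption = c("SHAPE", "SYMMETRIC")) {
  assumption <- match.arg(assumption)
  if (assumption == "SHAPE" && is.null(calls))
    stopf("the SHAPE assumption requires classification calls")
  m <- SummarizedExperiment::assay(se, "expr")
  surv <- survivalTable(se)
  fam <- if (!is.null(calls)) geneFamilies(calls) else
    stats::setNames(rep(NA_character_, nrow(m)), rownames(m))
  bfits <- if (!is.null(calls)) bimodalFits(calls) else list()
  rows <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    gid <- rownames(m)[i]
    gene_family <- fam[[gid]]
    use_family <- if (assumption == "SYMMETRIC") "NORMAL" else gene_family
    row <- data.frame(gene_id = gid,
                      family = ifelse(is.na(gene_family), "", gene_family),
                      rule = NA_character_, n1 = NA_integer_,
                      n2 = NA_integer_, chisq = NA_real_, p = NA_real_,
                      significant = NA, stringsAsFactors = FALSE)
    skip <- !is.na(gene_family) && gene_family == "UNKNOWN"
    if (!skip) {
      res <- tryCatch({
        sp <- splitPatients(m[i, ], use_family, bifit = bfits[[gid]],
                            tail_fraction = cfg$tail_fraction,
                            mode_split = cfg$mode_split)
        lr <- logrankTest(sp, surv)
        list(sp = sp, lr = lr)
      }, error = function(e) NULL)
      if (!is.null(res)) {
        row$rule <- res$sp$rule
        row$n1 <- res$lr$n1; row$n2 <- res$lr$n2
        row$chisq <- res$lr$statistic; row$p <- res$lr$p
        row$significant <- res$lr$p < cfg$alpha_survival
      }
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Random-assignment null for the prognostic scan
#'
#' For each permutation, every gene's group labels are shuffled while
#' preserving the group sizes, the log-rank test is recomputed, and the
#' number of nominally significant genes is recorded. Mirrors the
#' robustness check that no genes should be significant when patients
#' are randomly assigned to the two groups.
#'
#' @param surv Survival data.frame.
#' @param splits Named list of `"patient_split"` objects (one per gene).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param alpha Significance level (default 0.05).
#' @return A list: `counts` (significant-gene count per permutation)
#'   and `rate` (overall fraction of significant gene-permutations).
#' @export
randomSplitNull <- function(surv, splits, n_perm = 100L, seed = 1L,
                            alpha = 0.05) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  withLocalSeed(seed, {
    counts <- integer(n_perm)
    for (b in seq_len(n_perm)) {
      n_sig <- 0L
      for (sp in splits) {
        perm <- sp
        perm$group <- stats::setNames(sample(sp$group), names(sp$group))
        p <- tryCatch(logrankTest(perm, surv)$p, error = function(e) NA_real_)
        if (!is.na(p) && p < alpha) n_sig <- n_sig + 1L
      }
      counts[b] <- n_sig
    }
    list(counts = counts,
         rate = sum(counts) / (n_perm * length(splits)))
  })
}
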