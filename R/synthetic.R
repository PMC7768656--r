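## Seeded synthetic-cohort generator: genes drawn from the six-family
## panel, right-censored survival whose hazard optionally depends on a
## gene's long-tail or upper-mode membership. Every pipeline stage is
## testable against the emitted ground truth without any download.

#' Build one synthetic gene specification
#'
#' @param gene_id Unique gene identifier.
#' @param family One of the six generating families.
#' @param params Numeric parameters: two values for the unimodal
#'   families (see [newFitParams()] conventions); for `BIMODAL`, a
#'   vector `c(pi, mu1, mu2, sigma)`.
#' @param prognostic `"NONE"`, `"TAIL"` (long-tail membership drives
#'   hazard; unimodal families only) or `"MODE"` (upper-component
#'   membership; bimodal only).
#' @param hazard_ratio Hazard ratio of the risk group (1 iff
#'   `prognostic = "NONE"`).
#' @return A one-row data.frame.
#' @export
geneSpec <- function(gene_id, family, params,
                     prognostic = c("NONE", "TAIL", "MODE"),
                     hazard_ratio = 1) {
  prognostic <- match.arg(prognostic)
  family <- match.arg(family, setdiff(FAMILIES, "UNKNOWN"))
  if (prognostic == "MODE" && family != "BIMODAL")
    stopf("MODE prognostic requires a BIMODAL family")
  if (prognostic == "TAIL" && family == "BIMODAL")
    stopf("TAIL prognostic requires a unimodal family")
  if ((hazard_ratio == 1) != (prognostic == "NONE"))
    stopf("hazard_ratio must be 1 exactly when prognostic is NONE")
  if (hazard_ratio <= 0) stopf("hazard_ratio must be positive")
  if (family == "BIMODAL") {
    if (length(params) != 4 || params[1] <= 0 || params[1] >= 1 ||
        params[4] <= 0)
      stopf("BIMODAL expects params c(pi in (0,1), mu1, mu2, sigma > 0)")
  } else newFitParams(family, params)  # validates
  p <- c(as.numeric(params), rep(NA_real_, 4 - length(params)))
  data.frame(gene_id = gene_id, family = family,
             p1 = p[1], p2 = p[2], p3 = p[3], p4 = p[4],
             prognostic = prognostic, hazard_ratio = hazard_ratio,
             stringsAsFactors = FALSE)
}

#' Build a synthetic cohort specification
#'
#' @param gene_specs Data.frame of stacked [geneSpec()] rows.
#' @param n_samples Cohort size (>= 20).
#' @param baseline_hazard Baseline exponential event rate per day
#'   (default 1/1000: median survival around two years, typical of the
#'   aggressive-cancer cohorts this emulates).
#' @param censor_rate Expected censored fraction in [0, 1).
#' @param tail_fraction Tail mass defining `TAIL` risk membership.
#' @param seed Integer seed.
#' @return A list of class `"cohort_spec"`.
#' @export
cohortSpec <- function(gene_specs, n_samples, baseline_hazard = 1 / 1000,
                       censor_rate = 0.3, tail_fraction = 0.10,
                       seed = 1L) {
  if (n_samples < 20) stopf("n_samples must be >= 20")
  if (anyDuplicated(gene_specs$gene_id)) stopf("duplicated gene ids in spec")
  if (baseline_hazard <= 0) stopf("baseline_hazard must be positive")
  if (censor_rate < 0 || censor_rate >= 1)
    stopf("censor_rate must lie in [0, 1)")
  structure(list(gene_specs = gene_specs, n_samples = as.integer(n_samples),
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, tail_fraction = tail_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

drawGene <- function(family, p, n) {
  switch(family,
    NORMAL    = stats::rnorm(n, p[1], p[2]),
    LOGNORMAL = stats::rlnorm(n, p[1], p[2]),
    CAUCHY    = stats::rcauchy(n, p[1], p[2]),
    GAMMA     = stats::rgamma(n, shape = p[1], rate = p[2]),
    PARETO    = p[1] * stats::runif(n)^(-1 / p[2]),
    BIMODAL   = {
      z <- stats::rbinom(n, 1, p[1])
      stats::rnorm(n, ifelse(z == 1, p[3], p[2]), p[4])
    })
}

#' Simulate a cohort from a specification
#'
#' Expression: every gene sampled i.i.d. from its family (bimodal genes
#' via a Bernoulli component indicator). Survival: each sample's hazard
#' is `baseline * prod(hazard_ratio)` over the prognostic genes for
#' which the sample is in the risk group (`TAIL`: beyond the
#' long-tail empirical quantile; `MODE`: drawn from the upper
#' component); event times are exponential with that hazard, and
#' censoring is an independent per-sample exponential calibrated so the
#' expected censored fraction equals `censor_rate`. Identical seeds
#' give bit-identical output.
#'
#' @param spec A [cohortSpec()].
#' @return A list: `se` (aligned SummarizedExperiment: expression assay
#'   + `time_days`/`event` colData), `truth` (list with `genes` -- the
#'   spec plus generating info -- and `membership`, a logical
#'   prognostic-genes x samples matrix of risk-group membership).
#' @export
simulateCohort <- function(spec) {
  gs <- spec$gene_specs
  n <- spec$n_samples
  withLocalSeed(spec$seed, {
    sample_ids <- sprintf("S%03d", seq_len(n))
    expr <- matrix(0, nrow(gs), n,
                   dimnames = list(gs$gene_id, sample_ids))
    prog <- which(gs$prognostic != "NONE")
    membership <- matrix(FALSE, length(prog), n,
                         dimnames = list(gs$gene_id[prog], sample_ids))
    for (i in seq_len(nrow(gs))) {
      fam <- gs$family[i]
      p <- as.numeric(gs[i, c("p1", "p2", "p3", "p4")])
      if (fam == "BIMODAL" && gs$prognostic[i] == "MODE") {
        z <- stats::rbinom(n, 1, p[1])
        x <- stats::rnorm(n, ifelse(z == 1, p[3], p[2]), p[4])
        membership[gs$gene_id[i], ] <- z == 1
      } else {
        x <- drawGene(fam, p, n)
        if (gs$prognostic[i] == "TAIL") {
          q <- typedQuantile(x, 1 - spec$tail_fraction)
          membership[gs$gene_id[i], ] <- x > q
        }
      }
      expr[i, ] <- x
    }
    hazard <- rep(spec$baseline_hazard, n)
    for (g in rownames(membership)) {
      hr <- gs$hazard_ratio[gs$gene_id == g]
      hazard <- hazard * ifelse(membership[g, ], hr, 1)
    }
    event_time <- stats::rexp(n, rate = hazard)
    if (spec$censor_rate > 0) {
      ## P(censor) = mu/(lambda + mu) = censor_rate when
      ## mu = lambda * censor_rate / (1 - censor_rate)
      censor_time <- stats::rexp(
        n, rate = hazard * spec$censor_rate / (1 - spec$censor_rate))
    } else censor_time <- rep(Inf, n)
    time <- pmin(event_time, censor_time)
    event <- as.integer(event_time <= censor_time)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(expr = expr),
      colData = S4Vectors::DataFrame(time_days = time, event = event,
                                     row.names = sample_ids))
    S4Vectors::metadata(se)$scale <- "log2"
    list(se = se,
         truth = list(genes = gs, membership = membership))
  })
}

#' Benchmark cohort presets
#'
#' `CLASSIFY`: 600 genes, 100 per family, n = 300, no survival linkage
#' -- bimodal separations 3-5 sigma, Gamma shapes spread over 1-5,
#' Pareto indices over 2-4, moderate Normal/Lognormal/Cauchy
#' parameters. `SURVIVAL`: 500 genes with 20 bimodal-`MODE` and 10
#' Gamma-`TAIL` prognostic genes at hazard ratio 3, 30% censoring,
#' n = 300. `COMPARE`: the `SURVIVAL` design sized for repeated
#' train/test splitting (identical construction).
#'
#' @param preset `"CLASSIFY"`, `"SURVIVAL"` or `"COMPARE"`.
#' @param seed Integer seed (stored in the spec; presets with different
#'   seeds differ only in sampled values).
#' @param null_effects If `TRUE`, all planted hazard ratios are reset
#'   to 1 (a structure-matched null cohort).
#' @return A [cohortSpec()].
#' @export
benchmarkPanel <- function(preset = c("CLASSIFY", "SURVIVAL", "COMPARE"),
                           seed = 1L, null_effects = FALSE) {
  preset <- match.arg(toupper(preset), c("CLASSIFY", "SURVIVAL", "COMPARE"))
  specs <- list()
  add <- function(s) specs[[length(specs) + 1L]] <<- s
  if (preset == "CLASSIFY") {
    grid <- function(lo, hi, k) lo + (hi - lo) * (seq_len(k) - 1) / (k - 1)
    for (j in seq_len(100)) {
      add(geneSpec(sprintf("NORM%03d", j), "NORMAL", c(0, 1)))
      add(geneSpec(sprintf("LNORM%03d", j), "LOGNORMAL", c(1, 0.5)))
      add(geneSpec(sprintf("CAUCH%03d", j), "CAUCHY", c(0, 1)))
      add(geneSpec(sprintf("GAM%03d", j), "GAMMA",
                   c(grid(1, 5, 100)[j], 1)))
      add(geneSpec(sprintf("PAR%03d", j), "PARETO",
                   c(1, grid(2, 4, 100)[j])))
      add(geneSpec(sprintf("BIM%03d", j), "BIMODAL",
                   c(0.5, 0, grid(3, 5, 100)[j], 1)))
    }
    return(cohortSpec(do.call(rbind, specs), n_samples = 300,
                      censor_rate = 0, seed = seed))
  }
  ## SURVIVAL / COMPARE: 500 genes, 30 planted prognostic
  hr <- if (null_effects) 1 else 3
  prog_mode <- if (null_effects) "NONE" else "MODE"
  prog_tail <- if (null_effects) "NONE" else "TAIL"
  for (j in seq_len(20))
    add(geneSpec(sprintf("BIMPROG%02d", j), "BIMODAL", c(0.5, 0, 4, 1),
                 prognostic = prog_mode, hazard_ratio = hr))
  for (j in seq_len(10))
    add(geneSpec(sprintf("GAMPROG%02d", j), "GAMMA", c(2, 1),
                 prognostic = prog_tail, hazard_ratio = hr))
  fams <- c("NORMAL", "LOGNORMAL", "CAUCHY", "GAMMA", "BIMODAL")
  for (j in seq_len(470)) {
    fam <- fams[(j - 1) %% length(fams) + 1]
    add(switch(fam,
      NORMAL    = geneSpec(sprintf("NULLNORM%03d", j), "NORMAL", c(0, 1)),
      LOGNORMAL = geneSpec(sprintf("NULLLNORM%03d", j), "LOGNORMAL",
                           c(1, 0.5)),
      CAUCHY    = geneSpec(sprintf("NULLCAUCH%03d", j), "CAUCHY", c(0, 1)),
      GAMMA     = geneSpec(sprintf("NULLGAM%03d", j), "GAMMA", c(2, 1)),
      BIMODAL   = geneSpec(sprintf("NULLBIM%03d", j), "BIMODAL",
                           c(0.5, 0, 4, 1))))
  }
  cohortSpec(do.call(rbind, specs), n_samples = 300, censor_rate = 0.3,
             seed = seed)
}

#' Write a simulated cohort to disk
#'
#' Emits the TSV formats the readers accept: `expression.tsv`,
#' `clinical.tsv`, and `truth.tsv` (`gene_id family prognostic
#' hazard_ratio`).
#'
#' @param sim Result of [simulateCohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionMatrix(sim$se, file.path(dir, "expression.tsv"))
  surv <- survivalTable(sim$se)
  utils::write.table(surv, file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth$genes[, c("gene_id", "family", "prognostic",
                               "hazard_ratio")]
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
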