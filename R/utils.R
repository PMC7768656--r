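## Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator locally and restores the caller's RNG state on
#' exit, so seeded functions never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withLocalSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Deterministic per-gene seed stream
#'
#' Polynomial rolling hash of the gene identifier combined with the run
#' seed, reduced modulo a Mersenne prime so the result is a valid 32-bit
#' seed. Keying on the identifier (not the row position) makes per-gene
#' results invariant to gene order.
#'
#' @param gene_id Character scalar.
#' @param seed Integer run seed.
#' @return Integer seed in [0, 2^31 - 2].
#' @keywords internal
#' @noRd
geneSeed <- function(gene_id, seed) {
  bytes <- utf8ToInt(as.character(gene_id))
  h <- as.double(seed %% 2147483647L)
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

## stop()/warning() wrappers with consistent call. = FALSE
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Sample skewness (method-of-moments, biased form)
#' @keywords internal
#' @noRd
sampleSkewness <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

## Quantiles by linear interpolation at plotting positions (k-1)/(n-1),
## i.e. stats::quantile type 7 -- the convention used throughout.
typedQuantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}
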