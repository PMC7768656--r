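#' ShapeCalls: per-gene distribution-shape verdicts
#'
#' Container for the result of [classifyMatrix()]: one row per gene
#' with the assigned family, the bimodality index and the candidate
#' p-values, plus the fitted two-component mixtures of the bimodal
#' genes (needed later for mode-based patient splitting) and a snapshot
#' of the configuration that produced the calls.
#'
#' @slot calls A [S4Vectors::DataFrame] with columns `gene_id`,
#'   `family`, `bi`, `p_normal`, `p_lognormal`, `p_cauchy`, `p_gamma`,
#'   `p_pareto`; rownames are gene ids.
#' @slot bimodalFits Named list of `"bimodal_fit"` objects for the
#'   genes called `BIMODAL`.
#' @slot config The `"shape_config"` list used.
#'
#' @aliases ShapeCalls
#' @exportClass ShapeCalls
#' @importClassesFrom S4Vectors DataFrame
#' @name ShapeCalls-class
setClass("ShapeCalls",
  slots = c(calls = "DataFrame", bimodalFits = "list", config = "ANY"))

setValidity("ShapeCalls", function(object) {
  need <- c("gene_id", "family", "bi", "p_normal", "p_lognormal",
            "p_cauchy", "p_gamma", "p_pareto")
  df <- object@calls
  if (!all(need %in% colnames(df)))
    return(sprintf("calls must have columns: %s", paste(need, collapse = ", ")))
  if (anyDuplicated(df$gene_id)) return("duplicated gene ids")
  if (!all(df$family %in% FAMILIES))
    return("unknown family label in calls")
  extra <- setdiff(names(object@bimodalFits),
                   df$gene_id[df$family == "BIMODAL"])
  if (length(extra) > 0)
    return("bimodalFits contains genes not called BIMODAL")
  TRUE
})

#' Construct a ShapeCalls object
#'
#' @param calls DataFrame of per-gene calls (see [ShapeCalls-class]).
#' @param bimodalFits Named list of mixture fits for bimodal genes.
#' @param config The `"shape_config"` used.
#' @return A [ShapeCalls-class] object.
#' @export
ShapeCalls <- function(calls, bimodalFits = list(), config = shapeConfig()) {
  methods::new("ShapeCalls", calls = calls, bimodalFits = bimodalFits,
               config = config)
}

#' @describeIn ShapeCalls-class The per-gene call table (DataFrame).
#' @param x,object A `ShapeCalls` object.
#' @export
callTable <- function(x) x@calls

#' @describeIn ShapeCalls-class Named character vector of family labels.
#' @export
geneFamilies <- function(x) stats::setNames(x@calls$family, x@calls$gene_id)

#' @describeIn ShapeCalls-class Mixture fits of the bimodal genes.
#' @export
bimodalFits <- function(x) x@bimodalFits

#' @describeIn ShapeCalls-class Counts and fractions per family
#'   (including families with zero genes).
#' @export
familyCounts <- function(x) {
  n <- vapply(FAMILIES, function(f) sum(x@calls$family == f), 0L)
  data.frame(family = FAMILIES, count = n,
             fraction = n / max(1L, nrow(x@calls)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @describeIn ShapeCalls-class Compact display.
#' @exportMethod show
setMethod("show", "ShapeCalls", function(object) {
  fc <- familyCounts(object)
  cat(sprintf("ShapeCalls with %d gene(s)\n", nrow(object@calls)))
  keep <- fc$count > 0
  for (i in which(keep))
    cat(sprintf("  %-10s %5d (%.1f%%)\n", fc$family[i], fc$count[i],
                100 * fc$fraction[i]))
  invisible(NULL)
})

#' @export
#' @method as.data.frame ShapeCalls
as.data.frame.ShapeCalls <- function(x, ...) as.data.frame(callTable(x))

#' @describeIn ShapeCalls-class Number of genes called.
#' @exportMethod length
setMethod("length", "ShapeCalls", function(x) nrow(x@calls))
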