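#' Accessors for StabilityScore
#'
#' `stabilityValues()` returns the named per-candidate stability values
#' (lower = more stable); `stabilityMethod()` the algorithm identifier.
#'
#' @param x A [StabilityScore-class].
#' @name stabilityValues
#' @aliases stabilityMethod
NULL

#' @rdname stabilityValues
#' @export
setMethod("stabilityValues", "StabilityScore", function(x) x@values)

#' @rdname stabilityValues
#' @export
setMethod("stabilityMethod", "StabilityScore", function(x) x@method)

setMethod("show", "StabilityScore", function(object) {
  cat(sprintf("StabilityScore (%s, condition '%s'):\n",
              object@method, object@condition))
  v <- sort(object@values)
  cat(paste(sprintf("  %s: %.4f", names(v), v), collapse = "\n"), "\n")
})

#' Tidy a StabilityScore into a data frame
#'
#' @param score A [StabilityScore-class].
#' @param tieTolerance Tie tolerance for the rank column, see
#'   [competitionRanks()].
#' @return Data frame with columns `candidate`, `stability`, `rank`,
#'   `method`, `condition`, sorted most stable first.
#' @export
stabilityTable <- function(score, tieTolerance = 1e-12) {
  ranks <- rankValues(competitionRanks(score, tieTolerance))
  v <- stabilityValues(score)
  out <- data.frame(candidate = names(v), stability = unname(v),
                    rank = unname(ranks[names(v)]),
                    method = score@method, condition = score@condition)
  out[order(out$rank, out$candidate), , drop = FALSE]
}
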