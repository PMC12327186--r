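#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' CtTable: a validated qPCR Ct matrix with sample groups
#'
#' `CtTable` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single assay `"ct"` holding cycle-threshold values (candidates in rows,
#' samples in columns) and column metadata with a `group` label per sample
#' and a shared free-text `condition` label (e.g. `"motility"`). All
#' downstream stability algorithms consume this class.
#'
#' Validity requirements: every Ct value finite and in (0, 45] cycles (a
#' 40-cycle protocol plus headroom); unique candidate and sample
#' identifiers; at least 2 candidates and 2 samples; a `group` column in
#' `colData`. Group-aware operations additionally require >= 2 groups with
#' >= 2 samples each, checked at call time rather than by the class.
#'
#' @slot ... See [SummarizedExperiment::SummarizedExperiment]; the assay is
#'   named `"ct"`.
#' @seealso [CtTable()] for construction, [readCtTable()] for file input.
#' @export
setClass("CtTable", contains = "SummarizedExperiment")

.validCtTable <- function(object) {
  msgs <- character(0)
  if (!"ct" %in% SummarizedExperiment::assayNames(object))
    return("assay 'ct' is missing")
  ct <- SummarizedExperiment::assay(object, "ct")
  if (nrow(ct) < 2L) msgs <- c(msgs, "need >= 2 candidates")
  if (ncol(ct) < 2L) msgs <- c(msgs, "need >= 2 samples")
  if (is.null(rownames(ct)) || anyDuplicated(rownames(ct)))
    msgs <- c(msgs, "candidate identifiers must be present and unique")
  if (is.null(colnames(ct)) || anyDuplicated(colnames(ct)))
    msgs <- c(msgs, "sample identifiers must be present and unique")
  bad <- !is.finite(ct) | ct <= 0 | ct > 45
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    msgs <- c(msgs, sprintf(
      "Ct values must be finite and in (0, 45]; first offender at candidate '%s', sample '%s'",
      rownames(ct)[idx[1L]], colnames(ct)[idx[2L]]))
  }
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msgs <- c(msgs, "colData must contain a 'group' column")
  if (length(msgs)) msgs else TRUE
}
setValidity("CtTable", .validCtTable)

#' StabilityScore: one algorithm's per-candidate stability values
#'
#' Holds the stability value assigned to each candidate by a single
#' algorithm, on that algorithm's own scale. Lower is always more stable.
#'
#' @slot method Single string identifying the algorithm
#'   (`"delta_ct"`, `"genorm"`, `"normfinder"`, `"bestkeeper"`).
#' @slot values Named numeric vector, one non-negative value per candidate.
#' @slot condition Free-text condition label carried from the input table.
#' @seealso [deltaCtStability()], [geNormRank()], [normFinderStability()],
#'   [bestKeeperStats()], [competitionRanks()].
#' @export
setClass("StabilityScore", representation(
  method = "character", values = "numeric", condition = "character"))

setValidity("StabilityScore", function(object) {
  msgs <- character(0)
  if (length(object@method) != 1L) msgs <- c(msgs, "method must be a single string")
  if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
    msgs <- c(msgs, "values must be uniquely named by candidate")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msgs <- c(msgs, "stability values must be finite and >= 0")
  if (length(msgs)) msgs else TRUE
})

#' GeNormTrace: the stepwise geNorm exclusion record
#'
#' Records the full stepwise geNorm run: candidates excluded worst-first,
#' the M value each candidate carried at its exclusion step, the final
#' retained pair (which shares the last M), and the per-step subsets.
#'
#' @slot exclusionOrder Character vector of excluded candidates, worst
#'   first; the final pair is not listed here.
#' @slot mAtExclusion Named numeric vector: for every candidate, the M
#'   value recorded at the step where it left the analysis (the final pair
#'   records the final-step M).
#' @slot finalPair Character vector of the two candidates never excluded.
#' @slot steps List, one element per elimination step, each with fields
#'   `subset` (candidates present) and `m` (named M values on that subset).
#' @seealso [geNormRank()], [geNormV()].
#' @export
setClass("GeNormTrace", representation(
  exclusionOrder = "character", mAtExclusion = "numeric",
  finalPair = "character", steps = "list", condition = "character"))

setValidity("GeNormTrace", function(object) {
  msgs <- character(0)
  if (length(object@finalPair) != 2L)
    msgs <- c(msgs, "exactly two candidates must remain unexcluded")
  m <- object@mAtExclusion
  if (length(object@finalPair) == 2L &&
      all(object@finalPair %in% names(m)) &&
      !isTRUE(all.equal(m[[object@finalPair[1L]]], m[[object@finalPair[2L]]],
                        tolerance = 1e-12)))
    msgs <- c(msgs, "the final pair must share the final-step M value")
  if (length(msgs)) msgs else TRUE
})

#' NormFinderDecomposition: intra-/intergroup variance decomposition
#'
#' Per-candidate, per-group components of the model-based decomposition:
#' observed centered variances, bias-corrected intragroup variances,
#' intergroup deviations and their shrunken versions, and the estimated
#' between-candidate variance of group deviations.
#'
#' @slot s2 Candidates x groups matrix of observed centered variances
#'   (cycles^2), n_g - 1 denominator.
#' @slot sigma2 Candidates x groups matrix of corrected intragroup
#'   variances (cycles^2), clipped at 0.
#' @slot dHat Candidates x groups matrix of intergroup deviations (cycles);
#'   columns sum to 0 by construction.
#' @slot dTilde Shrunken deviations (cycles); never larger in magnitude
#'   than `dHat`.
#' @slot gamma2 Estimated between-candidate variance of the group
#'   deviations (cycles^2), clipped at 0.
#' @slot nPerGroup Named integer vector of group sample sizes.
#' @slot condition Condition label carried from the input table.
#' @seealso [normFinderDecompose()], [normFinderStability()].
#' @export
setClass("NormFinderDecomposition", representation(
  s2 = "matrix", sigma2 = "matrix", dHat = "matrix", dTilde = "matrix",
  gamma2 = "numeric", nPerGroup = "integer", condition = "character"))

setValidity("NormFinderDecomposition", function(object) {
  msgs <- character(0)
  if (any(object@sigma2 < 0) || any(object@s2 < 0))
    msgs <- c(msgs, "variances must be non-negative")
  if (length(object@gamma2) != 1L || object@gamma2 < 0)
    msgs <- c(msgs, "gamma2 must be a single non-negative value")
  if (any(colSums(object@dHat) > 1e-9))
    msgs <- c(msgs, "group deviations must sum to zero within each group")
  if (any(abs(object@dTilde) > abs(object@dHat) + 1e-12))
    msgs <- c(msgs, "shrinkage must never inflate a deviation")
  if (length(msgs)) msgs else TRUE
})

#' RankVector: per-method competition ranks
#'
#' Integer competition ranks ("1224" style with the minimum convention):
#' tied candidates share the smallest rank of their tie set and the next
#' distinct rank skips by the tie size.
#'
#' @slot method Single string identifying the originating method.
#' @slot ranks Named integer vector, one rank per candidate, starting at 1.
#' @slot ties List of character vectors, the tie sets of size >= 2.
#' @seealso [competitionRanks()], [ranksFromTiers()], [geometricMeanRank()].
#' @export
setClass("RankVector", representation(
  method = "character", ranks = "integer", ties = "list"))

setValidity("RankVector", function(object) {
  r <- sort(object@ranks)
  expected <- integer(0)
  pos <- 1L
  for (v in unique(r)) {
    n <- sum(r == v)
    expected <- c(expected, rep(pos, n)); pos <- pos + n
  }
  if (!identical(as.integer(r), expected))
    return("ranks must follow competition ranking (minimum convention)")
  TRUE
})

#' ConsensusRanking: geometric-mean aggregation of method ranks
#'
#' The RefFinder-style comprehensive ranking: per candidate, the geometric
#' mean of its per-method competition ranks, the 2-decimal truncated
#' display value, and the final order.
#'
#' @slot geomean Named numeric vector of geometric-mean ranks.
#' @slot display Named numeric vector, `geomean` truncated (floored) to two
#'   decimals — the convention used for printed consensus scores.
#' @slot finalOrder Character vector of candidates, most stable first;
#'   equal geomeans are ordered lexicographically.
#' @slot tiedFinal List of character vectors flagging candidates whose
#'   geomeans coincide exactly.
#' @slot methods Character vector of contributing method identifiers.
#' @seealso [geometricMeanRank()].
#' @export
setClass("ConsensusRanking", representation(
  geomean = "numeric", display = "numeric", finalOrder = "character",
  tiedFinal = "list", methods = "character"))

setValidity("ConsensusRanking", function(object) {
  k <- length(object@geomean)
  if (any(object@geomean < 1 - 1e-9) || any(object@geomean > k + 1e-9))
    return("geometric-mean ranks must lie in [1, number of candidates]")
  TRUE
})

#' SimSpec: parameterization of the synthetic Ct generator
#'
#' Full specification of the additive simulation model
#' `Ct = baseline + loading + group shift + noise` (see [simulateCt()]),
#' with a seed and a documented ground-truth disorder score
#' `sqrt(sigma^2 + delta^2 / 4)` per candidate used to define the true
#' stability ordering.
#'
#' @slot candidates Character vector of candidate identifiers.
#' @slot nPerGroup Named integer vector of group sizes (>= 1 group).
#' @slot baseline Per-candidate baseline Ct (cycles), in (0, 45).
#' @slot tau SD of the shared per-sample loading effect (cycles, >= 0).
#' @slot sigma Per-candidate noise SD (cycles, >= 0).
#' @slot delta Per-candidate shift (cycles) applied to the second group.
#' @slot nReplicates Technical replicates simulated per well (>= 1).
#' @slot replicateSD SD of replicate-level noise (cycles, >= 0).
#' @slot seed Integer random seed.
#' @slot condition Condition label stamped on generated tables.
#' @seealso [SimSpec()], [simulateCt()], [recoveryExperiment()].
#' @export
setClass("SimSpec", representation(
  candidates = "character", nPerGroup = "integer", baseline = "numeric",
  tau = "numeric", sigma = "numeric", delta = "numeric",
  nReplicates = "integer", replicateSD = "numeric", seed = "integer",
  condition = "character"))

setValidity("SimSpec", function(object) {
  msgs <- character(0)
  k <- length(object@candidates)
  if (k < 2L || anyDuplicated(object@candidates))
    msgs <- c(msgs, "need >= 2 uniquely named candidates")
  if (length(object@nPerGroup) < 1L || any(object@nPerGroup < 1L))
    msgs <- c(msgs, "each group needs >= 1 sample")
  for (s in c("baseline", "sigma", "delta"))
    if (length(slot(object, s)) != k)
      msgs <- c(msgs, sprintf("'%s' must have one value per candidate", s))
  if (any(object@baseline <= 0) || any(object@baseline >= 45))
    msgs <- c(msgs, "baselines must lie in (0, 45)")
  if (any(object@sigma < 0) || object@tau < 0 || object@replicateSD < 0)
    msgs <- c(msgs, "noise SDs must be >= 0")
  if (object@nReplicates < 1L) msgs <- c(msgs, "need >= 1 replicate")
  if (length(msgs)) msgs else TRUE
})
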