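#' Competition ranks from stability values
#'
#' Converts one algorithm's stability values (lower = more stable) into
#' integer competition ranks: candidates are sorted ascending; values
#' within `tieTolerance` of each other form a tie sharing the minimum
#' rank, and the next distinct rank skips by the tie size (1-2-2-4
#' style).
#'
#' @param score A [StabilityScore-class], or a named numeric vector of
#'   stability values.
#' @param tieTolerance Absolute tolerance below which two adjacent sorted
#'   values are considered tied. Default 1e-12 (exact ties only).
#' @param method Method label when `score` is a bare vector.
#' @return A [RankVector-class].
#' @examples
#' rankValues(competitionRanks(c(a = 0.83, b = 0.83, c = 0.97, d = 1.05)))
#' @export
competitionRanks <- function(score, tieTolerance = 1e-12,
                             method = "unspecified") {
  if (methods::is(score, "StabilityScore")) {
    method <- score@method
    score <- stabilityValues(score)
  }
  if (is.null(names(score)))
    .stopContract("stability values must be named by candidate")
  ord <- order(score, names(score))  # lexicographic within equal values
  sorted <- score[ord]
  tier_id <- integer(length(sorted))
  tier <- 1L
  tier_id[1L] <- tier
  for (i in seq_along(sorted)[-1L]) {
    if (sorted[i] - sorted[i - 1L] > tieTolerance) tier <- tier + 1L
    tier_id[i] <- tier
  }
  tiers <- split(names(sorted), tier_id)
  ranksFromTiers(unname(tiers), method = method)
}

#' Competition ranks from an ordered tier list
#'
#' Assigns competition ranks tier by tier: every candidate in a tier
#' shares the tier's minimum rank, and the next tier starts after the
#' cumulative candidate count. This is the natural encoding of a printed
#' stability ordering in which ">" separates tiers and comma-joined
#' candidates with equal printed values tie.
#'
#' @param tiers List of character vectors, best tier first, jointly
#'   partitioning the candidate set.
#' @param method Method label for the result.
#' @return A [RankVector-class].
#' @examples
#' rv <- ranksFromTiers(list("U6", "let7c", c("miR25", "miR26a"),
#'                           "miR92a", "miR100", "miR204"))
#' rankValues(rv)
#' @export
ranksFromTiers <- function(tiers, method = "unspecified") {
  cand <- unlist(tiers, use.names = FALSE)
  if (anyDuplicated(cand))
    .stopContract("a candidate appears in more than one tier")
  ranks <- integer(0)
  pos <- 1L
  ties <- list()
  for (tier in tiers) {
    ranks <- c(ranks, stats::setNames(rep(pos, length(tier)), tier))
    if (length(tier) > 1L) ties <- c(ties, list(sort(tier)))
    pos <- pos + length(tier)
  }
  methods::new("RankVector", method = method,
               ranks = stats::setNames(as.integer(ranks), names(ranks)),
               ties = ties)
}

#' Accessors for RankVector
#'
#' `rankValues()` returns the named integer ranks; `tieSets()` the list
#' of tie sets of size >= 2.
#'
#' @param x A [RankVector-class].
#' @name RankVector-accessors
#' @aliases rankValues tieSets
NULL

#' @rdname RankVector-accessors
#' @export
setMethod("rankValues", "RankVector", function(x) x@ranks)

#' @rdname RankVector-accessors
#' @export
setMethod("tieSets", "RankVector", function(x) x@ties)

setMethod("show", "RankVector", function(object) {
  cat(sprintf("RankVector (%s): ", object@method))
  r <- sort(object@ranks)
  cat(paste(sprintf("%s=%d", names(r), r), collapse = ", "), "\n")
})

#' Geometric-mean consensus ranking
#'
#' Aggregates per-method competition ranks into a comprehensive,
#' RefFinder-style consensus: for every candidate the geometric mean of
#' its ranks across methods. The display value is the geometric mean
#' truncated (floored, not rounded) to two decimals — the convention
#' used for printed consensus scores. The final order is ascending in
#' the geometric mean; exact ties are ordered lexicographically and
#' flagged in `tiedFinal`.
#'
#' @param vectors List of [RankVector-class] objects over the identical
#'   candidate set.
#' @return A [ConsensusRanking-class].
#' @examples
#' rv1 <- ranksFromTiers(list("a", "b", "c"))
#' rv2 <- ranksFromTiers(list("b", "a", "c"))
#' consensusDisplay(geometricMeanRank(list(rv1, rv2)))
#' @export
geometricMeanRank <- function(vectors) {
  if (length(vectors) < 1L)
    .stopContract("need at least one rank vector")
  cand <- sort(names(rankValues(vectors[[1L]])))
  for (v in vectors)
    if (!identical(sort(names(rankValues(v))), cand))
      .stopContract("all rank vectors must cover the same candidate set")
  rankMat <- vapply(vectors, function(v) rankValues(v)[cand],
                    numeric(length(cand)))
  rankMat <- matrix(rankMat, nrow = length(cand),
                    dimnames = list(cand, NULL))
  geo <- exp(rowMeans(log(rankMat)))
  ordered <- names(geo)[order(geo, names(geo))]  # exact ties: lexicographic
  dup <- geo[duplicated(geo) | duplicated(geo, fromLast = TRUE)]
  tied <- if (length(dup)) unname(split(names(dup), dup[])) else list()
  methods::new("ConsensusRanking", geomean = geo, display = .trunc2(geo),
               finalOrder = ordered, tiedFinal = tied,
               methods = vapply(vectors, function(v) v@method, character(1)))
}

#' Accessors for ConsensusRanking
#'
#' `consensusGeomean()` returns the full-precision geometric-mean ranks;
#' `consensusDisplay()` the 2-decimal truncated display values;
#' `finalOrder()` the candidates, most stable first.
#'
#' @param x A [ConsensusRanking-class].
#' @name ConsensusRanking-accessors
#' @aliases consensusGeomean consensusDisplay finalOrder
NULL

#' @rdname ConsensusRanking-accessors
#' @export
setMethod("consensusGeomean", "ConsensusRanking", function(x) x@geomean)

#' @rdname ConsensusRanking-accessors
#' @export
setMethod("consensusDisplay", "ConsensusRanking", function(x) x@display)

#' @rdname ConsensusRanking-accessors
#' @export
setMethod("finalOrder", "ConsensusRanking", function(x) x@finalOrder)

setMethod("show", "ConsensusRanking", function(object) {
  cat(sprintf("ConsensusRanking over methods: %s\n",
              paste(object@methods, collapse = ", ")))
  d <- object@display[object@finalOrder]
  for (i in seq_along(d))
    cat(sprintf("  %d. %s (%.2f)\n", i, names(d)[i], d[i]))
  if (length(object@tiedFinal))
    cat("  note: exact geomean ties present\n")
})
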