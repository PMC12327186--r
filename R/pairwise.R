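#' Pairwise Ct-difference SD matrix
#'
#' For every unordered candidate pair (i, j), the sample standard
#' deviation (n-1 denominator) of the per-sample Ct difference
#' `Ct_i(s) - Ct_j(s)`, pooled across groups within the condition. This
#' kernel underlies both the comparative delta-Ct method and the geNorm M
#' value: at amplification efficiency E = 2 the SD of the log2 expression
#' ratio of two candidates equals the SD of their Ct difference.
#'
#' The matrix is symmetric with a zero diagonal and is invariant both to
#' adding a per-candidate constant and to adding a shared per-sample
#' constant (loading/input variation) to all candidates.
#'
#' @param table A [CtTable-class] with >= 2 samples.
#' @return Symmetric numeric matrix, candidates x candidates, in cycles.
#' @seealso [deltaCtStability()], [geNormM()].
#' @examples
#' ct <- rbind(A = c(20, 21, 22, 23), C = c(20, 22, 21, 24))
#' colnames(ct) <- paste0("s", 1:4)
#' pairwiseSD(CtTable(ct))
#' @export
pairwiseSD <- function(table) {
  ct <- ctValues(table)
  if (ncol(ct) < 2L)
    .stopContract("pairwise SD undefined with fewer than 2 samples")
  k <- nrow(ct)
  out <- matrix(0, k, k, dimnames = list(rownames(ct), rownames(ct)))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      s <- stats::sd(ct[i, ] - ct[j, ])
      out[i, j] <- s
      out[j, i] <- s
    }
  }
  out
}

#' Comparative delta-Ct stability
#'
#' The comparative delta-Ct method scores each candidate by the mean of
#' the Ct-difference SDs against every other candidate: a candidate whose
#' difference to all others varies little across samples is stable.
#' Lower values are more stable.
#'
#' @param x A [CtTable-class] or a precomputed [pairwiseSD()] matrix.
#' @param condition Condition label for the result; taken from the table
#'   when `x` is a [CtTable-class].
#' @return A [StabilityScore-class] with method `"delta_ct"`.
#' @examples
#' ct <- rbind(A = c(20, 21, 22, 23), B = c(25, 26, 27, 28),
#'             C = c(20, 22, 21, 24))
#' colnames(ct) <- paste0("s", 1:4)
#' stabilityValues(deltaCtStability(CtTable(ct)))
#' @export
deltaCtStability <- function(x, condition = NULL) {
  if (methods::is(x, "CtTable")) {
    if (is.null(condition)) condition <- conditionLabel(x)
    x <- pairwiseSD(x)
  }
  if (is.null(condition)) condition <- "unspecified"
  if (nrow(x) < 2L) .stopContract("need >= 2 candidates")
  vals <- rowSums(x) / (nrow(x) - 1L)  # mean over j != i; diagonal is 0
  methods::new("StabilityScore", method = "delta_ct", values = vals,
               condition = condition)
}

#' geNorm expression-stability M value
#'
#' For each candidate in `subset`, M is the mean of the pairwise
#' log-ratio SDs against all other subset members. With Ct input and
#' amplification efficiency fixed at E = 2, the log2 ratio of two
#' candidates is their Ct difference, so M reduces to the mean pairwise
#' Ct-difference SD — and on the full panel equals the comparative
#' delta-Ct stability exactly.
#'
#' @param table A [CtTable-class].
#' @param subset Character vector of candidate identifiers (>= 2);
#'   defaults to all candidates.
#' @return A [StabilityScore-class] with method `"genorm"`, values for the
#'   subset members only.
#' @seealso [geNormRank()] for the stepwise ranking.
#' @export
geNormM <- function(table, subset = candidateNames(table)) {
  if (length(subset) < 2L)
    .stopContract("geNorm M requires a subset of >= 2 candidates")
  missing <- setdiff(subset, candidateNames(table))
  if (length(missing))
    .stopContract(sprintf("unknown candidates: %s",
                          paste(missing, collapse = ", ")))
  sdm <- pairwiseSD(table)[subset, subset, drop = FALSE]
  vals <- rowSums(sdm) / (length(subset) - 1L)
  methods::new("StabilityScore", method = "genorm", values = vals,
               condition = conditionLabel(table))
}

#' Stepwise geNorm ranking
#'
#' Runs the full geNorm procedure: compute M on the current candidate
#' subset, exclude the candidate with the highest M (recording that M),
#' and repeat until two candidates remain. The final pair cannot be
#' distinguished by the method and shares the final-step M and rank 1.
#' Ties in M (within 1e-12) are broken lexicographically by candidate
#' identifier for determinism.
#'
#' @param table A [CtTable-class] with >= 3 candidates.
#' @return A [GeNormTrace-class].
#' @examples
#' ct <- rbind(A = c(20, 21, 22, 23), B = c(25, 26, 27, 28),
#'             C = c(20, 22, 21, 24))
#' colnames(ct) <- paste0("s", 1:4)
#' tr <- geNormRank(CtTable(ct))
#' tr@finalPair
#' @export
geNormRank <- function(table) {
  cand <- candidateNames(table)
  if (length(cand) < 3L)
    .stopContract("stepwise geNorm requires >= 3 candidates")
  sdm <- pairwiseSD(table)
  current <- sort(cand)  # lexicographic base order makes tie-breaks stable
  exclusion <- character(0)
  mRecord <- stats::setNames(numeric(length(cand)), cand)
  steps <- list()
  while (length(current) > 2L) {
    sub <- sdm[current, current, drop = FALSE]
    m <- rowSums(sub) / (length(current) - 1L)
    worst <- current[which(m >= max(m) - 1e-12)][1L]  # lexicographic tie-break
    steps[[length(steps) + 1L]] <- list(subset = current, m = m)
    mRecord[worst] <- m[[worst]]
    exclusion <- c(exclusion, worst)
    current <- setdiff(current, worst)
  }
  sub <- sdm[current, current, drop = FALSE]
  mFinal <- rowSums(sub)  # mean over the single other member
  steps[[length(steps) + 1L]] <- list(subset = current, m = mFinal)
  mRecord[current] <- mFinal[current]
  methods::new("GeNormTrace", exclusionOrder = exclusion,
               mAtExclusion = mRecord[cand], finalPair = current,
               steps = steps, condition = conditionLabel(table))
}

#' Stability values and ranking from a geNorm trace
#'
#' `geNormStability()` converts a [GeNormTrace-class] to a
#' [StabilityScore-class] whose per-candidate value is the M recorded at
#' that candidate's exclusion step (the final pair carries the final M).
#' `geNormRankVector()` returns the corresponding competition ranks:
#' reverse exclusion order with the final pair tied at rank 1 (so the
#' next candidate ranks 3).
#'
#' @param trace A [GeNormTrace-class].
#' @return A [StabilityScore-class] or [RankVector-class].
#' @export
geNormStability <- function(trace) {
  methods::new("StabilityScore", method = "genorm",
               values = trace@mAtExclusion, condition = trace@condition)
}

#' @rdname geNormStability
#' @export
geNormRankVector <- function(trace) {
  tiers <- c(list(sort(trace@finalPair)),
             lapply(rev(trace@exclusionOrder), identity))
  ranksFromTiers(tiers, method = "genorm")
}

#' geNorm pairwise variation V(n/n+1)
#'
#' The geNorm companion statistic used to decide how many reference genes
#' to include in a normalization factor: the SD over samples of
#' `log2(NF_n / NF_{n+1})`, where `NF_k` is the geometric mean of the
#' relative quantities (`Q = 2^(minCt - Ct)` per candidate, E = 2) of the
#' top-k candidates of the stepwise ranking.
#'
#' @param trace A [GeNormTrace-class] from [geNormRank()].
#' @param table The [CtTable-class] the trace was computed from.
#' @param n Number of top candidates in the smaller factor;
#'   `2 <= n <` number of candidates.
#' @return A single non-negative numeric value.
#' @export
geNormV <- function(trace, table, n) {
  ranking <- c(sort(trace@finalPair), rev(trace@exclusionOrder))
  k <- length(ranking)
  if (n < 2L || n >= k)
    .stopContract(sprintf("n must satisfy 2 <= n < %d", k))
  ct <- ctValues(table)[ranking, , drop = FALSE]
  q <- 2^(apply(ct, 1L, min) - ct)  # relative quantities, E = 2
  nf <- function(kk) exp(colMeans(log(q[seq_len(kk), , drop = FALSE])))
  stats::sd(log2(nf(n) / nf(n + 1L)))
}
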