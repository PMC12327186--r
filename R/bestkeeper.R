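#' BestKeeper descriptive stability statistics
#'
#' Per candidate: n, min/max Ct, arithmetic and geometric mean Ct, the
#' BestKeeper dispersion statistic "SD (+/- Cp)" — implemented as the mean
#' absolute deviation (MAD) of the raw Ct values from their arithmetic
#' mean — and the coefficient of variation `CV = 100 * MAD / mean`.
#' Candidates with MAD <= 1 cycle are flagged as consistent; ranking is
#' ascending by MAD.
#'
#' @param table A [CtTable-class] with n >= 2 samples and all Ct > 0.
#' @return Data frame with columns `candidate`, `n`, `min`, `max`,
#'   `mean`, `geo_mean`, `mad`, `cv`, `consistent`, `rank` (competition
#'   ranks on MAD ascending).
#' @seealso [bestKeeperIndex()], [bestKeeperCorrelations()],
#'   [bestKeeperStability()].
#' @examples
#' ct <- rbind(A = c(20, 21, 23, 24), B = c(25, 25, 25, 25))
#' colnames(ct) <- paste0("s", 1:4)
#' bestKeeperStats(CtTable(ct))
#' @export
bestKeeperStats <- function(table) {
  ct <- ctValues(table)
  if (ncol(ct) < 2L) .stopContract("need >= 2 samples")
  if (any(ct <= 0))
    .stopValidation("geometric mean undefined for non-positive Ct")
  m <- rowMeans(ct)
  mad <- rowMeans(abs(ct - m))
  out <- data.frame(
    candidate = rownames(ct), n = ncol(ct),
    min = apply(ct, 1L, min), max = apply(ct, 1L, max),
    mean = unname(m),
    geo_mean = apply(ct, 1L, geometricMean),
    mad = unname(mad), cv = unname(100 * mad / m),
    consistent = unname(mad <= 1), row.names = NULL)
  score <- methods::new("StabilityScore", method = "bestkeeper",
                        values = stats::setNames(out$mad, out$candidate),
                        condition = conditionLabel(table))
  out$rank <- rankValues(competitionRanks(score))[out$candidate]
  out
}

#' BestKeeper index
#'
#' The per-sample BestKeeper index: the geometric mean of the Ct values
#' of the chosen candidates within each sample. It acts as a virtual
#' composite reference against which individual candidates are
#' correlated.
#'
#' @param table A [CtTable-class] with all Ct > 0.
#' @param subset Candidate identifiers to combine; defaults to all (no
#'   pre-exclusion of high-MAD candidates).
#' @return Named numeric vector, one index value (cycles) per sample.
#' @export
bestKeeperIndex <- function(table, subset = candidateNames(table)) {
  if (length(subset) < 1L) .stopContract("subset must be non-empty")
  missing <- setdiff(subset, candidateNames(table))
  if (length(missing))
    .stopContract(sprintf("unknown candidates: %s",
                          paste(missing, collapse = ", ")))
  ct <- ctValues(table)[subset, , drop = FALSE]
  if (any(ct <= 0))
    .stopValidation("geometric mean undefined for non-positive Ct")
  apply(ct, 2L, geometricMean)
}

#' Candidate-vs-index Pearson correlations
#'
#' Pearson correlation of each candidate's Ct profile with the
#' BestKeeper index, with the two-tailed p-value. Candidates (or an
#' index) with zero variance have no defined correlation and are
#' reported as `NA` with `undefined = TRUE` rather than dropped.
#'
#' @param table A [CtTable-class] with n >= 3 samples.
#' @param index Per-sample index from [bestKeeperIndex()]; computed from
#'   all candidates when omitted.
#' @return Data frame with columns `candidate`, `r`, `p`, `undefined`.
#' @export
bestKeeperCorrelations <- function(table, index = NULL) {
  ct <- ctValues(table)
  if (ncol(ct) < 3L)
    .stopContract("correlation requires >= 3 samples")
  if (is.null(index)) index <- bestKeeperIndex(table)
  if (length(index) != ncol(ct))
    .stopContract("index must have one value per sample")
  res <- lapply(rownames(ct), function(cand) {
    x <- ct[cand, ]
    if (stats::sd(x) == 0 || stats::sd(index) == 0)
      return(data.frame(candidate = cand, r = NA_real_, p = NA_real_,
                        undefined = TRUE))
    test <- stats::cor.test(x, index, method = "pearson")
    data.frame(candidate = cand, r = unname(test$estimate),
               p = test$p.value, undefined = FALSE)
  })
  do.call(rbind, res)
}

#' BestKeeper stability score
#'
#' The single stability value per candidate used for ranking and
#' consensus building: the mean absolute deviation of the raw Ct values
#' (lower = more stable). Correlation and CV are descriptive companions,
#' not rank-determining.
#'
#' @param table A [CtTable-class].
#' @return A [StabilityScore-class] with method `"bestkeeper"`.
#' @export
bestKeeperStability <- function(table) {
  stats_df <- bestKeeperStats(table)
  methods::new("StabilityScore", method = "bestkeeper",
               values = stats::setNames(stats_df$mad, stats_df$candidate),
               condition = conditionLabel(table))
}
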