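# Model-based stability in the NormFinder tradition.
#
# The model: Ct_igj = mu_i + a_gj + d_ig + e_igj, with a shared per-sample
# loading a_gj, a candidate-by-group interaction d_ig (the systematic
# intergroup deviation) and candidate noise e_igj ~ (0, sigma2_ig). The
# loading is removed by centering each sample across candidates; because
# that centering mixes the candidates' noises, the naive variance of the
# centered residuals is biased and a method-of-moments correction is
# applied (hence k >= 3). The deviation estimates are shrunk towards zero
# by a variance-ratio factor so candidates measured noisily do not get
# spuriously large deviations.

# Shared centering: grand-mean center per candidate, then subtract the
# across-candidate mean within each sample.
.nfCenter <- function(ct) {
  yc <- ct - rowMeans(ct)
  sweep(yc, 2L, colMeans(yc))
}

# Method-of-moments correction of centered variances for one group (or
# the pooled set): Var(x_i) = ((k-1)^2/k^2) s2_i + (1/k^2) sum_{i'!=i} s2_i'
# inverts to sigma2_i = (k/(k-2)) (s2_i - S/(k(k-1))), clipped at 0.
.nfCorrect <- function(s2) {
  k <- length(s2)
  out <- pmax(0, (k / (k - 2)) * (s2 - sum(s2) / (k * (k - 1))))
  names(out) <- names(s2)
  out
}

#' NormFinder-style variance decomposition
#'
#' Decomposes a grouped Ct table into per-candidate, per-group intragroup
#' variances and intergroup deviations under an additive model with a
#' shared per-sample loading effect (see the package vignette for the
#' estimators). Requires at least 3 candidates (the variance correction
#' is undefined below that) and at least 2 groups of 2; for ungrouped
#' data use [normFinderSingleGroup()].
#'
#' @param table A [CtTable-class] with k >= 3 candidates and >= 2 groups,
#'   each with >= 2 samples.
#' @return A [NormFinderDecomposition-class].
#' @seealso [normFinderStability()] for the stability value.
#' @export
normFinderDecompose <- function(table) {
  ct <- ctValues(table)
  k <- nrow(ct)
  if (k < 3L)
    .stopContract("the variance correction requires >= 3 candidates")
  g <- sampleGroups(table)
  if (length(unique(g)) < 2L)
    .stopContract(paste("single group: use normFinderSingleGroup()",
                        "for group-free stability"))
  idx <- .requireGroups(table)
  x <- .nfCenter(ct)
  groups <- names(idx)
  G <- length(groups)
  dHat <- s2 <- matrix(0, k, G, dimnames = list(rownames(ct), groups))
  for (gi in seq_len(G)) {
    xg <- x[, idx[[gi]], drop = FALSE]
    dHat[, gi] <- rowMeans(xg)
    s2[, gi] <- apply(xg, 1L, stats::var)
  }
  sigma2 <- apply(s2, 2L, .nfCorrect)
  dimnames(sigma2) <- dimnames(s2)
  nG <- vapply(idx, length, 1L)
  sampVar <- sweep(sigma2, 2L, nG, "/")   # sigma2_ig / n_g
  gamma2 <- max(0, stats::var(as.vector(dHat)) - mean(sampVar))
  shrink <- if (gamma2 == 0) matrix(0, k, G) else gamma2 / (gamma2 + sampVar)
  dTilde <- dHat * shrink
  dimnames(dTilde) <- dimnames(dHat)
  methods::new("NormFinderDecomposition", s2 = s2, sigma2 = sigma2,
               dHat = dHat, dTilde = dTilde, gamma2 = gamma2,
               nPerGroup = stats::setNames(as.integer(nG), groups),
               condition = conditionLabel(table))
}

#' NormFinder-style stability value
#'
#' Combines, per group, the magnitude of the shrunken intergroup
#' deviation and the intragroup sampling error of the group mean, then
#' averages over groups:
#' `rho_i = (1/G) * sum_g ( |dTilde_ig| + sqrt(sigma2_ig / n_g) )`.
#' Lower is more stable; a candidate is penalised both for differing
#' systematically between groups and for being noisy.
#'
#' @param decomp A [NormFinderDecomposition-class].
#' @return A [StabilityScore-class] with method `"normfinder"`.
#' @export
normFinderStability <- function(decomp) {
  sampSD <- sqrt(sweep(decomp@sigma2, 2L, decomp@nPerGroup, "/"))
  rho <- rowMeans(abs(decomp@dTilde) + sampSD)
  methods::new("StabilityScore", method = "normfinder", values = rho,
               condition = decomp@condition)
}

#' Group-free NormFinder-style stability
#'
#' Fallback for ungrouped designs: the corrected intragroup variance is
#' estimated on the pooled sample set (no deviation terms) and
#' `rho_i = sqrt(sigma2_i)`.
#'
#' @param table A [CtTable-class] with k >= 3 candidates.
#' @return A [StabilityScore-class] with method `"normfinder"`.
#' @export
normFinderSingleGroup <- function(table) {
  ct <- ctValues(table)
  if (nrow(ct) < 3L)
    .stopContract("the variance correction requires >= 3 candidates")
  if (ncol(ct) < 2L) .stopContract("need >= 2 samples")
  x <- .nfCenter(ct)
  s2 <- apply(x, 1L, stats::var)
  rho <- sqrt(.nfCorrect(s2))
  methods::new("StabilityScore", method = "normfinder", values = rho,
               condition = conditionLabel(table))
}
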