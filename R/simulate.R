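#' Construct a SimSpec
#'
#' Parameterizes the synthetic Ct generator. The defaults emulate a
#' typical reference-miRNA screening design in semen: 7 candidates, two
#' groups of 5 bulls, technical triplicates, baselines spread over the
#' working Ct range, a shared per-sample loading effect (RNA input /
#' efficiency variation) and heterogeneous per-candidate noise.
#'
#' The documented ground-truth disorder surrogate per candidate is
#' `sqrt(sigma^2 + delta^2 / 4)` — a ranking convention combining noise
#' and the group shift (a shift of delta applied to half the samples
#' contributes delta/2 of deviation on either side), not a claim about
#' any particular algorithm's estimand.
#'
#' @param k Number of candidates (used only when `candidates` is NULL).
#' @param candidates Candidate identifiers; default `"cand1"..."candk"`.
#' @param nPerGroup Named integer vector of group sizes; default two
#'   groups of 5 (`g1`, `g2`).
#' @param baseline Per-candidate baseline Ct (cycles); default evenly
#'   spread over \[18, 30\].
#' @param tau SD of the shared per-sample loading effect (cycles);
#'   default 0.8.
#' @param sigma Per-candidate biological/technical noise SD (cycles);
#'   default evenly spread over \[0.1, 1.5\].
#' @param delta Per-candidate shift (cycles) added in the second group;
#'   default 0 (all candidates group-stable).
#' @param nReplicates Technical replicates per well; default 3.
#' @param replicateSD SD of replicate-level noise (cycles); default 0.2.
#' @param seed Integer seed; the generator is fully reproducible.
#' @param condition Condition label stamped on generated tables.
#' @return A [SimSpec-class].
#' @seealso [simulateCt()], [recoveryExperiment()], [trueDisorder()].
#' @export
SimSpec <- function(k = 7L, candidates = NULL,
                    nPerGroup = c(g1 = 5L, g2 = 5L),
                    baseline = NULL, tau = 0.8, sigma = NULL,
                    delta = NULL, nReplicates = 3L, replicateSD = 0.2,
                    seed = 1L, condition = "synthetic") {
  if (is.null(candidates)) candidates <- paste0("cand", seq_len(k))
  k <- length(candidates)
  if (is.null(baseline)) baseline <- seq(18, 30, length.out = k)
  if (is.null(sigma)) sigma <- seq(0.1, 1.5, length.out = k)
  if (is.null(delta)) delta <- rep(0, k)
  if (is.null(names(nPerGroup)))
    names(nPerGroup) <- paste0("g", seq_along(nPerGroup))
  obj <- methods::new("SimSpec", candidates = candidates,
                      nPerGroup = as.integer(nPerGroup),
                      baseline = as.numeric(baseline), tau = as.numeric(tau),
                      sigma = as.numeric(sigma), delta = as.numeric(delta),
                      nReplicates = as.integer(nReplicates),
                      replicateSD = as.numeric(replicateSD),
                      seed = as.integer(seed), condition = condition)
  names(obj@nPerGroup) <- names(nPerGroup)
  methods::validObject(obj)
  obj
}

#' @rdname SimSpec-accessors
#' @name SimSpec-accessors
#' @aliases trueDisorder
#' @param x A [SimSpec-class].
#' @return `trueDisorder()`: named numeric vector of the ground-truth
#'   disorder surrogate `sqrt(sigma^2 + delta^2 / 4)` per candidate
#'   (lower = truly more stable).
#' @export
setMethod("trueDisorder", "SimSpec", function(x)
  stats::setNames(sqrt(x@sigma^2 + x@delta^2 / 4), x@candidates))

setMethod("show", "SimSpec", function(object) {
  cat(sprintf(
    "SimSpec: %d candidates, groups (%s), tau=%.2f, %d replicate(s), seed %d\n",
    length(object@candidates),
    paste(sprintf("%s=%d", names(object@nPerGroup), object@nPerGroup),
          collapse = ", "),
    object@tau, object@nReplicates, object@seed))
})

# Run fn() under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
.withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Simulate a Ct table with known ground truth
#'
#' Draws Ct values from the additive model
#' `Ct_igj = B_i + L_gj + delta_i * [g = 2] + e_igj`, where `L_gj ~
#' N(0, tau^2)` is a loading effect shared by all candidates within a
#' sample and `e_igj ~ N(0, sigma_i^2)` is candidate-specific noise.
#' With `nReplicates > 1`, independent `N(0, replicateSD^2)` replicate
#' noise is added per technical replicate and replicates are collapsed
#' by [collapseReplicates()]. Values are clamped to (0.1, 45) cycles to
#' respect the Ct validity range; at the default parameters clamping
#' never triggers. The same seed always yields the identical table.
#'
#' @param spec A [SimSpec-class].
#' @return A [CtTable-class]; `metadata(x)$truth` holds a data frame
#'   with the per-candidate `baseline`, `sigma`, `delta` and `disorder`
#'   (see [trueDisorder()]), and `metadata(x)$replicateQC` the replicate
#'   QC report when replicates were simulated.
#' @examples
#' tab <- simulateCt(SimSpec(seed = 42L))
#' dim(ctValues(tab))
#' @export
simulateCt <- function(spec) {
  stopifnot(methods::is(spec, "SimSpec"))
  k <- length(spec@candidates)
  nG <- spec@nPerGroup
  n <- sum(nG)
  groupLab <- rep(names(nG), nG)
  sampleIds <- paste0("s", sprintf("%02d", seq_len(n)))
  .withSeed(spec@seed, function() {
    loading <- stats::rnorm(n, 0, spec@tau)
    shift <- outer(spec@delta,
                   as.integer(groupLab == names(nG)[min(2L, length(nG))]) *
                     as.integer(length(nG) >= 2L))
    meanCt <- spec@baseline + matrix(loading, k, n, byrow = TRUE) + shift
    noise <- matrix(stats::rnorm(k * n, 0, spec@sigma), k, n)
    well <- meanCt + noise
    dimnames(well) <- list(spec@candidates, sampleIds)
    if (spec@nReplicates > 1L) {
      reps <- do.call(rbind, lapply(seq_len(spec@nReplicates), function(r) {
        repNoise <- matrix(stats::rnorm(k * n, 0, spec@replicateSD), k, n)
        data.frame(sample = rep(sampleIds, each = k),
                   candidate = rep(spec@candidates, n),
                   replicate = r,
                   ct = as.vector(pmin(pmax(well + repNoise, 0.1), 45)))
      }))
      collapsed <- collapseReplicates(reps)
      ctm <- collapsed$ct[spec@candidates, sampleIds]
      qc <- collapsed$qc
    } else {
      ctm <- pmin(pmax(well, 0.1), 45)
      qc <- NULL
    }
    tab <- CtTable(ctm, group = stats::setNames(groupLab, sampleIds),
                   condition = spec@condition)
    S4Vectors::metadata(tab)$truth <- data.frame(
      candidate = spec@candidates, baseline = spec@baseline,
      sigma = spec@sigma, delta = spec@delta,
      disorder = unname(trueDisorder(spec)))
    if (!is.null(qc)) S4Vectors::metadata(tab)$replicateQC <- qc
    tab
  })
}

#' Rank-recovery experiment on synthetic data
#'
#' Repeatedly simulates Ct tables from `spec` (with per-replicate seeds
#' derived from `seed`), runs the selected stability algorithms and the
#' geometric-mean consensus, and reports how often each method ranks the
#' ground-truth most-stable candidate (smallest [trueDisorder()]) first.
#' The spec must designate that candidate uniquely.
#'
#' @param spec A [SimSpec-class] with a strictly smallest disorder score.
#' @param methods Character subset of
#'   `c("delta_ct", "genorm", "normfinder", "bestkeeper")`.
#' @param nRep Number of simulation replicates.
#' @param seed Master seed for the experiment (replicate seeds are drawn
#'   from it; independent of `spec@seed`).
#' @return List with `truth` (the designated candidate), `topRate`
#'   (named fraction of replicates ranking it first, per method and
#'   `"consensus"`), and `rankDistribution` (list of candidate x rank
#'   count matrices per method).
#' @export
recoveryExperiment <- function(spec,
                               methods = c("delta_ct", "genorm",
                                           "normfinder", "bestkeeper"),
                               nRep = 100L, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  dis <- sort(trueDisorder(spec))
  if (length(dis) < 2L || dis[2L] - dis[1L] < 1e-12)
    .stopContract("spec must designate a unique most-stable candidate")
  truth <- names(dis)[1L]
  cand <- spec@candidates
  k <- length(cand)
  useGroups <- length(spec@nPerGroup) >= 2L &&
    all(spec@nPerGroup >= 2L)
  labels <- c(methods, "consensus")
  top <- stats::setNames(numeric(length(labels)), labels)
  rankDist <- lapply(stats::setNames(labels, labels), function(m)
    matrix(0L, k, k, dimnames = list(cand, paste0("rank", seq_len(k)))))
  repSeeds <- .withSeed(seed, function()
    sample.int(.Machine$integer.max - 1L, nRep))
  for (r in seq_len(nRep)) {
    rspec <- spec
    rspec@seed <- repSeeds[r]
    tab <- simulateCt(rspec)
    vectors <- list()
    for (m in methods) {
      rv <- switch(m,
        delta_ct   = competitionRanks(deltaCtStability(tab)),
        genorm     = geNormRankVector(geNormRank(tab)),
        normfinder = competitionRanks(if (useGroups)
          normFinderStability(normFinderDecompose(tab))
          else normFinderSingleGroup(tab)),
        bestkeeper = competitionRanks(bestKeeperStability(tab)))
      vectors[[m]] <- rv
      rk <- rankValues(rv)
      top[m] <- top[m] + as.integer(rk[truth] == 1L)
      for (cc in cand)
        rankDist[[m]][cc, rk[cc]] <- rankDist[[m]][cc, rk[cc]] + 1L
    }
    cons <- geometricMeanRank(vectors)
    consRank <- match(cand, finalOrder(cons))
    names(consRank) <- cand
    top["consensus"] <- top["consensus"] +
      as.integer(finalOrder(cons)[1L] == truth)
    for (cc in cand)
      rankDist[["consensus"]][cc, consRank[cc]] <-
        rankDist[["consensus"]][cc, consRank[cc]] + 1L
  }
  list(truth = truth, nRep = nRep, topRate = top / nRep,
       rankDistribution = rankDist)
}
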