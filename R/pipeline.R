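#' Run the full stability workflow on a Ct table
#'
#' Orchestrates the four stability algorithms and the geometric-mean
#' consensus on one Ct table: comparative delta-Ct, stepwise geNorm,
#' the NormFinder-style decomposition (group-based when the table has
#' >= 2 groups of >= 2 samples, group-free otherwise) and BestKeeper.
#'
#' @param table A [CtTable-class].
#' @param methods Character subset of
#'   `c("delta_ct", "genorm", "normfinder", "bestkeeper")`; default all.
#' @param tieTolerance Tie tolerance for [competitionRanks()].
#' @return A list of class `"stabilityResults"` with elements `scores`
#'   (named list of [StabilityScore-class]), `ranks` (named list of
#'   [RankVector-class]), `consensus` ([ConsensusRanking-class]),
#'   `genormTrace` ([GeNormTrace-class] or NULL), `bestkeeper` (the
#'   descriptive data frame with index correlations, or NULL) and
#'   `condition`.
#' @examples
#' res <- stabilityAnalysis(simulateCt(SimSpec(seed = 7L)))
#' finalOrder(res$consensus)
#' @export
stabilityAnalysis <- function(table,
                              methods = c("delta_ct", "genorm",
                                          "normfinder", "bestkeeper"),
                              tieTolerance = 1e-12) {
  methods <- match.arg(methods, several.ok = TRUE)
  g <- sampleGroups(table)
  grouped <- length(unique(g)) >= 2L &&
    all(table(g) >= 2L)
  scores <- list(); ranks <- list()
  genormTrace <- NULL; bk <- NULL
  for (m in methods) {
    if (m == "delta_ct") {
      scores[[m]] <- deltaCtStability(table)
      ranks[[m]] <- competitionRanks(scores[[m]], tieTolerance)
    } else if (m == "genorm") {
      genormTrace <- geNormRank(table)
      scores[[m]] <- geNormStability(genormTrace)
      ranks[[m]] <- geNormRankVector(genormTrace)
    } else if (m == "normfinder") {
      scores[[m]] <- if (grouped)
        normFinderStability(normFinderDecompose(table))
      else normFinderSingleGroup(table)
      ranks[[m]] <- competitionRanks(scores[[m]], tieTolerance)
    } else {
      bk <- bestKeeperStats(table)
      idx <- bestKeeperIndex(table)
      if (ncol(table) >= 3L)
        bk <- merge(bk, bestKeeperCorrelations(table, idx),
                    by = "candidate", sort = FALSE)
      scores[[m]] <- bestKeeperStability(table)
      ranks[[m]] <- competitionRanks(scores[[m]], tieTolerance)
    }
  }
  structure(list(scores = scores, ranks = ranks,
                 consensus = geometricMeanRank(unname(ranks)),
                 genormTrace = genormTrace, bestkeeper = bk,
                 condition = conditionLabel(table)),
            class = "stabilityResults")
}

#' @export
print.stabilityResults <- function(x, ...) {
  cat(sprintf("Stability analysis (condition '%s'), methods: %s\n",
              x$condition, paste(names(x$scores), collapse = ", ")))
  show(x$consensus)
  invisible(x)
}

#' Write a stability result bundle to disk
#'
#' Writes the per-method CSVs (`<method>.csv` with columns
#' `candidate,stability,rank,method,condition`), the BestKeeper
#' descriptive table and per-sample index when present, the consensus
#' CSV (`candidate,geomean,display,rank`), a geNorm trace JSON and a
#' machine-readable `summary.json` recording the package version and
#' the resolved options. Numeric CSV columns are written at 6 decimals;
#' the 2-decimal truncation appears only in the consensus `display`
#' column.
#'
#' @param results A `"stabilityResults"` list from [stabilityAnalysis()].
#' @param dir Output directory (created if needed).
#' @param table Optional originating [CtTable-class]; when given, the
#'   BestKeeper per-sample index is also written.
#' @return Invisibly, the paths written.
#' @export
writeStabilityResults <- function(results, dir, table = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  round6 <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, 6L)
    df
  }
  for (m in names(results$scores)) {
    p <- file.path(dir, paste0(m, ".csv"))
    utils::write.csv(round6(stabilityTable(results$scores[[m]])), p,
                     row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(results$bestkeeper)) {
    p <- file.path(dir, "bestkeeper_descriptives.csv")
    utils::write.csv(round6(results$bestkeeper), p, row.names = FALSE,
                     quote = FALSE)
    paths <- c(paths, p)
    if (!is.null(table)) {
      idx <- bestKeeperIndex(table)
      p <- file.path(dir, "bestkeeper_index.csv")
      utils::write.csv(data.frame(sample = names(idx),
                                  index = round(unname(idx), 6L)),
                       p, row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
  }
  cons <- results$consensus
  consDf <- data.frame(candidate = finalOrder(cons),
                       geomean = round(consensusGeomean(cons)[finalOrder(cons)], 6L),
                       display = consensusDisplay(cons)[finalOrder(cons)],
                       rank = seq_along(finalOrder(cons)))
  p <- file.path(dir, "consensus.csv")
  utils::write.csv(consDf, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  if (!is.null(results$genormTrace)) {
    tr <- results$genormTrace
    p <- file.path(dir, "genorm_trace.json")
    jsonlite::write_json(list(
      exclusion_order = tr@exclusionOrder,
      m_at_exclusion = as.list(round(tr@mAtExclusion, 6L)),
      final_pair = tr@finalPair), p, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    package = "CtStability",
    version = as.character(utils::packageVersion("CtStability")),
    condition = results$condition,
    methods = names(results$scores),
    final_order = finalOrder(cons),
    display = as.list(consensusDisplay(cons)[finalOrder(cons)])),
    p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' The bundled bovine semen per-method stability tiers
#'
#' Loads the packaged fixture encoding, for each semen-quality condition
#' (`motility`, `morphology`), the stability orderings reported for the
#' seven-candidate bovine semen panel by the four algorithms, as ordered
#' tier lists: each tier is a set of candidates, best tier first;
#' candidates within a tier reported with identical stability values and
#' therefore tied.
#'
#' @param path Optional alternative tiers JSON.
#' @return Nested list: condition -> method -> list of character tiers.
#' @seealso [bovineSemenConsensus()].
#' @export
bovineSemenTiers <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "bovine_semen_tiers.json",
                        package = "CtStability", mustWork = TRUE)
  raw <- jsonlite::read_json(path)
  lapply(raw, function(cond)
    lapply(cond, function(m) lapply(m, function(t) unlist(t))))
}

#' Consensus ranking for the bovine semen study fixture
#'
#' Rebuilds the four per-method competition rank vectors from the
#' bundled tier fixture for one condition and aggregates them with
#' [geometricMeanRank()]. For the motility condition the display values
#' reproduce the reported consensus scores for all seven candidates;
#' for morphology they reproduce six of seven — the reported U6 value
#' cannot be obtained from any integer ranks consistent with the
#' per-method orderings and is a documented discrepancy of the fixture
#' source (see the vignette).
#'
#' @param condition `"motility"` or `"morphology"`.
#' @param tiers Optional tier list as from [bovineSemenTiers()].
#' @return A [ConsensusRanking-class].
#' @examples
#' consensusDisplay(bovineSemenConsensus("motility"))
#' @export
bovineSemenConsensus <- function(condition = c("motility", "morphology"),
                                 tiers = bovineSemenTiers()) {
  condition <- match.arg(condition)
  methodTiers <- tiers[[condition]]
  vectors <- lapply(names(methodTiers), function(m)
    ranksFromTiers(methodTiers[[m]], method = m))
  geometricMeanRank(vectors)
}
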