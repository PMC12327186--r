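#' Read a Ct table and sample metadata from delimited files
#'
#' Reads a candidates x samples Ct matrix plus a sample metadata file and
#' returns a validated [CtTable-class]. Two dialects are supported:
#' \describe{
#'   \item{`"wide"`}{first column `candidate`, remaining columns one per
#'     sample, cells holding Ct values in cycles.}
#'   \item{`"long"`}{columns `sample,candidate,replicate,ct`; technical
#'     replicates are collapsed with [collapseReplicates()].}
#' }
#' The metadata file must have columns `sample,group,condition` and cover
#' every sample present in the Ct file. Candidate and sample order is
#' preserved from the input.
#'
#' @param path Path to the Ct file (CSV by default).
#' @param metadataPath Path to the sample metadata CSV.
#' @param dialect `"wide"` or `"long"`.
#' @param sep Field separator, `","` by default (use `"\t"` for TSV).
#' @param spreadThreshold Replicate-spread QC threshold in cycles, passed
#'   to [collapseReplicates()] for the long dialect.
#' @return A [CtTable-class]; for the long dialect, replicate QC flags are
#'   available in `metadata(x)$replicateQC`.
#' @examples
#' ctf <- tempfile(fileext = ".csv"); mdf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(candidate = c("A", "B"), s1 = c(20, 25),
#'                      s2 = c(21, 26)), ctf, row.names = FALSE)
#' write.csv(data.frame(sample = c("s1", "s2"), group = c("g1", "g2"),
#'                      condition = "demo"), mdf, row.names = FALSE)
#' readCtTable(ctf, mdf)
#' @export
readCtTable <- function(path, metadataPath, dialect = c("wide", "long"),
                        sep = ",", spreadThreshold = 0.5) {
  dialect <- match.arg(dialect)
  for (p in c(path, metadataPath))
    if (!file.exists(p)) .stopWith("ctsIOError", sprintf("file not found: %s", p))
  md <- utils::read.table(metadataPath, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("sample", "group", "condition")
  if (!all(need %in% colnames(md)))
    .stopValidation(sprintf("metadata must have columns %s",
                            paste(need, collapse = ",")))
  if (anyDuplicated(md$sample))
    .stopValidation("duplicate sample identifiers in metadata")

  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "wide") {
    if (colnames(raw)[1L] != "candidate")
      .stopParse("wide dialect requires first column 'candidate'")
    cand <- as.character(raw[[1L]])
    samples <- colnames(raw)[-1L]
    ct <- as.matrix(raw[, -1L, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(ct), nrow(ct), ncol(ct)))
    badcell <- is.na(num) & !is.na(ct)
    if (any(badcell)) {
      idx <- which(badcell, arr.ind = TRUE)[1L, ]
      .stopParse(sprintf(
        "non-numeric Ct value '%s' at candidate '%s', sample '%s'",
        ct[idx[1L], idx[2L]], cand[idx[1L]], samples[idx[2L]]))
    }
    if (anyNA(num)) .stopValidation("missing Ct values are not allowed")
    dimnames(num) <- list(cand, samples)
  } else {
    need_l <- c("sample", "candidate", "replicate", "ct")
    if (!all(need_l %in% colnames(raw)))
      .stopParse(sprintf("long dialect requires columns %s",
                         paste(need_l, collapse = ",")))
    ctv <- suppressWarnings(as.numeric(raw$ct))
    if (anyNA(ctv)) {
      i <- which(is.na(ctv))[1L]
      .stopParse(sprintf(
        "non-numeric Ct value '%s' at candidate '%s', sample '%s', replicate %s",
        raw$ct[i], raw$candidate[i], raw$sample[i], raw$replicate[i]))
    }
    raw$ct <- ctv
    collapsed <- collapseReplicates(raw, spreadThreshold = spreadThreshold)
    num <- collapsed$ct
  }

  if (anyDuplicated(rownames(num)))
    .stopValidation("duplicate candidate identifiers")
  missing <- setdiff(colnames(num), md$sample)
  if (length(missing))
    .stopValidation(sprintf("samples missing from metadata: %s",
                            paste(missing, collapse = ", ")))
  md <- md[match(colnames(num), md$sample), ]
  tab <- CtTable(num, group = md$group,
                 condition = unique(md$condition)[1L])
  if (dialect == "long") S4Vectors::metadata(tab)$replicateQC <- collapsed$qc
  tab
}

#' Write a CtTable to delimited files
#'
#' Writes the wide-dialect Ct CSV and companion metadata CSV understood by
#' [readCtTable()]. Values are written with full precision so a
#' write-then-read round trip reproduces Ct values to better than six
#' significant digits.
#'
#' @param table A [CtTable-class].
#' @param path Output path for the Ct matrix CSV.
#' @param metadataPath Output path for the metadata CSV.
#' @return Invisibly, `c(path, metadataPath)`.
#' @export
writeCtTable <- function(table, path, metadataPath) {
  ct <- ctValues(table)
  df <- data.frame(candidate = rownames(ct), ct, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  md <- data.frame(sample = colnames(ct),
                   group = unname(sampleGroups(table)),
                   condition = conditionLabel(table))
  utils::write.csv(md, metadataPath, row.names = FALSE, quote = FALSE)
  invisible(c(path, metadataPath))
}

#' Collapse technical replicates to one Ct per well
#'
#' Technical qPCR replicates (typically triplicates) are collapsed to a
#' single Ct per (candidate, sample) pair by the arithmetic mean.
#' Replicate sets whose spread (max - min) exceeds `spreadThreshold` are
#' flagged in the QC report but never dropped: silently altering the
#' effective n would corrupt downstream standard deviations.
#'
#' @param raw A data frame with columns `sample`, `candidate`, `ct` (and
#'   optionally `replicate`), one row per replicate measurement.
#' @param spreadThreshold QC flag threshold on the within-set spread, in
#'   cycles. Default 0.5.
#' @return A list with `ct` (candidates x samples numeric matrix; row and
#'   column order follow first appearance in `raw`) and `qc` (data frame
#'   with `candidate`, `sample`, `n`, `spread`, `flagged`).
#' @examples
#' raw <- data.frame(sample = "s1", candidate = "A", ct = c(20, 20.2, 20.4))
#' collapseReplicates(raw)$ct
#' @export
collapseReplicates <- function(raw, spreadThreshold = 0.5) {
  need <- c("sample", "candidate", "ct")
  if (!is.data.frame(raw) || !all(need %in% colnames(raw)))
    .stopValidation("replicate data needs columns sample, candidate, ct")
  if (nrow(raw) == 0L) .stopValidation("empty replicate set")
  if (any(!is.finite(raw$ct) | raw$ct <= 0 | raw$ct > 45))
    .stopValidation("replicate Ct values must be finite and in (0, 45]")
  cand <- unique(as.character(raw$candidate))
  samp <- unique(as.character(raw$sample))
  key <- interaction(factor(raw$candidate, cand), factor(raw$sample, samp),
                     drop = FALSE)
  sets <- split(raw$ct, key)
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty))
    .stopValidation(sprintf("no replicates for pair(s): %s",
                            paste(names(sets)[empty], collapse = ", ")))
  means <- vapply(sets, mean, numeric(1))
  spread <- vapply(sets, function(x) max(x) - min(x), numeric(1))
  ct <- matrix(means, nrow = length(cand), ncol = length(samp),
               dimnames = list(cand, samp))
  pairs <- expand.grid(candidate = cand, sample = samp,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  qc <- data.frame(pairs,
                   n = as.integer(vapply(sets, length, 1L)),
                   spread = unname(spread),
                   flagged = unname(spread > spreadThreshold))
  list(ct = ct, qc = qc)
}

#' Per-group Ct summary statistics
#'
#' For every candidate and group: n, mean Ct, SD (n-1 denominator) and
#' SEM (= SD / sqrt(n)), mirroring the per-group descriptive tables that
#' accompany reference-gene studies.
#'
#' @param table A [CtTable-class] with >= 2 groups of >= 2 samples.
#' @return Data frame with columns `candidate`, `group`, `n`, `mean`,
#'   `sd`, `sem`.
#' @export
summarizeGroupCt <- function(table) {
  idx <- .requireGroups(table)
  ct <- ctValues(table)
  out <- do.call(rbind, lapply(names(idx), function(g) {
    sub <- ct[, idx[[g]], drop = FALSE]
    n <- ncol(sub)
    m <- rowMeans(sub)
    s <- apply(sub, 1L, stats::sd)
    data.frame(candidate = rownames(ct), group = g, n = n,
               mean = unname(m), sd = unname(s), sem = unname(s / sqrt(n)),
               row.names = NULL)
  }))
  out[order(match(out$candidate, rownames(ct)), out$group), ]
}

#' Per-candidate two-group comparison of Ct values
#'
#' Runs a two-tailed unpaired t-test per candidate between the two sample
#' groups. The default is the Student equal-variance test; the Welch
#' variant is selectable. A stable reference candidate is expected to show
#' no significant group difference.
#'
#' @param table A [CtTable-class] with exactly 2 groups, each n >= 2.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @param alpha Significance level for the flag, default 0.05.
#' @return Data frame with columns `candidate`, `t`, `df`, `p`,
#'   `significant`.
#' @export
compareGroupCt <- function(table, variant = c("student", "welch"),
                           alpha = 0.05) {
  variant <- match.arg(variant)
  idx <- .requireGroups(table, exactly2 = TRUE)
  ct <- ctValues(table)
  res <- lapply(rownames(ct), function(cand) {
    x <- ct[cand, idx[[1L]]]
    y <- ct[cand, idx[[2L]]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # degenerate: no within-group variance; t is 0 when means agree,
      # infinite otherwise
      if (mean(x) == mean(y))
        return(data.frame(candidate = cand, t = 0, df = length(x) +
                            length(y) - 2, p = 1, significant = FALSE))
      return(data.frame(candidate = cand, t = Inf, df = length(x) +
                          length(y) - 2, p = 0, significant = TRUE))
    }
    tt <- stats::t.test(x, y, var.equal = (variant == "student"))
    data.frame(candidate = cand, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               significant = tt$p.value < alpha)
  })
  do.call(rbind, res)
}
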