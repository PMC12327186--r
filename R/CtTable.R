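#' Construct a CtTable
#'
#' Builds a validated [CtTable-class] from a numeric Ct matrix and
#' per-sample group labels.
#'
#' @param ct Numeric matrix of Ct values (cycles), candidates in rows,
#'   samples in columns; dimnames required.
#' @param group Character or factor of group labels, one per sample (in
#'   column order), or a named vector matching the column names. Defaults
#'   to a single group `"all"`.
#' @param condition Free-text condition label, e.g. `"motility"`.
#' @return A [CtTable-class] object.
#' @examples
#' ct <- matrix(c(20, 21, 22, 23, 25, 26, 27, 28), nrow = 2, byrow = TRUE,
#'              dimnames = list(c("A", "B"), paste0("s", 1:4)))
#' tab <- CtTable(ct, group = c("g1", "g1", "g2", "g2"))
#' sampleGroups(tab)
#' @export
CtTable <- function(ct, group = NULL, condition = "unspecified") {
  if (!is.matrix(ct) || !is.numeric(ct))
    .stopValidation("'ct' must be a numeric matrix")
  if (is.null(rownames(ct))) rownames(ct) <- paste0("c", seq_len(nrow(ct)))
  if (is.null(colnames(ct))) colnames(ct) <- paste0("s", seq_len(ncol(ct)))
  if (is.null(group)) group <- rep("all", ncol(ct))
  if (!is.null(names(group))) {
    missing <- setdiff(colnames(ct), names(group))
    if (length(missing))
      .stopValidation(sprintf("samples missing from group labels: %s",
                              paste(missing, collapse = ", ")))
    group <- group[colnames(ct)]
  }
  if (length(group) != ncol(ct))
    .stopValidation("'group' must supply one label per sample")
  obj <- methods::new(
    "CtTable",
    SummarizedExperiment::SummarizedExperiment(
      assays = list(ct = ct),
      colData = S4Vectors::DataFrame(
        group = as.character(group),
        condition = rep(condition, ncol(ct)),
        row.names = colnames(ct))))
  methods::validObject(obj)
  obj
}

#' Accessors for CtTable
#'
#' `ctValues()` returns the Ct matrix; `sampleGroups()` the named group
#' label vector; `conditionLabel()` the condition string;
#' `candidateNames()` the candidate identifiers.
#'
#' @param x A [CtTable-class].
#' @return See the individual descriptions.
#' @name CtTable-accessors
#' @aliases ctValues sampleGroups conditionLabel candidateNames
#' @examples
#' tab <- CtTable(matrix(20:23, 2, 2, dimnames = list(c("A", "B"),
#'                c("s1", "s2"))))
#' ctValues(tab)
NULL

#' @rdname CtTable-accessors
#' @export
setMethod("ctValues", "CtTable", function(x)
  SummarizedExperiment::assay(x, "ct"))

#' @rdname CtTable-accessors
#' @export
setMethod("sampleGroups", "CtTable", function(x) {
  g <- SummarizedExperiment::colData(x)$group
  names(g) <- colnames(x)
  g
})

#' @rdname CtTable-accessors
#' @export
setMethod("conditionLabel", "CtTable", function(x) {
  cond <- unique(SummarizedExperiment::colData(x)$condition)
  if (length(cond) != 1L) cond <- paste(cond, collapse = "+")
  cond
})

#' @rdname CtTable-accessors
#' @export
setMethod("candidateNames", "CtTable", function(x) rownames(x))

setMethod("show", "CtTable", function(object) {
  g <- table(sampleGroups(object))
  cat(sprintf(
    "CtTable: %d candidates x %d samples, condition '%s'\n",
    nrow(object), ncol(object), conditionLabel(object)))
  cat("  groups:", paste(sprintf("%s (n=%d)", names(g), as.integer(g)),
                         collapse = ", "), "\n")
  ct <- ctValues(object)
  cat(sprintf("  Ct range: [%.2f, %.2f] cycles\n", min(ct), max(ct)))
})

# Require >= 2 groups each with >= 2 samples; returns the split of sample
# indices by group.
.requireGroups <- function(table, exactly2 = FALSE) {
  g <- sampleGroups(table)
  split_idx <- split(seq_along(g), g)
  if (exactly2 && length(split_idx) != 2L)
    .stopContract(sprintf("exactly 2 groups required, found %d",
                          length(split_idx)))
  if (length(split_idx) < 2L)
    .stopContract("at least 2 groups required")
  small <- names(split_idx)[vapply(split_idx, length, 1L) < 2L]
  if (length(small))
    .stopContract(sprintf("each group needs >= 2 samples; too small: %s",
                          paste(small, collapse = ", ")))
  split_idx
}
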