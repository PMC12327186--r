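#' Load the bundled bovine semen candidate-miRNA panel
#'
#' Returns the reference-candidate panel assayed in the bovine semen
#' study: six mature miRNAs plus the U6 small nuclear RNA control, with
#' TaqMan Advanced assay identifiers and mature sequences.
#'
#' @param path Optional path to an alternative panel TSV with columns
#'   `assay_name`, `assay_id`, `mature_sequence`; defaults to the bundled
#'   fixture.
#' @return Data frame with columns `assay_name`, `assay_id`,
#'   `mature_sequence` and a derived `type` column (`"mirna"` for TaqMan
#'   miRNA assays, whose ids end in `_mir`; `"control"` otherwise).
#' @examples
#' panel <- loadCandidatePanel()
#' panel$assay_name
#' @export
loadCandidatePanel <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "candidate_panel.tsv",
                        package = "CtStability", mustWork = TRUE)
  panel <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  need <- c("assay_name", "assay_id", "mature_sequence")
  if (!all(need %in% colnames(panel)))
    .stopValidation(sprintf("panel must have columns %s",
                            paste(need, collapse = ",")))
  panel$type <- ifelse(grepl("_mir$", panel$assay_id), "mirna", "control")
  panel
}

#' Validate a candidate panel
#'
#' Checks that every sequence is non-empty and drawn from the expected
#' alphabet: mature miRNA sequences are RNA (`A`, `C`, `G`, `U`), control
#' sequences such as U6 snRNA are reported as DNA (`A`, `C`, `G`, `T`).
#' Problems are reported, never thrown, so a panel can be audited in full.
#'
#' @param panel Data frame as returned by [loadCandidatePanel()]; a `type`
#'   column is derived from `assay_id` if absent.
#' @return Data frame with one row per entry: `assay_name`, `type`,
#'   `length`, `valid`, `problem` (empty string when valid).
#' @examples
#' validatePanel(loadCandidatePanel())
#' @export
validatePanel <- function(panel) {
  if (!"type" %in% colnames(panel))
    panel$type <- ifelse(grepl("_mir$", panel$assay_id), "mirna", "control")
  check_one <- function(seq, type) {
    if (is.na(seq) || !nzchar(seq)) return("empty sequence")
    alphabet <- if (type == "mirna") "ACGU" else "ACGT"
    bad <- setdiff(strsplit(seq, "")[[1L]], strsplit(alphabet, "")[[1L]])
    if (length(bad))
      return(sprintf("characters outside {%s}: %s",
                     paste(strsplit(alphabet, "")[[1L]], collapse = ","),
                     paste(unique(bad), collapse = ",")))
    ""
  }
  problem <- mapply(check_one, panel$mature_sequence, panel$type,
                    USE.NAMES = FALSE)
  data.frame(assay_name = panel$assay_name, type = panel$type,
             length = nchar(ifelse(is.na(panel$mature_sequence), "",
                                   panel$mature_sequence)),
             valid = !nzchar(problem), problem = problem)
}
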