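# Cohort-definition helpers for bovine semen quality studies: morphology
# defect aggregation and approval, CASA kinematic ratios, quartile-based
# motility grouping.

.checkPct <- function(x, what) {
  if (any(!is.finite(x) | x < 0 | x > 100))
    .stopValidation(sprintf("%s must lie in [0, 100] percent", what))
}

#' Aggregate sperm morphology defects
#'
#' Sums the component defect percentages into the standard classes:
#' major defects (acrosomal abnormalities + head defects + vacuoles +
#' proximal cytoplasmic droplet + midpiece damage), minor defects
#' (detached head + bent tail), and total abnormalities (major + minor).
#' Percentages refer to fractions of >= 100 assessed spermatozoa.
#'
#' @param records Data frame with one row per sample and columns
#'   `acrosome`, `head`, `vacuoles`, `pcd`, `midpiece`, `detached_head`,
#'   `bent_tail` (percent).
#' @return The input with `major`, `minor`, `total` columns appended.
#' @examples
#' aggregateDefects(data.frame(acrosome = 3.2, head = 3.2, vacuoles = 2.8,
#'   pcd = 1.8, midpiece = 1.2, detached_head = 2.4, bent_tail = 8.0))
#' @export
aggregateDefects <- function(records) {
  majorCols <- c("acrosome", "head", "vacuoles", "pcd", "midpiece")
  minorCols <- c("detached_head", "bent_tail")
  need <- c(majorCols, minorCols)
  if (!all(need %in% colnames(records)))
    .stopValidation(sprintf("morphology records need columns: %s",
                            paste(need, collapse = ", ")))
  for (cc in need) .checkPct(records[[cc]], cc)
  records$major <- rowSums(records[, majorCols, drop = FALSE])
  records$minor <- rowSums(records[, minorCols, drop = FALSE])
  records$total <- records$major + records$minor
  records
}

#' Classify sperm morphology approval
#'
#' A sample fails ("non-approved") when major defects exceed 20% or
#' total abnormalities (major and minor combined) exceed 30%; both
#' thresholds are strict, so a sample sitting exactly at 20% / 30% is
#' approved. When printed major/minor aggregates are available they are
#' used as given rather than recomputed from components.
#'
#' @param major Major-defect percentage(s).
#' @param total Total-abnormality percentage(s).
#' @return Character vector, `"approved"` or `"non-approved"`.
#' @examples
#' classifyMorphology(24.0, 50.2)  # non-approved
#' classifyMorphology(12.2, 22.6)  # approved
#' classifyMorphology(20.0, 30.0)  # boundary: approved
#' @export
classifyMorphology <- function(major, total) {
  .checkPct(major, "major defects")
  .checkPct(total, "total abnormalities")
  ifelse(major > 20 | total > 30, "non-approved", "approved")
}

#' Derive CASA kinematic ratios
#'
#' Fills in the standard derived ratios from the three CASA velocities:
#' straightness `STR = 100 * VSL / VAP`, linearity
#' `LIN = 100 * VSL / VCL`, and wobble `WOB = 100 * VAP / VCL`. Under
#' the expected velocity ordering VSL <= VAP <= VCL all three lie in
#' \[0, 100\]; rows violating that ordering are flagged, not rejected,
#' since CASA systems occasionally emit them. Zero denominators yield
#' `NA` with a flag.
#'
#' @param records Data frame with columns `vsl`, `vap`, `vcl`
#'   (micrometres per second).
#' @return The input with `str_pct`, `lin_pct`, `wob_pct` and logical
#'   `kinematics_flagged` appended.
#' @examples
#' deriveKinematics(data.frame(vsl = 45, vap = 50, vcl = 90))
#' @export
deriveKinematics <- function(records) {
  need <- c("vsl", "vap", "vcl")
  if (!all(need %in% colnames(records)))
    .stopValidation("CASA records need columns vsl, vap, vcl")
  for (cc in need)
    if (any(!is.finite(records[[cc]]) | records[[cc]] < 0))
      .stopValidation(sprintf("'%s' must be finite and >= 0", cc))
  vsl <- records$vsl; vap <- records$vap; vcl <- records$vcl
  badDen <- vap == 0 | vcl == 0
  records$str_pct <- ifelse(vap == 0, NA_real_, 100 * vsl / vap)
  records$lin_pct <- ifelse(vcl == 0, NA_real_, 100 * vsl / vcl)
  records$wob_pct <- ifelse(vcl == 0, NA_real_, 100 * vap / vcl)
  records$kinematics_flagged <- badDen | !(vsl <= vap & vap <= vcl)
  records
}

#' Quartile-based motility grouping
#'
#' Allocates samples to motility cohorts by quartiles of a motility
#' metric: values at or below the first quartile form the
#' `"Low/Moderate"` group, values strictly above the third quartile the
#' `"High"` group; the middle half is left unassigned. Quartiles use
#' linear interpolation between order statistics
#' ([stats::quantile()] type 7) by default; the type is configurable
#' because membership near Q1/Q3 can depend on it.
#'
#' @param values Named numeric vector of per-sample motility percentages
#'   (n >= 4).
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @return Data frame with columns `sample`, `value`, `group`
#'   (`"Low/Moderate"`, `"High"`, or `NA` for the middle), plus
#'   attributes `q1`, `q3` and `degenerate` (TRUE when Q1 == Q3).
#' @examples
#' quartileGroups(setNames(1:8, paste0("b", 1:8)))
#' @export
quartileGroups <- function(values, type = 7) {
  if (length(values) < 4L)
    .stopContract("quartile grouping requires >= 4 values")
  .checkPct(values, "motility values")
  if (is.null(names(values)))
    names(values) <- paste0("sample", seq_along(values))
  q <- stats::quantile(values, probs = c(0.25, 0.75), type = type,
                       names = FALSE)
  group <- rep(NA_character_, length(values))
  group[values <= q[1L]] <- "Low/Moderate"
  group[values > q[2L]] <- "High"
  out <- data.frame(sample = names(values), value = unname(values),
                    group = group)
  attr(out, "q1") <- q[1L]
  attr(out, "q3") <- q[2L]
  attr(out, "degenerate") <- q[1L] == q[2L]
  out
}

#' Two-group summary with unpaired t-test
#'
#' Mean +/- SEM per group and a two-tailed unpaired t-test between the
#' two groups, the reporting convention for cohort characteristics
#' (motility, kinematics, defect rates).
#'
#' @param values Numeric vector of measurements.
#' @param group Group label per value (exactly 2 distinct labels, each
#'   with n >= 2).
#' @param variant `"student"` or `"welch"`, as in [compareGroupCt()].
#' @param alpha Significance level, default 0.05.
#' @return List with `summary` (data frame: group, n, mean, sem) and
#'   `test` (data frame: t, df, p, significant).
#' @export
groupSummary <- function(values, group, variant = c("student", "welch"),
                         alpha = 0.05) {
  variant <- match.arg(variant)
  if (length(values) != length(group))
    .stopContract("'values' and 'group' must have equal length")
  parts <- split(values, group)
  if (length(parts) != 2L)
    .stopContract(sprintf("exactly 2 groups required, found %d",
                          length(parts)))
  if (any(vapply(parts, length, 1L) < 2L))
    .stopContract("each group needs >= 2 values")
  summ <- data.frame(
    group = names(parts),
    n = vapply(parts, length, 1L),
    mean = vapply(parts, mean, numeric(1)),
    sem = vapply(parts, function(x) stats::sd(x) / sqrt(length(x)),
                 numeric(1)),
    row.names = NULL)
  x <- parts[[1L]]; y <- parts[[2L]]
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    equal <- mean(x) == mean(y)
    test <- data.frame(t = if (equal) 0 else Inf,
                       df = length(x) + length(y) - 2,
                       p = if (equal) 1 else 0,
                       significant = !equal)
  } else {
    tt <- stats::t.test(x, y, var.equal = (variant == "student"))
    test <- data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
                       p = tt$p.value, significant = tt$p.value < alpha)
  }
  list(summary = summ, test = test)
}
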