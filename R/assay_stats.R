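# Small-sample assay computations used in validation figures: qPCR relative
# expression (2^-dCt), dual-luciferase percent-of-control normalisation, and
# unpaired two-sample t-tests (Welch and Student).

#' qPCR relative expression by the 2^-dCt method
#'
#' Expression of a target relative to a reference (housekeeping) RNA from
#' threshold cycles: `2^-(ct_target - ct_reference)`. Vectorised.
#'
#' @param ct_target,ct_reference positive, finite threshold cycle values.
#' @return Strictly positive relative expression value(s).
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (length(ct_target) != length(ct_reference))
    stop_oasig("ct_target and ct_reference must have equal length",
               "oasig_validation_error")
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)) ||
      any(ct_target <= 0) || any(ct_reference <= 0))
    stop_oasig("Ct values must be finite and positive", "oasig_validation_error")
  2^-(ct_target - ct_reference)
}

#' Dual-luciferase activity as percent of control
#'
#' Each well's firefly luminescence is normalised to its renilla
#' co-transfection control; the mimic condition is then expressed as a
#' percentage of the mean control ratio (wells are unpaired, so means are
#' compared, not per-well pairs).
#'
#' @param firefly,renilla numeric luminescence readings per well
#'   (`renilla > 0`).
#' @param condition character vector per well, each `"mimic"` or
#'   `"control"`; both conditions must be present.
#' @return Percentage: `100 * mean(mimic ratios) / mean(control ratios)`.
#' @export
luciferase_percent_of_control <- function(firefly, renilla, condition) {
  n <- length(firefly)
  if (length(renilla) != n || length(condition) != n)
    stop_oasig("firefly, renilla and condition must have equal length",
               "oasig_validation_error")
  bad <- setdiff(unique(condition), c("mimic", "control"))
  if (length(bad))
    stop_oasig(sprintf("unknown condition(s): %s", paste(bad, collapse = ", ")),
               "oasig_validation_error")
  if (!all(c("mimic", "control") %in% condition))
    stop_oasig("need at least one well per condition (mimic and control)",
               "oasig_validation_error")
  if (any(!is.finite(renilla)) || any(renilla <= 0))
    stop_oasig("renilla luminescence must be finite and > 0",
               "oasig_validation_error")
  ratio <- firefly / renilla
  denom <- mean(ratio[condition == "control"])
  if (denom == 0)
    stop_oasig("mean control ratio is zero; percent of control undefined",
               "oasig_validation_error")
  100 * mean(ratio[condition == "mimic"]) / denom
}

check_t_groups <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop_oasig("each group needs at least 2 observations",
               "oasig_validation_error")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_oasig("observations must be finite", "oasig_validation_error")
}

# Degenerate-variance contract shared by both tests: two constant, equal
# groups differ by nothing (t = 0, p = 1); constant groups with unequal
# means admit no t statistic.
t_degenerate <- function(x, y, df) {
  if (isTRUE(all.equal(mean(x), mean(y))))
    list(t = 0, df = df, p = 1)
  else
    stop_oasig("zero variance with unequal means: t-test undefined",
               "oasig_degenerate_error")
}

#' Welch's unpaired two-sample t-test
#'
#' Two-tailed unpaired t-test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom), as used for qPCR group
#' comparisons.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return List with `t`, `df` and two-tailed `p`.
#' @export
welch_t_test <- function(x, y) {
  check_t_groups(x, y)
  if (stats::var(x) + stats::var(y) == 0)
    return(t_degenerate(x, y, length(x) + length(y) - 2))
  fit <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Student's unpaired two-sample t-test
#'
#' Two-tailed unpaired t-test with pooled variance, as used for
#' dual-luciferase reporter comparisons.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return List with `t`, `df` and two-tailed `p`.
#' @export
student_t_test <- function(x, y) {
  check_t_groups(x, y)
  if (stats::var(x) + stats::var(y) == 0)
    return(t_degenerate(x, y, length(x) + length(y) - 2))
  fit <- stats::t.test(x, y, var.equal = TRUE, alternative = "two.sided")
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}
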