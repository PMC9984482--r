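# Functional-outcome labelling: dichotomized mRS and the severity-adjusted
# rule combining mRS with admission NIHSS.

check_mrs <- function(mrs) {
  if (anyNA(mrs) || any(mrs != as.integer(mrs)) || any(mrs < 0 | mrs > 6)) {
    ppv_abort("`mrs` must be integers in 0..6", "ppv_bad_outcome")
  }
  as.integer(mrs)
}

check_nihss <- function(nihss) {
  if (anyNA(nihss) || any(nihss != as.integer(nihss)) ||
      any(nihss < 0 | nihss > 42)) {
    ppv_abort("`nihss` must be integers in 0..42", "ppv_bad_outcome")
  }
  as.integer(nihss)
}

#' Dichotomized modified Rankin Scale outcome
#'
#' Unfavorable outcome is defined as mRS >= 3 (dependence or death),
#' favorable as mRS <= 2.
#'
#' @param mrs Integer vector of modified Rankin Scale scores (0-6).
#' @return Integer vector, 1 = unfavorable, 0 = favorable.
#' @examples
#' dichotomize_mrs(c(0, 2, 3, 6)) # 0 0 1 1
#' @export
dichotomize_mrs <- function(mrs) {
  mrs <- check_mrs(mrs)
  as.integer(mrs >= 3L)
}

#' Severity-adjusted functional outcome
#'
#' Grades the mRS against admission stroke severity: the outcome is
#' unfavorable when mRS is 2-6 with admission NIHSS <= 7, or mRS 3-6 with
#' NIHSS 8-14, or mRS 4-6 with NIHSS > 14; favorable otherwise. A mild
#' stroke that still leaves the patient with mRS 2 counts as unfavorable,
#' while the same mRS after a severe stroke counts as favorable.
#'
#' @param mrs Integer vector of mRS scores (0-6).
#' @param nihss Integer vector of admission NIHSS scores (0-42), recycled
#'   against `mrs` if scalar.
#' @return Integer vector, 1 = unfavorable, 0 = favorable.
#' @examples
#' severity_adjusted_outcome(2, 7)  # 1: mild stroke, residual dependence
#' severity_adjusted_outcome(3, 20) # 0: severe stroke, mRS 3 is favorable
#' @export
severity_adjusted_outcome <- function(mrs, nihss) {
  mrs <- check_mrs(mrs)
  nihss <- check_nihss(nihss)
  if (length(nihss) == 1L) nihss <- rep(nihss, length(mrs))
  if (length(mrs) == 1L) mrs <- rep(mrs, length(nihss))
  if (length(mrs) != length(nihss)) {
    ppv_abort("`mrs` and `nihss` must have matching lengths",
              "ppv_bad_outcome")
  }
  unfav <- (mrs >= 2L & nihss <= 7L) |
    (mrs >= 3L & nihss >= 8L & nihss <= 14L) |
    (mrs >= 4L & nihss > 14L)
  as.integer(unfav)
}

#' Label outcomes for a cohort table
#'
#' Appends 0/1 unfavorable-outcome columns for the requested horizons
#' (1 = unfavorable). The dichotomized rule uses `mrs_30d` / `mrs_90d`
#' alone; the severity-adjusted rule additionally uses `nihss_admission`.
#'
#' @param cohort Cohort data frame with `mrs_30d`, `mrs_90d` and (for the
#'   severity-adjusted rule) `nihss_admission`.
#' @param rule `"dichotomized"` or `"severity_adjusted"`.
#' @param horizons Character subset of `c("30d", "90d")`.
#' @return The cohort as a tibble with `unfavorable_<horizon>` columns
#'   appended (named `unfavorable_adj_<horizon>` for the severity rule).
#' @export
label_outcomes <- function(cohort,
                           rule = c("dichotomized", "severity_adjusted"),
                           horizons = c("30d", "90d")) {
  rule <- match.arg(rule)
  horizons <- match.arg(horizons, several.ok = TRUE)
  cohort <- tibble::as_tibble(cohort)
  for (h in horizons) {
    mrs_col <- paste0("mrs_", h)
    if (!mrs_col %in% names(cohort)) {
      ppv_abort(paste0("cohort is missing column ", mrs_col),
                "ppv_bad_input")
    }
    lab <- if (rule == "dichotomized") {
      dichotomize_mrs(cohort[[mrs_col]])
    } else {
      severity_adjusted_outcome(cohort[[mrs_col]],
                                cohort[["nihss_admission"]])
    }
    out_col <- if (rule == "dichotomized") {
      paste0("unfavorable_", h)
    } else {
      paste0("unfavorable_adj_", h)
    }
    cohort[[out_col]] <- lab
  }
  cohort
}
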