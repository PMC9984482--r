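# Pulse-pressure derivation, sampling validation and the seven PPV summaries.

#' Pulse pressure from systolic and diastolic readings
#'
#' Pulse pressure (PP) is the pulsatile component of blood pressure,
#' `sbp - dbp` in mmHg. A reading with `sbp <= dbp` is physiologically
#' invalid and rejected with the index of the offending reading.
#'
#' @param sbp,dbp Numeric vectors of systolic and diastolic pressure (mmHg),
#'   equal length.
#' @return Numeric vector of pulse pressures (mmHg), same length and order.
#' @examples
#' pulse_pressure(154, 91) # 63
#' pulse_pressure(c(150, 160, 140), c(90, 90, 90))
#' @export
pulse_pressure <- function(sbp, dbp) {
  if (length(sbp) == 0L) {
    ppv_abort("empty series: no readings to derive pulse pressure from",
              "ppv_empty_series")
  }
  if (length(sbp) != length(dbp)) {
    ppv_abort("`sbp` and `dbp` must have the same length", "ppv_bad_input")
  }
  if (anyNA(sbp) || anyNA(dbp)) {
    ppv_abort("missing SBP/DBP values are not allowed", "ppv_bad_input")
  }
  bad <- which(sbp <= dbp)
  if (length(bad) > 0L) {
    ppv_abort(
      sprintf("non-positive pulse pressure (sbp <= dbp) at reading %d of %d",
              bad[1L], length(sbp)),
      "ppv_invalid_reading", index = bad
    )
  }
  sbp - dbp
}

#' Derive the pulse-pressure column for a readings table
#'
#' Takes a blood-pressure readings table (one row per reading, columns
#' `sbp` and `dbp`, optionally `patient_id` and `time_offset_hours`) and
#' returns it as a tibble with a `pp` column appended.
#'
#' @param readings A data frame with numeric `sbp` and `dbp` columns.
#' @return A tibble: the input rows with `pp = sbp - dbp` (mmHg) appended.
#' @export
derive_pulse_pressure <- function(readings) {
  readings <- check_readings(readings, require_time = FALSE)
  dplyr::mutate(readings, pp = pulse_pressure(.data$sbp, .data$dbp))
}

check_readings <- function(readings, require_time = TRUE) {
  if (!is.data.frame(readings)) {
    ppv_abort("`readings` must be a data frame", "ppv_bad_input")
  }
  if (nrow(readings) == 0L) {
    ppv_abort("empty series: no readings supplied", "ppv_empty_series")
  }
  need <- c("sbp", "dbp", if (require_time) "time_offset_hours")
  missing_cols <- setdiff(need, names(readings))
  if (length(missing_cols) > 0L) {
    ppv_abort(paste0("readings table is missing column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "ppv_bad_input")
  }
  tibble::as_tibble(readings)
}

#' Sampling-completeness policy for a 72-h BP series
#'
#' The monitoring schedule is nominally one reading every `interval_hours`
#' from hour 0 through `window_hours` (19 slots for 4-h intervals over
#' 72 h, endpoints inclusive). A series is accepted when at least
#' `min_fraction` of the expected slots are observed and no gap between
#' successive readings exceeds `max_gap_hours`.
#'
#' @param interval_hours Nominal spacing between readings (h). Default 4.
#' @param min_fraction Minimum observed/expected reading ratio in (0, 1].
#'   Default 0.8.
#' @param max_gap_hours Largest tolerated gap between successive readings
#'   (h); must be at least `interval_hours`. Default 8 (twice the nominal
#'   interval).
#' @param window_hours Nominal observation window (h). Default 72.
#' @return An object of class `sampling_policy`.
#' @export
sampling_policy <- function(interval_hours = 4, min_fraction = 0.8,
                            max_gap_hours = 8, window_hours = 72) {
  if (!(min_fraction > 0 && min_fraction <= 1)) {
    ppv_abort("`min_fraction` must lie in (0, 1]", "ppv_bad_policy")
  }
  if (max_gap_hours < interval_hours) {
    ppv_abort("`max_gap_hours` must be >= `interval_hours`", "ppv_bad_policy")
  }
  if (interval_hours <= 0 || window_hours <= 0) {
    ppv_abort("`interval_hours` and `window_hours` must be positive",
              "ppv_bad_policy")
  }
  structure(
    list(interval_hours = interval_hours, min_fraction = min_fraction,
         max_gap_hours = max_gap_hours, window_hours = window_hours),
    class = "sampling_policy"
  )
}

expected_slots <- function(policy) {
  policy$window_hours / policy$interval_hours + 1
}

#' Validate sampling completeness of BP series
#'
#' Applies a [sampling_policy()] to each patient's reading series and
#' returns a per-patient verdict. A series is `accepted` when its reading
#' count reaches `min_fraction` of the expected slot count and no gap
#' between successive readings exceeds `max_gap_hours`; otherwise the
#' machine-readable `reason` is `"too_few_readings"` or `"gap_too_large"`
#' (count checked first).
#'
#' @param readings Data frame with `patient_id` (optional for a single
#'   series), `time_offset_hours`, `sbp`, `dbp`.
#' @param policy A [sampling_policy()].
#' @return A tibble with one row per patient: `patient_id`, `n_readings`,
#'   `accepted`, `reason` (`NA` when accepted).
#' @export
validate_sampling <- function(readings, policy = sampling_policy()) {
  stopifnot(inherits(policy, "sampling_policy"))
  readings <- check_readings(readings)
  if (!"patient_id" %in% names(readings)) readings$patient_id <- "series"
  bad_time <- readings$time_offset_hours < 0 |
    readings$time_offset_hours > policy$window_hours
  if (any(bad_time)) {
    ppv_abort("time offsets outside [0, window_hours]", "ppv_bad_input")
  }
  n_expected <- expected_slots(policy)
  readings |>
    dplyr::arrange(.data$patient_id, .data$time_offset_hours) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_readings = dplyr::n(),
      max_gap = if (dplyr::n() > 1L) max(diff(.data$time_offset_hours)) else Inf,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$n_readings < policy$min_fraction * n_expected ~ "too_few_readings",
        .data$max_gap > policy$max_gap_hours ~ "gap_too_large",
        TRUE ~ NA_character_
      ),
      accepted = is.na(.data$reason)
    ) |>
    dplyr::select("patient_id", "n_readings", "accepted", "reason")
}

#' Pulse-pressure variability summaries of one PP series
#'
#' For a series \eqn{x_1, \dots, x_n} of pulse-pressure readings the seven
#' summaries are: the mean; the sample standard deviation
#' \eqn{SD = \sqrt{\sum (x_i - \bar x)^2 / (n-1)}}; the coefficient of
#' variation \eqn{CV = 100\, SD / \bar x}; the successive variation
#' \eqn{SV = \sqrt{\sum_{i<n} (x_{i+1} - x_i)^2 / (n-1)}}; the average real
#' variability \eqn{ARV = \sum_{i<n} |x_{i+1} - x_i| / (n-1)}; the
#' max-min difference \eqn{DMM = \max x - \min x}; and the maximal
#' successive change \eqn{MSC = \max_i |x_{i+1} - x_i|}.
#'
#' @param pp Numeric vector of pulse-pressure values (mmHg), in reading
#'   order, length at least 2.
#' @return A one-row tibble with columns `mean_pp`, `sd`, `cv`, `sv`,
#'   `arv`, `dmm`, `msc`, `n_readings`. `cv` is `NaN` when `mean_pp` is 0.
#' @examples
#' summarize_ppv(c(60, 70, 50, 60))
#' @export
summarize_ppv <- function(pp) {
  if (!is.numeric(pp) || anyNA(pp)) {
    ppv_abort("`pp` must be a numeric vector without missing values",
              "ppv_bad_input")
  }
  n <- length(pp)
  if (n < 2L) {
    ppv_abort("variability indices need at least 2 readings",
              "ppv_too_short")
  }
  d <- diff(pp)
  mean_pp <- mean(pp)
  s <- stats::sd(pp)
  cv <- if (mean_pp > 0) 100 * s / mean_pp else NaN
  tibble::tibble(
    mean_pp = mean_pp,
    sd = s,
    cv = cv,
    sv = sqrt(sum(d^2) / (n - 1)),
    arv = mean(abs(d)),
    dmm = max(pp) - min(pp),
    msc = max(abs(d)),
    n_readings = n
  )
}

#' Per-patient PPV indices from a readings table
#'
#' Derives pulse pressure, applies the sampling policy, and computes the
#' PPV summaries for every accepted patient series. Rejected series keep
#' their row with `NA` indices and the rejection reason. Readings are
#' sorted by time within patient; duplicated time offsets within a patient
#' are an error.
#'
#' @param readings Data frame with `patient_id`, `time_offset_hours`,
#'   `sbp`, `dbp` (one row per reading).
#' @param policy A [sampling_policy()], or `NULL` to skip the
#'   completeness check (all series with >= 2 readings are summarised).
#' @return A tibble with one row per patient: validity verdict columns
#'   from [validate_sampling()] plus the [summarize_ppv()] columns.
#' @export
ppv_indices <- function(readings, policy = sampling_policy()) {
  readings <- check_readings(readings)
  if (!"patient_id" %in% names(readings)) readings$patient_id <- "series"
  readings <- dplyr::arrange(readings, .data$patient_id,
                             .data$time_offset_hours)
  dup <- readings |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::filter(duplicated(.data$time_offset_hours)) |>
    dplyr::ungroup()
  if (nrow(dup) > 0L) {
    ppv_abort(
      sprintf("duplicated time offsets within patient(s): %s",
              paste(unique(dup$patient_id), collapse = ", ")),
      "ppv_bad_input"
    )
  }
  readings <- derive_pulse_pressure(readings)
  verdict <- if (is.null(policy)) {
    readings |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(n_readings = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(
        reason = ifelse(.data$n_readings < 2L, "too_few_readings",
                        NA_character_),
        accepted = is.na(.data$reason)
      ) |>
      dplyr::select("patient_id", "n_readings", "accepted", "reason")
  } else {
    validate_sampling(readings, policy)
  }
  accepted_rows <- dplyr::semi_join(
    readings, dplyr::filter(verdict, .data$accepted), by = "patient_id"
  )
  idx <- if (nrow(accepted_rows) == 0L) {
    tibble::tibble(patient_id = character(), mean_pp = numeric(),
                   sd = numeric(), cv = numeric(), sv = numeric(),
                   arv = numeric(), dmm = numeric(), msc = numeric())
  } else {
    accepted_rows |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(summarize_ppv(.data$pp), .groups = "drop") |>
      dplyr::select(-"n_readings")
  }
  dplyr::left_join(verdict, idx, by = "patient_id")
}

#' Read a BP readings CSV
#'
#' Expected header: `patient_id,time_offset_hours,sbp,dbp`, one row per
#' reading, decimal point, UTF-8. Rows need not be pre-sorted; they are
#' sorted by patient and time on load. Tied time offsets within a patient
#' are an error.
#'
#' @param path Path to the CSV file.
#' @return A sorted tibble of readings.
#' @export
read_bp_readings <- function(path) {
  readings <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      time_offset_hours = readr::col_double(),
      sbp = readr::col_double(),
      dbp = readr::col_double()
    )
  )
  readings <- check_readings(readings)
  readings <- dplyr::arrange(readings, .data$patient_id,
                             .data$time_offset_hours)
  dup <- readings |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::filter(duplicated(.data$time_offset_hours)) |>
    dplyr::ungroup()
  if (nrow(dup) > 0L) {
    ppv_abort("duplicated time offsets within a patient on load",
              "ppv_bad_input")
  }
  readings
}
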