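# Synthetic cohort generator: serial PP readings with controllable
# within-patient fluctuation and outcomes drawn from a logistic link to a
# chosen PPV index. Emulates the structure of a 203-patient acute
# ischemic stroke cohort monitored 4-hourly over 72 h.

#' Specification of a synthetic stroke cohort
#'
#' Defaults describe a cohort of 203 acute ischemic stroke patients with
#' 4-hourly blood-pressure readings over 72 h (19 nominal slots), a
#' population pulse-pressure mean of 57 +/- 14 mmHg across patients,
#' within-patient fluctuation scales drawn uniformly from 5-25 mmHg, and
#' unfavorable 30-day outcome generated from a logistic model on the
#' realized PP SD index with an odds ratio of 4.8 per 10 mmHg, giving
#' roughly 40% unfavorable outcomes.
#'
#' @param n_patients Cohort size (>= 10). Default 203.
#' @param thrombolysis_rate Probability of rtPA treatment. Default 0.20.
#' @param window_hours,interval_hours Monitoring window and nominal
#'   reading spacing (h). Defaults 72 and 4.
#' @param pp_mean_population,pp_between_sd Mean and SD (mmHg) of the
#'   across-patient distribution of per-patient mean PP. Defaults 57, 14.
#' @param pp_within_sd_range Length-2 range (mmHg) from which each
#'   patient's within-series fluctuation SD is drawn uniformly.
#'   Default `c(5, 25)`.
#' @param drift_per_day Linear PP trend in mmHg per 24 h. Default 0.
#' @param ar1_rho Lag-1 autocorrelation of within-patient fluctuations
#'   (0 = independent Gaussian noise, the default).
#' @param missing_rate Per-slot dropout probability. Default 0.05.
#' @param outcome_model List with elements `index` (which PPV index drives
#'   outcome; default `"sd"`), `beta_per_mmHg` (log-odds per mmHg of the
#'   index; default `log(4.8)/10`), `intercept` (`NULL` = solved so the
#'   expected unfavorable prevalence is `target_prevalence` at the
#'   midpoint index value), `target_prevalence` (default 0.40),
#'   `beta_age`, `beta_female`, `beta_mi`, `beta_thrombolysed`,
#'   `beta_mean_pp` (all default 0; age and mean PP enter centred at
#'   their population means), and `intercept_shift_90d` (added to the
#'   90-day linear predictor; default -0.1, slightly fewer late
#'   unfavorable outcomes).
#' @param covariates List of marginal covariate distributions: `age_mean`,
#'   `age_sd`, and Bernoulli rates `female`, `diabetes`, `hypertension`,
#'   `atrial_fibrillation`, `heart_failure`, `myocardial_infarction`,
#'   `prior_stroke`, `smoking`, `coronary_heart_disease`.
#' @param seed Integer seed; mandatory, the cohort is a pure function of
#'   the spec including the seed.
#' @return An object of class `cohort_spec` (a validated list with all
#'   defaults resolved).
#' @export
cohort_spec <- function(n_patients = 203,
                        thrombolysis_rate = 0.20,
                        window_hours = 72,
                        interval_hours = 4,
                        pp_mean_population = 57,
                        pp_between_sd = 14,
                        pp_within_sd_range = c(5, 25),
                        drift_per_day = 0,
                        ar1_rho = 0,
                        missing_rate = 0.05,
                        outcome_model = list(),
                        covariates = list(),
                        seed) {
  if (missing(seed) || is.null(seed)) {
    ppv_abort("`seed` is mandatory for reproducibility", "ppv_bad_spec")
  }
  if (n_patients < 10) {
    ppv_abort("degenerate spec: n_patients must be >= 10", "ppv_bad_spec")
  }
  rates <- c(thrombolysis_rate, missing_rate)
  if (any(rates < 0 | rates > 1)) {
    ppv_abort("rates must lie in [0, 1]", "ppv_bad_spec")
  }
  if (pp_between_sd <= 0 || any(pp_within_sd_range <= 0) ||
      pp_within_sd_range[1] > pp_within_sd_range[2]) {
    ppv_abort("fluctuation scales must be positive (lo <= hi)",
              "ppv_bad_spec")
  }
  if (abs(ar1_rho) >= 1) {
    ppv_abort("`ar1_rho` must lie in (-1, 1)", "ppv_bad_spec")
  }
  om <- utils::modifyList(list(
    index = "sd", beta_per_mmHg = log(4.8) / 10, intercept = NULL,
    target_prevalence = 0.40, beta_age = 0, beta_female = 0, beta_mi = 0,
    beta_thrombolysed = 0, beta_mean_pp = 0, intercept_shift_90d = -0.1
  ), outcome_model)
  if (om$target_prevalence <= 0 || om$target_prevalence >= 1) {
    ppv_abort("degenerate spec: target prevalence must be inside (0, 1)",
              "ppv_bad_spec")
  }
  if (is.null(om$intercept)) {
    om$intercept <- stats::qlogis(om$target_prevalence) -
      om$beta_per_mmHg * mean(pp_within_sd_range)
  }
  cv <- utils::modifyList(list(
    age_mean = 68, age_sd = 13, female = 0.47, diabetes = 0.21,
    hypertension = 0.66, atrial_fibrillation = 0.24, heart_failure = 0.09,
    myocardial_infarction = 0.14, prior_stroke = 0.20, smoking = 0.19,
    coronary_heart_disease = 0.26
  ), covariates)
  structure(
    list(n_patients = as.integer(n_patients),
         thrombolysis_rate = thrombolysis_rate,
         window_hours = window_hours, interval_hours = interval_hours,
         pp_mean_population = pp_mean_population,
         pp_between_sd = pp_between_sd,
         pp_within_sd_range = pp_within_sd_range,
         drift_per_day = drift_per_day, ar1_rho = ar1_rho,
         missing_rate = missing_rate, outcome_model = om,
         covariates = cv, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# truncated normal by redraw; deterministic under the active seed
rnorm_min <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < lower)) {
    i <- which(x < lower)
    x[i] <- stats::rnorm(length(i), mean, sd)
  }
  x
}

#' Generate a synthetic stroke cohort
#'
#' Simulates, per patient: baseline covariates; a per-patient mean PP and
#' within-patient fluctuation SD; 4-hourly PP readings as mean + noise
#' (independent Gaussian or AR(1)) + optional drift, with per-slot
#' dropout; SBP/DBP reconstructed around a drawn mean arterial pressure
#' as `sbp = map + 2/3 pp`, `dbp = map - 1/3 pp`, so `sbp - dbp`
#' reproduces the simulated PP exactly. The unfavorable outcome is drawn
#' from a Bernoulli with logit equal to the spec's linear predictor
#' evaluated at the *realized* PPV index of the simulated series; mRS
#' (0-6) and admission NIHSS are then derived from the same latent
#' severity so that the outcome bands are internally consistent.
#'
#' @param spec A [cohort_spec()].
#' @return A list with class `ppv_cohort`: `cohort` (one row per patient,
#'   baseline covariates, admission BP, `mrs_30d`, `mrs_90d`), `readings`
#'   (one row per BP reading), and the resolved `spec`.
#' @examples
#' sim <- generate_cohort(cohort_spec(n_patients = 20, seed = 1))
#' dplyr::count(sim$cohort, mrs_30d >= 3)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_patients
  cv <- spec$covariates
  om <- spec$outcome_model
  id <- sprintf("P%04d", seq_len(n))

  age <- round(rnorm_min(n, cv$age_mean, cv$age_sd, 18))
  female <- stats::rbinom(n, 1, cv$female)
  comorb <- lapply(
    cv[c("diabetes", "hypertension", "atrial_fibrillation", "heart_failure",
         "myocardial_infarction", "prior_stroke", "smoking",
         "coronary_heart_disease")],
    function(p) stats::rbinom(n, 1, p)
  )
  thrombolysed <- stats::rbinom(n, 1, spec$thrombolysis_rate)

  # admission pressures (single measurement at arrival, before the series)
  adm_pp <- rnorm_min(n, 63, 20, 10)
  adm_dbp <- rnorm_min(n, 91, 15, 40)

  # per-patient series parameters
  mu <- rnorm_min(n, spec$pp_mean_population, spec$pp_between_sd, 25)
  wsd <- stats::runif(n, spec$pp_within_sd_range[1],
                      spec$pp_within_sd_range[2])
  map_pat <- stats::rnorm(n, 112, 10)

  slots <- seq(0, spec$window_hours, by = spec$interval_hours)
  k <- length(slots)
  # innovations: k x n, AR(1) across rows when requested, unit variance
  z <- matrix(stats::rnorm(k * n), nrow = k)
  if (spec$ar1_rho != 0) {
    e <- z
    for (t in 2:k) {
      e[t, ] <- spec$ar1_rho * e[t - 1, ] +
        sqrt(1 - spec$ar1_rho^2) * z[t, ]
    }
    z <- e
  }
  pp_mat <- sweep(sweep(z, 2, wsd, `*`), 2, mu, `+`) +
    spec$drift_per_day * slots / 24
  pp_mat <- pmax(pp_mat, 5)  # floor at a physiologically minimal PP

  keep <- matrix(stats::rbinom(k * n, 1, 1 - spec$missing_rate) == 1,
                 nrow = k)
  few <- colSums(keep) < 2L
  keep[1:2, few] <- TRUE  # a series needs at least one successive pair

  map_noise <- matrix(stats::rnorm(k * n, 0, 5), nrow = k)
  map_mat <- sweep(map_noise, 2, map_pat, `+`)

  readings <- tibble::tibble(
    patient_id = rep(id, each = k),
    time_offset_hours = rep(slots, times = n),
    pp = as.vector(pp_mat),
    map = as.vector(map_mat),
    kept = as.vector(keep)
  ) |>
    dplyr::filter(.data$kept) |>
    dplyr::mutate(
      sbp = .data$map + 2 / 3 * .data$pp,
      dbp = .data$map - 1 / 3 * .data$pp
    ) |>
    dplyr::select("patient_id", "time_offset_hours", "sbp", "dbp")

  # realized indices of the simulated (post-dropout) series drive outcome
  idx <- readings |>
    derive_pulse_pressure() |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(summarize_ppv(.data$pp), .groups = "drop")
  idx <- idx[match(id, idx$patient_id), ]
  driver <- idx[[om$index]]
  if (is.null(driver)) {
    ppv_abort(sprintf("unknown outcome-model index '%s'", om$index),
              "ppv_bad_spec")
  }

  lp <- om$intercept + om$beta_per_mmHg * driver +
    om$beta_age * (age - cv$age_mean) +
    om$beta_female * female +
    om$beta_mi * comorb$myocardial_infarction +
    om$beta_thrombolysed * thrombolysed +
    om$beta_mean_pp * (idx$mean_pp - spec$pp_mean_population)

  # shared logistic latent: u < plogis(lp) is Bernoulli(plogis(lp)), and
  # the same u keeps the 30- and 90-day outcomes strongly correlated
  u <- stats::runif(n)
  sev30 <- lp - stats::qlogis(u)            # > 0 iff unfavorable at 30 d
  sev90 <- lp + om$intercept_shift_90d - stats::qlogis(u)
  mrs_from_latent <- function(s) {
    ifelse(s > 0,
           pmin(6, 3 + floor(s)),
           pmax(0, 2 + ceiling(s)))
  }
  mrs_30d <- as.integer(mrs_from_latent(sev30))
  mrs_90d <- as.integer(mrs_from_latent(sev90))
  nihss <- as.integer(pmin(42, pmax(0, round(
    10 + 2.5 * sev30 + stats::rnorm(n, 0, 3)
  ))))

  cohort <- tibble::tibble(
    patient_id = id, age = age, female = female,
    diabetes = comorb$diabetes, hypertension = comorb$hypertension,
    atrial_fibrillation = comorb$atrial_fibrillation,
    heart_failure = comorb$heart_failure,
    myocardial_infarction = comorb$myocardial_infarction,
    prior_stroke = comorb$prior_stroke, smoking = comorb$smoking,
    coronary_heart_disease = comorb$coronary_heart_disease,
    nihss_admission = nihss, thrombolysed = thrombolysed,
    admission_sbp = adm_dbp + adm_pp, admission_dbp = adm_dbp,
    admission_pp = adm_pp,
    mrs_30d = mrs_30d, mrs_90d = mrs_90d
  )
  structure(list(cohort = cohort, readings = readings, spec = spec),
            class = "ppv_cohort")
}

#' @export
print.ppv_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic stroke cohort: %d patients, %d BP readings (seed %d)\n",
    nrow(x$cohort), nrow(x$readings), x$spec$seed
  ))
  invisible(x)
}

fixture_registry <- c("tiny_cohort_n20", "worked_series", "null_cohort")

#' Deterministic packaged fixtures
#'
#' Small, versioned datasets used in examples and tests:
#' \describe{
#'   \item{worked_series}{a single 4-reading BP series whose PP sequence
#'     is 60, 70, 50, 60 mmHg — the worked example for the PPV formulas.}
#'   \item{tiny_cohort_n20}{a 20-patient synthetic cohort with both
#'     outcome classes present, for smoke tests.}
#'   \item{null_cohort}{a 200-patient cohort generated with a zero index
#'     effect (outcome independent of PPV).}
#' }
#'
#' @param name Fixture name from the registry above.
#' @return `worked_series`: a readings tibble. Cohort fixtures: a
#'   `ppv_cohort` list (see [generate_cohort()]).
#' @examples
#' derive_pulse_pressure(make_fixture("worked_series"))$pp
#' @export
make_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% fixture_registry) {
    ppv_abort(
      sprintf("unknown fixture '%s'; available: %s",
              if (is.character(name) && length(name) == 1L) name else "?",
              paste(fixture_registry, collapse = ", ")),
      "ppv_unknown_fixture"
    )
  }
  switch(
    name,
    worked_series = tibble::tibble(
      patient_id = "W001",
      time_offset_hours = c(0, 4, 8, 12),
      sbp = c(140, 150, 130, 140),
      dbp = c(80, 80, 80, 80)
    ),
    tiny_cohort_n20 = generate_cohort(
      cohort_spec(n_patients = 20, missing_rate = 0, seed = 2020L)
    ),
    null_cohort = generate_cohort(
      cohort_spec(n_patients = 200,
                  outcome_model = list(beta_per_mmHg = 0),
                  seed = 7L)
    )
  )
}
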