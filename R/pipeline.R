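# End-to-end pipeline: ingest -> sampling validation -> PPV indices ->
# outcome labelling -> correlation / group-difference / logistic / ROC
# tables, with machine- and display-precision writers and an exclusion
# flowchart file.

#' Analysis configuration
#'
#' @param cohort_file,readings_file Paths to the cohort and BP-readings
#'   CSV files.
#' @param out_dir Output directory (created if absent).
#' @param policy A [sampling_policy()].
#' @param horizons Outcome horizons to analyse, subset of
#'   `c("30d", "90d")`.
#' @param subgroup `"all"`, `"thrombolysed"` or `"non_thrombolysed"`:
#'   which patients enter the logistic and ROC analyses.
#' @param indices PPV index columns to analyse. Default the six
#'   variability indices; mean PP is always carried along as a covariate
#'   and correlation row.
#' @param models Logistic models to fit, subset of `c("M1","M2","M3","M4")`.
#' @param alpha Significance level for reporting. Default 0.05.
#' @param seed Integer seed recorded in the run log (the default analysis
#'   path is deterministic and does not consume randomness).
#' @param write_figures Write ROC curve plots (PNG) per index/horizon.
#'   Default `FALSE`; result tables are always written.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(cohort_file, readings_file, out_dir,
                            policy = sampling_policy(),
                            horizons = c("30d", "90d"),
                            subgroup = c("all", "thrombolysed",
                                         "non_thrombolysed"),
                            indices = c("cv", "sv", "msc", "dmm", "arv",
                                        "sd"),
                            models = c("M1", "M2", "M3", "M4"),
                            alpha = 0.05, seed = 1L,
                            write_figures = FALSE) {
  subgroup <- match.arg(subgroup)
  horizons <- match.arg(horizons, several.ok = TRUE)
  models <- match.arg(models, several.ok = TRUE)
  if (!(alpha > 0 && alpha < 1)) {
    ppv_abort("`alpha` must lie in (0, 1)", "ppv_bad_config")
  }
  if (length(indices) < 1L) {
    ppv_abort("at least one index must be analysed", "ppv_bad_config")
  }
  structure(
    list(cohort_file = cohort_file, readings_file = readings_file,
         out_dir = out_dir, policy = policy, horizons = horizons,
         subgroup = subgroup, indices = indices, models = models,
         alpha = alpha, seed = as.integer(seed),
         write_figures = isTRUE(write_figures)),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from JSON or YAML
#'
#' Unknown fields are rejected; missing fields take the
#' [analysis_config()] defaults. The `policy` field, if present, is a
#' mapping with the [sampling_policy()] fields.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("cohort_file", "readings_file", "out_dir", "policy",
             "horizons", "subgroup", "indices", "models", "alpha",
             "seed", "write_figures")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0L) {
    ppv_abort(paste0("unknown config field(s): ",
                     paste(extra, collapse = ", ")),
              "ppv_bad_config")
  }
  if (!is.null(raw$policy)) {
    raw$policy <- do.call(sampling_policy, raw$policy)
  }
  do.call(analysis_config, raw)
}

#' Read a cohort CSV
#'
#' @param path Path to a cohort CSV (one row per patient; see
#'   [generate_cohort()] for the column schema).
#' @return A tibble with `patient_id` as character.
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  if (!"patient_id" %in% names(cohort)) {
    ppv_abort("cohort file is missing `patient_id`", "ppv_bad_input")
  }
  cohort$patient_id <- as.character(cohort$patient_id)
  if (anyDuplicated(cohort$patient_id)) {
    ppv_abort("duplicated patient_id in cohort file", "ppv_bad_input")
  }
  cohort
}

#' Write a simulated cohort to disk
#'
#' Writes `cohort.csv`, `bp_readings.csv` and `spec.json` (the resolved
#' generator spec including the seed) to a directory.
#'
#' @param sim A `ppv_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort_files <- function(sim, dir) {
  stopifnot(inherits(sim, "ppv_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("cohort.csv", "bp_readings.csv", "spec.json"))
  readr::write_csv(sim$cohort, paths[1])
  readr::write_csv(sim$readings, paths[2])
  jsonlite::write_json(unclass(sim$spec), paths[3], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(paths)
}

table1_variables <- c(
  "age", "female", "diabetes", "hypertension", "atrial_fibrillation",
  "heart_failure", "myocardial_infarction", "prior_stroke", "smoking",
  "coronary_heart_disease", "nihss_admission", "thrombolysed",
  "admission_sbp", "admission_dbp", "admission_pp"
)

# Baseline table: outcome groups compared variable-by-variable with the
# Mann-Whitney U test (including binary variables, matching the report
# style of the baseline table; chi-square is available via `binary_test`).
baseline_table <- function(cohort, horizon, binary_test = c("u", "chisq")) {
  binary_test <- match.arg(binary_test)
  cohort <- label_outcomes(cohort, "dichotomized", horizon)
  out <- cohort[[paste0("unfavorable_", horizon)]]
  vars <- intersect(table1_variables, names(cohort))
  purrr::map_dfr(vars, function(v) {
    x <- cohort[[v]]
    fav <- x[out == 0]; unf <- x[out == 1]
    p <- if (binary_test == "chisq" && all(x %in% c(0, 1))) {
      suppressWarnings(stats::chisq.test(table(x, out))$p.value)
    } else {
      mann_whitney_u(fav, unf)$p_value
    }
    tibble::tibble(
      variable = v, horizon = horizon,
      favorable_mean = mean(fav), favorable_sd = stats::sd(fav),
      unfavorable_mean = mean(unf), unfavorable_sd = stats::sd(unf),
      n_favorable = length(fav), n_unfavorable = length(unf),
      p_value = p
    )
  })
}

# Correlation table: Spearman rho of each index against the raw mRS score
# per horizon, in the thrombolysis / non-thrombolysis subgroups and the
# whole cohort, plus the U test comparing index levels between the two
# treatment subgroups.
correlation_table <- function(cohort, indices, horizons) {
  rows <- c(indices, "mean_pp")
  purrr::map_dfr(rows, function(ix) {
    groups <- list(
      thrombolysis = dplyr::filter(cohort, .data$thrombolysed == 1),
      non_thrombolysis = dplyr::filter(cohort, .data$thrombolysed == 0),
      all = cohort
    )
    u_p <- if (nrow(groups$thrombolysis) > 0 &&
               nrow(groups$non_thrombolysis) > 0) {
      mann_whitney_u(groups$thrombolysis[[ix]],
                     groups$non_thrombolysis[[ix]])$p_value
    } else {
      NA_real_
    }
    purrr::map_dfr(names(groups), function(g) {
      dat <- groups[[g]]
      purrr::map_dfr(horizons, function(h) {
        mrs <- dat[[paste0("mrs_", h)]]
        res <- tryCatch(spearman_rho(dat[[ix]], mrs),
                        error = function(e) NULL)
        tibble::tibble(
          index = ix, group = g, horizon = h, n = nrow(dat),
          index_mean = mean(dat[[ix]]), index_sd = stats::sd(dat[[ix]]),
          rho = if (is.null(res)) NA_real_ else res$rho,
          p_value = if (is.null(res)) NA_real_ else res$p_value,
          u_test_p_thromb_vs_non = u_p
        )
      })
    })
  })
}

round_df <- function(df, digits_map) {
  for (col in names(digits_map)) {
    if (col %in% names(df)) df[[col]] <- round(df[[col]], digits_map[[col]])
  }
  df
}

write_table_pair <- function(df, out_dir, stem, digits_map) {
  machine <- file.path(out_dir, paste0(stem, ".csv"))
  display <- file.path(out_dir, paste0(stem, "_display.csv"))
  readr::write_csv(df, machine)
  readr::write_csv(round_df(df, digits_map), display)
  c(machine, display)
}

#' Run the full PPV analysis pipeline
#'
#' Reads the cohort and readings files, applies the sampling policy,
#' computes per-patient PPV indices, labels outcomes, and writes
#' per-horizon analogues of the baseline, correlation, logistic-model and
#' ROC tables, an exclusion flowchart count file, and a run log. Each
#' table is written at full machine precision and as a rounded display
#' version. The analysis path is deterministic: the same config and data
#' give byte-identical tables.
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list with the result tibbles (`baseline`,
#'   `correlations`, `models`, `roc`), the `exclusions` table, the
#'   per-patient `analysis_table`, and the written file `paths`.
#' @export
run_ppv_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- read_cohort(config$cohort_file)
  readings <- read_bp_readings(config$readings_file)
  n_in <- nrow(cohort)

  idx <- ppv_indices(readings, config$policy)
  merged <- dplyr::left_join(cohort, idx, by = "patient_id")
  merged$reason[is.na(merged$n_readings)] <- "too_few_readings"
  merged$accepted[is.na(merged$accepted)] <- FALSE
  mrs_cols <- paste0("mrs_", config$horizons)
  missing_fu <- !stats::complete.cases(merged[mrs_cols])
  excl_cat <- dplyr::case_when(
    !merged$accepted ~ merged$reason,
    missing_fu ~ "missing_followup",
    TRUE ~ NA_character_
  )
  analysis_table <- merged[is.na(excl_cat), , drop = FALSE]
  cats <- c("too_few_readings", "gap_too_large", "missing_followup")
  exclusions <- tibble::tibble(
    category = c(cats, "analyzed", "total"),
    count = c(unname(vapply(cats,
                            function(ct) sum(excl_cat == ct, na.rm = TRUE),
                            integer(1))),
              nrow(analysis_table), n_in)
  )

  if (nrow(analysis_table) < 2L) {
    ppv_abort("fewer than 2 patients pass sampling validation",
              "ppv_data_error")
  }

  sub <- switch(config$subgroup,
                all = analysis_table,
                thrombolysed = dplyr::filter(analysis_table,
                                             .data$thrombolysed == 1),
                non_thrombolysed = dplyr::filter(analysis_table,
                                                 .data$thrombolysed == 0))

  baseline <- purrr::map_dfr(config$horizons,
                             function(h) baseline_table(analysis_table, h))
  correlations <- correlation_table(analysis_table, config$indices,
                                    config$horizons)

  models <- tibble::tibble()
  roc <- tibble::tibble()
  skipped <- character()
  if (nrow(sub) < 2L ||
      any(vapply(config$horizons, function(h) {
        length(unique(dichotomize_mrs(sub[[paste0("mrs_", h)]]))) < 2L
      }, logical(1)))) {
    skipped <- config$subgroup
    rlang::warn(sprintf(
      "subgroup '%s' skipped for models/ROC: too few patients or single-class outcome",
      config$subgroup))
  } else {
    models <- purrr::map_dfr(config$horizons, function(h) {
      purrr::map_dfr(config$indices, function(ix) {
        run_model_suite(sub, ix, h, models = config$models)
      })
    })
    roc <- purrr::map_dfr(config$horizons, function(h) {
      lab <- dichotomize_mrs(sub[[paste0("mrs_", h)]])
      purrr::map_dfr(config$indices, function(ix) {
        r <- roc_analysis(sub[[ix]], lab)
        if (config$write_figures) {
          fig <- file.path(config$out_dir,
                           sprintf("roc_%s_%s.png", ix, h))
          ggplot2::ggsave(fig, autoplot(r), width = 5, height = 5,
                          dpi = 150)
        }
        dplyr::bind_cols(tibble::tibble(index = ix, horizon = h),
                         glance(r))
      })
    })
  }

  paths <- c(
    write_table_pair(baseline, config$out_dir, "table1_baseline",
                     list(favorable_mean = 1, favorable_sd = 1,
                          unfavorable_mean = 1, unfavorable_sd = 1,
                          p_value = 3)),
    write_table_pair(correlations, config$out_dir, "table2_correlations",
                     list(index_mean = 1, index_sd = 1, rho = 3,
                          p_value = 3, u_test_p_thromb_vs_non = 3)),
    if (nrow(models)) {
      write_table_pair(models, config$out_dir, "table3_models",
                       list(or = 3, ci_low = 3, ci_high = 3, p_value = 3))
    },
    if (nrow(roc)) {
      write_table_pair(roc, config$out_dir, "table4_roc",
                       list(auc = 3, ci_low = 3, ci_high = 3, cutoff = 0,
                            youden_index = 2, sensitivity = 2,
                            specificity = 2, p_value = 3))
    }
  )
  excl_path <- file.path(config$out_dir, "exclusions.csv")
  readr::write_csv(exclusions, excl_path)

  log_lines <- c(
    sprintf("ppvstroke version: %s", utils::packageVersion("ppvstroke")),
    sprintf("config hash: %s",
            rlang::hash(unclass(config)[setdiff(names(unclass(config)),
                                                "out_dir")])),
    sprintf("seed: %d", config$seed),
    sprintf("patients in / analyzed: %d / %d", n_in, nrow(analysis_table)),
    sprintf("subgroup: %s (n = %d)%s", config$subgroup, nrow(sub),
            if (length(skipped)) " [models skipped]" else ""),
    if (nrow(models)) {
      sprintf("models converged: %d / %d",
              sum(models$converged, na.rm = TRUE), nrow(models))
    } else {
      "models converged: 0 / 0"
    }
  )
  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(log_lines, log_path)

  invisible(list(
    baseline = baseline, correlations = correlations, models = models,
    roc = roc, exclusions = exclusions, analysis_table = analysis_table,
    paths = c(paths, excl_path, log_path)
  ))
}
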