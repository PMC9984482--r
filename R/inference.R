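# Inference battery: Spearman rank correlation, Mann-Whitney U, logistic
# models M1-M4 with ORs per 10 mmHg, and ROC analysis (DeLong CI, Youden).

#' Spearman rank correlation
#'
#' Pearson correlation of the midrank-transformed vectors, with the
#' two-sided p-value from the t approximation on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return A one-row tibble: `rho`, `statistic` (t), `p_value`, `n`.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)) # rho = 0.6
#' @export
spearman_rho <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n != length(y)) ppv_abort("`x` and `y` lengths differ", "ppv_bad_input")
  if (n < 3L) ppv_abort("need at least 3 paired observations", "ppv_bad_input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    ppv_abort("Spearman rho is undefined for a constant vector",
              "ppv_degenerate")
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    tstat <- sign(rho) * Inf
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(rho = rho, statistic = tstat, p_value = p, n = n)
}

#' Mann-Whitney U test
#'
#' Rank-sum U with midranks for ties, reported as `u = min(Ua, Ub)`.
#' The two-sided p-value uses exact enumeration of group assignments when
#' both groups have at most `exact_max` observations, and otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric vectors, both nonempty.
#' @param exact_max Largest per-group size for exact enumeration. Default 8.
#' @return A one-row tibble: `u` (min of the two U statistics), `u_first`
#'   (U of sample `a`: concordant pairs where `a > b`, ties counted 1/2),
#'   `p_value`, `method`, `n1`, `n2`.
#' @examples
#' mann_whitney_u(c(1, 3, 5), c(2, 4, 6)) # u = 3
#' @export
mann_whitney_u <- function(a, b, exact_max = 8L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) {
    ppv_abort("both groups must be nonempty", "ppv_bad_input")
  }
  pooled <- c(a, b)
  r <- rank(pooled)
  ua <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ub <- n1 * n2 - ua
  u <- min(ua, ub)
  use_exact <- n1 <= exact_max && n2 <= exact_max
  if (use_exact) {
    n <- n1 + n2
    idx <- utils::combn(n, n1)
    ua_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    umin_all <- pmin(ua_all, n1 * n2 - ua_all)
    p <- mean(umin_all <= u + 1e-9)
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - n1 * n2 / 2 + 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z))
    }
    method <- "normal_approx"
  }
  tibble::tibble(u = u, u_first = ua, p_value = p, method = method,
                 n1 = n1, n2 = n2)
}

#' Logistic regression with odds ratios per predictor step
#'
#' Binomial maximum-likelihood fit (IRLS, coefficient tolerance 1e-8, at
#' most 100 iterations) of `outcome ~ predictor + covariates`. The
#' predictor of interest is divided by `per` before fitting, so its
#' exponentiated coefficient is the odds ratio per `per`-unit increase
#' (default: per 10 mmHg, the reporting convention for PPV indices).
#' Confidence intervals are Wald: `exp(beta +/- 1.96 se)`.
#'
#' @param data Data frame holding the model variables.
#' @param outcome Name of the 0/1 outcome column.
#' @param predictor Name of the (numeric) predictor of interest.
#' @param covariates Character vector of additional covariate columns.
#' @param per Unit step for the odds ratio of `predictor`. Default 10.
#' @return An object of class `ppv_logit`; see [tidy.ppv_logit()] and
#'   [glance.ppv_logit()].
#' @export
fit_logistic <- function(data, outcome, predictor,
                         covariates = character(), per = 10) {
  vars <- c(outcome, predictor, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0L) {
    ppv_abort(paste0("data is missing column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "ppv_bad_input")
  }
  df <- tibble::as_tibble(data)[vars]
  n_in <- nrow(df)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n_dropped <- n_in - nrow(df)
  y <- df[[outcome]]
  if (!all(y %in% c(0, 1))) {
    ppv_abort("outcome must be coded 0/1", "ppv_bad_outcome")
  }
  if (length(unique(y)) < 2L) {
    ppv_abort("degenerate outcome: only one class present",
              "ppv_degenerate")
  }
  df[[predictor]] <- df[[predictor]] / per
  rhs <- paste(c(sprintf("`%s`", predictor),
                 sprintf("`%s`", covariates)), collapse = " + ")
  fml <- stats::as.formula(sprintf("`%s` ~ %s", outcome, rhs))
  mm <- stats::model.matrix(fml, data = df)
  if (qr(mm)$rank < ncol(mm)) {
    ppv_abort("singular design matrix (constant or collinear predictors)",
              "ppv_singular")
  }
  if (nrow(df) <= ncol(mm)) {
    ppv_abort("more parameters than usable observations", "ppv_bad_input")
  }
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) invokeRestart("muffleWarning")
  )
  mu <- fit$fitted.values
  separated <- any(mu < 1e-8 | mu > 1 - 1e-8) ||
    any(abs(stats::coef(fit)) > 15)
  converged <- fit$converged && !separated
  est <- summary(fit)$coefficients
  rownames(est) <- gsub("`", "", rownames(est))
  term <- predictor
  beta <- est[term, "Estimate"]
  se <- est[term, "Std. Error"]
  structure(
    list(
      fit = fit, outcome = outcome, predictor = predictor,
      covariates = covariates, per = per,
      or = exp(beta), ci_low = exp(beta - 1.96 * se),
      ci_high = exp(beta + 1.96 * se),
      p_value = est[term, "Pr(>|z|)"],
      n_used = nrow(df), n_dropped = n_dropped,
      converged = converged, separated = separated
    ),
    class = "ppv_logit"
  )
}

#' @export
print.ppv_logit <- function(x, ...) {
  cat(sprintf(
    "Logistic fit: %s ~ %s%s\n  OR per %g: %.3f (95%% CI %.3f-%.3f), p = %.4g, n = %d%s\n",
    x$outcome, x$predictor,
    if (length(x$covariates)) paste0(" + ", paste(x$covariates, collapse = " + ")) else "",
    x$per, x$or, x$ci_low, x$ci_high, x$p_value, x$n_used,
    if (!x$converged) " [NOT CONVERGED / separated]" else ""
  ))
  invisible(x)
}

#' Tidy a logistic fit
#'
#' @param x A `ppv_logit` object.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`
#'   (log-odds), `std.error`, `statistic`, `p.value`, plus the odds ratio
#'   and Wald 95% bounds. The predictor-of-interest row is on the
#'   per-`per` scale.
#' @export
tidy.ppv_logit <- function(x, ...) {
  est <- unname(summary(x$fit)$coefficients)
  terms <- gsub("`", "", rownames(summary(x$fit)$coefficients))
  tibble::tibble(
    term = terms,
    estimate = est[, 1],
    std.error = est[, 2],
    statistic = est[, 3],
    p.value = est[, 4],
    odds.ratio = exp(est[, 1]),
    conf.low = exp(est[, 1] - 1.96 * est[, 2]),
    conf.high = exp(est[, 1] + 1.96 * est[, 2])
  )
}

#' Glance at a logistic fit
#'
#' @param x A `ppv_logit` object.
#' @param ... Unused.
#' @return A one-row tibble: odds ratio per step, Wald CI, p-value,
#'   sample sizes, deviance, AIC, convergence flag.
#' @export
glance.ppv_logit <- function(x, ...) {
  tibble::tibble(
    predictor = x$predictor, per = x$per,
    or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, n_used = x$n_used, n_dropped = x$n_dropped,
    deviance = x$fit$deviance, aic = x$fit$aic, converged = x$converged
  )
}

#' Logistic model suite M1-M4 for one PPV index
#'
#' Fits the four logistic models relating a PPV index to unfavorable
#' outcome at one horizon, each reporting the odds ratio per 10 mmHg
#' (per 10 percentage points for CV):
#' \describe{
#'   \item{M1}{unadjusted: outcome ~ index}
#'   \item{M2}{adjusted for thrombolysis and mean PP}
#'   \item{M3}{as M2, but the outcome is the severity-adjusted label}
#'   \item{M4}{M2 plus age, sex and history of myocardial infarction}
#' }
#' M1, M2 and M4 use the dichotomized mRS outcome. Per-model failures
#' (degenerate outcome, singular design) are captured in the `error`
#' column; the remaining models are still returned.
#'
#' @param cohort Cohort tibble containing the index column, `mrs_30d` /
#'   `mrs_90d`, `nihss_admission`, `thrombolysed`, `mean_pp`, `age`,
#'   `female`, `myocardial_infarction`.
#' @param index Name of the PPV index column (e.g. `"sd"`).
#' @param horizon `"30d"` or `"90d"`.
#' @param models Subset of `c("M1","M2","M3","M4")` to fit.
#' @param per Odds-ratio step (default 10 mmHg).
#' @return A tibble with one row per model: `model`, `predictor`,
#'   `horizon`, `outcome_rule`, `or`, `ci_low`, `ci_high`, `p_value`,
#'   `n_used`, `converged`, `error`.
#' @export
run_model_suite <- function(cohort, index, horizon = c("30d", "90d"),
                            models = c("M1", "M2", "M3", "M4"), per = 10) {
  horizon <- match.arg(horizon)
  models <- match.arg(models, several.ok = TRUE)
  cohort <- label_outcomes(cohort, "dichotomized", horizon)
  cohort <- label_outcomes(cohort, "severity_adjusted", horizon)
  dich <- paste0("unfavorable_", horizon)
  adj <- paste0("unfavorable_adj_", horizon)
  specs <- list(
    M1 = list(outcome = dich, covs = character(), rule = "dichotomized"),
    M2 = list(outcome = dich, covs = c("thrombolysed", "mean_pp"),
              rule = "dichotomized"),
    M3 = list(outcome = adj, covs = c("thrombolysed", "mean_pp"),
              rule = "severity_adjusted"),
    M4 = list(outcome = dich,
              covs = c("thrombolysed", "mean_pp", "age", "female",
                       "myocardial_infarction"),
              rule = "dichotomized")
  )
  purrr::map_dfr(models, function(m) {
    sp <- specs[[m]]
    res <- tryCatch(
      fit_logistic(cohort, sp$outcome, index, sp$covs, per = per),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      tibble::tibble(
        model = m, predictor = index, horizon = horizon,
        outcome_rule = sp$rule, or = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, p_value = NA_real_, n_used = NA_integer_,
        converged = FALSE, error = conditionMessage(res)
      )
    } else {
      tibble::tibble(
        model = m, predictor = index, horizon = horizon,
        outcome_rule = sp$rule, or = res$or, ci_low = res$ci_low,
        ci_high = res$ci_high, p_value = res$p_value,
        n_used = res$n_used, converged = res$converged,
        error = NA_character_
      )
    }
  })
}

#' ROC analysis with DeLong confidence interval and Youden cut-off
#'
#' Empirical ROC over the observed score values, with higher scores
#' predicting the positive (unfavorable) class. The AUC is the
#' Mann-Whitney concordance probability (ties counted 1/2, equal to the
#' trapezoid area); its variance, 95% CI and the test of AUC = 0.5 use
#' DeLong's placement-value method. Youden's index is the maximum of
#' sensitivity + specificity - 1 over thresholds of the form
#' "positive if score >= t"; the reported cut-off is the smallest
#' observed score attaining that maximum.
#'
#' @param scores Numeric predictor values (e.g. a PPV index, mmHg).
#' @param labels 0/1 class labels (1 = unfavorable); both classes must be
#'   present.
#' @return An object of class `ppv_roc` with fields `auc`, `auc_ci95`,
#'   `auc_se`, `youden_index`, `cutoff`, `sensitivity`, `specificity`,
#'   `p_value`, `n_pos`, `n_neg` and the ROC `curve` tibble.
#' @examples
#' roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
roc_analysis <- function(scores, labels) {
  keep <- stats::complete.cases(scores, labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(scores) != length(labels)) {
    ppv_abort("`scores` and `labels` lengths differ", "ppv_bad_input")
  }
  if (!all(labels %in% c(0, 1))) {
    ppv_abort("labels must be coded 0/1", "ppv_bad_outcome")
  }
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  n1 <- length(pos); n0 <- length(neg)
  if (n1 == 0L || n0 == 0L) {
    ppv_abort("both outcome classes must be present", "ppv_degenerate")
  }
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  # DeLong placement values
  psi <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  var_auc <- if (n1 > 1) stats::var(v10) / n1 else 0
  var_auc <- var_auc + if (n0 > 1) stats::var(v01) / n0 else 0
  se <- sqrt(var_auc)
  ci <- c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se)
       else if (auc == 0.5) 1 else 0
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  jmax <- max(j)
  at <- which(j >= jmax - 1e-12)
  best <- at[1L]  # thresholds ascending: ties break toward the lower value
  curve <- tibble::tibble(
    threshold = c(-Inf, thr),
    sensitivity = c(1, sens),
    specificity = c(0, spec),
    fpr = 1 - c(0, spec)
  )
  structure(
    list(auc = auc, auc_ci95 = ci, auc_se = se, youden_index = jmax,
         cutoff = thr[best], sensitivity = sens[best],
         specificity = spec[best], p_value = p,
         n_pos = n1, n_neg = n0, curve = curve),
    class = "ppv_roc"
  )
}

#' @export
print.ppv_roc <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f (95%% CI %.3f-%.3f), p = %.4g\n  Youden %.2f at cut-off %g (sens %.2f, spec %.2f); %d pos / %d neg\n",
    x$auc, x$auc_ci95[1], x$auc_ci95[2], x$p_value,
    x$youden_index, x$cutoff, x$sensitivity, x$specificity,
    x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' Tidy a ROC result
#'
#' @param x A `ppv_roc` object.
#' @param ... Unused.
#' @return The ROC curve as a tibble (`threshold`, `sensitivity`,
#'   `specificity`, `fpr`).
#' @export
tidy.ppv_roc <- function(x, ...) x$curve

#' Glance at a ROC result
#'
#' @param x A `ppv_roc` object.
#' @param ... Unused.
#' @return A one-row tibble: `auc`, `ci_low`, `ci_high`, `cutoff`,
#'   `youden_index`, `sensitivity`, `specificity`, `p_value`, `n_pos`,
#'   `n_neg`.
#' @export
glance.ppv_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, ci_low = x$auc_ci95[1], ci_high = x$auc_ci95[2],
    cutoff = x$cutoff, youden_index = x$youden_index,
    sensitivity = x$sensitivity, specificity = x$specificity,
    p_value = x$p_value, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Plot a ROC curve
#'
#' @param object A `ppv_roc` object.
#' @param ... Unused.
#' @return A ggplot of the empirical ROC curve with the chance diagonal
#'   and the Youden-optimal operating point.
#' @export
autoplot.ppv_roc <- function(object, ...) {
  pt <- tibble::tibble(fpr = 1 - object$specificity,
                       sensitivity = object$sensitivity)
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = pt, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.3f (95%% CI %.3f-%.3f)",
                      object$auc, object$auc_ci95[1], object$auc_ci95[2]),
      subtitle = sprintf("Youden %.2f at cut-off %g",
                         object$youden_index, object$cutoff)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ppv_roc
#' @param x A `ppv_roc` object.
#' @export
plot_roc <- function(x, ...) autoplot.ppv_roc(x, ...)
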