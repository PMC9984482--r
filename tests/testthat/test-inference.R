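test_that("Spearman rho matches rank algebra and base R", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_rho(1:3, c(30, 20, 10))$rho, -1)
  expect_equal(spearman_rho(1:4, c(2, 1, 4, 3))$rho, 0.6)
  expect_error(spearman_rho(c(1, 1, 1), 1:3), class = "ppv_degenerate")
  expect_error(spearman_rho(1:2, 1:2), class = "ppv_bad_input")

  withr::with_seed(11, {
    for (i in 1:20) {
      x <- rnorm(25)
      y <- 0.4 * x + rnorm(25)
      got <- spearman_rho(x, y)
      ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                              exact = FALSE))
      expect_equal(got$rho, unname(ref$estimate))
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
      # invariance under strictly monotone transforms
      expect_equal(spearman_rho(exp(x), y)$rho, got$rho)
      expect_equal(spearman_rho(x, y^3)$rho, got$rho)
    }
  })
})

test_that("Mann-Whitney U matches brute-force pair counting", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$u, 0)
  expect_equal(mann_whitney_u(c(1, 3, 5), c(2, 4, 6))$u, 3)
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p_value, 1, tolerance = 0.05)
  expect_error(mann_whitney_u(numeric(0), 1:3), class = "ppv_bad_input")

  withr::with_seed(21, {
    for (i in 1:30) {
      a <- sample(1:10, sample(2:8, 1), replace = TRUE)
      b <- sample(1:10, sample(2:8, 1), replace = TRUE)
      got <- mann_whitney_u(a, b)
      ua <- oracle_u_first(a, b)
      expect_equal(got$u_first, ua)
      expect_equal(got$u, min(ua, length(a) * length(b) - ua))
      expect_equal(got$method, "exact")
      # base R reports the U of the first sample
      ref <- suppressWarnings(stats::wilcox.test(a, b))
      expect_equal(unname(ref$statistic), ua)
    }
  })
})

test_that("large-sample U p-values agree with the corrected normal approximation", {
  withr::with_seed(22, {
    for (i in 1:10) {
      a <- rnorm(30); b <- rnorm(25, 0.3)
      got <- mann_whitney_u(a, b)
      expect_equal(got$method, "normal_approx")
      ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("logistic fit reproduces the 2x2 cross-product odds ratio", {
  dat <- tibble::tibble(
    y = c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20)),
    x = c(rep(1, 30), rep(0, 30))
  )
  fit <- fit_logistic(dat, "y", "x", per = 1)
  expect_equal(fit$or, 4.0, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lt(fit$ci_low, fit$or)
  expect_gt(fit$ci_high, fit$or)
})

test_that("odds ratio per 10 mmHg equals exp(10 * per-mmHg coefficient)", {
  coh <- analysis_cohort(seed = 3)
  coh$y <- dichotomize_mrs(coh$mrs_30d)
  per10 <- fit_logistic(coh, "y", "sd", per = 10)
  per1 <- fit_logistic(coh, "y", "sd", per = 1)
  expect_equal(per10$or, exp(10 * log(per1$or)), tolerance = 1e-8)
  # same fitted probabilities regardless of predictor scaling
  expect_equal(per10$fit$fitted.values, per1$fit$fitted.values,
               tolerance = 1e-8)
  # OR of the index is invariant to affine shifts of another covariate
  shifted <- dplyr::mutate(coh, mean_pp = mean_pp + 100)
  f1 <- fit_logistic(coh, "y", "sd", covariates = "mean_pp")
  f2 <- fit_logistic(shifted, "y", "sd", covariates = "mean_pp")
  expect_equal(f1$or, f2$or, tolerance = 1e-8)
})

test_that("degenerate logistic designs are rejected or flagged", {
  dat <- tibble::tibble(y = rep(c(0, 1), 20), x = rnorm(40))
  dat$x2 <- dat$x
  expect_error(fit_logistic(dat, "y", "x", covariates = "x2"),
               class = "ppv_singular")
  dat$const <- 5
  expect_error(fit_logistic(dat, "y", "const"), class = "ppv_singular")
  expect_error(fit_logistic(dplyr::mutate(dat, y = 1), "y", "x"),
               class = "ppv_degenerate")
  # perfect separation is flagged, not silently reported
  sep <- tibble::tibble(y = rep(c(0, 1), each = 20),
                        x = c(rnorm(20, 0), rnorm(20, 50)))
  fit <- fit_logistic(sep, "y", "x", per = 1)
  expect_false(fit$converged)
})

test_that("tidy/glance expose the fitted logistic model", {
  coh <- analysis_cohort(seed = 4)
  coh$y <- dichotomize_mrs(coh$mrs_30d)
  fit <- fit_logistic(coh, "y", "sd", covariates = "mean_pp")
  td <- tidy(fit)
  expect_true(all(c("(Intercept)", "sd", "mean_pp") %in% td$term))
  expect_equal(td$odds.ratio[td$term == "sd"], fit$or)
  gl <- glance(fit)
  expect_equal(gl$or, fit$or)
  expect_equal(gl$n_used, nrow(coh))
})

test_that("model suite fits M1-M4 with the documented covariate sets", {
  coh <- analysis_cohort(seed = 5)
  suite <- run_model_suite(coh, "sd", "30d")
  expect_equal(suite$model, c("M1", "M2", "M3", "M4"))
  expect_equal(suite$outcome_rule,
               c("dichotomized", "dichotomized", "severity_adjusted",
                 "dichotomized"))
  expect_true(all(suite$converged))
  expect_true(all(suite$ci_low <= suite$or & suite$or <= suite$ci_high))
  expect_true(all(suite$or > 0))
})

test_that("model suite recovers a known effect within its Wald CI", {
  coh <- analysis_cohort(seed = 6,
                         outcome_model = list(beta_per_mmHg = log(4.5) / 10))
  suite <- run_model_suite(coh, "sd", "30d", models = c("M1", "M2"))
  expect_true(all(suite$ci_low <= 4.5 & 4.5 <= suite$ci_high))
})

test_that("model suite propagates per-model failures without dropping rows", {
  coh <- analysis_cohort(seed = 8)
  coh$flat <- 12
  suite <- run_model_suite(coh, "flat", "30d")
  expect_equal(nrow(suite), 4)
  expect_true(all(!is.na(suite$error)))

  coh0 <- dplyr::mutate(coh, mrs_30d = 0L)
  suite0 <- run_model_suite(coh0, "sd", "30d")
  expect_true(all(grepl("one class", suite0$error)))
})

test_that("ROC analysis handles separation, reversal and degenerate labels", {
  perfect <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$youden_index, 1)
  expect_equal(perfect$cutoff, 3)
  expect_equal(perfect$p_value, 0)

  worse <- roc_analysis(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(worse$auc, 0.25)

  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)), class = "ppv_degenerate")
})

test_that("AUC equals the Mann-Whitney concordance probability", {
  withr::with_seed(31, {
    for (i in 1:50) {
      n <- sample(10:40, 1)
      scores <- rnorm(n)
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) next
      r <- roc_analysis(scores, labels)
      u <- mann_whitney_u(scores[labels == 1], scores[labels == 0])
      expect_equal(r$auc, u$u_first / (u$n1 * u$n2), tolerance = 1e-12)
      expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    }
  })
})

test_that("AUC and DeLong interval agree with pROC", {
  withr::with_seed(32, {
    for (i in 1:10) {
      n <- 60
      labels <- rbinom(n, 1, 0.45)
      if (length(unique(labels)) < 2) next
      scores <- rnorm(n) + labels
      got <- roc_analysis(scores, labels)
      ref <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
      expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
      # pROC uses qnorm(0.975); this package reports the 1.96 convention,
      # so compare the underlying DeLong standard error instead
      ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
      se_ref <- (ci[3] - ci[1]) / (2 * qnorm(0.975))
      expect_equal(got$auc_se, se_ref, tolerance = 1e-8)
    }
  })
})

test_that("Youden cut-off is an observed score attaining the maximum", {
  withr::with_seed(33, {
    for (i in 1:20) {
      scores <- round(rnorm(50, 15, 5), 1)
      labels <- rbinom(50, 1, plogis((scores - 15) / 5))
      if (length(unique(labels)) < 2) next
      r <- roc_analysis(scores, labels)
      expect_true(r$cutoff %in% scores)
      pos <- scores[labels == 1]; neg <- scores[labels == 0]
      j_all <- vapply(sort(unique(scores)),
                      function(t) mean(pos >= t) + mean(neg < t) - 1,
                      numeric(1))
      expect_equal(r$youden_index, max(j_all), tolerance = 1e-12)
      attaining <- sort(unique(scores))[j_all >= max(j_all) - 1e-12]
      expect_equal(r$cutoff, min(attaining))
    }
  })
})
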