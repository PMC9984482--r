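# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use explicit loops / pair counting, not the vectorised
# code paths of the package.

oracle_ppv <- function(pp) {
  n <- length(pp)
  xbar <- sum(pp) / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (pp[i] - xbar)^2
  sd <- sqrt(ss / (n - 1))
  sv2 <- 0; arv <- 0; msc <- 0
  for (i in seq_len(n - 1)) {
    d <- pp[i + 1] - pp[i]
    sv2 <- sv2 + d^2
    arv <- arv + abs(d)
    if (abs(d) > msc) msc <- abs(d)
  }
  lo <- pp[1]; hi <- pp[1]
  for (i in seq_len(n)) {
    if (pp[i] < lo) lo <- pp[i]
    if (pp[i] > hi) hi <- pp[i]
  }
  list(mean_pp = xbar, sd = sd, cv = 100 * sd / xbar,
       sv = sqrt(sv2 / (n - 1)), arv = arv / (n - 1),
       dmm = hi - lo, msc = msc)
}

# literal restatement of the three severity-adjusted branches, scalar
oracle_severity <- function(mrs, nihss) {
  if (nihss <= 7) {
    if (mrs >= 2 && mrs <= 6) return(1L)
  } else if (nihss >= 8 && nihss <= 14) {
    if (mrs >= 3 && mrs <= 6) return(1L)
  } else {
    if (mrs >= 4 && mrs <= 6) return(1L)
  }
  0L
}

# brute-force Mann-Whitney pair count: # {a_i > b_j} + 1/2 # {a_i == b_j}
oracle_u_first <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# brute-force AUC by pair counting (positives scored above negatives)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  oracle_u_first(pos, neg) / (length(pos) * length(neg))
}

random_pp_series <- function(n = sample(2:30, 1)) {
  round(runif(n, 30, 90) + rnorm(n, 0, 10), 2)
}

# a small analysis-ready cohort table (indices joined to covariates)
analysis_cohort <- function(seed, n = 203, ...) {
  sim <- generate_cohort(cohort_spec(n_patients = n, seed = seed, ...))
  idx <- ppv_indices(sim$readings)
  dplyr::filter(dplyr::left_join(sim$cohort, idx, by = "patient_id"),
                accepted)
}
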