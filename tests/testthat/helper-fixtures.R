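# Shared fixtures: small cohorts built in code, and a memoized small DWF fit
# reused by the core/importance tests.

# Small numeric cohort with a weak linear signal in the first two features.
toy_cohort <- function(n = 120, p = 8, seed = 42, effect = 1.5) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("lab", seq_len(p))))
    eta <- effect * (X[, 1] * 0.8 + X[, 2] * 0.6) - 0.8
    y <- as.integer(stats::runif(n) < stats::plogis(eta))
    # guarantee both classes are workable
    if (sum(y) < 20) y[seq_len(20)] <- 1L
    if (sum(1 - y) < 20) y[n + 1 - seq_len(20)] <- 0L
    cohort_table(X, y)
  })
}

# Two well-separated Gaussian blobs (6 sd apart): any reasonable learner
# separates them perfectly on the training set.
blob_data <- function(n = 60, seed = 7) {
  withr::with_seed(seed, {
    n2 <- n / 2
    X <- rbind(matrix(stats::rnorm(n2 * 2, mean = 0), n2, 2),
               matrix(stats::rnorm(n2 * 2, mean = 6), n2, 2))
    colnames(X) <- c("A", "B")
    list(x = X, y = rep(c(0L, 1L), each = n2))
  })
}

# One small fitted DWF model (2x2 grid), computed once per test run.
.fit_cache <- new.env(parent = emptyenv())
fixture_dwf_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    co <- toy_cohort(n = 140, p = 8, seed = 11)
    ctl <- dwf_control(selectors = c("T_score", "Fisher"),
                       learners = c("LR", "DT"),
                       top_n_classifiers = 4, search_iter = 3, seed = 5)
    .fit_cache$fit <- dwf(co, control = ctl)
    .fit_cache$cohort <- co
  }
  list(fit = .fit_cache$fit, cohort = .fit_cache$cohort)
}
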