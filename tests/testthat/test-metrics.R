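test_that("confusion counts with resistant as the positive class", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cm)[c("TP", "FN", "TN", "FP")],
               list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$FN + perfect$FP, 0)
  expect_error(confusion(c(1, 0), c(1)), "mismatch")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
  # pooled matrix = elementwise sum of fold matrices
  pooled <- cm + perfect
  expect_equal(pooled$TP, cm$TP + perfect$TP)
})

test_that("metric suite handles degenerate cells without crashing", {
  cm <- structure(list(TP = 0L, FP = 2L, TN = 3L, FN = 0L),
                  class = "dwf_confusion")
  ms <- metric_suite(cm)
  expect_true(is.na(ms["sensitivity"]))
  expect_true(is.na(ms["gmean"]))
  expect_false(is.na(ms["specificity"]))
  # invariant: G-mean is exactly sqrt(sens * spec)
  cm2 <- confusion(rep(c(1, 0), c(30, 70)),
                   rep(c(1, 0, 1, 0), c(20, 10, 15, 55)))
  ms2 <- metric_suite(cm2)
  expect_equal(ms2[["gmean"]],
               sqrt(ms2[["sensitivity"]] * ms2[["specificity"]]),
               tolerance = 1e-12)
})

test_that("rank AUC equals brute-force pair counting with tie credit", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_rank(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  withr::with_seed(8, {
    sc <- sample(seq(0, 1, 0.1), 20, replace = TRUE)  # forces ties
    y <- rbinom(20, 1, 0.5)
  })
  pos <- sc[y == 1]; neg <- sc[y == 0]
  conc <- 0; ties <- 0
  for (a in pos) for (b in neg) {
    if (a > b) conc <- conc + 1 else if (a == b) ties <- ties + 1
  }
  expect_equal(auc_rank(sc, y),
               (conc + 0.5 * ties) / (length(pos) * length(neg)),
               tolerance = 1e-12)
  # invariant to strictly monotone transforms of the scores
  expect_equal(auc_rank(qlogis(pmin(pmax(sc, 0.01), 0.99)), y),
               auc_rank(pmin(pmax(sc, 0.01), 0.99), y))
})

test_that("DeLong variance matches the longhand structural components", {
  withr::with_seed(15, {
    y <- rep(c(1, 0), c(12, 18))
    a <- runif(30) + 0.4 * y
    b <- runif(30) + 0.2 * y
  })
  res <- delong_test(a, b, y)
  # longhand: placement values and their empirical covariances
  pos <- which(y == 1); neg <- which(y == 0)
  m <- length(pos); n <- length(neg)
  plc <- function(s) {
    v10 <- sapply(pos, function(i) (sum(s[neg] < s[i]) + 0.5 * sum(s[neg] == s[i])) / n)
    v01 <- sapply(neg, function(j) (sum(s[pos] > s[j]) + 0.5 * sum(s[pos] == s[j])) / m)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- plc(a); pb <- plc(b)
  cv <- function(u, v) sum((u - mean(u)) * (v - mean(v))) / (length(u) - 1)
  var_long <- (cv(pa$v10, pa$v10) - 2 * cv(pa$v10, pb$v10) +
                 cv(pb$v10, pb$v10)) / m +
              (cv(pa$v01, pa$v01) - 2 * cv(pa$v01, pb$v01) +
                 cv(pb$v01, pb$v01)) / n
  expect_equal(res$var, var_long, tolerance = 1e-12)
  expect_equal(res$delta, pa$auc - pb$auc, tolerance = 1e-12)
  # cross-check p-value against the reference implementation
  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(res$p_value, as.numeric(ref$p.value), tolerance = 1e-9)
})

test_that("DeLong test is symmetric and null on identical scores", {
  withr::with_seed(16, {
    y <- rbinom(40, 1, 0.4)
    a <- runif(40)
    b <- runif(40)
  })
  same <- delong_test(a, a, y)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
  ab <- delong_test(a, b, y)
  ba <- delong_test(b, a, y)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("fold confidence intervals follow the t formula with truncation", {
  const <- fold_ci(rep(0.8, 5))
  expect_equal(as.numeric(const), c(0.8, 0.8, 0.8))
  ci <- fold_ci(c(0.7, 0.8))
  hw <- qt(0.975, 1) * sd(c(0.7, 0.8)) / sqrt(2)
  expect_equal(ci[["mean"]], 0.75)
  expect_equal(ci[["lower"]], 0.75 - hw)
  expect_equal(ci[["upper"]], 1)  # truncated at 1 (0.75 + hw > 1)
  expect_error(fold_ci(0.5), "at least 2")
})

test_that("univariable report: calibration, separation, scale equivariance", {
  # null feature: the Wald CI covers OR = 1 in at least ~90% of replicates
  cover <- logical(100)
  for (r in 1:100) {
    withr::with_seed(700 + r, {
      y <- rbinom(80, 1, 0.3)
      if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
      x <- rnorm(80)
    })
    co <- cohort_table(cbind(f = x), y)
    rep_ <- univariable_report(co)
    cover[r] <- rep_$or_lower <= 1 && rep_$or_upper >= 1
  }
  expect_gte(mean(cover), 0.90)

  # perfectly separating feature: flagged, not fatal
  y <- rep(c(0L, 1L), each = 15)
  co_sep <- cohort_table(cbind(f = y * 10 + seq(0.01, 0.3, 0.01)), y)
  expect_false(univariable_report(co_sep)$converged)

  # doubling the scale halves the slope
  withr::with_seed(5, {
    x <- rnorm(120)
    y2 <- rbinom(120, 1, plogis(x))
  })
  r1 <- univariable_report(cohort_table(cbind(f = x), y2))
  r2 <- univariable_report(cohort_table(cbind(f = 2 * x), y2))
  expect_equal(r2$beta, r1$beta / 2, tolerance = 1e-6)
  expect_equal(r2$auc, r1$auc)
})
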