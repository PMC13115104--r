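test_that("capping truncates at the upper limit and nothing else", {
  m <- matrix(c(15, 6.6, 500, NA), 2, 2,
              dimnames = list(NULL, c("WBC", "CA125")))
  r <- reference_ranges(c(WBC = 9.5))
  out <- cap_values(m, r)
  expect_equal(unname(out[1, "WBC"]), 9.5)
  expect_equal(unname(out[2, "WBC"]), 6.6)
  expect_equal(unname(out[1, "CA125"]), 500)  # unmapped feature untouched
  expect_true(is.na(out[2, "CA125"]))
  expect_true(all(out <= m, na.rm = TRUE))  # monotone non-increasing
  expect_warning(cap_values(m, reference_ranges(c(XYZ = 1))), "unknown")
})

test_that("imputer handles complete, constant, and exactly linear data", {
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  st <- fit_imputer(X)
  expect_identical(apply_imputer(st, X), X)  # identity on complete data

  Xc <- cbind(a = rep(5, 10), b = rnorm(10))
  Xc[3, "a"] <- NA
  filled <- apply_imputer(fit_imputer(Xc), Xc)
  expect_equal(unname(filled[3, "a"]), 5, tolerance = 1e-9)

  # y = 2x exactly: imputed hole must match the least-squares oracle on the
  # complete rows (wide-range predictor keeps the ridge stabilizer inert)
  set.seed(1)
  x <- runif(30, 1, 100)
  Y <- cbind(x = x, y = 2 * x)
  Y[7, "y"] <- NA
  complete <- Y[-7, ]
  oracle_coef <- solve(crossprod(cbind(1, complete[, "x"])),
                       crossprod(cbind(1, complete[, "x"]), complete[, "y"]))
  oracle <- oracle_coef[1] + oracle_coef[2] * x[7]
  filled <- apply_imputer(fit_imputer(Y), Y)
  expect_equal(unname(filled[7, "y"]), unname(oracle), tolerance = 1e-6)
  expect_equal(unname(filled[7, "y"]), 2 * x[7], tolerance = 1e-6)

  Yall <- Y
  Yall[, "y"] <- NA
  expect_error(fit_imputer(Yall), "entirely missing")
})

test_that("Box-Cox lambda matches a dense grid-search oracle and reduces skew", {
  skew <- function(v) mean((v - mean(v))^3) / stats::sd(v)^3
  loglik <- function(lambda, x) {
    z <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
    n <- length(x)
    -n / 2 * log(stats::var(z) * (n - 1) / n) + (lambda - 1) * sum(log(x))
  }
  set.seed(4)
  x_exp <- matrix(rexp(1000, rate = 0.5), ncol = 1,
                  dimnames = list(NULL, "m"))
  st <- fit_boxcox(x_exp)
  grid <- seq(-2, 2, by = 0.01)
  oracle <- grid[which.max(vapply(grid, loglik, numeric(1),
                                  x = x_exp[, 1] + st$shift[1]))]
  expect_lt(abs(st$lambda[1] - oracle), 0.011)  # within one grid step
  z <- apply_boxcox(st, x_exp)
  expect_lt(abs(skew(z[, 1])), abs(skew(x_exp[, 1])))

  # near-normal data: lambda ~ 1; exact lognormal: lambda ~ 0
  set.seed(5)
  xn <- matrix(rnorm(2000, 50, 5), ncol = 1, dimnames = list(NULL, "n"))
  expect_equal(fit_boxcox(xn)$lambda[1], 1, tolerance = 0.25)
  xl <- matrix(rlnorm(2000), ncol = 1, dimnames = list(NULL, "l"))
  expect_equal(fit_boxcox(xl)$lambda[1], 0, tolerance = 0.05)

  xc <- matrix(rep(3, 10), ncol = 1, dimnames = list(NULL, "c"))
  expect_equal(fit_boxcox(xc)$lambda[1], 1)
})

test_that("min-max scaling maps to [0,1] with clipping", {
  m <- matrix(c(2, 4, 6), 3, 1, dimnames = list(NULL, "f"))
  st <- fit_minmax(m)
  expect_equal(as.numeric(apply_minmax(st, m)), c(0, 0.5, 1))
  expect_equal(as.numeric(apply_minmax(st, matrix(10, 1, 1))), 1)  # clipped
  expect_equal(as.numeric(apply_minmax(st, matrix(-5, 1, 1))), 0)
  cm <- matrix(rep(7, 4), 4, 1, dimnames = list(NULL, "f"))
  expect_true(all(apply_minmax(fit_minmax(cm), cm) == 0))
})

test_that("fitted pipeline is deterministic, bounded, and train-only", {
  co <- toy_cohort(n = 90, p = 6, seed = 8)
  X <- co$features
  X[sample(length(X), 12)] <- NA
  train <- X[1:60, ]
  val <- X[61:90, ]
  pp <- preprocess_fit(train, reference_ranges(c(lab1 = 1.5)))
  expect_true(all(pp$train >= 0 & pp$train <= 1))
  v1 <- preprocess_apply(pp, val)
  v2 <- preprocess_apply(pp, val)
  expect_identical(v1, v2)
  expect_true(all(v1 >= 0 & v1 <= 1))

  # leakage probe: the fitted state must not change when the validation
  # rows change (only training rows are inputs to the fit)
  val_perturbed <- val + 100
  pp2 <- preprocess_fit(train, reference_ranges(c(lab1 = 1.5)))
  pp$train <- pp2$train <- NULL
  expect_identical(pp, pp2)
  expect_false(identical(preprocess_apply(pp2, val),
                         preprocess_apply(pp2, val_perturbed)))
})

test_that("preprocess state serializes to JSON and restores", {
  co <- toy_cohort(n = 40, p = 4, seed = 12)
  X <- co$features
  X[c(3, 50)] <- NA
  pp <- preprocess_fit(X)
  path <- withr::local_tempfile(fileext = ".json")
  write_preprocess(pp, path)
  back <- read_preprocess(path)
  expect_equal(preprocess_apply(back, X), preprocess_apply(pp, X),
               tolerance = 1e-12)
})
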