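# Forces a column to have exactly the requested sample mean and sd.
exact_moments <- function(n, mean, sd, seed) {
  withr::with_seed(seed, {
    v <- rnorm(n)
    as.numeric(scale(v)) * sd + mean
  })
}

test_that("T score reproduces the two-sample t formula exactly", {
  x1 <- exact_moments(50, 1.0, 0.5, seed = 1)
  x0 <- exact_moments(50, 0.0, 0.5, seed = 2)
  X <- cbind(f = c(x1, x0))
  y <- rep(c(1L, 0L), each = 50)
  s <- score_features("T_score", X, y)
  expect_equal(s, 10.0, tolerance = 1e-10)  # |1 - 0| / sqrt(.25/50 + .25/50)
})

test_that("F score and Fisher score match longhand formulas on 5 features", {
  withr::with_seed(9, {
    X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- rep(c(0L, 1L), each = 30)
    X[, 2] <- X[, 2] + y
  })
  f_ours <- score_features("F_score", X, y)
  f_oracle <- vapply(1:5, function(j) {
    summary(stats::aov(X[, j] ~ factor(y)))[[1]][["F value"]][1]
  }, numeric(1))
  expect_equal(f_ours, f_oracle, tolerance = 1e-8)

  fi_ours <- score_features("Fisher", X, y)
  fi_oracle <- vapply(1:5, function(j) {
    v <- X[, j]
    m <- mean(v); m1 <- mean(v[y == 1]); m0 <- mean(v[y == 0])
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    num <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
    den <- sum((v[y == 1] - m1)^2) + sum((v[y == 0] - m0)^2)
    num / den
  }, numeric(1))
  expect_equal(fi_ours, fi_oracle, tolerance = 1e-10)

  # a feature identical in both classes has zero between-class scatter
  Xc <- cbind(X, same = rep(c(1, 2), 30))
  expect_equal(score_features("Fisher", Xc, y)[6], 0)
})

test_that("mutual-information greedy ranking matches a longhand reference", {
  withr::with_seed(14, {
    n <- 150
    y <- rep(c(0L, 1L), each = n / 2)
    X <- cbind(a = y + rnorm(n, sd = 0.4), b = rnorm(n),
               c = y + rnorm(n, sd = 0.4) * 2, d = rnorm(n))
  })
  # longhand: discretize, compute I(f;y), assert the first greedy pick is
  # the max-MI feature for all three criteria
  disc <- apply(X, 2, function(v) {
    as.integer(cut(v, breaks = unique(quantile(v, seq(0, 1, 0.2))),
                   include.lowest = TRUE))
  })
  mi <- function(a, b) {
    tab <- table(a, b) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    s <- 0
    for (i in seq_along(pa)) for (j in seq_along(pb)) {
      if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
    }
    s
  }
  rel <- vapply(1:4, function(j) mi(disc[, j], y), numeric(1))
  best_first <- which.max(rel)
  for (crit in c("JMI", "DISR", "ICAP")) {
    s <- score_features(crit, X, y)
    expect_equal(which.max(s), best_first, info = crit)
    # scores encode a full ranking: all distinct
    expect_length(unique(s), 4)
  }
})

test_that("Laplacian score matches its direct graph formula", {
  withr::with_seed(3, {
    X <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("f", 1:5)))
  })
  ours <- score_features("Laplacian", X, rep(c(0L, 1L), 15))
  # longhand: same graph construction, textbook formula
  W <- dwfusion:::knn_affinity(X, 5)
  D <- diag(rowSums(W))
  L <- D - W
  one <- rep(1, nrow(X))
  oracle <- vapply(1:5, function(j) {
    f <- X[, j]
    ft <- f - as.numeric((f %*% D %*% one) / (one %*% D %*% one)) * one
    as.numeric((ft %*% L %*% ft) / (ft %*% D %*% ft))
  }, numeric(1))
  expect_equal(ours, -oracle, tolerance = 1e-10)
})

test_that("reliefF matches a longhand double-loop reference", {
  withr::with_seed(6, {
    n <- 40
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
    X[, 1] <- X[, 1] + y
  })
  k <- 10
  p1 <- mean(y == 1)
  w_oracle <- numeric(4)
  d2 <- as.matrix(dist(X))^2
  diag(d2) <- Inf
  for (i in seq_len(n)) {
    same <- setdiff(which(y == y[i]), i)
    opp <- which(y != y[i])
    hits <- same[order(d2[i, same], seq_along(same))[1:k]]
    miss <- opp[order(d2[i, opp], seq_along(opp))[1:k]]
    pri <- if (y[i] == 1) p1 else 1 - p1
    pmiss <- 1 - pri
    for (j in 1:4) {
      w_oracle[j] <- w_oracle[j] -
        mean(abs(X[hits, j] - X[i, j])) / n +
        (pmiss / (1 - pri)) * mean(abs(X[miss, j] - X[i, j])) / n
    }
  }
  expect_equal(score_features("reliefF", X, y), w_oracle, tolerance = 1e-10)
})

test_that("every native selector ranks a perfect predictor first", {
  natives <- c("F_score", "T_score", "Fisher", "Laplacian", "reliefF",
               "JMI", "DISR", "ICAP")
  for (r in 1:3) {
    withr::with_seed(100 + r, {
      n <- 80
      y <- rep(c(0L, 1L), each = n / 2)
      X <- cbind(y + rnorm(n, sd = 0.05),
                 matrix(rnorm(n * 4, sd = 0.3), n, 4))
      colnames(X) <- paste0("f", 1:5)
    })
    for (s in natives) {
      expect_equal(which.max(score_features(s, X, y)), 1L,
                   info = sprintf("%s rep %d", s, r))
    }
  }
})

test_that("all 14 selectors are callable and permutation-equivariant", {
  withr::with_seed(23, {
    n <- 60
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(runif(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
    # distinct signal strength per feature so no two features tie exactly
    # (a deterministic tie-break cannot be equivariant under exact ties)
    for (j in 1:6) X[, j] <- X[, j] + 0.12 * j * y
  })
  perm <- c(4, 1, 6, 2, 5, 3)
  for (s in list_selectors()) {
    sc <- score_features(s, X, y)
    expect_length(sc, 6)
    expect_true(all(is.finite(sc)), info = s)
    sc_perm <- score_features(s, X[, perm], y)
    # MCFS runs coordinate-descent lasso fits whose convergence point is
    # column-order sensitive at ~1e-5; all others are exactly equivariant
    tol <- if (s == "MCFS") 1e-3 else 1e-6
    expect_equal(sc_perm, sc[perm], tolerance = tol, info = s)
  }
})

test_that("top_k keeps the k largest with index tie-breaks", {
  expect_identical(top_k(c(A = 3, B = 1, C = 2), 2), c(1L, 3L))
  expect_identical(top_k(rep(1, 4), 2), c(1L, 2L))
  expect_identical(top_k(c(2, 9, 4), 3), c(2L, 3L, 1L))
  expect_error(top_k(1:3, 0), "positive")
  expect_error(top_k(1:3, 4), "exceeds")
})
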