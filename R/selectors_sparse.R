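# Sparse-learning feature selectors. Each follows its published iterative
# algorithm (majorize-minimize reweighting of the l2,1 penalty, spectral
# embeddings on a 5-NN heat-kernel graph); the relevance score is the l2 norm
# of each feature's weight-matrix row.

one_hot <- function(y) {
  Y <- matrix(0, length(y), 2)
  Y[cbind(seq_along(y), y + 1L)] <- 1
  Y
}

# Least-squares loss + l2,1 penalty: min ||XW - Y||_F^2 + gamma ||W||_2,1,
# solved by majorize-minimize reweighting of the penalty (each step is a
# ridge solve with per-feature weights 1 / (2 ||w_j||)). Convex objective,
# monotone iteration.
sel_ls_l21 <- function(x, y, gamma = 0.1, max_iter = 50L) {
  X <- scale(x, center = TRUE, scale = FALSE)
  Y <- one_hot(y)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  p <- ncol(X)
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  g <- rep(1, p)
  W <- NULL
  for (it in seq_len(max_iter)) {
    W <- solve(XtX + gamma * diag(g, p), XtY)
    wn <- sqrt(rowSums(W^2))
    g_new <- 1 / (2 * pmax(wn, 1e-8))
    if (max(abs(g_new - g) / pmax(g, 1)) < 1e-8) break
    g <- g_new
  }
  sqrt(rowSums(W^2))
}

# Logistic loss + l2,1 penalty via IRLS with majorized penalty.
sel_ll_l21 <- function(x, y, gamma = 0.05, max_iter = 50L) {
  X <- cbind(1, x)
  p <- ncol(x)
  w <- rep(0, p + 1)
  g <- rep(1, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% w)
    mu <- 1 / (1 + exp(-eta))
    wt <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y - mu) / wt
    A <- crossprod(X * wt, X)
    diag(A)[-1] <- diag(A)[-1] + gamma * g
    w_new <- solve(A, crossprod(X * wt, z * wt))
    g <- 1 / (2 * pmax(abs(w_new[-1]), 1e-8))
    if (max(abs(w_new - w)) < 1e-6) {
      w <- w_new
      break
    }
    w <- w_new
  }
  abs(w[-1])
}

# Normalized-Laplacian spectral embedding (smallest nontrivial eigenvectors).
spectral_embedding <- function(W, n_vectors = 5L) {
  d <- pmax(rowSums(W), 1e-12)
  n <- nrow(W)
  Dm <- 1 / sqrt(d)
  Lsym <- diag(n) - (Dm * W) %*% diag(Dm, n)
  e <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  idx <- order(e$values)[2:(min(n_vectors, n - 1L) + 1L)]
  sweep(e$vectors[, idx, drop = FALSE], 1, Dm, `*`)
}

# Multi-cluster feature selection: spectral embedding + per-eigenvector l1
# regression; a feature's score is its largest absolute coefficient.
sel_mcfs <- function(x, n_neighbors = 5L, n_clusters = 5L) {
  if (stats::sd(as.vector(x)) == 0) return(rep(0, ncol(x)))
  W <- knn_affinity(x, n_neighbors)
  Yv <- spectral_embedding(W, n_clusters)
  p <- ncol(x)
  coefs <- vapply(seq_len(ncol(Yv)), function(kk) {
    fit <- glmnet::glmnet(x, Yv[, kk], alpha = 1, standardize = FALSE,
                          intercept = TRUE, nlambda = 50)
    lam <- max(fit$lambda) * 0.05
    as.numeric(abs(glmnet::coef.glmnet(fit, s = lam)[-1]))
  }, numeric(p))
  apply(matrix(coefs, nrow = p), 1, max)
}

# Nonnegative discriminative feature selection: nonnegative spectral
# clustering with an l2,1-regularized regression of the indicators on the
# features; multiplicative updates, deterministic spectral initialization.
sel_ndfs <- function(x, n_neighbors = 5L, n_clusters = 2L, alpha = 1,
                     beta = 1, max_iter = 30L) {
  n <- nrow(x)
  p <- ncol(x)
  if (stats::sd(as.vector(x)) == 0) return(rep(0, p))
  Wg <- knn_affinity(x, n_neighbors)
  d <- rowSums(Wg)
  L <- diag(d) - Wg
  Fm <- abs(spectral_embedding(Wg, n_clusters)) + 1e-4
  g <- rep(1, p)
  XtX <- crossprod(x)
  Wmat <- matrix(0, p, ncol(Fm))
  lambda_big <- 1e4  # enforces F'F ~ I
  for (it in seq_len(max_iter)) {
    Wmat <- solve(XtX + alpha * diag(g, p), crossprod(x, Fm))
    g <- 1 / (2 * pmax(sqrt(rowSums(Wmat^2)), 1e-8))
    XW <- x %*% Wmat
    M <- L + beta * (diag(n) - XW %*% solve(crossprod(XW) +
                                              1e-8 * diag(ncol(XW)), t(XW)))
    num <- lambda_big * Fm
    den <- M %*% Fm + lambda_big * Fm %*% crossprod(Fm)
    Fm <- Fm * sqrt(pmax(num, 0) / pmax(den, 1e-12))
    Fm[!is.finite(Fm)] <- 1e-4
  }
  sqrt(rowSums(Wmat^2))
}

# Unsupervised discriminative feature selection: local total-scatter matrix
# from 5-NN neighborhoods, l2,1-regularized trace minimization over
# orthogonal projections (eigenvector iteration with reweighted penalty).
sel_udfs <- function(x, n_neighbors = 5L, n_components = 2L, gamma = 0.1,
                     max_iter = 20L) {
  n <- nrow(x)
  p <- ncol(x)
  if (stats::sd(as.vector(x)) == 0) return(rep(0, p))
  d2 <- as.matrix(stats::dist(x))^2
  diag(d2) <- Inf
  Lg <- matrix(0, n, n)
  kk <- min(n_neighbors, n - 1L)
  H <- diag(kk + 1L) - matrix(1 / (kk + 1L), kk + 1L, kk + 1L)
  for (i in seq_len(n)) {
    nb <- c(i, order(d2[i, ], seq_len(n))[seq_len(kk)])
    Lg[nb, nb] <- Lg[nb, nb] + H
  }
  M <- crossprod(x, Lg %*% x)
  M <- (M + t(M)) / 2
  g <- rep(1, p)
  W <- NULL
  for (it in seq_len(max_iter)) {
    A <- M + gamma * diag(g, p)
    e <- eigen((A + t(A)) / 2, symmetric = TRUE)
    W <- e$vectors[, order(e$values)[seq_len(min(n_components, p))],
                   drop = FALSE]
    g_new <- 1 / (2 * pmax(sqrt(rowSums(W^2)), 1e-8))
    if (max(abs(g_new - g)) < 1e-6) break
    g <- g_new
  }
  sqrt(rowSums(W^2))
}
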