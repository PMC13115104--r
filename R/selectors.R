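#' The feature-selector registry
#'
#' Fourteen feature-scoring methods share one contract: given a complete,
#' scaled training matrix (and labels, for the supervised ones) they return
#' one finite relevance score per feature, larger = more relevant. Methods
#' whose native criterion is "smaller is better" (Laplacian score) are
#' negated so the sign convention is uniform.
#'
#' @return character vector of selector ids.
#' @export
list_selectors <- function() {
  c("F_score", "T_score", "DISR", "Fisher", "ICAP", "JMI", "Laplacian",
    "LL_l21", "LS_l21", "MCFS", "NDFS", "reliefF", "TraceRatio", "UDFS")
}

#' Score all features with one selector
#'
#' @param selector_id one of [list_selectors()].
#' @param x complete numeric matrix (training split only).
#' @param y binary 0/1 labels (ignored by the unsupervised selectors, which
#'   still require the argument so every selector is call-compatible).
#' @param k target subset size; used by the selectors whose criterion is
#'   subset-based (TraceRatio) — the returned vector still scores every
#'   feature.
#' @param n_bins equal-frequency bins for the mutual-information family.
#' @param n_neighbors graph neighbors for Laplacian/MCFS/NDFS/UDFS (5) —
#'   reliefF uses 10 hits/misses.
#' @return numeric vector of length `ncol(x)`, higher = better.
#' @export
score_features <- function(selector_id, x, y, k = 10L, n_bins = 5L,
                           n_neighbors = 5L) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("selector input must be complete (impute first)")
  supervised <- !selector_id %in% c("Laplacian", "MCFS", "NDFS", "UDFS")
  if (supervised) {
    if (!is_binary01(y) || length(unique(y)) != 2L) {
      stop("supervised selectors need binary labels with both classes")
    }
  }
  s <- switch(selector_id,
    F_score = sel_f_score(x, y),
    T_score = sel_t_score(x, y),
    Fisher = sel_fisher(x, y),
    Laplacian = sel_laplacian(x, n_neighbors = n_neighbors),
    reliefF = sel_relieff(x, y, n_neighbors = 10L),
    JMI = sel_mi_greedy(x, y, criterion = "JMI", n_bins = n_bins),
    DISR = sel_mi_greedy(x, y, criterion = "DISR", n_bins = n_bins),
    ICAP = sel_mi_greedy(x, y, criterion = "ICAP", n_bins = n_bins),
    TraceRatio = sel_trace_ratio(x, y, k = k),
    LS_l21 = sel_ls_l21(x, y),
    LL_l21 = sel_ll_l21(x, y),
    MCFS = sel_mcfs(x, n_neighbors = n_neighbors),
    NDFS = sel_ndfs(x, n_neighbors = n_neighbors),
    UDFS = sel_udfs(x, n_neighbors = n_neighbors),
    stop(sprintf("unknown selector '%s'", selector_id))
  )
  s[!is.finite(s)] <- 0
  unname(s)
}

#' Indices of the k best-scoring features
#'
#' Descending score; ties broken by ascending feature index so rankings are
#' deterministic.
#'
#' @param scores per-feature scores from [score_features()].
#' @param k number of features to keep.
#' @return integer vector of feature indices, best first.
#' @export
top_k <- function(scores, k = 10L) {
  if (k <= 0) stop("k must be positive")
  if (k > length(scores)) stop("k exceeds the number of features")
  order(-scores, seq_along(scores))[seq_len(k)]
}

# ---- simple filter scores -------------------------------------------------

class_stats <- function(x, y) {
  i1 <- y == 1
  i0 <- !i1
  list(n1 = sum(i1), n0 = sum(i0),
       m1 = colMeans(x[i1, , drop = FALSE]),
       m0 = colMeans(x[i0, , drop = FALSE]),
       v1 = apply(x[i1, , drop = FALSE], 2, stats::var),
       v0 = apply(x[i0, , drop = FALSE], 2, stats::var))
}

# One-way ANOVA F statistic per feature (two groups).
sel_f_score <- function(x, y) {
  st <- class_stats(x, y)
  n <- st$n1 + st$n0
  gm <- (st$n1 * st$m1 + st$n0 * st$m0) / n
  msb <- st$n1 * (st$m1 - gm)^2 + st$n0 * (st$m0 - gm)^2  # df = 1
  msw <- ((st$n1 - 1) * st$v1 + (st$n0 - 1) * st$v0) / (n - 2)
  out <- ifelse(msw == 0, ifelse(msb > 0, Inf, 0), msb / msw)
  out
}

# Absolute Welch two-sample t statistic per feature.
sel_t_score <- function(x, y) {
  st <- class_stats(x, y)
  se <- sqrt(st$v1 / st$n1 + st$v0 / st$n0)
  d <- abs(st$m1 - st$m0)
  ifelse(se == 0, ifelse(d > 0, Inf, 0), d / se)
}

# Fisher score: between-class over within-class scatter per feature.
sel_fisher <- function(x, y) {
  st <- class_stats(x, y)
  n <- st$n1 + st$n0
  gm <- (st$n1 * st$m1 + st$n0 * st$m0) / n
  num <- st$n1 * (st$m1 - gm)^2 + st$n0 * (st$m0 - gm)^2
  den <- st$n1 * st$v1 * (st$n1 - 1) / st$n1 + st$n0 * st$v0 * (st$n0 - 1) / st$n0
  ifelse(den == 0, ifelse(num > 0, Inf, 0), num / den)
}

# ---- graph utilities ------------------------------------------------------

# Symmetric k-NN affinity with heat kernel; width = mean squared distance.
knn_affinity <- function(x, n_neighbors = 5L) {
  d2 <- as.matrix(stats::dist(x))^2
  n <- nrow(d2)
  t_heat <- mean(d2[upper.tri(d2)])
  if (!is.finite(t_heat) || t_heat == 0) t_heat <- 1
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dv <- d2[i, ]
    dv[i] <- Inf
    nn <- order(dv, seq_len(n))[seq_len(min(n_neighbors, n - 1L))]
    W[i, nn] <- exp(-d2[i, nn] / t_heat)
  }
  pmax(W, t(W))  # symmetrize: keep edge if either end claims it
}

# Laplacian score (smaller = better locality preservation) -> negated.
sel_laplacian <- function(x, n_neighbors = 5L) {
  W <- knn_affinity(x, n_neighbors)
  d <- rowSums(W)
  D1 <- sum(d)
  scores <- vapply(seq_len(ncol(x)), function(j) {
    f <- x[, j]
    ft <- f - sum(f * d) / D1
    den <- sum(ft^2 * d)
    if (den < 1e-12) return(2)  # constant feature: worst locality
    num <- sum(ft * (d * ft - drop(W %*% ft)))  # f' L f
    num / den
  }, numeric(1))
  -scores
}

# reliefF with 10 nearest hits/misses, all instances, |a - b| difference
# (features are expected on a common [0,1] scale).
sel_relieff <- function(x, y, n_neighbors = 10L) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  diag(d2) <- Inf
  w <- numeric(ncol(x))
  p1 <- mean(y == 1)
  for (i in seq_len(n)) {
    same <- which(y == y[i])
    same <- same[same != i]
    opp <- which(y != y[i])
    kh <- min(n_neighbors, length(same))
    km <- min(n_neighbors, length(opp))
    if (kh == 0 || km == 0) next
    hits <- same[order(d2[i, same], seq_along(same))[seq_len(kh)]]
    miss <- opp[order(d2[i, opp], seq_along(opp))[seq_len(km)]]
    dh <- colMeans(abs(x[hits, , drop = FALSE] -
                         matrix(x[i, ], kh, ncol(x), byrow = TRUE)))
    dm <- colMeans(abs(x[miss, , drop = FALSE] -
                         matrix(x[i, ], km, ncol(x), byrow = TRUE)))
    p_miss <- if (y[i] == 1) 1 - p1 else p1
    w <- w - dh / n + (p_miss / (1 - (if (y[i] == 1) p1 else 1 - p1))) * dm / n
  }
  w
}

# ---- mutual-information family -------------------------------------------

# Equal-frequency discretization into n_bins integer codes 1..B.
discretize_ef <- function(x, n_bins = 5L) {
  apply(x, 2, function(col) {
    br <- unique(stats::quantile(col, probs = seq(0, 1, length.out = n_bins + 1),
                                 type = 7))
    if (length(br) < 2) return(rep(1L, length(col)))
    as.integer(cut(col, breaks = br, include.lowest = TRUE))
  })
}

entropy_codes <- function(...) {
  # joint entropy (nats) of one or more integer code vectors
  tab <- table(...)
  p <- tab[tab > 0] / sum(tab)
  -sum(p * log(p))
}

mi_codes <- function(a, b) {
  entropy_codes(a) + entropy_codes(b) - entropy_codes(a, b)
}

cmi_codes <- function(a, b, z) {
  # I(a; b | z)
  entropy_codes(a, z) + entropy_codes(b, z) - entropy_codes(a, b, z) -
    entropy_codes(z)
}

# Greedy forward selection under JMI / DISR / ICAP criteria; the returned
# score encodes the selection order (first selected = highest).
sel_mi_greedy <- function(x, y, criterion, n_bins = 5L) {
  p <- ncol(x)
  xd <- discretize_ef(x, n_bins)
  yd <- as.integer(y)
  rel <- vapply(seq_len(p), function(j) mi_codes(xd[, j], yd), numeric(1))
  selected <- integer(0)
  remaining <- seq_len(p)
  order_out <- integer(0)
  while (length(remaining) > 0) {
    if (length(selected) == 0L) {
      pick <- remaining[which.max(rel[remaining])]
    } else {
      obj <- vapply(remaining, function(f) {
        switch(criterion,
          JMI = sum(vapply(selected, function(s) {
            # I({f, s}; y)
            fs <- xd[, f] * (n_bins + 1L) + xd[, s]
            mi_codes(fs, yd)
          }, numeric(1))),
          DISR = sum(vapply(selected, function(s) {
            fs <- xd[, f] * (n_bins + 1L) + xd[, s]
            h <- entropy_codes(fs, yd)
            if (h < 1e-12) 0 else mi_codes(fs, yd) / h
          }, numeric(1))),
          ICAP = rel[f] - sum(vapply(selected, function(s) {
            max(0, mi_codes(xd[, f], xd[, s]) -
                  cmi_codes(xd[, f], xd[, s], yd))
          }, numeric(1)))
        )
      }, numeric(1))
      pick <- remaining[which.max(obj)]
    }
    order_out <- c(order_out, pick)
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  scores <- numeric(p)
  scores[order_out] <- seq(p, 1)
  scores
}

# ---- trace ratio ----------------------------------------------------------

# Trace-ratio criterion with Fisher (LDA) within/between graphs; iteratively
# finds lambda* = max_S tr(Sb_S)/tr(Sw_S) over size-k subsets and returns the
# per-feature score a_j - lambda* b_j.
sel_trace_ratio <- function(x, y, k = 10L, max_iter = 50L) {
  n <- nrow(x)
  k <- min(k, ncol(x))
  st <- class_stats(x, y)
  # per-feature within scatter b_j and between scatter a_j
  b <- (st$n1 - 1) * st$v1 + (st$n0 - 1) * st$v0
  gm <- (st$n1 * st$m1 + st$n0 * st$m0) / n
  a <- st$n1 * (st$m1 - gm)^2 + st$n0 * (st$m0 - gm)^2
  b <- pmax(b, 1e-12)
  S <- top_k(a / b, k)
  lambda <- sum(a[S]) / sum(b[S])
  for (it in seq_len(max_iter)) {
    sc <- a - lambda * b
    S_new <- top_k(sc, k)
    lambda_new <- sum(a[S_new]) / sum(b[S_new])
    if (setequal(S_new, S) || abs(lambda_new - lambda) < 1e-10) {
      lambda <- lambda_new
      break
    }
    S <- S_new
    lambda <- lambda_new
  }
  a - lambda * b
}
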