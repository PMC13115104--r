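# Natively implemented boosting learners: SAMME adaptive boosting over rpart
# trees, and oblivious-tree (symmetric) gradient boosting with logistic loss
# — the depth-synchronized tree family used for purely numeric tabular data.

# SAMME AdaBoost with rpart base trees (binary case: SAMME = discrete
# AdaBoost). Stops early on a perfect or useless weak learner.
adaboost_fit <- function(x, y, n_estimators = 100L, maxdepth = 1L,
                         learning_rate = 1) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  yf <- factor(y, levels = c(0, 1))
  df <- data.frame(y = yf, x)
  trees <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, minsplit = 2, cp = -1,
                               xval = 0)
  for (t in seq_len(n_estimators)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- as.integer(as.character(stats::predict(fit, df, type = "class")))
    mis <- pred != y
    err <- sum(w[mis])
    if (err <= 1e-10) {          # perfect weak learner dominates
      trees[[length(trees) + 1L]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) break        # no better than chance under current weights
    alpha <- learning_rate * log((1 - err) / err)
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * mis)
    w <- w / sum(w)
  }
  if (length(trees) == 0L) {     # fall back to the class prior
    return(list(trees = list(), alphas = numeric(0), prior = mean(y)))
  }
  list(trees = trees, alphas = alphas, prior = mean(y))
}

adaboost_predict <- function(fit, xnew) {
  if (length(fit$trees) == 0L) return(rep(fit$prior, nrow(xnew)))
  df <- as.data.frame(xnew)
  s <- rep(0, nrow(xnew))
  for (t in seq_along(fit$trees)) {
    pred <- as.integer(as.character(stats::predict(fit$trees[[t]], df,
                                                   type = "class")))
    s <- s + fit$alphas[t] * (2 * pred - 1)
  }
  s <- s / sum(fit$alphas)       # normalized vote margin in [-1, 1]
  1 / (1 + exp(-2 * s))
}

# --- oblivious-tree gradient boosting --------------------------------------

# Quantile binning (at most n_bins) shared by fit and predict.
oblivious_bins <- function(x, n_bins = 16L) {
  lapply(seq_len(ncol(x)), function(j) {
    qs <- unique(stats::quantile(x[, j],
                                 probs = seq(0, 1, length.out = n_bins + 1),
                                 type = 7))
    # interior cut points only
    if (length(qs) <= 2) numeric(0) else qs[-c(1, length(qs))]
  })
}

bin_codes <- function(x, edges) {
  vapply(seq_len(ncol(x)), function(j) {
    if (length(edges[[j]]) == 0) rep(1L, nrow(x)) else
      findInterval(x[, j], edges[[j]]) + 1L
  }, integer(nrow(x)))
}

# Gradient boosting with symmetric (oblivious) trees: every level of a tree
# applies one shared (feature, threshold) split to all current leaves, so a
# depth-d tree is a lookup table over d binary conditions. Logistic loss,
# Newton leaf values with L2 regularization.
oblivious_gbdt_fit <- function(x, y, nrounds = 100L, eta = 0.1, depth = 4L,
                               l2 = 1, seed = 1L) {
  n <- nrow(x)
  p <- ncol(x)
  edges <- oblivious_bins(x)
  codes <- bin_codes(x, edges)
  n_bins_j <- vapply(edges, function(e) length(e) + 1L, integer(1))
  prior <- min(max(mean(y), 1e-6), 1 - 1e-6)
  f0 <- log(prior / (1 - prior))
  F <- rep(f0, n)
  trees <- list()
  if (all(n_bins_j < 2L)) {
    return(list(f0 = f0, trees = trees, edges = edges, eta = eta))
  }
  for (m in seq_len(nrounds)) {
    pr <- 1 / (1 + exp(-F))
    g <- pr - y
    h <- pmax(pr * (1 - pr), 1e-12)
    leaf <- rep(1L, n)
    n_leaves <- 1L
    splits <- matrix(NA_integer_, depth, 2)
    for (lvl in seq_len(depth)) {
      # histogram split search: per feature, accumulate (g, h) by
      # (leaf, bin), then scan thresholds via cumulative sums
      Gt <- rowsum(g, leaf)
      Ht <- rowsum(h, leaf)
      base_sum <- sum(Gt^2 / (Ht + l2))
      best_gain <- 0
      best <- NULL
      for (j in seq_len(p)) {
        B <- n_bins_j[j]
        if (B < 2L) next
        idx <- (leaf - 1L) * B + codes[, j]
        rs <- rowsum(cbind(g, h), idx)
        full <- matrix(0, B * n_leaves, 2)
        full[as.integer(rownames(rs)), ] <- rs
        cG <- apply(matrix(full[, 1], B, n_leaves), 2, cumsum)
        cH <- apply(matrix(full[, 2], B, n_leaves), 2, cumsum)
        cG <- matrix(cG, B, n_leaves)
        cH <- matrix(cH, B, n_leaves)
        GL <- cG[-B, , drop = FALSE]
        HL <- cH[-B, , drop = FALSE]
        GR <- rep(cG[B, ], each = B - 1L) - GL
        HR <- rep(cH[B, ], each = B - 1L) - HL
        gains <- rowSums(matrix(GL^2 / (HL + l2) + GR^2 / (HR + l2),
                                B - 1L, n_leaves)) - base_sum
        bj <- which.max(gains)
        if (gains[bj] > best_gain + 1e-12) {
          best_gain <- gains[bj]
          best <- c(j, bj)
        }
      }
      if (is.null(best)) break
      splits[lvl, ] <- best
      side <- codes[, best[1]] > best[2]
      leaf <- leaf * 2L - as.integer(!side)
      # compact leaf ids to 1..2^lvl
      leaf <- match(leaf, sort(unique(leaf)))
      n_leaves <- max(leaf)
    }
    used <- !is.na(splits[, 1])
    if (!any(used)) break
    vals_raw <- vapply(seq_len(n_leaves), function(l) {
      -sum(g[leaf == l]) / (sum(h[leaf == l]) + l2)
    }, numeric(1))
    F <- F + eta * vals_raw[leaf]
    trees[[length(trees) + 1L]] <- list(splits = splits[used, , drop = FALSE],
                                        values = vals_raw,
                                        leaf_map = sort(unique(
                                          tree_leaf_ids(codes, splits[used, , drop = FALSE]))))
    if (max(abs(g)) < 1e-8) break
  }
  list(f0 = f0, trees = trees, edges = edges, eta = eta)
}

# Raw (uncompacted) leaf id from the split list.
tree_leaf_ids <- function(codes, splits) {
  leaf <- rep(1L, nrow(codes))
  for (lvl in seq_len(nrow(splits))) {
    side <- codes[, splits[lvl, 1]] > splits[lvl, 2]
    leaf <- leaf * 2L - as.integer(!side)
  }
  leaf
}

oblivious_gbdt_predict <- function(fit, xnew) {
  F <- rep(fit$f0, nrow(xnew))
  if (length(fit$trees)) {
    codes <- bin_codes(xnew, fit$edges)
    for (tr in fit$trees) {
      raw <- tree_leaf_ids(codes, tr$splits)
      leaf <- match(raw, tr$leaf_map)
      # unseen leaf pattern (possible off-training-range): no update
      upd <- !is.na(leaf)
      F[upd] <- F[upd] + fit$eta * tr$values[leaf[upd]]
    }
  }
  1 / (1 + exp(-F))
}
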