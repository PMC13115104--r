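#' Borderline-SMOTE oversampling of the minority class
#'
#' Implements the borderline-1 variant: a minority point is in the DANGER
#' set iff at least half but not all of its `m` nearest neighbors (Euclidean
#' distance over all training points, ties broken by row index) belong to
#' the majority class; points with purely-majority neighborhoods are treated
#' as noise and skipped. Synthetic samples are drawn on the segment between
#' a DANGER point `p` and one of its `k` nearest minority neighbors `q`:
#' `s = p + u (q - p)`, `u ~ Uniform(0, 1)`. Synthesis cycles over the
#' DANGER points until the requested minority:majority ratio is reached.
#' Intended for scaled training folds only; never oversample before
#' splitting.
#'
#' @param x numeric matrix of (scaled) training features.
#' @param y binary labels; the minority class is detected automatically.
#' @param m_neighbors neighborhood size for DANGER detection.
#' @param k_neighbors candidate minority neighbors for synthesis.
#' @param target_ratio desired minority:majority count ratio (<= 1).
#' @param seed RNG seed for reproducible synthesis.
#' @return list with `x`, `y` (original rows first, in input order),
#'   `parents` (two-column matrix of parent row indices per synthetic row)
#'   and `n_synthetic`.
#' @export
borderline_smote <- function(x, y, m_neighbors = 5L, k_neighbors = 5L,
                             target_ratio = 1, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (ncol(x) == 0) stop("empty feature set")
  if (!is_binary01(y) || length(unique(y)) != 2L) {
    stop("both classes must be present")
  }
  counts <- table(factor(y, levels = c(0, 1)))
  minority <- as.integer(names(which.min(counts)))
  n_min <- min(counts)
  n_maj <- max(counts)
  if (n_min < 2L) stop("minority class needs at least 2 members")
  deficit <- floor(target_ratio * n_maj) - n_min
  out_unchanged <- list(x = x, y = y,
                        parents = matrix(integer(0), 0, 2,
                                         dimnames = list(NULL, c("p", "q"))),
                        n_synthetic = 0L)
  if (deficit <= 0) return(out_unchanged)

  d2 <- as.matrix(stats::dist(x))^2
  diag(d2) <- Inf
  min_idx <- which(y == minority)
  # DANGER: m/2 <= majority neighbors < m among the m nearest overall
  order_ties <- function(dv) order(dv, seq_along(dv))
  danger <- integer(0)
  for (i in min_idx) {
    nn <- order_ties(d2[i, ])[seq_len(m_neighbors)]
    m_maj <- sum(y[nn] != minority)
    if (m_maj >= m_neighbors / 2 && m_maj < m_neighbors) danger <- c(danger, i)
  }
  if (length(danger) == 0L) {
    warning("no borderline (DANGER) minority points: returning input unchanged")
    return(out_unchanged)
  }
  # k nearest minority neighbors of each danger point (excluding itself)
  knn_min <- lapply(danger, function(i) {
    cand <- setdiff(min_idx, i)
    cand[order_ties(d2[i, cand])[seq_len(min(k_neighbors, length(cand)))]]
  })
  synth <- matrix(NA_real_, deficit, ncol(x))
  parents <- matrix(NA_integer_, deficit, 2,
                    dimnames = list(NULL, c("p", "q")))
  with_seed(seed, {
    for (s in seq_len(deficit)) {
      di <- ((s - 1L) %% length(danger)) + 1L
      p <- danger[di]
      q <- knn_min[[di]][sample.int(length(knn_min[[di]]), 1L)]
      u <- stats::runif(1)
      synth[s, ] <- x[p, ] + u * (x[q, ] - x[p, ])
      parents[s, ] <- c(p, q)
    }
  })
  colnames(synth) <- colnames(x)
  list(x = rbind(x, synth), y = c(y, rep(minority, deficit)),
       parents = parents, n_synthetic = as.integer(deficit))
}

#' Audit a fold plan for oversampling leakage
#'
#' Asserts that every synthetic row's parents are members of the training
#' split of their fold and that validation folds contain only original rows
#' with their original class counts. Any violation is a hard failure of the
#' pipeline; this audit runs automatically inside [dwf()].
#'
#' @param fold_assignment integer vector: validation fold of each original
#'   row.
#' @param fold_audits list per fold with `train_rows` (original row indices
#'   of the training split), `parents` (parent matrix from
#'   [borderline_smote()], indices into `train_rows`), and
#'   `val_rows`.
#' @return list with `ok` (logical) and `violations` (character vector).
#' @export
guard_no_leakage <- function(fold_assignment, fold_audits) {
  violations <- character(0)
  n <- length(fold_assignment)
  for (f in seq_along(fold_audits)) {
    a <- fold_audits[[f]]
    train_rows <- a$train_rows
    val_rows <- a$val_rows
    if (length(intersect(train_rows, val_rows))) {
      violations <- c(violations,
                      sprintf("fold %d: training and validation rows overlap", f))
    }
    if (!all(fold_assignment[val_rows] == f)) {
      violations <- c(violations,
                      sprintf("fold %d: validation rows not assigned to this fold", f))
    }
    if (nrow(a$parents %||% matrix(0, 0, 2)) > 0) {
      parent_orig <- train_rows[as.vector(a$parents)]
      if (anyNA(parent_orig) || any(!parent_orig %in% train_rows) ||
          any(parent_orig %in% val_rows)) {
        violations <- c(violations,
                        sprintf("fold %d: synthetic parents outside the training split", f))
      }
      if (any(as.vector(a$parents) > length(train_rows))) {
        violations <- c(violations,
                        sprintf("fold %d: synthetic parents reference synthetic rows beyond the original training split", f))
      }
    }
    if (any(val_rows > n)) {
      violations <- c(violations,
                      sprintf("fold %d: validation fold contains non-original rows", f))
    }
  }
  list(ok = length(violations) == 0L, violations = violations)
}
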