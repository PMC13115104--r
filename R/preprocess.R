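#' Cap values at clinical reference-range upper limits
#'
#' Values above a feature's standard upper limit are truncated to that limit
#' so extreme pathological magnitudes do not dominate the classifiers;
#' features without a mapped limit pass through unchanged, as do missing
#' cells. Capping is monotone: output never exceeds input.
#'
#' @param x a [cohort_table()] or numeric matrix with named columns.
#' @param ranges a [reference_ranges()] map (may be empty).
#' @return object of the same type as `x`.
#' @export
cap_values <- function(x, ranges) {
  if (inherits(x, "cohort_table")) {
    x$features <- cap_values(x$features, ranges)
    return(x)
  }
  stopifnot(is.matrix(x))
  if (length(ranges) == 0) return(x)
  unknown <- setdiff(names(ranges), colnames(x))
  if (length(unknown)) {
    warning(sprintf("reference ranges for unknown features ignored: %s",
                    paste(unknown, collapse = ", ")))
  }
  for (f in intersect(names(ranges), colnames(x))) {
    x[, f] <- pmin(x[, f], ranges[[f]])
  }
  x
}

#' Fit the chained-equation imputer
#'
#' Multivariate imputation by chained equations: starting from per-feature
#' observed means, each incomplete feature is repeatedly regressed on all
#' other features (ridge-stabilized least squares, penalty 1e-3) and its
#' missing cells replaced by the fitted values, sweeping until the largest
#' change of any imputed cell falls below 1e-3 of that feature's observed
#' standard deviation, or `max_iter` sweeps. The returned state carries one
#' regression per feature so new tables with holes in any column can be
#' completed deterministically.
#'
#' @param x numeric matrix with `NA` holes; every column needs at least one
#'   observed value.
#' @param max_iter maximum number of chained sweeps.
#' @param ridge ridge stabilizer added to the normal equations.
#' @return imputer state (list); see [apply_imputer()].
#' @export
fit_imputer <- function(x, max_iter = 30L, ridge = 1e-3) {
  stopifnot(is.matrix(x))
  p <- ncol(x)
  obs <- !is.na(x)
  if (any(colSums(obs) == 0)) {
    stop("feature entirely missing: cannot impute")
  }
  mu <- colMeans(x, na.rm = TRUE)
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  sds[!is.finite(sds) | sds == 0] <- 1e-12
  filled <- x
  for (j in seq_len(p)) filled[!obs[, j], j] <- mu[j]
  incomplete <- which(colSums(!obs) > 0)
  ridge_fit <- function(z, yv) {
    Z <- cbind(1, z)
    A <- crossprod(Z)
    diag(A)[-1] <- diag(A)[-1] + ridge
    drop(solve(A, crossprod(Z, yv)))
  }
  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (j in incomplete) {
      rows_obs <- obs[, j]
      co <- ridge_fit(filled[rows_obs, -j, drop = FALSE], x[rows_obs, j])
      pred <- drop(cbind(1, filled[!rows_obs, -j, drop = FALSE]) %*% co)
      delta <- max(delta, max(abs(pred - filled[!rows_obs, j])) / sds[j])
      filled[!rows_obs, j] <- pred
    }
    if (length(incomplete) == 0L || delta < 1e-3) break
  }
  # one regression per feature on the completed matrix, for apply()
  models <- lapply(seq_len(p), function(j) {
    ridge_fit(filled[, -j, drop = FALSE], filled[, j])
  })
  list(means = mu, sds = sds, models = models, max_iter = as.integer(max_iter),
       p = p)
}

#' Apply a fitted imputer to a (possibly incomplete) matrix
#'
#' Deterministic given the fitted state: observed cells are untouched,
#' missing cells start at the training means and are updated with the stored
#' per-feature regressions until stable.
#'
#' @param state result of [fit_imputer()].
#' @param x numeric matrix with the training columns.
#' @return completed matrix.
#' @export
apply_imputer <- function(state, x) {
  stopifnot(is.matrix(x), ncol(x) == state$p)
  obs <- !is.na(x)
  if (all(obs)) return(x)
  filled <- x
  for (j in seq_len(ncol(x))) filled[!obs[, j], j] <- state$means[j]
  incomplete <- which(colSums(!obs) > 0)
  # fixed sweep count (no data-dependent early stop) so each row's
  # completion is independent of which other rows are present
  for (iter in seq_len(state$max_iter)) {
    for (j in incomplete) {
      co <- state$models[[j]]
      pred <- drop(cbind(1, filled[!obs[, j], -j, drop = FALSE]) %*% co)
      filled[!obs[, j], j] <- pred
    }
  }
  filled
}

# Box-Cox transform of a positive vector for a given lambda.
boxcox_transform <- function(x, lambda) {
  x <- pmax(x, 1e-12)
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

# Profile log-likelihood of the Box-Cox lambda for one feature.
boxcox_loglik <- function(lambda, x) {
  n <- length(x)
  z <- boxcox_transform(x, lambda)
  v <- stats::var(z) * (n - 1) / n
  if (!is.finite(v) || v <= 0) return(-Inf)
  -n / 2 * log(v) + (lambda - 1) * sum(log(x))
}

#' Fit per-feature Box-Cox transforms
#'
#' For each feature a positivity shift `max(0, 1e-6 - min)` is applied and
#' the power parameter `lambda` chosen by maximum profile likelihood
#' (searched over `[-5, 5]`). The transform is
#' `((x + shift)^lambda - 1) / lambda`, or `log(x + shift)` when
#' `lambda = 0`. Constant features get `lambda = 1` (identity up to an
#' affine map).
#'
#' @param x complete numeric matrix (run the imputer first).
#' @param features `"all"` or names of the columns to transform; the rest
#'   get `lambda = 1`, `shift` chosen for positivity.
#' @return list with numeric vectors `shift` and `lambda`.
#' @export
fit_boxcox <- function(x, features = "all") {
  stopifnot(is.matrix(x), !anyNA(x))
  p <- ncol(x)
  shift <- pmax(0, 1e-6 - apply(x, 2, min))
  lambda <- rep(1, p)
  idx <- if (identical(features, "all")) seq_len(p) else
    which(colnames(x) %in% features)
  for (j in idx) {
    xs <- x[, j] + shift[j]
    if (stats::sd(xs) == 0) {
      dwf_log("constant feature '%s': Box-Cox lambda fixed at 1",
              colnames(x)[j] %||% j)
      next
    }
    opt <- stats::optimize(function(l) boxcox_loglik(l, xs),
                           interval = c(-5, 5), maximum = TRUE, tol = 1e-5)
    lambda[j] <- opt$maximum
  }
  list(shift = shift, lambda = lambda)
}

#' @rdname fit_boxcox
#' @param state result of `fit_boxcox()`.
#' @export
apply_boxcox <- function(state, x) {
  stopifnot(is.matrix(x), ncol(x) == length(state$lambda))
  for (j in seq_len(ncol(x))) {
    x[, j] <- boxcox_transform(x[, j] + state$shift[j], state$lambda[j])
  }
  x
}

#' Fit/apply min-max scaling to the unit interval
#'
#' Training columns map onto `[0, 1]`; values outside the training range
#' (e.g. on a validation fold) are clipped into `[0, 1]`. A constant column
#' maps to 0.
#'
#' @param x numeric matrix.
#' @return `fit_minmax()` returns a list with `min` and `max` per column.
#' @export
fit_minmax <- function(x) {
  stopifnot(is.matrix(x), !anyNA(x))
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}

#' @rdname fit_minmax
#' @param state result of `fit_minmax()`.
#' @export
apply_minmax <- function(state, x) {
  stopifnot(is.matrix(x), ncol(x) == length(state$min))
  rng <- state$max - state$min
  for (j in seq_len(ncol(x))) {
    x[, j] <- if (rng[j] == 0) 0 else (x[, j] - state$min[j]) / rng[j]
  }
  pmin(pmax(x, 0), 1)
}

#' Fit the full preprocessing pipeline on training data
#'
#' Applies, in order: reference-range capping, chained-equation imputation,
#' Box-Cox transformation, min-max scaling. All statistics are learned from
#' the rows given here (a training split); [preprocess_apply()] reuses the
#' fitted state only, so validation rows never leak into it. Outcome labels
#' are never read.
#'
#' @param x numeric feature matrix of the training split (may contain `NA`).
#' @param ranges a [reference_ranges()] map (optional).
#' @param boxcox_features `"all"` or column names to Box-Cox transform.
#' @param max_iter imputer sweep cap.
#' @return list of class `dwf_preprocess` with the fitted state and
#'   `$train`, the transformed training matrix.
#' @export
preprocess_fit <- function(x, ranges = reference_ranges(numeric(0)),
                           boxcox_features = "all", max_iter = 30L) {
  stopifnot(is.matrix(x))
  capped <- cap_values(x, ranges)
  imputer <- fit_imputer(capped, max_iter = max_iter)
  complete <- apply_imputer(imputer, capped)
  bc <- fit_boxcox(complete, features = boxcox_features)
  z <- apply_boxcox(bc, complete)
  mm <- fit_minmax(z)
  out <- list(ranges = ranges, imputer = imputer, boxcox = bc, minmax = mm,
              feature_names = colnames(x))
  out$train <- apply_minmax(mm, z)
  class(out) <- "dwf_preprocess"
  out
}

#' Apply a fitted preprocessing pipeline
#'
#' @param model a `dwf_preprocess` from [preprocess_fit()].
#' @param x feature matrix with the training columns (may contain `NA`).
#' @return transformed matrix with all values in `[0, 1]`.
#' @export
preprocess_apply <- function(model, x) {
  stopifnot(inherits(model, "dwf_preprocess"), is.matrix(x))
  if (!is.null(model$feature_names)) {
    if (!all(model$feature_names %in% colnames(x))) {
      stop("input is missing training feature columns")
    }
    x <- x[, model$feature_names, drop = FALSE]
  }
  capped <- cap_values(x, model$ranges)
  complete <- apply_imputer(model$imputer, capped)
  z <- apply_boxcox(model$boxcox, complete)
  apply_minmax(model$minmax, z)
}

#' Serialize / restore a fitted preprocessing model as JSON
#' @param model a `dwf_preprocess`.
#' @param path file path.
#' @export
write_preprocess <- function(model, path) {
  model$train <- NULL
  writeLines(jsonlite::serializeJSON(model, digits = NA), path)
  invisible(path)
}

#' @rdname write_preprocess
#' @export
read_preprocess <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}
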