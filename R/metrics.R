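#' Confusion matrix for binary predictions
#'
#' The resistant group (label 1) is the positive class throughout.
#'
#' @param labels true 0/1 labels.
#' @param predicted predicted 0/1 labels.
#' @return list of class `dwf_confusion` with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(labels, predicted) {
  if (length(labels) != length(predicted)) stop("length mismatch")
  if (!is_binary01(labels) || !is_binary01(predicted)) {
    stop("labels and predictions must be binary 0/1")
  }
  structure(
    list(TP = sum(labels == 1 & predicted == 1),
         FP = sum(labels == 0 & predicted == 1),
         TN = sum(labels == 0 & predicted == 0),
         FN = sum(labels == 1 & predicted == 0)),
    class = "dwf_confusion"
  )
}

#' @export
print.dwf_confusion <- function(x, ...) {
  m <- matrix(c(x$TP, x$FP, x$FN, x$TN), 2, 2,
              dimnames = list(truth = c("resistant", "sensitive"),
                              predicted = c("resistant", "sensitive")))
  print(m)
  invisible(x)
}

# Sum of per-fold confusion matrices (pooled matrix).
#' @export
`+.dwf_confusion` <- function(e1, e2) {
  structure(list(TP = e1$TP + e2$TP, FP = e1$FP + e2$FP,
                 TN = e1$TN + e2$TN, FN = e1$FN + e2$FN),
            class = "dwf_confusion")
}

#' Metric suite from a confusion matrix
#'
#' Computes sensitivity (recall of the resistant class), specificity,
#' accuracy, PPV, NPV and the G-mean `sqrt(sensitivity * specificity)`.
#' A zero denominator yields `NA` (flagged, never an error) so degenerate
#' subgroup cells are reported rather than crashing.
#'
#' @param cm a `dwf_confusion`.
#' @return named numeric vector.
#' @export
metric_suite <- function(cm) {
  stopifnot(inherits(cm, "dwf_confusion"))
  total <- cm$TP + cm$FP + cm$TN + cm$FN
  if (total == 0) stop("empty confusion matrix")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(cm$TP, cm$TP + cm$FN)
  spec <- safe_div(cm$TN, cm$TN + cm$FP)
  c(accuracy = (cm$TP + cm$TN) / total,
    sensitivity = sens, specificity = spec,
    ppv = safe_div(cm$TP, cm$TP + cm$FP),
    npv = safe_div(cm$TN, cm$TN + cm$FN),
    gmean = if (is.na(sens) || is.na(spec)) NA_real_ else sqrt(sens * spec))
}

#' Rank-based AUC (Mann-Whitney with midranks)
#'
#' Equals the trapezoidal area under the ROC curve; ties contribute 1/2 via
#' midranks.
#'
#' @param scores numeric risk scores (higher = more resistant).
#' @param labels true 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!is_binary01(labels) || length(unique(labels)) != 2L) {
    stop("labels must contain both classes")
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# G-mean of thresholded scores; the screening metric of the framework.
gmean_at <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  sens_den <- sum(labels == 1)
  spec_den <- sum(labels == 0)
  if (sens_den == 0 || spec_den == 0) return(NA_real_)
  sens <- sum(pred == 1 & labels == 1) / sens_den
  spec <- sum(pred == 0 & labels == 0) / spec_den
  sqrt(sens * spec)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two risk scores computed on the same patients using
#' the structural-components (placement value) estimate of the variance of
#' the AUC difference, with a two-sided normal reference for the p-value.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels true 0/1 labels.
#' @return list with `auc_a`, `auc_b`, `delta`, `var`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    stop("length mismatch")
  }
  if (!is_binary01(labels) || length(unique(labels)) != 2L) {
    stop("labels must contain both classes")
  }
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  m <- length(pos)
  n <- length(neg)
  comp <- function(s) {
    # placement values: V10[i] = P(score_neg < s_i) + .5 P(=); V01 analog
    x <- s[pos]
    y <- s[neg]
    v10 <- vapply(x, function(xi) (sum(y < xi) + 0.5 * sum(y == xi)) / n,
                  numeric(1))
    v01 <- vapply(y, function(yi) (sum(x > yi) + 0.5 * sum(x == yi)) / m,
                  numeric(1))
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  a <- comp(scores_a)
  b <- comp(scores_b)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  # var(AUC_a - AUC_b) via the components' covariance matrix
  contrast <- c(1, -1)
  v <- drop(contrast %*% (s10 / m + s01 / n) %*% contrast)
  delta <- a$auc - b$auc
  if (v <= 0) {
    if (abs(delta) > 1e-12) stop("zero variance with nonzero AUC difference")
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = a$auc, auc_b = b$auc, delta = delta, var = v, z = z,
       p_value = p)
}

#' Fold-aggregated 95% confidence interval
#'
#' Mean of per-fold metric values with a t-interval
#' `mean +/- t(0.975, n-1) * sd / sqrt(n)`, truncated to `[0, 1]`.
#'
#' @param values per-fold metric values (length >= 2, `NA` dropped).
#' @return named vector `(mean, lower, upper)`.
#' @export
fold_ci <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 fold values")
  m <- mean(values)
  hw <- stats::qt(0.975, n - 1) * stats::sd(values) / sqrt(n)
  c(mean = m, lower = max(0, m - hw), upper = min(1, m + hw))
}

#' Univariable screening report
#'
#' For each feature, fits a single-predictor logistic regression of the
#' outcome and reports the per-unit odds ratio with Wald 95% CI and p-value,
#' plus the rank AUC of the raw feature. Rows with a missing value for a
#' feature are dropped for that feature's fit. Non-convergence (including
#' perfect separation) is flagged per feature, never fatal.
#'
#' @param cohort a [cohort_table()].
#' @return data.frame with one row per feature: `feature`, `auc`, `beta`,
#'   `or`, `or_lower`, `or_upper`, `p_value`, `converged`.
#' @export
univariable_report <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  X <- cohort$features
  y <- cohort$outcome
  rows <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    ok <- !is.na(x)
    xj <- x[ok]
    yj <- y[ok]
    out <- data.frame(feature = colnames(X)[j], auc = NA_real_,
                      beta = NA_real_, or = NA_real_, or_lower = NA_real_,
                      or_upper = NA_real_, p_value = NA_real_,
                      converged = FALSE, stringsAsFactors = FALSE)
    if (length(unique(yj)) != 2L || stats::sd(xj) == 0) return(out)
    out$auc <- auc_rank(xj, yj)
    fit <- withCallingHandlers(
      suppressWarnings(stats::glm(yj ~ xj, family = stats::binomial(),
                                  control = stats::glm.control(maxit = 100))),
      error = function(e) NULL)
    if (is.null(fit)) return(out)
    beta <- stats::coef(fit)[["xj"]]
    se <- sqrt(diag(stats::vcov(fit)))[["xj"]]
    # huge |beta| or SE signals quasi-separation
    conv <- isTRUE(fit$converged) && is.finite(beta) && is.finite(se) &&
      abs(beta) < 1e2 && se < 1e2
    out$beta <- beta
    out$or <- exp(beta)
    out$or_lower <- exp(beta - 1.96 * se)
    out$or_upper <- exp(beta + 1.96 * se)
    out$p_value <- 2 * stats::pnorm(-abs(beta / se))
    out$converged <- conv
    out
  })
  do.call(rbind, rows)
}
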