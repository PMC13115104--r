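#' The learner registry
#'
#' Twelve classifier families share one contract: tune by randomized search
#' with a stratified internal 3-fold cross-validation on the training rows
#' (model selection by mean inner-fold G-mean at threshold 0.5), refit on
#' all rows, and emit class-1 (resistant) probabilities. Backends: logistic
#' regression and ridge/L2 via glmnet; decision tree via rpart; random
#' forest, extremely randomized trees and class-balanced random forest via
#' ranger; RBF support vector machine via e1071 with a Platt-style sigmoid
#' calibrated on seeded inner folds; depthwise gradient boosting, regularized
#' extreme gradient boosting and leaf-wise (loss-guide) histogram boosting
#' via xgboost; SAMME adaptive boosting over rpart trees and oblivious-tree
#' (symmetric) gradient boosting implemented natively.
#'
#' @return character vector of learner ids.
#' @export
list_learners <- function() {
  c("AdaBoost", "BalancedRF", "CatBoost", "DT", "ExtraTrees",
    "GradientBoosting", "KNN", "LGBM", "LR", "RF", "SVM", "XGBoost")
}

# One randomized draw from a learner's hyperparameter search space. Uses the
# current RNG stream (callers wrap in with_seed()).
sample_params <- function(learner_id, p) {
  runif1 <- function(a, b) stats::runif(1, a, b)
  logu <- function(a, b) 10^stats::runif(1, a, b)
  switch(learner_id,
    LR = list(lambda = logu(-3, 2)),
    KNN = list(k = sample(3:15, 1)),
    SVM = list(cost = logu(-2, 2), gamma = logu(-3, 1)),
    DT = list(maxdepth = sample(2:10, 1), minsplit = sample(c(5L, 10L, 20L), 1),
              cp = logu(-4, -1)),
    RF = list(num_trees = sample(50:300, 1),
              mtry = sample(seq_len(max(1L, p)), 1),
              min_node = sample(1:10, 1)),
    ExtraTrees = list(num_trees = sample(50:300, 1),
                      mtry = sample(seq_len(max(1L, p)), 1),
                      min_node = sample(1:10, 1)),
    BalancedRF = list(num_trees = sample(50:300, 1),
                      mtry = sample(seq_len(max(1L, p)), 1),
                      min_node = sample(1:10, 1)),
    GradientBoosting = list(nrounds = sample(50:300, 1), eta = logu(-3, 0.5),
                            max_depth = sample(2:6, 1),
                            subsample = runif1(0.5, 1)),
    XGBoost = list(nrounds = sample(50:300, 1), eta = logu(-3, 0.5),
                   max_depth = sample(2:10, 1), lambda = logu(-2, 1),
                   subsample = runif1(0.5, 1), colsample = runif1(0.5, 1)),
    LGBM = list(nrounds = sample(50:300, 1), eta = logu(-3, 0.5),
                max_leaves = sample(c(7L, 15L, 31L, 63L), 1),
                min_child_weight = logu(-1, 1)),
    AdaBoost = list(n_estimators = sample(50:200, 1),
                    maxdepth = sample(1:3, 1), learning_rate = logu(-2, 0)),
    CatBoost = list(nrounds = sample(30:150, 1), eta = logu(-2, 0),
                    depth = sample(3:6, 1), l2 = logu(-1, 1)),
    stop(sprintf("unknown learner '%s'", learner_id))
  )
}

# Fit one learner with fixed hyperparameters. x: numeric matrix (selected
# features), y: 0/1. Returns an internal fit object for predict_fit().
fit_learner <- function(learner_id, x, y, params, seed = 1L) {
  fit <- switch(learner_id,
    LR = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = params$lambda, standardize = FALSE),
    KNN = list(x = x, y = y, k = min(params$k, nrow(x))),
    SVM = fit_svm_platt(x, y, cost = params$cost, gamma = params$gamma,
                        seed = seed),
    DT = {
      df <- data.frame(y = factor(y, levels = c(0, 1)), x)
      rpart::rpart(y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = params$maxdepth, minsplit = params$minsplit,
                     cp = params$cp, xval = 0))
    },
    RF = ranger::ranger(y = factor(y, levels = c(0, 1)), x = as.data.frame(x),
                        num.trees = params$num_trees,
                        mtry = min(params$mtry, ncol(x)),
                        min.node.size = params$min_node, probability = TRUE,
                        seed = seed, num.threads = 1),
    ExtraTrees = ranger::ranger(y = factor(y, levels = c(0, 1)),
                                x = as.data.frame(x),
                                num.trees = params$num_trees,
                                mtry = min(params$mtry, ncol(x)),
                                min.node.size = params$min_node,
                                splitrule = "extratrees",
                                num.random.splits = 1, probability = TRUE,
                                seed = seed, num.threads = 1),
    BalancedRF = {
      frac <- min(table(factor(y, levels = c(0, 1)))) / length(y)
      ranger::ranger(y = factor(y, levels = c(0, 1)), x = as.data.frame(x),
                     num.trees = params$num_trees,
                     mtry = min(params$mtry, ncol(x)),
                     min.node.size = params$min_node, probability = TRUE,
                     sample.fraction = c(frac, frac), replace = TRUE,
                     seed = seed, num.threads = 1)
    },
    GradientBoosting = xgb_fit(x, y, nrounds = params$nrounds, seed = seed,
                               extra = list(eta = params$eta,
                                            max_depth = params$max_depth,
                                            subsample = params$subsample,
                                            lambda = 0, alpha = 0)),
    XGBoost = xgb_fit(x, y, nrounds = params$nrounds, seed = seed,
                      extra = list(eta = params$eta,
                                   max_depth = params$max_depth,
                                   lambda = params$lambda,
                                   subsample = params$subsample,
                                   colsample_bytree = params$colsample)),
    LGBM = xgb_fit(x, y, nrounds = params$nrounds, seed = seed,
                   extra = list(eta = params$eta, max_depth = 0,
                                grow_policy = "lossguide",
                                max_leaves = params$max_leaves,
                                tree_method = "hist",
                                min_child_weight = params$min_child_weight)),
    AdaBoost = adaboost_fit(x, y, n_estimators = params$n_estimators,
                            maxdepth = params$maxdepth,
                            learning_rate = params$learning_rate),
    CatBoost = oblivious_gbdt_fit(x, y, nrounds = params$nrounds,
                                  eta = params$eta, depth = params$depth,
                                  l2 = params$l2, seed = seed),
    stop(sprintf("unknown learner '%s'", learner_id))
  )
  list(learner_id = learner_id, fit = fit, params = params)
}

xgb_fit <- function(x, y, nrounds, seed, extra) {
  params <- c(list(objective = "binary:logistic", nthread = 1,
                   seed = as.integer(seed)), extra)
  bst <- xgboost::xgb.train(params = params,
                            data = xgboost::xgb.DMatrix(x, label = y),
                            nrounds = nrounds, verbose = 0)
  bst
}

# Native k-NN class-1 probability: mean neighbor label, distance ties broken
# by training row index for determinism.
knn_predict <- function(fit, xnew) {
  tr <- fit$x
  k <- fit$k
  apply(xnew, 1, function(row) {
    d2 <- colSums((t(tr) - row)^2)
    mean(fit$y[order(d2, seq_along(d2))[seq_len(k)]])
  })
}

# RBF SVM with our own Platt-style sigmoid: libsvm's built-in probability
# model shuffles with an unseedable RNG, so decision values are calibrated
# on seeded stratified inner folds instead.
fit_svm_platt <- function(x, y, cost, gamma, seed = 1L, calib_folds = 3L) {
  yf <- factor(y, levels = c(0, 1))
  main <- e1071::svm(x, yf, kernel = "radial", cost = cost, gamma = gamma,
                     scale = FALSE, probability = FALSE)
  folds <- stratified_folds(y, min(calib_folds, min(table(yf))),
                            seed = seed)
  dec <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L) next
    m <- e1071::svm(x[tr, , drop = FALSE], yf[tr], kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
    dv <- attr(stats::predict(m, x[!tr, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    dec[!tr] <- orient_decision(dv)
  }
  ok <- !is.na(dec)
  sig <- platt_sigmoid(dec[ok], y[ok])
  list(svm = main, platt = sig)
}

# libsvm labels the decision column by class order seen in training; make
# positive values always point at class 1.
orient_decision <- function(dv) {
  cn <- colnames(dv)[1]
  v <- as.numeric(dv[, 1])
  if (identical(cn, "0/1")) -v else v
}

# Platt's sigmoid p = 1/(1 + exp(a d + b)) with smoothed targets, fitted by
# cross-entropy minimization.
platt_sigmoid <- function(dec, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  t_hi <- (n1 + 1) / (n1 + 2)
  t_lo <- 1 / (n0 + 2)
  tgt <- ifelse(y == 1, t_hi, t_lo)
  nll <- function(ab) {
    eta <- pmin(pmax(ab[1] * dec + ab[2], -30), 30)
    p <- 1 / (1 + exp(eta))
    -sum(tgt * log(pmax(p, 1e-12)) + (1 - tgt) * log(pmax(1 - p, 1e-12)))
  }
  opt <- stats::optim(c(-1, 0), nll, method = "BFGS")
  list(a = opt$par[1], b = opt$par[2])
}

# Class-1 probabilities from an internal fit object.
predict_fit <- function(model, xnew) {
  id <- model$learner_id
  fit <- model$fit
  p <- switch(id,
    LR = as.numeric(stats::predict(fit, xnew, type = "response")),
    KNN = as.numeric(knn_predict(fit, xnew)),
    SVM = {
      dv <- attr(stats::predict(fit$svm, xnew, decision.values = TRUE),
                 "decision.values")
      d <- orient_decision(dv)
      eta <- pmin(pmax(fit$platt$a * d + fit$platt$b, -30), 30)
      1 / (1 + exp(eta))
    },
    DT = stats::predict(fit, newdata = as.data.frame(xnew),
                        type = "prob")[, "1"],
    RF = ,
    ExtraTrees = ,
    BalancedRF = stats::predict(fit, data = as.data.frame(xnew),
                                num.threads = 1)$predictions[, "1"],
    GradientBoosting = ,
    XGBoost = ,
    LGBM = as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(xnew))),
    AdaBoost = adaboost_predict(fit, xnew),
    CatBoost = oblivious_gbdt_predict(fit, xnew),
    stop(sprintf("unknown learner '%s'", id))
  )
  pmin(pmax(as.numeric(p), 0), 1)
}

# Stratified fold assignment; per-class remainders are offset cumulatively
# across classes so fold sizes stay within one of each other.
stratified_folds <- function(y, n_folds, seed = 1L) {
  assignment <- integer(length(y))
  offset <- 0L
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold_of <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
      assignment[idx] <- fold_of
      offset <- (offset + length(idx)) %% n_folds
    }
  })
  assignment
}

#' Tune and fit one learner on a training split
#'
#' Draws `search_iter` hyperparameter settings from the learner's search
#' space, scores each by the mean G-mean (threshold 0.5) over a stratified
#' internal cross-validation of the rows given here, and refits the best
#' setting on all rows. Deterministic given `seed`; the outer validation
#' fold is never seen.
#'
#' @param learner_id one of [list_learners()].
#' @param x numeric training matrix already restricted to the selected
#'   features (column names retained).
#' @param y binary 0/1 training labels.
#' @param inner_folds internal folds for tuning.
#' @param search_iter randomized-search draws.
#' @param seed integer seed for the draws, fold split and stochastic fits.
#' @return object of class `dwf_learner`.
#' @export
tune_and_fit <- function(learner_id, x, y, inner_folds = 3L,
                         search_iter = 20L, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (length(unique(y)) < 2L) stop("degenerate training set: single class")
  learner_id <- match.arg(learner_id, list_learners())
  inner_folds <- min(inner_folds, min(table(y)))
  folds <- stratified_folds(y, inner_folds, seed = stage_seed(seed, "tune"))
  draws <- with_seed(seed, {
    lapply(seq_len(search_iter), function(i) sample_params(learner_id, ncol(x)))
  })
  orig_names <- colnames(x)
  # neutral syntactic column names: clinical labels like "GRAN#", "A/G" or
  # "NA" are not valid in the formula/data.frame interfaces of the backends
  colnames(x) <- paste0("F", seq_len(ncol(x)))
  cv_score <- vapply(seq_along(draws), function(i) {
    ps <- draws[[i]]
    gs <- vapply(seq_len(inner_folds), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L || !any(!tr)) return(NA_real_)
      m <- fit_learner(learner_id, x[tr, , drop = FALSE], y[tr], ps,
                       seed = stage_seed(seed, "tune", fold = f, cell = i))
      gmean_at(predict_fit(m, x[!tr, , drop = FALSE]), y[!tr], 0.5)
    }, numeric(1))
    mean(gs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(cv_score)  # first max wins: deterministic
  model <- fit_learner(learner_id, x, y, draws[[best]],
                       seed = stage_seed(seed, "tune", fold = 0L, cell = 0L))
  structure(
    list(learner_id = learner_id, params = draws[[best]],
         cv_gmean = cv_score[best], model = model,
         feature_names = orig_names),
    class = "dwf_learner"
  )
}

#' Class-1 probabilities from a fitted learner
#'
#' Columns of `x` are aligned to the training feature list by name before
#' prediction, so column order does not matter.
#'
#' @param object a `dwf_learner` from [tune_and_fit()].
#' @param x numeric matrix containing (at least) the training features.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(object, x) {
  stopifnot(inherits(object, "dwf_learner"), is.matrix(x))
  fn <- object$feature_names
  if (!is.null(fn)) {
    if (!all(fn %in% colnames(x))) stop("feature mismatch at predict time")
    x <- x[, fn, drop = FALSE]
  }
  colnames(x) <- paste0("F", seq_len(ncol(x)))
  predict_fit(object$model, x)
}
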