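#' Combined classifier quality score
#'
#' `CS = w_auc * AUC + w_gmean * G-mean` (defaults 0.6/0.4): the scalar that
#' feeds the softmax weighting of the fused ensemble.
#'
#' @param auc,gmean validation metrics in `[0, 1]`.
#' @param weights length-2 coefficients summing to 1.
#' @return numeric combined score.
#' @export
combined_score <- function(auc, gmean, weights = c(0.6, 0.4)) {
  if (any(auc < 0 | auc > 1, na.rm = TRUE) ||
      any(gmean < 0 | gmean > 1, na.rm = TRUE)) {
    stop("auc and gmean must lie in [0, 1]")
  }
  weights[1] * auc + weights[2] * gmean
}

#' Temperature softmax weights
#'
#' `w_i = exp(cs_i / T) / sum_j exp(cs_j / T)`, computed with
#' max-subtraction for overflow safety. Low temperature concentrates weight
#' on the best combined scores; as `T -> 0` the weights approach the argmax
#' indicator, as `T -> Inf` they approach uniform.
#'
#' @param cs numeric combined scores.
#' @param temperature softmax temperature `T > 0`.
#' @return weights summing to 1, ordered like `cs`.
#' @export
softmax_weights <- function(cs, temperature = 0.1) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (length(cs) == 0) stop("empty score list")
  z <- cs / temperature
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Weighted fusion of base-classifier probabilities
#'
#' Elementwise convex combination `sum_i w_i P_i` of aligned probability
#' vectors.
#'
#' @param probabilities list (or matrix with one column per classifier) of
#'   probability vectors of equal length.
#' @param weights nonnegative weights summing to 1.
#' @return fused probability vector.
#' @export
fuse <- function(probabilities, weights) {
  if (is.list(probabilities)) {
    lens <- lengths(probabilities)
    if (length(unique(lens)) != 1) stop("length mismatch across classifiers")
    P <- do.call(cbind, probabilities)
  } else {
    P <- as.matrix(probabilities)
  }
  if (ncol(P) != length(weights)) stop("length mismatch")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  drop(P %*% weights)
}

#' G-mean-optimal classification threshold
#'
#' Scans the candidate thresholds induced by the score vector (midpoints
#' between consecutive distinct sorted scores, plus guards below the
#' smallest and above the largest score) and returns the one maximizing
#' `sqrt(sensitivity * specificity)`; ties go to the smallest threshold.
#'
#' @param scores fused probabilities on the validation fold.
#' @param labels true 0/1 labels (both classes present).
#' @return list with `threshold` and `gmean`.
#' @export
optimize_threshold <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!is_binary01(labels) || length(unique(labels)) != 2L) {
    stop("labels must contain both classes")
  }
  u <- sort(unique(scores))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  cand <- sort(unique(c(u[1] / 2, mids, (u[length(u)] + 1) / 2)))
  cand <- cand[cand > 0 & cand < 1]
  if (length(cand) == 0) cand <- 0.5
  gm <- vapply(cand, function(th) gmean_at(scores, labels, th), numeric(1))
  best <- which.max(gm)  # which.max returns the first (smallest) maximizer
  list(threshold = cand[best], gmean = gm[best])
}

#' Stratified outer cross-validation folds
#'
#' Every patient lands in exactly one validation fold; class proportions are
#' preserved and per-class remainders are spread over different folds so
#' fold sizes differ by at most one.
#'
#' @param cohort a [cohort_table()] (or a bare 0/1 label vector).
#' @param n number of folds.
#' @param seed RNG seed.
#' @return integer fold assignment (1..n) per patient.
#' @export
make_outer_folds <- function(cohort, n = 5L, seed = 1L) {
  y <- if (inherits(cohort, "cohort_table")) cohort$outcome else cohort
  if (min(table(y)) < n) stop("class too small to stratify into this many folds")
  stratified_folds(y, n, seed = seed)
}

#' Rank grid cells and keep the best
#'
#' Descending validation G-mean; ties broken by higher AUC, then by
#' selector/learner id. Fewer than `n` cells yields all of them with a
#' warning.
#'
#' @param cells data.frame with columns `selector`, `learner`, `auc`,
#'   `gmean` (one row per successful grid cell).
#' @param n number of cells to keep.
#' @return the top rows of `cells`, ranked.
#' @export
select_top <- function(cells, n = 10L) {
  if (NROW(cells) == 0) stop("no successful grid cells")
  ord <- order(-cells$gmean, -cells$auc, cells$selector, cells$learner)
  if (NROW(cells) < n) {
    warning(sprintf("only %d cells available for a top-%d selection",
                    NROW(cells), n))
  }
  cells[ord[seq_len(min(n, NROW(cells)))], , drop = FALSE]
}

# Evaluate the selector x learner grid for one fold. Selector scores are
# computed once per selector and shared across learners. Returns a
# data.frame of metrics plus parallel lists of fitted models, feature sets
# and validation probabilities. Per-cell failures are caught and logged.
evaluate_grid <- function(x_train, y_train, x_val, y_val, x_select, y_select,
                          control, fold, master_seed) {
  p <- ncol(x_train)
  k <- min(control$top_k_features, p)
  sel_feats <- list()
  for (s in control$selectors) {
    sel_feats[[s]] <- tryCatch({
      sc <- score_features(s, x_select, y_select, k = k)
      top_k(sc, k)
    }, error = function(e) {
      dwf_log("fold %d selector %s failed: %s", fold, s, conditionMessage(e),
              verbose = control$verbose)
      NULL
    })
  }
  rows <- list()
  models <- list()
  feats <- list()
  probs <- list()
  ci <- 0L
  for (s in control$selectors) {
    if (is.null(sel_feats[[s]])) next
    fidx <- sel_feats[[s]]
    for (l in control$learners) {
      ci <- ci + 1L
      res <- tryCatch({
        m <- tune_and_fit(l, x_train[, fidx, drop = FALSE], y_train,
                          inner_folds = control$n_inner_folds,
                          search_iter = control$search_iter,
                          seed = stage_seed(master_seed, "tune", fold, ci))
        pv <- predict_proba(m, x_val)
        list(model = m, p = pv,
             auc = auc_rank(pv, y_val), gmean = gmean_at(pv, y_val, 0.5))
      }, error = function(e) {
        dwf_log("fold %d cell %s x %s failed: %s", fold, s, l,
                conditionMessage(e), verbose = control$verbose)
        NULL
      })
      if (is.null(res)) next
      id <- paste(s, l, sep = ":")
      rows[[id]] <- data.frame(selector = s, learner = l, auc = res$auc,
                               gmean = res$gmean, stringsAsFactors = FALSE)
      models[[id]] <- res$model
      feats[[id]] <- fidx
      probs[[id]] <- res$p
    }
  }
  cells <- do.call(rbind, rows)
  if (!is.null(cells)) {
    cells$cs <- combined_score(cells$auc, cells$gmean, control$cs_weights)
    cells$cell_id <- rownames(cells) <- names(rows)
  }
  dwf_log("fold %d: %d/%d grid cells succeeded", fold, NROW(cells),
          length(control$selectors) * length(control$learners),
          verbose = control$verbose)
  list(cells = cells, models = models, features = feats, probs = probs,
       attempted = ci)
}

#' Fit a dynamic weighted fusion ensemble
#'
#' The full pipeline, per outer fold: the preprocessing pipeline is fitted
#' on the training split only (capping, chained-equation imputation,
#' Box-Cox, min-max); the minority class of the training split is
#' oversampled with Borderline-SMOTE; each enabled feature selector picks
#' its top features; each enabled learner is tuned by randomized search
#' under an internal stratified cross-validation and fitted; all grid cells
#' are screened on the validation fold by G-mean, the best
#' `top_n_classifiers` are fused with temperature-softmax weights of the
#' combined score `0.6 AUC + 0.4 G-mean`, and the decision threshold is
#' optimized for G-mean on the fused validation scores. Pooled
#' out-of-fold predictions, recurrence-frequency feature importance and an
#' evaluation report are attached. An oversampling leakage audit runs at the
#' end and any violation aborts the fit.
#'
#' @param x a [cohort_table()], or a formula (see Details).
#' @param ... passed between methods.
#' @param ranges optional [reference_ranges()] for value capping.
#' @param control a [dwf_control()].
#'
#' @details The formula method accepts `outcome ~ .` (all remaining numeric
#' columns as features) or an explicit feature list, with `data` a
#' data.frame; it builds the cohort and forwards to the cohort method.
#'
#' @return an object of class `dwf`; see [predict.dwf()],
#'   [summary.dwf()], [dwf_importance()].
#' @export
dwf <- function(x, ...) UseMethod("dwf")

#' @rdname dwf
#' @param data data.frame holding outcome and features (formula method).
#' @export
dwf.formula <- function(x, data, ranges = NULL, control = dwf_control(),
                        ...) {
  lhs <- all.vars(x[[2]])
  if (length(lhs) != 1L || !lhs %in% names(data)) {
    stop("formula must name one outcome column present in the data")
  }
  rhs <- attr(stats::terms(x, data = data), "term.labels")
  feat_cols <- if (length(rhs) == 0) setdiff(names(data), lhs) else rhs
  mat <- as.matrix(data[, feat_cols, drop = FALSE])
  storage.mode(mat) <- "double"
  cohort <- cohort_table(mat, data[[lhs]])
  dwf.cohort_table(cohort, ranges = ranges, control = control, ...)
}

#' @rdname dwf
#' @export
dwf.cohort_table <- function(x, ranges = NULL, control = dwf_control(), ...) {
  cohort <- x
  y <- cohort$outcome
  X <- cohort$features
  ranges <- ranges %||% reference_ranges(numeric(0))
  if (min(table(y)) < 2 * control$n_outer_folds) {
    stop("minority class too small for the outer cross-validation")
  }
  master <- control$seed
  folds <- make_outer_folds(cohort, control$n_outer_folds,
                            seed = stage_seed(master, "folds"))
  fold_fits <- vector("list", control$n_outer_folds)
  audits <- vector("list", control$n_outer_folds)
  pooled_scores <- rep(NA_real_, length(y))
  pooled_pred <- rep(NA_integer_, length(y))
  cell_pool <- list()  # per-cell pooled validation scores across folds

  for (f in seq_len(control$n_outer_folds)) {
    val_rows <- which(folds == f)
    train_all <- which(folds != f)
    if (control$honest_selection) {
      sub <- stratified_folds(y[train_all], 5L,
                              seed = stage_seed(master, "misc", f))
      eval_rows <- train_all[sub == 1L]    # ~20% tuning slice
      train_rows <- train_all[sub != 1L]
    } else {
      eval_rows <- val_rows
      train_rows <- train_all
    }
    prep <- preprocess_fit(X[train_rows, , drop = FALSE], ranges,
                           boxcox_features = control$boxcox_features)
    x_tr <- prep$train
    x_eval <- preprocess_apply(prep, X[eval_rows, , drop = FALSE])
    y_tr <- y[train_rows]
    y_eval <- y[eval_rows]

    if (isTRUE(control$smote$enabled)) {
      sm <- borderline_smote(x_tr, y_tr,
                             m_neighbors = control$smote$m_neighbors,
                             k_neighbors = control$smote$k_neighbors,
                             target_ratio = control$smote$target_ratio,
                             seed = stage_seed(master, "smote", f))
    } else {
      sm <- list(x = x_tr, y = y_tr,
                 parents = matrix(integer(0), 0, 2), n_synthetic = 0L)
    }
    audits[[f]] <- list(train_rows = train_rows, val_rows = val_rows,
                        parents = sm$parents)
    if (control$select_before_oversample) {
      x_sel <- x_tr; y_sel <- y_tr
    } else {
      x_sel <- sm$x; y_sel <- sm$y
    }
    grid <- evaluate_grid(sm$x, sm$y, x_eval, y_eval, x_sel, y_sel,
                          control, f, master)
    if (is.null(grid$cells)) stop(sprintf("fold %d: every grid cell failed", f))
    top <- select_top(grid$cells, control$top_n_classifiers)
    w <- softmax_weights(top$cs, control$temperature)
    top_probs <- lapply(top$cell_id, function(id) grid$probs[[id]])
    p_fusion_eval <- fuse(top_probs, w)
    th <- optimize_threshold(p_fusion_eval, y_eval)

    if (control$honest_selection) {
      x_val <- preprocess_apply(prep, X[val_rows, , drop = FALSE])
      val_probs <- lapply(top$cell_id, function(id) {
        predict_proba(grid$models[[id]], x_val)
      })
      p_fusion_val <- fuse(val_probs, w)
    } else {
      p_fusion_val <- p_fusion_eval
    }
    pooled_scores[val_rows] <- p_fusion_val
    pooled_pred[val_rows] <- as.integer(p_fusion_val > th$threshold)
    for (id in grid$cells$cell_id) {
      cp <- cell_pool[[id]] %||% rep(NA_real_, length(y))
      cp[eval_rows] <- grid$probs[[id]]
      cell_pool[[id]] <- cp
    }
    fold_fits[[f]] <- list(
      fold = f, preprocess = prep, cells = grid$cells,
      attempted = grid$attempted, top = top, weights = w,
      threshold = th$threshold, val_gmean = th$gmean,
      val_rows = val_rows,
      models = grid$models[top$cell_id],
      features = grid$features[top$cell_id],
      all_features = grid$features
    )
    dwf_log("fold %d fused: gmean %.3f at threshold %.3f", f, th$gmean,
            th$threshold, verbose = control$verbose)
  }
  audit <- guard_no_leakage(folds, audits)
  if (!audit$ok) {
    stop(paste(c("oversampling leakage audit failed:", audit$violations),
               collapse = "\n"))
  }
  model <- structure(
    list(control = control, ranges = ranges, folds = folds,
         fold_fits = fold_fits, outcome = y,
         patient_ids = cohort$patient_ids,
         feature_names = colnames(X),
         pooled_scores = pooled_scores, pooled_pred = pooled_pred,
         cell_pool = cell_pool, audit = audit),
    class = "dwf"
  )
  model$importance <- dwf_importance(model)
  model$report <- dwf_evaluate(model)
  model
}

#' Predict resistance risk with a fitted DWF model
#'
#' Deployment scoring: each fold's ensemble preprocesses the new rows with
#' its own fitted state, fuses its top classifiers with its softmax weights,
#' and the per-fold fused scores are averaged with equal weights. The
#' predicted label is 1 (resistant) iff the averaged score exceeds the mean
#' of the per-fold optimized thresholds. Passing `fold` scores each row
#' with a single fold's ensemble instead (e.g. the fold that held the row
#' out during training, to reproduce pooled cross-validation scores).
#'
#' @param object a fitted `dwf` model.
#' @param newdata a [cohort_table()], data.frame, or numeric matrix holding
#'   the training feature columns.
#' @param fold optional integer vector (one per row) naming the fold
#'   ensemble that should score each row; `NULL` averages all folds.
#' @param ... unused.
#' @return data.frame with `patient_id`, `fused_score`, `predicted_label`.
#' @export
predict.dwf <- function(object, newdata, fold = NULL, ...) {
  if (inherits(newdata, "cohort_table")) {
    X <- newdata$features
    ids <- newdata$patient_ids
  } else if (is.data.frame(newdata)) {
    X <- as.matrix(newdata[, intersect(names(newdata), object$feature_names),
                           drop = FALSE])
    storage.mode(X) <- "double"
    ids <- as.character(seq_len(nrow(X)))
  } else {
    X <- newdata
    ids <- as.character(seq_len(nrow(X)))
  }
  if (!all(object$feature_names %in% colnames(X))) {
    stop("newdata is missing training feature columns")
  }
  X <- X[, object$feature_names, drop = FALSE]
  fold_scores <- vapply(object$fold_fits, function(ff) {
    xv <- preprocess_apply(ff$preprocess, X)
    probs <- lapply(ff$top$cell_id, function(id) {
      predict_proba(ff$models[[id]], xv)
    })
    fuse(probs, ff$weights)
  }, numeric(nrow(X)))
  fold_scores <- matrix(fold_scores, nrow = nrow(X))
  thresholds <- vapply(object$fold_fits, `[[`, numeric(1), "threshold")
  if (is.null(fold)) {
    score <- rowMeans(fold_scores)
    thr <- mean(thresholds)
    lab <- as.integer(score > thr)
  } else {
    stopifnot(length(fold) == nrow(X))
    score <- fold_scores[cbind(seq_len(nrow(X)), fold)]
    lab <- as.integer(score > thresholds[fold])
  }
  data.frame(patient_id = ids, fused_score = score, predicted_label = lab,
             stringsAsFactors = FALSE)
}

#' @export
print.dwf <- function(x, ...) {
  ctl <- x$control
  cat("Dynamic weighted fusion ensemble\n")
  cat(sprintf("  grid: %d selectors x %d learners; %d outer folds\n",
              length(ctl$selectors), length(ctl$learners), ctl$n_outer_folds))
  cat(sprintf("  fusion: top %d cells, softmax T = %g, CS = %.1f AUC + %.1f G-mean\n",
              ctl$top_n_classifiers, ctl$temperature, ctl$cs_weights[1],
              ctl$cs_weights[2]))
  pm <- x$report$pooled_metrics
  cat(sprintf("  pooled: AUC %.3f | accuracy %.3f | sensitivity %.3f | specificity %.3f | G-mean %.3f\n",
              x$report$pooled_auc, pm["accuracy"], pm["sensitivity"],
              pm["specificity"], pm["gmean"]))
  invisible(x)
}

#' @export
summary.dwf <- function(object, ...) {
  structure(list(report = object$report,
                 importance = utils::head(object$importance, 10),
                 control = object$control),
            class = "summary.dwf")
}

#' @export
print.summary.dwf <- function(x, ...) {
  r <- x$report
  cat("Per-fold validation metrics (mean [95% CI] across folds):\n")
  print(round(r$ci_table, 3))
  cat("\nPooled confusion matrix (rows = truth, resistant = positive):\n")
  print(r$pooled_confusion)
  cat(sprintf("\nPooled AUC: %.3f  (fold-mean AUC %.3f)\n", r$pooled_auc,
              r$ci_table["auc", "mean"]))
  cat("\nTop features by recurrence frequency:\n")
  print(x$importance, row.names = FALSE)
  invisible(x)
}

#' @export
coef.dwf <- function(object, ...) {
  do.call(rbind, lapply(object$fold_fits, function(ff) {
    data.frame(fold = ff$fold, cell = ff$top$cell_id, gmean = ff$top$gmean,
               auc = ff$top$auc, cs = ff$top$cs, weight = ff$weights,
               stringsAsFactors = FALSE)
  }))
}

#' @export
residuals.dwf <- function(object, ...) {
  object$outcome - object$pooled_scores
}

#' @export
plot.dwf <- function(x, type = c("importance", "roc"), n_features = 15, ...) {
  type <- match.arg(type)
  if (type == "importance") {
    imp <- utils::head(x$importance, n_features)
    graphics::barplot(rev(imp$score), names.arg = rev(imp$feature),
                      horiz = TRUE, las = 1, col = "steelblue",
                      xlab = "ranking score (selection frequency)",
                      main = "Recurrence-frequency feature importance")
  } else {
    o <- order(x$pooled_scores, decreasing = TRUE)
    y <- x$outcome[o]
    tpr <- cumsum(y == 1) / sum(y == 1)
    fpr <- cumsum(y == 0) / sum(y == 0)
    graphics::plot(c(0, fpr), c(0, tpr), type = "l", col = "firebrick",
                   xlab = "1 - specificity", ylab = "sensitivity",
                   main = sprintf("Pooled ROC (AUC %.3f)", x$report$pooled_auc))
    graphics::abline(0, 1, lty = 2, col = "grey")
  }
  invisible(x)
}

#' Evaluation report for a fitted DWF model
#'
#' Per-fold metric table with fold-aggregated t-intervals, the pooled
#' confusion matrix and metric suite, the pooled AUC, and a DeLong
#' comparison of the fused model against the best pooled single grid cell.
#'
#' @param model a fitted `dwf`.
#' @return list of class `dwf_report`.
#' @export
dwf_evaluate <- function(model) {
  y <- model$outcome
  fold_metrics <- lapply(model$fold_fits, function(ff) {
    vr <- ff$val_rows
    sc <- model$pooled_scores[vr]
    pd <- model$pooled_pred[vr]
    cm <- confusion(y[vr], pd)
    c(auc = auc_rank(sc, y[vr]), metric_suite(cm))
  })
  fm <- do.call(rbind, fold_metrics)
  ci_table <- t(apply(fm, 2, function(v) fold_ci(v)))
  pooled_cm <- Reduce(`+`, lapply(model$fold_fits, function(ff) {
    confusion(y[ff$val_rows], model$pooled_pred[ff$val_rows])
  }))
  # best single cell on pooled out-of-fold scores (cells present in every fold)
  complete_cells <- names(model$cell_pool)[
    vapply(model$cell_pool, function(v) !anyNA(v), logical(1))]
  delong <- NULL
  best_cell <- NULL
  if (length(complete_cells)) {
    cell_gmeans <- vapply(complete_cells, function(id) {
      gmean_at(model$cell_pool[[id]], y, 0.5)
    }, numeric(1))
    best_cell <- complete_cells[order(-cell_gmeans,
                                      complete_cells)][1]
    delong <- delong_test(model$pooled_scores, model$cell_pool[[best_cell]], y)
  }
  structure(
    list(fold_metrics = fm, ci_table = ci_table,
         pooled_confusion = pooled_cm,
         pooled_metrics = metric_suite(pooled_cm),
         pooled_auc = auc_rank(model$pooled_scores, y),
         best_cell = best_cell, delong_vs_best_cell = delong),
    class = "dwf_report"
  )
}

#' Export a DWF evaluation report as JSON
#' @param model a fitted `dwf`.
#' @param path output path.
#' @export
write_report <- function(model, path) {
  r <- model$report
  obj <- list(
    fold_metrics = as.data.frame(r$fold_metrics),
    ci = as.data.frame(cbind(metric = rownames(r$ci_table), r$ci_table)),
    pooled_confusion = unclass(r$pooled_confusion),
    pooled_metrics = as.list(r$pooled_metrics),
    pooled_auc = r$pooled_auc,
    best_cell = r$best_cell,
    delong_vs_best_cell = r$delong_vs_best_cell,
    importance = model$importance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
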