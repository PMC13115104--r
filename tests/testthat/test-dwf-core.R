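test_that("stratified outer folds balance both classes and reproduce", {
  y <- c(rep(1L, 91), rep(0L, 231))
  f <- make_outer_folds(y, 5, seed = 3)
  sizes <- table(f)
  expect_true(all(sizes >= 64 & sizes <= 65))
  res_per_fold <- table(f[y == 1])
  expect_true(all(res_per_fold >= 18 & res_per_fold <= 19))
  expect_identical(make_outer_folds(y, 5, seed = 3), f)
  expect_false(identical(make_outer_folds(y, 5, seed = 4), f))

  tiny <- make_outer_folds(c(0L, 0L, 1L, 1L), 2, seed = 1)
  expect_equal(as.numeric(table(tiny)), c(2, 2))
  expect_error(make_outer_folds(c(0L, 1L, 1L), 2), "too small")
})

test_that("combined score is the fixed AUC/G-mean blend", {
  expect_equal(combined_score(1, 1), 1)
  expect_equal(combined_score(0.5, 0), 0.30)
  expect_equal(combined_score(0.760, 0.757), 0.7588)
  expect_error(combined_score(1.2, 0.5), "\\[0, 1\\]")
})

test_that("softmax weights normalize, order, and hit both temperature limits", {
  w <- softmax_weights(rep(0.7, 10), 0.1)
  expect_equal(w, rep(0.1, 10))
  w2 <- softmax_weights(c(0.8, 0.7), 0.1)
  expect_equal(w2, c(1 / (1 + exp(-1)), 1 / (1 + exp(1))), tolerance = 1e-12)
  withr::with_seed(2, {
    for (r in 1:20) {
      cs <- runif(sample(2:12, 1))
      w <- softmax_weights(cs, runif(1, 0.01, 5))
      expect_equal(sum(w), 1, tolerance = 1e-12)
      expect_identical(order(w), order(cs))
    }
  })
  cs <- c(0.61, 0.93, 0.40)
  expect_equal(softmax_weights(cs, 1e-4), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(softmax_weights(cs, 1e4), rep(1 / 3, 3), tolerance = 1e-3)
  expect_error(softmax_weights(cs, 0), "temperature")
})

test_that("fusion is the exact weighted average and stays convex", {
  withr::with_seed(11, {
    P <- replicate(10, runif(25), simplify = FALSE)
    w <- softmax_weights(runif(10), 0.3)
  })
  fused <- fuse(P, w)
  oracle <- numeric(25)
  for (i in 1:10) oracle <- oracle + w[i] * P[[i]]
  expect_equal(fused, oracle, tolerance = 1e-12)
  Pm <- do.call(cbind, P)
  expect_true(all(fused >= apply(Pm, 1, min) - 1e-12))
  expect_true(all(fused <= apply(Pm, 1, max) + 1e-12))
  expect_equal(fuse(list(P[[1]], P[[1]]), c(0.4, 0.6)), P[[1]])
  expect_equal(fuse(P[1:2], c(1, 0)), P[[1]])
  expect_error(fuse(list(runif(3), runif(4)), c(0.5, 0.5)), "mismatch")
})

test_that("threshold optimization attains the dense-grid maximum", {
  # perfectly separated scores: G-mean 1 at the optimum
  sep <- optimize_threshold(c(0.8, 0.9, 0.7, 0.1, 0.2, 0.3),
                            c(1, 1, 1, 0, 0, 0))
  expect_equal(sep$gmean, 1)
  expect_true(sep$threshold > 0.3 && sep$threshold < 0.7)
  expect_error(optimize_threshold(runif(5), rep(1, 5)), "both classes")

  grid <- seq(0, 1, length.out = 1001)
  for (r in 1:5) {
    withr::with_seed(300 + r, {
      sc <- runif(50)
      y <- rbinom(50, 1, 0.35)
    })
    if (length(unique(y)) < 2) next
    opt <- optimize_threshold(sc, y)
    gm_grid <- vapply(grid, function(th) dwfusion:::gmean_at(sc, y, th),
                      numeric(1))
    # with continuous scores the candidate scan can only beat an evenly
    # spaced sweep, never lose to it
    expect_gte(opt$gmean, max(gm_grid, na.rm = TRUE) - 1e-12)
    expect_equal(dwfusion:::gmean_at(sc, y, opt$threshold), opt$gmean,
                 tolerance = 1e-12)
    expect_true(opt$threshold > 0 && opt$threshold < 1)
  }
})

test_that("top-cell selection ranks by G-mean with AUC tie-breaks", {
  cells <- data.frame(
    selector = c("s1", "s1", "s2", "s2"),
    learner = c("l1", "l2", "l1", "l2"),
    auc = c(0.70, 0.65, 0.70, 0.80),
    gmean = c(0.6, 0.6, 0.5, 0.9))
  top <- select_top(cells, 2)
  expect_identical(top$learner, c("l2", "l1"))
  expect_identical(top$selector, c("s2", "s1"))  # tie on gmean: auc decides
  expect_warning(all4 <- select_top(cells, 10), "only 4")
  expect_equal(nrow(all4), 4)
  expect_error(select_top(cells[0, ], 3), "no successful")
})

test_that("a small DWF fit honors its structural contracts", {
  fx <- fixture_dwf_fit()
  fit <- fx$fit
  co <- fx$cohort
  expect_s3_class(fit, "dwf")
  # pooled predictions cover the whole cohort
  expect_false(anyNA(fit$pooled_scores))
  expect_length(fit$pooled_scores, nrow(co$features))
  expect_true(fit$audit$ok)
  # degenerate 2x2 grid: weights over 4 cells, summing to 1
  for (ff in fit$fold_fits) {
    expect_equal(nrow(ff$top), 4)
    expect_equal(sum(ff$weights), 1, tolerance = 1e-12)
    expect_true(all(ff$weights > 0))
    expect_true(ff$threshold > 0 && ff$threshold < 1)
  }
  # importance scores normalized by the actual cell count (4 x 5 folds)
  expect_equal(attr(fit$importance, "n_cells"), 20L)
  expect_true(all(fit$importance$score >= 0 & fit$importance$score <= 1))
  # fitting twice with the same master seed reproduces all cell metrics
  refit <- dwf(co, control = fit$control)
  for (f in seq_along(fit$fold_fits)) {
    expect_equal(refit$fold_fits[[f]]$cells, fit$fold_fits[[f]]$cells)
  }
  expect_identical(refit$pooled_scores, fit$pooled_scores)
})

test_that("deployment prediction averages fold ensembles; labels follow scores", {
  fx <- fixture_dwf_fit()
  fit <- fx$fit
  co <- fx$cohort
  pr <- predict(fit, co)
  expect_equal(nrow(pr), nrow(co$features))
  # longhand loop oracle: deployment score = mean of the 5 fold scores
  fold_scores <- sapply(fit$fold_fits, function(ff) {
    xv <- preprocess_apply(ff$preprocess, co$features)
    fuse(lapply(ff$top$cell_id, function(id) {
      predict_proba(ff$models[[id]], xv)
    }), ff$weights)
  })
  expect_equal(pr$fused_score, rowMeans(fold_scores), tolerance = 1e-12)
  thr <- mean(sapply(fit$fold_fits, `[[`, "threshold"))
  expect_identical(pr$predicted_label, as.integer(pr$fused_score > thr))
  # scoring each row with its own held-out fold reproduces pooled scores
  pr_fold <- predict(fit, co, fold = fit$folds)
  expect_equal(pr_fold$fused_score, fit$pooled_scores, tolerance = 1e-12)
  expect_error(predict(fit, co$features[, 1:3]), "missing")
})

test_that("validation rows cannot influence fold-local fitted state", {
  co <- toy_cohort(n = 120, p = 6, seed = 19)
  ctl <- dwf_control(selectors = c("F_score", "T_score"),
                     learners = c("LR", "DT"), top_n_classifiers = 4,
                     search_iter = 2, seed = 21)
  fit1 <- dwf(co, control = ctl)
  # perturb the *features* of fold 1's validation rows (labels untouched, so
  # the fold assignment is identical)
  co2 <- co
  v1 <- which(fit1$folds == 1)
  co2$features[v1, ] <- co2$features[v1, ] + 5
  fit2 <- dwf(co2, control = ctl)
  expect_identical(fit2$folds, fit1$folds)
  f1a <- fit1$fold_fits[[1]]
  f1b <- fit2$fold_fits[[1]]
  # preprocessing state, selected features and tuned hyperparameters of the
  # fold that held those rows out are unchanged
  expect_equal(f1a$preprocess$minmax, f1b$preprocess$minmax)
  expect_equal(f1a$preprocess$boxcox, f1b$preprocess$boxcox)
  expect_identical(f1a$all_features, f1b$all_features)
  for (id in f1a$top$cell_id) {
    expect_identical(f1a$models[[id]]$params, f1b$models[[id]]$params)
  }
  # ...while the validation metrics of that fold do change
  expect_false(isTRUE(all.equal(f1a$cells$auc, f1b$cells$auc)))
})

test_that("summary, coefficients and residual accessors are coherent", {
  fx <- fixture_dwf_fit()
  fit <- fx$fit
  s <- summary(fit)
  expect_s3_class(s, "summary.dwf")
  cf <- coef(fit)
  expect_equal(nrow(cf), 4 * 5)
  agg <- tapply(cf$weight, cf$fold, sum)
  expect_equal(as.numeric(agg), rep(1, 5), tolerance = 1e-12)
  r <- residuals(fit)
  expect_equal(r, fit$outcome - fit$pooled_scores)
  expect_output(print(fit), "Dynamic weighted fusion")
})
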