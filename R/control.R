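#' Control parameters for a DWF fit
#'
#' Bundles every tunable of the dynamic weighted fusion pipeline. The
#' defaults reproduce the published configuration: a 5-fold outer
#' cross-validation with 3 inner folds for randomized hyperparameter search,
#' the top 10 features per selector, the top 10 base classifiers per fold,
#' softmax temperature `T = 0.1`, and a combined score `0.6 * AUC +
#' 0.4 * G-mean`.
#'
#' @param n_outer_folds number of outer (stratified) cross-validation folds.
#' @param n_inner_folds inner folds for randomized-search tuning.
#' @param top_k_features features kept by each selector.
#' @param top_n_classifiers base classifiers fused per fold.
#' @param temperature softmax temperature `T` (> 0); low values concentrate
#'   weight on the best-scoring classifiers.
#' @param cs_weights length-2 numeric `(AUC, G-mean)` coefficients of the
#'   combined score; must sum to 1.
#' @param selectors character vector of enabled selector ids
#'   (see [list_selectors()]).
#' @param learners character vector of enabled learner ids
#'   (see [list_learners()]).
#' @param search_iter randomized-search draws per learner.
#' @param smote list of Borderline-SMOTE settings: `m_neighbors` (danger
#'   detection), `k_neighbors` (synthesis), `target_ratio`
#'   (minority:majority after resampling, \eqn{\le} 1), `enabled`.
#' @param select_before_oversample if `TRUE`, selectors score the original
#'   training rows rather than the oversampled set.
#' @param honest_selection if `TRUE`, each training split donates a 20%
#'   tuning slice used for ranking/weighting/thresholding so the validation
#'   fold is never reused for selection.
#' @param boxcox_features `"all"` or a character vector of feature names to
#'   Box-Cox transform.
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @param verbose emit progress messages.
#' @return a list of class `dwf_control`.
#' @export
dwf_control <- function(n_outer_folds = 5L, n_inner_folds = 3L,
                        top_k_features = 10L, top_n_classifiers = 10L,
                        temperature = 0.1, cs_weights = c(0.6, 0.4),
                        selectors = list_selectors(),
                        learners = list_learners(),
                        search_iter = 20L,
                        smote = list(m_neighbors = 5L, k_neighbors = 5L,
                                     target_ratio = 1, enabled = TRUE),
                        select_before_oversample = FALSE,
                        honest_selection = FALSE,
                        boxcox_features = "all",
                        seed = 1L, verbose = FALSE) {
  stopifnot(n_outer_folds >= 2L, n_inner_folds >= 2L)
  if (temperature <= 0) stop("temperature must be > 0")
  if (length(cs_weights) != 2L || abs(sum(cs_weights) - 1) > 1e-8) {
    stop("cs_weights must be two coefficients summing to 1")
  }
  selectors <- match.arg(selectors, list_selectors(), several.ok = TRUE)
  learners <- match.arg(learners, list_learners(), several.ok = TRUE)
  grid_size <- length(selectors) * length(learners)
  if (grid_size < 1L) stop("empty selector/learner grid")
  smote_defaults <- list(m_neighbors = 5L, k_neighbors = 5L,
                         target_ratio = 1, enabled = TRUE)
  smote <- utils::modifyList(smote_defaults, smote)
  if (smote$m_neighbors < 1L || smote$k_neighbors < 1L) {
    stop("SMOTE neighbor counts must be >= 1")
  }
  if (smote$target_ratio > 1 || smote$target_ratio <= 0) {
    stop("SMOTE target ratio must be in (0, 1]")
  }
  structure(
    list(n_outer_folds = as.integer(n_outer_folds),
         n_inner_folds = as.integer(n_inner_folds),
         top_k_features = as.integer(top_k_features),
         top_n_classifiers = as.integer(top_n_classifiers),
         temperature = temperature, cs_weights = as.numeric(cs_weights),
         selectors = selectors, learners = learners,
         search_iter = as.integer(search_iter), smote = smote,
         select_before_oversample = isTRUE(select_before_oversample),
         honest_selection = isTRUE(honest_selection),
         boxcox_features = boxcox_features,
         seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "dwf_control"
  )
}

#' Read/write a run configuration as JSON
#' @param path JSON file path.
#' @return `read_run_config()` returns a `dwf_control`.
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$smote)) obj$smote <- as.list(obj$smote)
  do.call(dwf_control, obj)
}

#' @rdname read_run_config
#' @param control a `dwf_control`.
#' @export
write_run_config <- function(control, path) {
  jsonlite::write_json(unclass(control), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
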