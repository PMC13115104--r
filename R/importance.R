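#' Recurrence-frequency feature importance
#'
#' Counts how often each feature appears in the selected-feature sets of the
#' fused top classifiers — by default the top 10 cells of each of the 5
#' folds, i.e. 50 optimized classifiers. The ranking score is
#' `count / n_cells`, so a feature chosen by every fused classifier scores
#' exactly 1 and scores are multiples of `1/50` at the default
#' configuration. Ties are broken by feature name.
#'
#' @param model a fitted [dwf()] model.
#' @return data.frame (class `dwf_importance`) with `feature`, `count`,
#'   `score`, `rank`, in descending score order; every feature is listed,
#'   including zero-count ones.
#' @export
dwf_importance <- function(model) {
  stopifnot(inherits(model, "dwf"))
  if (length(model$fold_fits) == 0) stop("no fitted folds")
  fn <- model$feature_names
  counts <- stats::setNames(integer(length(fn)), fn)
  n_cells <- 0L
  for (ff in model$fold_fits) {
    for (fidx in ff$features) {
      counts[fn[fidx]] <- counts[fn[fidx]] + 1L
      n_cells <- n_cells + 1L
    }
  }
  score <- as.numeric(counts) / n_cells
  ord <- order(-score, fn)
  out <- data.frame(feature = fn[ord], count = as.integer(counts[ord]),
                    score = score[ord], rank = seq_along(fn),
                    stringsAsFactors = FALSE)
  attr(out, "n_cells") <- n_cells
  class(out) <- c("dwf_importance", "data.frame")
  out
}

#' Union of features selected anywhere in the grid
#'
#' Two populations of cells can define the union: the fused top cells only
#' (`cells = "top"`), or every successful grid cell (`cells = "all"`).
#'
#' @param model a fitted [dwf()] model.
#' @param cells which cell population to union over.
#' @return list with `features` (character vector) and `provenance`
#'   (data.frame fold/cell/feature).
#' @export
unique_selected_features <- function(model, cells = c("top", "all")) {
  stopifnot(inherits(model, "dwf"))
  cells <- match.arg(cells)
  fn <- model$feature_names
  prov <- list()
  for (ff in model$fold_fits) {
    sets <- if (cells == "top") ff$features else ff$all_features
    for (id in names(sets)) {
      prov[[length(prov) + 1L]] <- data.frame(
        fold = ff$fold, cell = id, feature = fn[sets[[id]]],
        stringsAsFactors = FALSE)
    }
  }
  prov <- do.call(rbind, prov)
  list(features = sort(unique(prov$feature)), provenance = prov)
}

#' Write an importance ranking to CSV and/or JSON
#' @param importance a `dwf_importance`.
#' @param path output path; extension picks the format (.csv or .json).
#' @export
write_importance <- function(importance, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(importance, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(importance, path, row.names = FALSE)
  }
  invisible(path)
}
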