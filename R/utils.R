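# Internal helpers: seeded evaluation, stage-derived seeds, logging.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derivation from one master seed. Offsets are
# small named constants so every stochastic stage draws from an independent,
# documented stream; the result always stays inside 32-bit integer range.
stage_seed <- function(master, stage, fold = 0L, cell = 0L) {
  stages <- c(folds = 1L, preprocess = 2L, smote = 3L, select = 4L,
              tune = 5L, generate = 6L, misc = 7L)
  s <- stages[[stage]]
  v <- (as.double(master) * 7919 + s * 104729 + fold * 15485863 +
          cell * 32452843) %% 2147483629
  as.integer(v) + 1L
}

dwf_log <- function(..., verbose = getOption("dwfusion.verbose", FALSE)) {
  if (isTRUE(verbose)) {
    message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
  }
  invisible(NULL)
}

is_binary01 <- function(y) {
  !anyNA(y) && all(y %in% c(0, 1))
}
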