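#' Cohort tables
#'
#' A `cohort_table` holds a patient-by-feature numeric matrix of routine
#' laboratory/clinical measurements together with a binary outcome per
#' patient. The positive class (outcome `1`) is the platinum-resistant group;
#' `0` marks platinum-sensitive patients. Missing measurements are stored as
#' `NA` in the feature matrix and exposed through [missing_mask()].
#'
#' @param features numeric matrix (rows = patients, columns = features) with
#'   `NA` for missing cells. Column names are the feature labels; the `#`
#'   suffix used for absolute blood-cell counts is kept verbatim.
#' @param outcome binary vector (`0`/`1`), one entry per row of `features`;
#'   `1` is the resistant (positive) class.
#' @param patient_ids optional identifiers; defaults to row numbers.
#' @return an object of class `cohort_table`.
#' @seealso [read_cohort()], [generate_cohort()]
#' @export
cohort_table <- function(features, outcome, patient_ids = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("V", seq_len(ncol(features)))
  }
  if (anyDuplicated(colnames(features))) {
    stop("duplicate feature names in cohort")
  }
  outcome <- as.numeric(outcome)
  if (length(outcome) != nrow(features)) {
    stop("outcome length does not match number of patients")
  }
  if (!is_binary01(outcome)) {
    stop("outcome must be binary 0/1 with no missing values")
  }
  if (length(unique(outcome)) != 2L) {
    stop("single-class outcome: both classes must be present")
  }
  if (is.null(patient_ids)) patient_ids <- as.character(seq_len(nrow(features)))
  patient_ids <- as.character(patient_ids)
  if (length(patient_ids) != nrow(features)) {
    stop("patient_ids length does not match number of patients")
  }
  structure(
    list(features = features, outcome = as.integer(outcome),
         patient_ids = patient_ids),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  n <- nrow(x$features)
  p <- ncol(x$features)
  cat(sprintf("cohort_table: %d patients x %d features\n", n, p))
  cat(sprintf("  outcome: %d resistant (positive) / %d sensitive\n",
              sum(x$outcome == 1L), sum(x$outcome == 0L)))
  cat(sprintf("  missing cells: %d (%.2f%%)\n", sum(is.na(x$features)),
              100 * mean(is.na(x$features))))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$features)

#' Boolean mask of missing feature cells
#' @param x a `cohort_table`.
#' @return logical matrix, `TRUE` where the measurement is absent.
#' @export
missing_mask <- function(x) {
  stopifnot(inherits(x, "cohort_table"))
  is.na(x$features)
}

#' @rdname cohort_table
#' @param x a `cohort_table`.
#' @export
feature_names <- function(x) {
  stopifnot(inherits(x, "cohort_table"))
  colnames(x$features)
}

# Row subset preserving class; used by the fold machinery.
cohort_subset <- function(x, rows) {
  structure(
    list(features = x$features[rows, , drop = FALSE],
         outcome = x$outcome[rows], patient_ids = x$patient_ids[rows]),
    class = "cohort_table"
  )
}

#' Read a cohort from a delimited text file
#'
#' Parses a comma-separated table (header row, `.` decimal, UTF-8) into a
#' [cohort_table()]. Empty strings and `"NA"` are treated as missing, as is
#' any cell that does not coerce to a number; the missing mask records them.
#' Column order is preserved.
#'
#' @param path file path of the CSV.
#' @param outcome_column name of the binary outcome column (1 = resistant).
#' @param id_column optional name of a patient-identifier column.
#' @return a `cohort_table`.
#' @export
read_cohort <- function(path, outcome_column, id_column = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = c("", "NA"),
                         fileEncoding = "UTF-8")
  if (!outcome_column %in% names(raw)) {
    stop(sprintf("outcome column '%s' not found", outcome_column))
  }
  ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(raw)) stop(sprintf("id column '%s' not found", id_column))
    ids <- raw[[id_column]]
  }
  y <- suppressWarnings(as.numeric(raw[[outcome_column]]))
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("outcome column must contain only 0/1 values")
  }
  if (length(unique(y)) != 2L) stop("single-class outcome")
  drop_cols <- c(outcome_column, id_column)
  feat_cols <- setdiff(names(raw), drop_cols)
  if (anyDuplicated(feat_cols)) stop("duplicate feature names")
  mat <- vapply(feat_cols, function(cn) suppressWarnings(as.numeric(raw[[cn]])),
                numeric(nrow(raw)))
  mat <- matrix(mat, nrow = nrow(raw),
                dimnames = list(NULL, feat_cols))
  cohort_table(mat, y, patient_ids = ids)
}

#' Write a cohort to CSV
#'
#' Missing cells are written as empty strings so that
#' `read_cohort(write_cohort(x))` round-trips numeric values bit-identically.
#'
#' @param x a `cohort_table`.
#' @param path output file path.
#' @param outcome_column name for the outcome column.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, outcome_column = "outcome") {
  stopifnot(inherits(x, "cohort_table"))
  df <- as.data.frame(x$features, check.names = FALSE)
  # format() with digits = 17 round-trips doubles exactly
  df[] <- lapply(df, function(col) {
    out <- vapply(col, function(v) {
      if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE)
    }, character(1))
    out
  })
  df <- cbind(patient_id = x$patient_ids, df,
              stats::setNames(data.frame(x$outcome), outcome_column))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-feature reference-range map
#'
#' Reference ranges give the standard upper limit of each laboratory feature;
#' values above the limit are capped during preprocessing. Accepts either a
#' JSON object (`{"WBC": 9.5, ...}`) or a two-column CSV (`feature,upper`).
#' Features of the cohort without an entry pass through uncapped; entries for
#' unknown features are ignored with a warning at cap time.
#'
#' @param path JSON or CSV file path.
#' @return named numeric vector of upper limits (class `reference_ranges`).
#' @export
read_reference_ranges <- function(path) {
  is_json <- grepl("\\.json$", path, ignore.case = TRUE)
  if (is_json) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (length(obj) == 0) return(reference_ranges(numeric(0)))
    lim <- unlist(obj)
    lim2 <- suppressWarnings(as.numeric(lim))
    if (anyNA(lim2)) stop("non-numeric reference limit")
    names(lim2) <- names(lim)
    reference_ranges(lim2)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) == 0) return(reference_ranges(numeric(0)))
    lim <- suppressWarnings(as.numeric(df[[2]]))
    if (anyNA(lim)) stop("non-numeric reference limit")
    reference_ranges(stats::setNames(lim, as.character(df[[1]])))
  }
}

#' @rdname read_reference_ranges
#' @param limits named numeric vector of finite, positive upper limits.
#' @export
reference_ranges <- function(limits) {
  limits <- unlist(limits)
  if (length(limits)) {
    limits <- stats::setNames(as.numeric(limits), names(limits))
    if (anyNA(limits) || any(!is.finite(limits))) stop("reference limits must be finite")
    if (any(limits <= 0)) stop("reference limits must be positive")
    if (is.null(names(limits)) || any(names(limits) == "")) {
      stop("reference limits must be named by feature")
    }
  }
  structure(limits, class = "reference_ranges")
}

#' Write reference ranges as JSON
#' @param ranges a `reference_ranges` object.
#' @param path output path.
#' @export
write_reference_ranges <- function(ranges, path) {
  jsonlite::write_json(as.list(unclass(ranges)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
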