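# Feature roster of the emulated cohort: 2 clinical characteristics, 24
# complete-blood-count values, 29 liver/renal panel values, 8 tumor markers
# and 7 coagulation measurements (70 total). Each row: block, marginal
# family, location and scale (meanlog/sdlog for the lognormal family). The
# '#' suffix marks absolute blood-cell counts and is kept verbatim.
synth_feature_table <- function() {
  f <- function(name, block, family, loc, scale) {
    data.frame(name = name, block = block, family = family, loc = loc,
               scale = scale, stringsAsFactors = FALSE)
  }
  rbind(
    f("Age", "clinical", "normal", 56, 10),
    f("BMI", "clinical", "normal", 23.3, 3),
    f("WBC", "cbc", "normal", 6.8, 2), f("LYM", "cbc", "normal", 24, 8),
    f("MID", "cbc", "normal", 8, 3), f("GRAN", "cbc", "normal", 68, 10),
    f("EOS", "cbc", "normal", 2, 1.5), f("BASO", "cbc", "normal", 0.5, 0.3),
    f("LYM#", "cbc", "normal", 1.6, 0.6), f("MID#", "cbc", "normal", 0.5, 0.2),
    f("GRAN#", "cbc", "normal", 4.7, 1.8), f("EOS#", "cbc", "normal", 0.15, 0.1),
    f("BASO#", "cbc", "normal", 0.03, 0.02), f("RBC", "cbc", "normal", 4.3, 0.5),
    f("HGB", "cbc", "normal", 128, 15), f("HCT", "cbc", "normal", 38, 4),
    f("MCV", "cbc", "normal", 90, 5), f("MCH", "cbc", "normal", 30, 2),
    f("MCHC", "cbc", "normal", 330, 10), f("RDWCV", "cbc", "normal", 13.5, 1.5),
    f("RDWSD", "cbc", "normal", 43, 3), f("PLT", "cbc", "normal", 260, 80),
    f("MPV", "cbc", "normal", 10, 1), f("PCT", "cbc", "normal", 0.25, 0.07),
    f("PDW", "cbc", "normal", 14, 2), f("NL", "cbc", "normal", 3.9, 2),
    f("TBIL", "hepatorenal", "normal", 11, 5),
    f("DBIL", "hepatorenal", "normal", 3.5, 1.5),
    f("IBIL", "hepatorenal", "normal", 7.5, 3.5),
    f("ALP", "hepatorenal", "normal", 75, 25),
    f("ALT", "hepatorenal", "normal", 18, 10),
    f("AST", "hepatorenal", "normal", 20, 8),
    f("ASTM", "hepatorenal", "normal", 1.2, 0.4),
    f("LDH", "hepatorenal", "normal", 180, 50),
    f("GGT", "hepatorenal", "normal", 25, 15),
    f("TP", "hepatorenal", "normal", 70, 6),
    f("ALB", "hepatorenal", "normal", 42, 4),
    f("GELO", "hepatorenal", "normal", 28, 4),
    f("A/G", "hepatorenal", "normal", 1.5, 0.3),
    f("NEFA", "hepatorenal", "normal", 0.5, 0.2),
    f("PA", "hepatorenal", "normal", 220, 50),
    f("GLDH", "hepatorenal", "normal", 5, 3),
    f("CYSC", "hepatorenal", "normal", 0.9, 0.2),
    f("GA", "hepatorenal", "normal", 13, 2.5),
    f("UREA", "hepatorenal", "normal", 4.4, 1.3),
    f("CRE", "hepatorenal", "normal", 62, 12),
    f("UA", "hepatorenal", "normal", 290, 70),
    f("GLU", "hepatorenal", "normal", 5.2, 1),
    f("CA", "hepatorenal", "normal", 2.3, 0.12),
    f("P", "hepatorenal", "normal", 1.15, 0.18),
    f("MG", "hepatorenal", "normal", 0.88, 0.08),
    f("K", "hepatorenal", "normal", 4.1, 0.4),
    f("NA", "hepatorenal", "normal", 140, 3),
    f("CL", "hepatorenal", "normal", 103, 3),
    f("TCO2", "hepatorenal", "normal", 25, 2.5),
    f("SCCA", "tumor", "lognormal", 0.1, 0.6),
    f("CA19-9", "tumor", "lognormal", 2.4, 1.1),
    f("CA125", "tumor", "lognormal", 4.5, 1.6),
    f("AFP", "tumor", "lognormal", 1.1, 0.6),
    f("CEA", "tumor", "lognormal", 0.6, 0.8),
    f("NSE", "tumor", "lognormal", 2.6, 0.5),
    f("HCG-B", "tumor", "lognormal", 0.3, 0.9),
    f("HE4", "tumor", "lognormal", 4.6, 1.0),
    f("PT", "coag", "normal", 11.5, 1),
    f("FIB", "coag", "normal", 3.9, 0.9),
    f("APTT", "coag", "normal", 27, 3),
    f("TT", "coag", "normal", 17, 1.5),
    f("INR", "coag", "normal", 0.95, 0.08),
    f("DDI", "coag", "lognormal", 0.0, 1.0),
    f("FDP", "coag", "lognormal", 1.6, 0.6)
  )
}

# Standardized latent mean shifts of the resistant class (positive =
# elevated in resistant patients). Directions follow the reported
# class-dependent alterations; magnitudes are calibration choices placing
# single-feature discrimination in the weak univariable regime.
default_class_effects <- function() {
  c(Age = 0.45, NL = 0.35, GRAN = 0.35, `GRAN#` = 0.30, WBC = 0.25,
    UREA = 0.25, FIB = 0.30, FDP = 0.30, LYM = -0.30)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the structure of the study cohort the package was
#' designed around: 322 patients (91 resistant / 231 sensitive), 70
#' laboratory/clinical features in correlated blocks (blood count,
#' liver/renal, tumor markers, coagulation, plus Age/BMI), right-skewed
#' (lognormal) tumor markers, FDP and D-dimer, ~1.62% missing cells
#' completely at random, and standardized latent mean shifts of the
#' resistant class in Age, NL, GRAN, GRAN#, WBC, UREA, FIB, FDP (up) and
#' LYM (down).
#'
#' @param n_resistant,n_sensitive class sizes (labels are exact, not
#'   sampled).
#' @param within_cor latent correlation inside a feature block.
#' @param between_cor latent correlation across blocks.
#' @param effects named vector of standardized latent class shifts.
#' @param missing_rate fraction of feature cells punched missing (the
#'   outcome is never missing).
#' @param seed default seed used by [generate_cohort()] when none is given.
#' @return list of class `synth_cohort_config`.
#' @export
synth_cohort_config <- function(n_resistant = 91L, n_sensitive = 231L,
                                within_cor = 0.5, between_cor = 0.1,
                                effects = default_class_effects(),
                                missing_rate = 0.0162, seed = 1L) {
  stopifnot(n_resistant >= 2L, n_sensitive >= 2L)
  if (missing_rate < 0 || missing_rate >= 1) stop("missing rate must be in [0, 1)")
  if (between_cor > within_cor) stop("between-block correlation exceeds within-block")
  if (within_cor >= 1 || between_cor < 0) stop("correlations must be in [0, 1)")
  feats <- synth_feature_table()
  unknown <- setdiff(names(effects), feats$name)
  if (length(unknown)) stop(sprintf("unknown effect features: %s",
                                    paste(unknown, collapse = ", ")))
  structure(list(n_resistant = as.integer(n_resistant),
                 n_sensitive = as.integer(n_sensitive),
                 within_cor = within_cor, between_cor = between_cor,
                 effects = effects, missing_rate = missing_rate,
                 features = feats, seed = as.integer(seed)),
            class = "synth_cohort_config")
}

synth_correlation <- function(cfg) {
  feats <- cfg$features
  p <- nrow(feats)
  S <- matrix(cfg$between_cor, p, p)
  for (b in unique(feats$block)) {
    idx <- which(feats$block == b)
    S[idx, idx] <- cfg$within_cor
  }
  diag(S) <- 1
  S
}

#' Generate a synthetic cohort
#'
#' Draws correlated latent Gaussians under the block-correlation matrix,
#' adds the standardized class shifts to the resistant rows, maps each
#' latent column through its marginal (normal location/scale, or
#' exponentiation for the lognormal-family features), punches missing cells
#' completely at random at the configured rate, and returns a labeled
#' [cohort_table()] with exact class counts. Rows are shuffled so class is
#' not confounded with row order.
#'
#' @param cfg a [synth_cohort_config()].
#' @param seed RNG seed (defaults to the config's).
#' @return a `cohort_table`.
#' @export
generate_cohort <- function(cfg = synth_cohort_config(), seed = NULL) {
  stopifnot(inherits(cfg, "synth_cohort_config"))
  seed <- seed %||% cfg$seed
  feats <- cfg$features
  p <- nrow(feats)
  n <- cfg$n_resistant + cfg$n_sensitive
  S <- synth_correlation(cfg)
  L <- tryCatch(chol(S), error = function(e)
    stop("block correlation matrix is not positive definite"))
  with_seed(stage_seed(seed, "generate"), {
    y <- c(rep(1L, cfg$n_resistant), rep(0L, cfg$n_sensitive))
    Z <- matrix(stats::rnorm(n * p), n, p) %*% L
    shift <- stats::setNames(rep(0, p), feats$name)
    shift[names(cfg$effects)] <- cfg$effects
    Z <- Z + tcrossprod(as.numeric(y == 1L), shift)
    X <- vapply(seq_len(p), function(j) {
      if (feats$family[j] == "lognormal") {
        exp(feats$loc[j] + feats$scale[j] * Z[, j])
      } else {
        feats$loc[j] + feats$scale[j] * Z[, j]
      }
    }, numeric(n))
    colnames(X) <- feats$name
    if (cfg$missing_rate > 0) {
      holes <- which(stats::runif(n * p) < cfg$missing_rate)
      X[holes] <- NA_real_
    }
    ord <- sample.int(n)
    cohort_table(X[ord, , drop = FALSE], y[ord],
                 patient_ids = sprintf("P%03d", seq_len(n)))
  })
}

#' Stand-in reference ranges from a synthetic cohort
#'
#' Caps each feature at the 97.5th percentile of the sensitive class — a
#' synthetic surrogate for laboratory upper reference limits.
#'
#' @param cohort a generated [cohort_table()].
#' @return a [reference_ranges()] map.
#' @export
synthetic_reference_ranges <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  sens <- cohort$features[cohort$outcome == 0L, , drop = FALSE]
  caps <- apply(sens, 2, stats::quantile, probs = 0.975, na.rm = TRUE)
  caps <- caps[is.finite(caps) & caps > 0]
  reference_ranges(caps)
}

#' Diagnostics of a generated cohort against its configuration
#'
#' Reports realized class counts, missing fraction, mean within-block vs
#' between-block sample correlation (lognormal features are log-transformed
#' first), and realized standardized class shifts for the effect features;
#' flags deviations beyond a Monte-Carlo tolerance.
#'
#' @param cohort a generated [cohort_table()].
#' @param cfg the [synth_cohort_config()] used.
#' @param missing_tol absolute tolerance on the realized missing fraction.
#' @return list of diagnostics with a logical `ok` per check.
#' @export
validate_structure <- function(cohort, cfg, missing_tol = 0.005) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(cfg, "synth_cohort_config"))
  feats <- cfg$features
  X <- cohort$features[, feats$name, drop = FALSE]
  for (j in which(feats$family == "lognormal")) X[, j] <- log(pmax(X[, j], 1e-12))
  y <- cohort$outcome
  miss_frac <- mean(is.na(cohort$features))
  C <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  same_block <- outer(feats$block, feats$block, `==`)
  off <- upper.tri(C)
  within <- mean(C[off & same_block], na.rm = TRUE)
  between <- mean(C[off & !same_block], na.rm = TRUE)
  shifts <- vapply(names(cfg$effects), function(f) {
    v <- X[, f]
    sd_p <- sqrt(((sum(y == 1) - 1) * stats::var(v[y == 1], na.rm = TRUE) +
                    (sum(y == 0) - 1) * stats::var(v[y == 0], na.rm = TRUE)) /
                   (length(v) - 2))
    (mean(v[y == 1], na.rm = TRUE) - mean(v[y == 0], na.rm = TRUE)) / sd_p
  }, numeric(1))
  list(
    n_resistant = sum(y == 1L), n_sensitive = sum(y == 0L),
    counts_ok = sum(y == 1L) == cfg$n_resistant &&
      sum(y == 0L) == cfg$n_sensitive,
    missing_fraction = miss_frac,
    missing_ok = abs(miss_frac - cfg$missing_rate) <= missing_tol,
    within_block_cor = within, between_block_cor = between,
    correlation_ok = within > between,
    realized_shifts = shifts,
    shift_sign_ok = all(sign(shifts) == sign(cfg$effects))
  )
}
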