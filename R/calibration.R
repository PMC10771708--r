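#' Published cohort calibration tables
#'
#' The package ships the printed summary statistics of a 903-patient
#' orthodontic cohort: the sample allocation over the nine skeletal cells
#' (3 sagittal classes x 3 vertical types, split by sex), the per-cell
#' mean and standard deviation of every cephalometric indicator, and the
#' per-cell linear coefficients (slope `k`, intercept `b`) relating each
#' aesthetic outcome (FHR, FA) to the SN-OP angle. These tables are the
#' default calibration of the synthetic-cohort generator and the anchor
#' for all parameter-recovery checks.
#'
#' @name calibration
NULL

# sagittal classes and vertical types in canonical order
SAGITTAL_LEVELS <- c("I", "II", "III")
VERTICAL_LEVELS <- c("hypo", "nor", "hyper")

#' Canonical skeletal cell identifiers
#'
#' @return Character vector of the nine `sagittal.vertical` cell ids in
#'   canonical order (sagittal fastest varying last).
#' @export
cell_levels <- function() {
  as.vector(t(outer(SAGITTAL_LEVELS, VERTICAL_LEVELS, paste, sep = ".")))
}

#' Combine sagittal and vertical labels into a cell id
#'
#' @param sagittal Character vector of sagittal classes (`"I"`, `"II"`, `"III"`).
#' @param vertical Character vector of vertical types (`"hypo"`, `"nor"`, `"hyper"`).
#' @return Character vector like `"III.hypo"`.
#' @export
cell_id <- function(sagittal, vertical) {
  stopifnot(all(sagittal %in% SAGITTAL_LEVELS), all(vertical %in% VERTICAL_LEVELS))
  paste(sagittal, vertical, sep = ".")
}

#' @rdname calibration
#' @return `allocation_table()`: a tibble with one row per skeletal cell and
#'   columns `sagittal`, `vertical`, `female`, `male`, `total` (sums to 903).
#' @export
allocation_table <- function() {
  tibble::tibble(
    sagittal = rep(SAGITTAL_LEVELS, each = 3L),
    vertical = rep(VERTICAL_LEVELS, times = 3L),
    female   = c(62L, 67L, 63L, 52L, 65L, 62L, 62L, 64L, 53L),
    male     = c(40L, 42L, 43L, 33L, 42L, 39L, 41L, 39L, 34L),
    total    = c(102L, 109L, 106L, 85L, 107L, 101L, 103L, 103L, 87L)
  )
}

# per-cell mean/SD of every indicator; column order: I.hypo, I.nor, I.hyper,
# II.hypo, II.nor, II.hyper, III.hypo, III.nor, III.hyper
.feature_means <- list(
  N_ANS = c(51.9, 52.4, 53.0, 53.1, 52.5, 53.1, 52.7, 52.8, 53.5),
  S_N   = c(63.1, 63.2, 63.0, 64.3, 63.2, 62.7, 64.0, 63.8, 63.0),
  Ptm_A = c(45.5, 44.1, 43.6, 47.6, 46.0, 45.1, 44.8, 44.1, 42.4),
  SNA   = c(82.3, 80.1, 78.6, 83.8, 82.2, 80.9, 81.6, 80.0, 77.3),
  NA_FH = c(91.6, 90.8, 89.5, 92.2, 92.2, 91.5, 90.1, 89.8, 87.9),
  PP_FH = c(0.1, 0.9, 1.0, 1.0, 0.6, 1.0, 0.9, 0.8, 1.5),
  Go_Po = c(72.6, 71.7, 70.6, 70.0, 69.2, 67.9, 75.7, 74.2, 74.2),
  Go_Co = c(59.9, 56.3, 53.2, 60.3, 55.7, 52.3, 60.9, 58.8, 54.6),
  S_Go  = c(79.2, 74.2, 70.4, 79.8, 73.8, 69.8, 80.4, 77.0, 71.9),
  SN_OP = c(13.7, 17.8, 19.9, 16.1, 18.4, 21.9, 11.2, 14.7, 17.5),
  FHR   = c(70.1, 64.4, 60.4, 69.3, 64.3, 59.8, 70.8, 65.8, 60.9),
  FA    = c(89.4, 88.2, 86.7, 86.8, 86.3, 84.5, 92.2, 91.3, 89.5),
  FH_MP = c(18.0, 24.0, 29.0, 21.7, 25.8, 32.1, 17.5, 23.0, 27.6),
  SN_MP = c(27.3, 34.7, 40.0, 30.1, 35.8, 42.7, 26.0, 32.8, 38.2),
  SNB   = c(79.1, 76.9, 75.4, 77.7, 76.0, 74.0, 82.6, 81.0, 78.4),
  ANB   = c(3.2, 3.2, 3.2, 6.1, 6.2, 6.9, -1.0, -0.9, -1.1)
)

.feature_sds <- list(
  N_ANS = c(3.2, 3.5, 3.3, 4.3, 3.0, 3.2, 2.9, 3.3, 3.5),
  S_N   = c(3.7, 4.2, 3.3, 4.1, 4.1, 3.8, 4.2, 4.1, 3.8),
  Ptm_A = c(3.2, 3.5, 3.4, 3.7, 3.4, 2.8, 3.1, 3.9, 3.2),
  SNA   = c(2.7, 2.3, 3.2, 2.3, 3.1, 2.8, 3.3, 3.1, 2.9),
  NA_FH = c(3.0, 2.6, 2.4, 2.9, 2.5, 3.3, 2.9, 2.9, 2.3),
  PP_FH = c(3.0, 2.6, 2.8, 2.5, 2.9, 3.2, 2.7, 3.5, 3.0),
  Go_Po = c(5.0, 5.0, 4.5, 5.2, 4.6, 4.3, 4.6, 5.8, 4.5),
  Go_Co = c(4.3, 4.3, 4.3, 5.0, 3.7, 4.5, 5.0, 4.9, 3.7),
  S_Go  = c(5.8, 5.0, 5.9, 7.0, 4.3, 5.6, 6.3, 6.2, 4.2),
  SN_OP = c(3.8, 3.0, 3.1, 3.2, 3.8, 3.5, 3.7, 4.0, 4.2),
  FHR   = c(3.0, 1.0, 2.5, 2.6, 1.5, 2.7, 3.3, 1.7, 2.0),
  FA    = c(2.7, 2.8, 2.5, 2.7, 2.7, 3.5, 2.5, 3.2, 2.8),
  FH_MP = c(3.6, 3.4, 3.8, 3.5, 3.5, 4.8, 3.4, 3.1, 3.4),
  SN_MP = c(3.7, 2.5, 3.2, 3.5, 3.1, 4.3, 3.4, 2.7, 3.6),
  SNB   = c(2.6, 2.3, 3.3, 2.3, 3.2, 3.0, 3.7, 3.6, 3.5),
  ANB   = c(0.9, 1.1, 1.1, 0.8, 1.0, 1.5, 1.9, 1.9, 1.8)
)

#' @rdname calibration
#' @return `feature_calibration()`: a tibble with one row per
#'   (cell, indicator) pair and columns `sagittal`, `vertical`, `field`,
#'   `mean`, `sd` covering all sixteen cephalometric indicators.
#' @export
feature_calibration <- function() {
  fields <- names(.feature_means)
  tibble::tibble(
    sagittal = rep(rep(SAGITTAL_LEVELS, each = 3L), times = length(fields)),
    vertical = rep(rep(VERTICAL_LEVELS, times = 3L), times = length(fields)),
    field    = rep(fields, each = 9L),
    mean     = unlist(.feature_means, use.names = FALSE),
    sd       = unlist(.feature_sds, use.names = FALSE)
  )
}

# per-cell slope/intercept of outcome vs SN-OP; same cell order as above
.slope_tables <- list(
  FHR = list(
    k    = c(-0.28, -0.28, -0.28, -0.27, -0.28, -0.29, -0.26, -0.28, -0.27),
    k_sd = c(0.03, 0.04, 0.04, 0.04, 0.04, 0.04, 0.03, 0.03, 0.04),
    b    = c(73.07, 70.14, 66.97, 72.97, 70.12, 67.74, 72.61, 70.73, 66.97),
    b_sd = c(2.11, 1.69, 2.80, 1.28, 1.96, 2.82, 2.52, 2.33, 1.68)
  ),
  FA = list(
    k    = c(-0.40, -0.31, -0.25, -0.37, -0.32, -0.23, -0.47, -0.41, -0.34),
    k_sd = c(0.07, 0.09, 0.09, 0.06, 0.07, 0.08, 0.07, 0.08, 0.09),
    b    = c(95.47, 94.21, 91.45, 94.42, 93.14, 90.63, 96.78, 96.07, 94.72),
    b_sd = c(2.25, 2.50, 3.27, 2.44, 2.57, 3.50, 2.14, 2.30, 2.41)
  )
)

#' @rdname calibration
#' @param outcome One of `"FHR"` or `"FA"`.
#' @return `slope_calibration()`: a tibble with one row per skeletal cell and
#'   columns `sagittal`, `vertical`, `k`, `k_sd`, `b`, `b_sd` — the linear
#'   coefficients of the named outcome against SN-OP.
#' @export
slope_calibration <- function(outcome = c("FHR", "FA")) {
  outcome <- match.arg(outcome)
  tab <- .slope_tables[[outcome]]
  tibble::tibble(
    sagittal = rep(SAGITTAL_LEVELS, each = 3L),
    vertical = rep(VERTICAL_LEVELS, times = 3L),
    k = tab$k, k_sd = tab$k_sd, b = tab$b, b_sd = tab$b_sd
  )
}

#' Pooled indicator statistics across the nine skeletal cells
#'
#' Pools the per-cell calibration into one mean and SD per indicator.
#' The pooled mean is the unweighted mean of the nine cell means; the
#' pooled SD combines within-cell variance with between-cell spread,
#' `sqrt(mean(sd^2) + var(means))`. Used for the default record
#' plausibility windows (mean +/- 5 pooled SD).
#'
#' @return A tibble with columns `field`, `mean`, `sd`.
#' @export
pooled_field_stats <- function() {
  fields <- names(.feature_means)
  m <- vapply(fields, function(f) mean(.feature_means[[f]]), numeric(1))
  s <- vapply(fields, function(f) {
    sqrt(mean(.feature_sds[[f]]^2) + stats::var(.feature_means[[f]]))
  }, numeric(1))
  tibble::tibble(field = fields, mean = unname(m), sd = unname(s))
}
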