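#' Counterfactual SN-OP sweep grid
#'
#' The default grid rotates the occlusal plane from 9 to 25 degrees in
#' 1-degree steps (17 points). The grid is absolute, not centered on a
#' patient's own SN-OP, so a sweep may extrapolate beyond an individual's
#' plausible occlusion by design.
#'
#' @param start,stop Grid endpoints in degrees (`start < stop`).
#' @param step Positive step in degrees; both endpoints are included when
#'   `stop - start` is a multiple of `step`.
#' @return A `sweep_grid` list with `start`, `stop`, `step`, `values`.
#' @export
sweep_grid <- function(start = 9, stop = 25, step = 1) {
  if (!is.finite(start) || !is.finite(stop) || !is.finite(step) ||
      start >= stop || step <= 0) {
    stop("sweep grid requires start < stop and step > 0", call. = FALSE)
  }
  structure(list(start = start, stop = stop, step = step,
                 values = seq(start, stop, by = step)),
            class = "sweep_grid")
}

#' Build a patient's counterfactual input matrix
#'
#' One row per grid value: the SN-OP column runs over the grid while the
#' other nine surrogate inputs are frozen at the patient's measured
#' values. The patient's own SN-OP need not lie inside the grid.
#'
#' @param record One-row data frame (or named list) with the surrogate
#'   input fields.
#' @param grid A [sweep_grid()].
#' @return Numeric matrix, `length(grid$values)` x 10, with the surrogate
#'   input columns in canonical order.
#' @export
build_sweep_matrix <- function(record, grid = sweep_grid()) {
  if (!inherits(grid, "sweep_grid")) stop("grid must be a sweep_grid", call. = FALSE)
  record <- as.list(record)
  fields <- surrogate_input_fields()
  g <- length(grid$values)
  X <- matrix(NA_real_, nrow = g, ncol = length(fields),
              dimnames = list(NULL, fields))
  for (f in fields) {
    X[, f] <- if (f == "SN_OP") grid$values else rep(as.numeric(record[[f]]), g)
  }
  X
}

#' Per-patient least-squares line over the sweep
#'
#' Closed-form ordinary least squares of the predicted outcome on the
#' swept SN-OP values: `k = sum((x - xbar)(y - ybar)) / sum((x - xbar)^2)`,
#' `b = ybar - k xbar`. For a constant response the slope is 0, the
#' intercept the common value, and R-squared is defined as 0 with a
#' degenerate-fit flag.
#'
#' @param grid_values Swept SN-OP values (length >= 2, not constant).
#' @param predictions Predicted outcome at each grid value.
#' @return List with `k`, `b`, `r2`, `n_grid`, `degenerate`.
#' @export
fit_patient_line <- function(grid_values, predictions) {
  x <- as.numeric(grid_values); y <- as.numeric(predictions)
  stopifnot(length(x) == length(y), length(x) >= 2)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate design: sweep grid is constant", call. = FALSE)
  k <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b <- mean(y) - k * mean(x)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    return(list(k = 0, b = mean(y), r2 = 0, n_grid = length(x), degenerate = TRUE))
  }
  ssr <- sum((y - (b + k * x))^2)
  list(k = k, b = b, r2 = 1 - ssr / sst, n_grid = length(x), degenerate = FALSE)
}

#' Run the SN-OP sweep for every patient of a cohort
#'
#' Builds each patient's counterfactual matrix, predicts the outcome with
#' the surrogate, and extracts the per-patient slope and intercept by
#' least squares. Records are processed independently: dropping one does
#' not change any other patient's coefficients.
#'
#' @param model A trained `ceph_surrogate` for the matching outcome.
#' @param cohort A `ceph_cohort`.
#' @param grid A [sweep_grid()].
#' @param outcome Outcome tag stored in the result (defaults to the
#'   model's own tag).
#' @return Tibble with columns `id`, `outcome`, `k`, `b`, `r2`, `n_grid`,
#'   `degenerate`. Slope units: percentage points per degree for FHR,
#'   degrees per degree for FA.
#' @export
run_sweep <- function(model, cohort, grid = sweep_grid(), outcome = model$outcome) {
  fields <- surrogate_input_fields()
  n <- nrow(cohort)
  g <- length(grid$values)
  base <- as.matrix(as.data.frame(cohort)[, fields])
  # one stacked prediction call: rows are grid-major within each patient
  big <- base[rep(seq_len(n), each = g), , drop = FALSE]
  big[, "SN_OP"] <- rep(grid$values, times = n)
  pred <- predict(model, big)
  Y <- matrix(pred, nrow = g, ncol = n)
  x <- grid$values
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  k <- drop(crossprod(Y, xc)) / sxx
  ybar <- colMeans(Y)
  b <- ybar - k * mean(x)
  sst <- colSums((Y - matrix(ybar, g, n, byrow = TRUE))^2)
  fitted <- outer(x, k) + matrix(b, g, n, byrow = TRUE)
  ssr <- colSums((Y - fitted)^2)
  degenerate <- sst == 0
  r2 <- ifelse(degenerate, 0, 1 - ssr / sst)
  k[degenerate] <- 0
  b[degenerate] <- ybar[degenerate]
  tibble::tibble(id = cohort$id, outcome = outcome, k = k, b = b,
                 r2 = r2, n_grid = g, degenerate = degenerate)
}

#' Summarize per-patient slopes by skeletal cell
#'
#' @param slopes Tibble from [run_sweep()] (or generating truth with the
#'   same columns).
#' @param labels Tibble `id`, `sagittal`, `vertical` covering every slope id.
#' @return Tibble with one row per cell plus `Total` margins: columns
#'   `sagittal`, `vertical`, `n`, `k_mean`, `k_sd`, `b_mean`, `b_sd`.
#'   Empty cells are reported with `n = 0` and `NA` statistics.
#' @export
summarize_slopes <- function(slopes, labels) {
  stopifnot(all(c("id", "k", "b") %in% names(slopes)),
            all(c("id", "sagittal", "vertical") %in% names(labels)))
  if (!all(slopes$id %in% labels$id)) {
    stop("labels must cover every slope id", call. = FALSE)
  }
  df <- merge(as.data.frame(slopes), as.data.frame(labels), by = "id")
  cell_stats <- function(sub, sg, vt) {
    tibble::tibble(
      sagittal = sg, vertical = vt, n = nrow(sub),
      k_mean = if (nrow(sub) > 0) mean(sub$k) else NA_real_,
      k_sd = if (nrow(sub) > 1) stats::sd(sub$k) else NA_real_,
      b_mean = if (nrow(sub) > 0) mean(sub$b) else NA_real_,
      b_sd = if (nrow(sub) > 1) stats::sd(sub$b) else NA_real_
    )
  }
  rows <- list()
  for (sg in SAGITTAL_LEVELS) {
    for (vt in VERTICAL_LEVELS) {
      rows[[length(rows) + 1L]] <-
        cell_stats(df[df$sagittal == sg & df$vertical == vt, ], sg, vt)
    }
    rows[[length(rows) + 1L]] <- cell_stats(df[df$sagittal == sg, ], sg, "Total")
  }
  for (vt in VERTICAL_LEVELS) {
    rows[[length(rows) + 1L]] <- cell_stats(df[df$vertical == vt, ], "Total", vt)
  }
  rows[[length(rows) + 1L]] <- cell_stats(df, "Total", "Total")
  do.call(rbind, rows)
}
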