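#' Min-max normalization bounds
#'
#' Computes per-feature minima and maxima on the training split only. The
#' forward transform maps min to -1 and max to +1; values outside the
#' training range extrapolate linearly (no clipping).
#'
#' @param inputs Numeric matrix (or data frame) of training inputs.
#' @param outputs Numeric vector of training outcomes.
#' @return A `norm_bounds` list with `input_min`, `input_max`, `out_min`,
#'   `out_max`.
#' @export
fit_bounds <- function(inputs, outputs) {
  X <- as.matrix(inputs)
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  flat <- which(hi <= lo)
  if (length(flat) > 0) {
    nm <- colnames(X)[flat]
    if (is.null(nm)) nm <- as.character(flat)
    stop("degenerate feature(s) with no spread in the training split: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  if (max(outputs) <= min(outputs)) {
    stop("degenerate outcome: no spread in the training split", call. = FALSE)
  }
  structure(list(input_min = lo, input_max = hi,
                 out_min = min(outputs), out_max = max(outputs)),
            class = "norm_bounds")
}

#' @rdname fit_bounds
#' @param x Matrix of raw inputs (`normalize_inputs`) or normalized
#'   outcome vector (`denormalize_output`) / raw outcome (`normalize_output`).
#' @param bounds A `norm_bounds` object.
#' @export
normalize_inputs <- function(x, bounds) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, bounds$input_min, `-`), 2,
        bounds$input_max - bounds$input_min, `/`) * 2 - 1
}

#' @rdname fit_bounds
#' @export
normalize_output <- function(x, bounds) {
  2 * (x - bounds$out_min) / (bounds$out_max - bounds$out_min) - 1
}

#' @rdname fit_bounds
#' @export
denormalize_output <- function(x, bounds) {
  (x + 1) / 2 * (bounds$out_max - bounds$out_min) + bounds$out_min
}

#' Random train/validation/test split
#'
#' Disjoint, exhaustive, deterministic given the seed. Split sizes follow
#' the ratios with largest-remainder rounding (earlier splits win remainder
#' ties, so 903 rows at 70:15:15 give 632/136/135).
#'
#' @param n Number of rows.
#' @param ratios Three positive fractions (normalized to sum 1).
#' @param seed RNG seed.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  if (length(ratios) != 3 || any(ratios <= 0)) {
    stop("ratios must be three positive fractions", call. = FALSE)
  }
  sizes <- largest_remainder(n, ratios)
  set.seed(seed)
  perm <- sample.int(n)
  list(train = sort(perm[seq_len(sizes[1])]),
       val = sort(perm[sizes[1] + seq_len(sizes[2])]),
       test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}

# forward pass on normalized inputs; weights = list(W1, b1, w2, b2)
.forward <- function(Xn, w) {
  Z <- tanh(sweep(Xn %*% w$W1, 2, w$b1, `+`))
  drop(Z %*% w$w2) + w$b2
}

.unpack <- function(par, p, h) {
  i <- 0L
  W1 <- matrix(par[i + seq_len(p * h)], p, h); i <- i + p * h
  b1 <- par[i + seq_len(h)]; i <- i + h
  w2 <- par[i + seq_len(h)]; i <- i + h
  b2 <- par[i + 1L]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

.pack <- function(w) c(as.vector(w$W1), w$b1, w$w2, w$b2)

#' Train a feedforward surrogate model
#'
#' A three-layer feedforward network (10 inputs by default, one tanh
#' hidden layer, linear output) fitted by full-batch quasi-Newton (BFGS)
#' minimization of the mean squared error in normalized space. Rows are
#' split into train/validation/test sets; normalization bounds come from
#' the training split only. Training proceeds in epochs of
#' `iters_per_epoch` optimizer iterations; it halts after `patience`
#' consecutive epochs without validation-MSE improvement, and the weights
#' returned are those of the best validation epoch (earliest on ties).
#'
#' @param inputs n x p matrix or data frame of inputs.
#' @param outcome Length-n outcome vector (original units).
#' @param hidden Hidden-layer width (default 10).
#' @param ratios Train/validation/test fractions (default 70:15:15).
#' @param seed Controls both the split and the weight initialization.
#' @param max_epochs Epoch cap; reaching it without an early stop sets the
#'   `converged = FALSE` flag (the model is still returned).
#' @param patience Early-stopping patience in epochs.
#' @param iters_per_epoch BFGS iterations per epoch.
#' @param restarts Independent random initializations; the fit with the
#'   best validation MSE is kept.
#' @param outcome_name Label stored on the model (`"FHR"`, `"FA"`, ...).
#' @param split Optional pre-computed split (as from [split_dataset()]).
#' @return A `ceph_surrogate` object.
#' @export
train_surrogate <- function(inputs, outcome, hidden = 10L,
                            ratios = c(0.70, 0.15, 0.15), seed = 1L,
                            max_epochs = 1000L, patience = 6L,
                            iters_per_epoch = 25L, restarts = 1L,
                            outcome_name = "outcome", split = NULL) {
  X <- as.matrix(inputs)
  y <- as.numeric(outcome)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n < 50) stop("need at least 50 rows to train a surrogate", call. = FALSE)
  if (is.null(split)) split <- split_dataset(n, ratios, seed = seed)
  bounds <- fit_bounds(X[split$train, , drop = FALSE], y[split$train])
  Xn <- normalize_inputs(X, bounds)
  yn <- normalize_output(y, bounds)
  tr <- split$train; va <- split$val; te <- split$test
  Xtr <- Xn[tr, , drop = FALSE]; ytr <- yn[tr]
  mse <- function(par, idx) {
    w <- .unpack(par, p, hidden)
    mean((.forward(Xn[idx, , drop = FALSE], w) - yn[idx])^2)
  }
  loss <- function(par) {
    w <- .unpack(par, p, hidden)
    mean((.forward(Xtr, w) - ytr)^2)
  }
  grad <- function(par) {
    w <- .unpack(par, p, hidden)
    A <- sweep(Xtr %*% w$W1, 2, w$b1, `+`)
    Z <- tanh(A)
    r <- 2 * (drop(Z %*% w$w2) + w$b2 - ytr) / length(ytr)
    dZ <- (r %o% w$w2) * (1 - Z^2)
    c(as.vector(crossprod(Xtr, dZ)), colSums(dZ), drop(crossprod(Z, r)), sum(r))
  }
  npar <- p * hidden + hidden + hidden + 1L
  set.seed(seed + 1L)  # split consumed `seed`; init stream is offset
  best_model <- NULL
  for (rs in seq_len(restarts)) {
    par <- stats::runif(npar, -0.5, 0.5)
    trace <- vector("list", max_epochs)
    best_val <- Inf; best_par <- par; best_epoch <- 0L; stale <- 0L
    converged <- FALSE
    for (e in seq_len(max_epochs)) {
      opt <- stats::optim(par, loss, grad, method = "BFGS",
                          control = list(maxit = iters_per_epoch))
      par <- opt$par
      m_tr <- loss(par)
      if (!is.finite(m_tr)) stop("training diverged: non-finite loss", call. = FALSE)
      m_va <- mse(par, va); m_te <- mse(par, te)
      trace[[e]] <- c(epoch = e, train = m_tr, val = m_va, test = m_te)
      if (m_va < best_val) {
        best_val <- m_va; best_par <- par; best_epoch <- e; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) { converged <- TRUE; break }
      }
    }
    trace <- tibble::as_tibble(do.call(rbind, trace[!vapply(trace, is.null, logical(1))]))
    cand <- list(
      weights = .unpack(best_par, p, hidden), bounds = bounds, trace = trace,
      best_epoch = best_epoch, best_val_mse = best_val, split = split,
      seed = seed, converged = converged,
      hyperparams = list(hidden = hidden, ratios = ratios,
                         max_epochs = max_epochs, patience = patience,
                         iters_per_epoch = iters_per_epoch, restarts = restarts),
      outcome = outcome_name,
      input_names = colnames(X)
    )
    if (is.null(best_model) || cand$best_val_mse < best_model$best_val_mse) {
      best_model <- cand
    }
  }
  if (!best_model$converged) {
    warning("surrogate training reached max_epochs without early stop",
            call. = FALSE)
  }
  structure(best_model, class = "ceph_surrogate")
}

#' Predict from a trained surrogate
#'
#' Normalizes the inputs with the model's training-split bounds, runs the
#' forward pass, and inverse-normalizes the output. Deterministic and
#' row-wise independent.
#'
#' @param object A `ceph_surrogate`.
#' @param newdata m x p matrix or data frame of inputs (columns matched by
#'   name when available).
#' @param ... Unused.
#' @return Numeric vector of predictions in original outcome units.
#' @export
predict.ceph_surrogate <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$bounds$input_min)) {
    stop(sprintf("input has %d columns; model expects %d",
                 ncol(X), length(object$bounds$input_min)), call. = FALSE)
  }
  if (!is.null(colnames(X)) && !is.null(object$input_names) &&
      all(object$input_names %in% colnames(X))) {
    X <- X[, object$input_names, drop = FALSE]
  }
  Xn <- normalize_inputs(X, object$bounds)
  denormalize_output(.forward(Xn, object$weights), object$bounds)
}

#' Per-split fit quality of a surrogate
#'
#' @param model A `ceph_surrogate`.
#' @param inputs,outcome The full dataset the model was trained on.
#' @return Tibble with one row per split: `split`, `n`, `r` (Pearson),
#'   `r2`, `mse_norm` (MSE in normalized units).
#' @export
surrogate_fit_stats <- function(model, inputs, outcome) {
  X <- as.matrix(inputs); y <- as.numeric(outcome)
  out <- lapply(c("train", "val", "test"), function(s) {
    idx <- model$split[[s]]
    pred <- predict(model, X[idx, , drop = FALSE])
    r <- stats::cor(pred, y[idx])
    mse_n <- mean((normalize_output(pred, model$bounds) -
                     normalize_output(y[idx], model$bounds))^2)
    tibble::tibble(split = s, n = length(idx), r = r, r2 = r^2, mse_norm = mse_n)
  })
  do.call(rbind, out)
}

#' Agreement diagnostics between predicted and observed values
#'
#' Pearson correlation, a paired t-test on the differences, and
#' Bland-Altman limits of agreement (mean difference +/- 1.96 SD of the
#' differences) with the fraction of pairs falling inside the limits.
#'
#' @param predicted,actual Equal-length numeric vectors (n >= 3).
#' @return An `agreement_report` list: `r` (NA when either vector has zero
#'   variance), `t`, `p` (t = 0, p = 1 when all differences are equal),
#'   `mean_diff`, `sd_diff`, `loa_lower`, `loa_upper`, `frac_within`, `n`.
#' @export
evaluate_agreement <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual), length(actual) >= 3)
  d <- predicted - actual
  r <- if (stats::sd(predicted) == 0 || stats::sd(actual) == 0) {
    NA_real_
  } else {
    stats::cor(predicted, actual)
  }
  sd_d <- stats::sd(d)
  # constant differences up to floating-point jitter: no paired evidence
  if (sd_d <= 1e-10 * max(1, abs(mean(d)))) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    ht <- stats::t.test(predicted, actual, paired = TRUE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  lo <- mean(d) - 1.96 * sd_d
  hi <- mean(d) + 1.96 * sd_d
  structure(list(
    r = r, t = tt$statistic, p = tt$p.value,
    mean_diff = mean(d), sd_diff = sd_d,
    loa_lower = lo, loa_upper = hi,
    frac_within = mean(d >= lo & d <= hi),
    n = length(d)
  ), class = "agreement_report")
}

#' Serialize / load a surrogate model as JSON
#'
#' @param model A `ceph_surrogate`.
#' @param path JSON file path.
#' @return `write_surrogate()` returns `path` invisibly; `read_surrogate()`
#'   a `ceph_surrogate`.
#' @export
write_surrogate <- function(model, path) {
  payload <- list(
    weights = lapply(model$weights, function(w) unclass(w)),
    bounds = unclass(model$bounds),
    trace = as.data.frame(model$trace),
    best_epoch = model$best_epoch, best_val_mse = model$best_val_mse,
    split = model$split, seed = model$seed, converged = model$converged,
    hyperparams = model$hyperparams, outcome = model$outcome,
    input_names = model$input_names,
    dim_W1 = dim(model$weights$W1)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- x$weights
  w$W1 <- matrix(unlist(w$W1), x$dim_W1[1], x$dim_W1[2])
  w$b1 <- as.numeric(w$b1); w$w2 <- as.numeric(w$w2); w$b2 <- as.numeric(w$b2)
  bounds <- structure(list(
    input_min = unlist(x$bounds$input_min),
    input_max = unlist(x$bounds$input_max),
    out_min = as.numeric(x$bounds$out_min),
    out_max = as.numeric(x$bounds$out_max)
  ), class = "norm_bounds")
  structure(list(
    weights = w, bounds = bounds, trace = tibble::as_tibble(x$trace),
    best_epoch = x$best_epoch, best_val_mse = x$best_val_mse,
    split = lapply(x$split, as.integer), seed = x$seed,
    converged = x$converged, hyperparams = x$hyperparams,
    outcome = x$outcome, input_names = x$input_names
  ), class = "ceph_surrogate")
}
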