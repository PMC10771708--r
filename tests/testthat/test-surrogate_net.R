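test_that("min-max bounds map the training range onto [-1, 1] exactly", {
  X <- cbind(a = c(9, 25, 17), b = c(0, 10, 5))
  bounds <- fit_bounds(X, c(1, 2, 3))
  Xn <- normalize_inputs(X, bounds)
  expect_equal(Xn[, "a"], c(-1, 1, 0))
  expect_equal(Xn[, "b"], c(-1, 1, 0))
  # output round trip is the identity
  y <- runif(20, 50, 90)
  b2 <- fit_bounds(X, y[1:3])
  expect_equal(denormalize_output(normalize_output(y, b2), b2), y,
               tolerance = 1e-9)
  expect_error(fit_bounds(cbind(a = c(1, 1, 1), b = 1:3), 1:3), "a")
})

test_that("rows outside the training range extrapolate beyond [-1, 1]", {
  set.seed(2)
  X <- matrix(runif(60), 20, 3)
  bounds <- fit_bounds(X, runif(20))
  beyond <- matrix(c(2, 2, 2), 1, 3)
  expect_true(all(normalize_inputs(beyond, bounds) > 1))
})

test_that("splits are disjoint, exhaustive, proportional and seed-determined", {
  s <- split_dataset(100, c(0.70, 0.15, 0.15), seed = 3)
  expect_equal(lengths(s), c(train = 70L, val = 15L, test = 15L))
  s903 <- split_dataset(903, seed = 3)
  expect_equal(lengths(s903), c(train = 632L, val = 136L, test = 135L))
  expect_equal(sort(unlist(s903)), 1:903, ignore_attr = TRUE)
  expect_identical(split_dataset(903, seed = 3), s903)
  expect_false(identical(split_dataset(903, seed = 4), s903))
  expect_error(split_dataset(10, c(0.5, 0.5, 0)), "positive")
})

test_that("a zero-noise affine outcome is fitted essentially exactly", {
  d <- linear_data()
  model <- linear_model()
  stats <- surrogate_fit_stats(model, d$X, d$y)
  expect_gte(stats$r[stats$split == "test"], 0.999)
  expect_lte(stats$mse_norm[stats$split == "test"], 1e-4)
  # predictions reproduce the training outcomes
  pred <- predict(model, d$X[model$split$train, ])
  expect_lt(max(abs(pred - d$y[model$split$train])), 0.01)
})

test_that("training is reproducible and early stopping returns the best epoch", {
  d <- linear_data()
  # the tight epoch cap is intentional: hitting it must flag, not fail
  expect_warning(
    train_surrogate(d$X, d$y, seed = 9, iters_per_epoch = 20,
                    max_epochs = 30, patience = 4),
    "max_epochs")
  m1 <- suppressWarnings(
    train_surrogate(d$X, d$y, seed = 9, iters_per_epoch = 20,
                    max_epochs = 30, patience = 4))
  m2 <- suppressWarnings(
    train_surrogate(d$X, d$y, seed = 9, iters_per_epoch = 20,
                    max_epochs = 30, patience = 4))
  expect_false(m1$converged)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$trace, m2$trace)
  expect_equal(m1$best_val_mse, min(m1$trace$val))
  expect_equal(m1$best_epoch, which.min(m1$trace$val))
})

test_that("a permuted outcome yields no real test-set association", {
  d <- linear_data()
  set.seed(21)
  y_perm <- sample(d$y)
  m <- train_surrogate(d$X, y_perm, seed = 5, iters_per_epoch = 50,
                       outcome_name = "null")
  idx <- m$split$test
  ct <- stats::cor.test(predict(m, d$X[idx, ]), y_perm[idx],
                        alternative = "greater")
  expect_gt(ct$p.value, 0.05)
})

test_that("prediction is pure, batch-consistent and continuous in SN-OP", {
  model <- linear_model()
  d <- linear_data()
  batch <- predict(model, d$X[1:8, ])
  rowwise <- vapply(1:8, function(i) predict(model, d$X[i, , drop = FALSE]),
                    numeric(1))
  expect_equal(batch, rowwise)
  x <- d$X[1, , drop = FALSE]
  for (delta in c(1e-3, 1e-6)) {
    x2 <- x; x2[, "SN_OP"] <- x2[, "SN_OP"] + delta
    expect_lt(abs(predict(model, x2) - predict(model, x)), delta * 10)
  }
  expect_error(predict(model, d$X[, 1:4]), "columns")
})

test_that("agreement diagnostics handle exact, shifted and noisy pairs", {
  y <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  a <- evaluate_agreement(y, y)
  expect_equal(a$r, 1)
  expect_equal(a$mean_diff, 0)
  expect_equal(c(a$loa_lower, a$loa_upper), c(0, 0))
  expect_equal(a$t, 0)
  expect_equal(a$p, 1)

  b <- evaluate_agreement(y + 1, y)
  expect_equal(b$mean_diff, 1)
  expect_equal(b$sd_diff, 0)
  expect_equal(b$r, 1)

  const <- evaluate_agreement(rep(2, 5), y)
  expect_true(is.na(const$r))

  set.seed(33)
  act <- rnorm(5000, 70, 5)
  pred <- act + rnorm(5000, 0, 1)
  cov <- evaluate_agreement(pred, act)
  expect_equal(cov$frac_within, 0.95, tolerance = 0.01)
})

test_that("surrogate models survive a JSON round trip", {
  model <- linear_model()
  d <- linear_data()
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogate(model, path)
  back <- read_surrogate(path)
  expect_equal(predict(back, d$X[1:5, ]), predict(model, d$X[1:5, ]))
  expect_equal(back$best_epoch, model$best_epoch)
  expect_equal(as.data.frame(back$trace), as.data.frame(model$trace))
})
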