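test_that("published-cohort allocation is reproduced exactly", {
  alloc <- allocate_cells(903, "published_exact")
  expect_equal(alloc$total,
               c(102L, 109L, 106L, 85L, 107L, 101L, 103L, 103L, 87L))
  expect_equal(sum(alloc$female), 550L)
  expect_equal(sum(alloc$male), 353L)
  expect_equal(sum(alloc$total), 903L)
  expect_error(allocate_cells(500, "published_exact"), "903")
})

test_that("proportional and uniform allocation distribute n over all cells", {
  u <- allocate_cells(9, "uniform")
  expect_equal(u$total, rep(1L, 9))

  p <- allocate_cells(300, "proportional")
  expect_equal(sum(p$total), 300L)
  ref <- allocation_table()
  target <- 300 * ref$total / 903
  expect_true(all(abs(p$total - target) <= 1))
  expect_error(allocate_cells(5, "proportional"), ">= 9")
})

test_that("largest-remainder apportionment sums exactly and favours big remainders", {
  expect_equal(largest_remainder(100, c(0.70, 0.15, 0.15)), c(70L, 15L, 15L))
  expect_equal(largest_remainder(903, c(0.70, 0.15, 0.15)), c(632L, 136L, 135L))
  expect_equal(sum(largest_remainder(17, runif(5, 0.1, 1))), 17L)
})

test_that("forced SN-OP with zero noise reproduces the printed linear model", {
  quiet <- generator_config(sigma_fhr = 0, sigma_fa = 0,
                            alpha = c(a1 = 0, a2 = 0, a3 = 0))
  set.seed(1)
  r1 <- sample_record("I", "hypo", quiet, force_sn_op = 14)
  expect_equal(r1$FHR, 73.07 - 0.28 * 14)  # = 69.15

  set.seed(1)
  r2 <- sample_record("III", "hypo", quiet, force_sn_op = 11.2)
  expect_equal(r2$FA, 96.78 - 0.47 * 11.2)  # = 91.516
})

test_that("all-zero SDs collapse the sampler onto the cell mean vector", {
  flat <- feature_calibration()
  flat$sd <- 0
  cfg <- generator_config(features = flat, sigma_fhr = 0, sigma_fa = 0)
  rec <- sample_record("II", "nor", cfg)
  cc <- flat[flat$sagittal == "II" & flat$vertical == "nor", ]
  mu <- stats::setNames(cc$mean, cc$field)
  for (f in c(surrogate_input_fields(), "FH_MP", "SN_MP", "ANB")) {
    expect_equal(rec[[f]], unname(mu[[f]]), info = f)
  }
  expect_equal(rec$SNB, rec$SNA - rec$ANB)
  # outcomes follow the linear model at the mean SN-OP
  expect_equal(rec$FHR, 70.12 - 0.28 * mu[["SN_OP"]], ignore_attr = TRUE)
})

test_that("cohorts are a pure function of the config", {
  cfg <- generator_config(n = 60, allocation = "proportional", seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a$cohort), as.data.frame(b$cohort))
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(generator_config(n = 60, allocation = "proportional",
                                         seed = 100))
  expect_false(identical(a$cohort$SN_OP, c2$cohort$SN_OP))
})

test_that("per-cell sample moments of the surrogate inputs match the calibration", {
  gen <- default_gen()
  cohort <- gen$cohort
  labels <- cohort_labels(cohort)
  cal <- feature_calibration()
  for (sg in c("I", "II", "III")) {
    for (vt in c("hypo", "nor", "hyper")) {
      idx <- labels$sagittal == sg & labels$vertical == vt
      m <- sum(idx)
      cc <- cal[cal$sagittal == sg & cal$vertical == vt, ]
      for (f in surrogate_input_fields()) {
        mu <- cc$mean[cc$field == f]
        sd <- cc$sd[cc$field == f]
        expect_lt(abs(mean(cohort[[f]][idx]) - mu), 3 * sd / sqrt(m))
      }
    }
  }
})

test_that("the generating mean is exactly linear in SN-OP with slope k", {
  cfg <- generator_config()
  rec <- mean_record("III", "hypo")
  for (outc in c("FHR", "FA")) {
    truth <- slope_calibration(outc)
    k <- truth$k[truth$sagittal == "III" & truth$vertical == "hypo"]
    h <- 0.5
    up <- rec; up$SN_OP <- rec$SN_OP + h
    dn <- rec; dn$SN_OP <- rec$SN_OP - h
    deriv <- (generating_outcome_mean(up, "III", "hypo", cfg, outc) -
                generating_outcome_mean(dn, "III", "hypo", cfg, outc)) / (2 * h)
    expect_equal(deriv, k, tolerance = 1e-9)
  }
})

test_that("repeated measures reduce to the truth at zero noise and zero bias", {
  gen <- small_gen()
  ratings <- repeated_measures(gen$cohort[1:10, ], n_raters = 3, n_sessions = 2,
                               noise_sd = 0, bias_sd = 0, seed = 4)
  truth <- as.matrix(as.data.frame(gen$cohort[1:10, ])[, ceph_fields()])
  for (r in 1:3) for (s in 1:2) {
    expect_equal(unname(ratings[r, s, , ]), unname(truth))
  }
})

test_that("rating variance decomposes into the configured components", {
  gen <- default_gen()
  ratings <- repeated_measures(gen$cohort, n_raters = 6, n_sessions = 2,
                               noise_sd = 1, bias_sd = 0.5, seed = 12)
  # within rater-and-record, session differences carry only 2 * noise_sd^2
  d <- ratings[1, 1, , "SNA"] - ratings[1, 2, , "SNA"]
  expect_equal(stats::var(d) / 2, 1, tolerance = 0.10)
  # residual about the truth carries noise + bias variance
  truth <- as.data.frame(gen$cohort)$SNA
  resid <- as.vector(sweep(ratings[, , , "SNA"], 3, truth, `-`))
  expect_equal(stats::var(resid), 1 + 0.25, tolerance = 0.10)
})
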