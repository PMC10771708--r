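# memoized fixtures shared across test files (built once per session)
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# calibrated cohort at the published size
default_gen <- function() fixture("default_gen", function() {
  generate_cohort(generator_config(seed = 101))
})

# small proportional cohort for cheap structural tests
small_gen <- function() fixture("small_gen", function() {
  generate_cohort(generator_config(n = 180, allocation = "proportional", seed = 7))
})

# zero-noise affine outcome over realistic input ranges; SN-OP coefficient -0.28
linear_data <- function() fixture("linear_data", function() {
  set.seed(11)
  n <- 300
  fields <- surrogate_input_fields()
  X <- matrix(stats::runif(n * 10, 40, 90), n, 10, dimnames = list(NULL, fields))
  X[, "SN_OP"] <- stats::runif(n, 9, 25)
  X[, "PP_FH"] <- stats::runif(n, -5, 7)
  beta <- stats::setNames(
    c(0.05, -0.03, 0.02, 0.01, -0.02, 0.04, -0.01, 0.03, 0.12, -0.28), fields)
  y <- 70 + drop(X %*% beta)
  list(X = X, y = y, beta = beta)
})

linear_model <- function() fixture("linear_model", function() {
  d <- linear_data()
  train_surrogate(d$X, d$y, seed = 5, iters_per_epoch = 100, patience = 12,
                  outcome_name = "linear")
})

# one-row tibble holding a cell's calibration means (valid record)
mean_record <- function(sagittal, vertical, id = "mean", sex = "F") {
  cal <- feature_calibration()
  cc <- cal[cal$sagittal == sagittal & cal$vertical == vertical, ]
  rec <- tibble::as_tibble(as.list(stats::setNames(cc$mean, cc$field)))
  cbind(tibble::tibble(id = id, sex = sex), rec)[, c("id", "sex", ceph_fields())]
}

# all nine cell-mean records as one cohort
mean_cohort <- function() {
  rows <- list()
  for (sg in c("I", "II", "III")) {
    for (vt in c("hypo", "nor", "hyper")) {
      rows[[length(rows) + 1L]] <- mean_record(sg, vt, id = paste(sg, vt, sep = "."))
    }
  }
  new_cohort(do.call(rbind, rows), provenance = "imported")
}
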