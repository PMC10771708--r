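#' Pipeline run configuration
#'
#' One global seed expands deterministically into per-stage seeds
#' (cohort generation, FHR training, FA training, reliability simulation)
#' so any stage can be re-run in isolation and reproduce the full run.
#'
#' @param seed Global integer seed.
#' @param generator A [generator_config()]; its own seed is overwritten by
#'   the derived generation seed.
#' @param rules Classification rules.
#' @param hidden,ratios,patience,max_epochs,iters_per_epoch,restarts
#'   Surrogate hyperparameters (see [train_surrogate()]).
#' @param grid A [sweep_grid()].
#' @param alpha Significance level for the statistical layer.
#' @param n_reliability Number of records in the simulated reliability
#'   study (raters re-measuring a random subset).
#' @return A `run_config` list with a `seeds` element.
#' @export
run_config <- function(seed = 1L,
                       generator = generator_config(),
                       rules = classification_rules(),
                       hidden = 10L, ratios = c(0.70, 0.15, 0.15),
                       patience = 6L, max_epochs = 1000L,
                       iters_per_epoch = 25L, restarts = 1L,
                       grid = sweep_grid(), alpha = 0.05,
                       n_reliability = 50L) {
  seeds <- derive_seeds(seed)
  generator$seed <- seeds[["generate"]]
  structure(list(
    seed = as.integer(seed), seeds = seeds, generator = generator,
    rules = rules, hidden = hidden, ratios = ratios, patience = patience,
    max_epochs = max_epochs, iters_per_epoch = iters_per_epoch,
    restarts = restarts, grid = grid, alpha = alpha,
    n_reliability = as.integer(n_reliability)
  ), class = "run_config")
}

#' Expand a global seed into per-stage seeds
#'
#' @param seed Global integer seed.
#' @return Named integer vector with elements `generate`, `train_fhr`,
#'   `train_fa`, `reliability`, all below 2^31.
#' @export
derive_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(2147483646L, 4L),
                  c("generate", "train_fhr", "train_fa", "reliability"))
}

.stage_file <- function(outdir, name) file.path(outdir, name)

#' Pipeline stage commands
#'
#' Each command runs one stage and, when `outdir` is given, writes its
#' artifacts as flat CSV/JSON files. [cmd_run_all()] chains them and is
#' numerically identical to running the single commands with the same
#' derived seeds.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @return `cmd_generate()`: list with `cohort` and `truth`.
#' @export
cmd_generate <- function(config, outdir = NULL) {
  gen <- generate_cohort(config$generator)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(gen$cohort, .stage_file(outdir, "cohort.csv"))
    utils::write.csv(as.data.frame(gen$truth),
                     .stage_file(outdir, "truth.csv"), row.names = FALSE)
  }
  gen
}

#' @rdname cmd_generate
#' @param cohort A `ceph_cohort`.
#' @return `cmd_classify()`: output of [classify_cohort()].
#' @export
cmd_classify <- function(cohort, config = run_config(), outdir = NULL) {
  cls <- classify_cohort(cohort, config$rules)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    joined <- cbind(as.data.frame(cohort),
                    cls$labels[, c("sagittal", "vertical")])
    utils::write.csv(joined, .stage_file(outdir, "cohort_labeled.csv"),
                     row.names = FALSE)
  }
  cls
}

#' @rdname cmd_generate
#' @param outcome `"FHR"` or `"FA"`.
#' @return `cmd_train()`: a `ceph_surrogate`.
#' @export
cmd_train <- function(cohort, outcome = c("FHR", "FA"),
                      config = run_config(), outdir = NULL) {
  outcome <- match.arg(outcome)
  seed <- config$seeds[[if (outcome == "FHR") "train_fhr" else "train_fa"]]
  X <- as.matrix(as.data.frame(cohort)[, surrogate_input_fields()])
  y <- cohort[[outcome]]
  model <- train_surrogate(X, y, hidden = config$hidden, ratios = config$ratios,
                           seed = seed, max_epochs = config$max_epochs,
                           patience = config$patience,
                           iters_per_epoch = config$iters_per_epoch,
                           restarts = config$restarts, outcome_name = outcome)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_surrogate(model, .stage_file(outdir, paste0("model_", outcome, ".json")))
    utils::write.csv(as.data.frame(model$trace),
                     .stage_file(outdir, paste0("curves_", outcome, ".csv")),
                     row.names = FALSE)
  }
  model
}

#' @rdname cmd_generate
#' @param model A trained `ceph_surrogate`.
#' @return `cmd_sweep()`: per-patient slope tibble.
#' @export
cmd_sweep <- function(model, cohort, config = run_config(), outdir = NULL) {
  slopes <- run_sweep(model, cohort, config$grid)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(slopes),
                     .stage_file(outdir, paste0("slopes_", model$outcome, ".csv")),
                     row.names = FALSE)
  }
  slopes
}

#' @rdname cmd_generate
#' @param slopes Per-patient slope tibble.
#' @param labels Tibble `id`, `sagittal`, `vertical`.
#' @return `cmd_stats()`: output of [build_slope_table()].
#' @export
cmd_stats <- function(slopes, labels, config = run_config(), outdir = NULL) {
  tab <- build_slope_table(slopes, labels, alpha = config$alpha)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    tag <- slopes$outcome[1]
    utils::write.csv(as.data.frame(tab$table),
                     .stage_file(outdir, paste0("table_", tag, ".csv")),
                     row.names = FALSE)
    report <- list(
      cells = as.data.frame(tab$cells),
      intra = lapply(tab$intra, .report_json),
      inter = lapply(tab$inter, .report_json)
    )
    jsonlite::write_json(report,
                         .stage_file(outdir, paste0("comparison_", tag, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  tab
}

.report_json <- function(rep) {
  list(route = rep$route,
       omnibus = rep$omnibus,
       levene_p = rep$screening$levene_p,
       all_normal = rep$screening$all_normal,
       pairwise = as.data.frame(rep$pairwise),
       alpha = rep$alpha)
}

#' @rdname cmd_generate
#' @return `cmd_run_all()`: a `run_report` list with per-stage summaries
#'   (cohort counts, classification agreement, surrogate fit statistics,
#'   grand-mean slopes, annotated tables, reliability ICC ranges), the
#'   derived seeds, a config hash, and — when `outdir` is given — a
#'   `manifest.json` listing every artifact.
#' @export
cmd_run_all <- function(config = run_config(), outdir = NULL) {
  t0 <- Sys.time()
  gen <- cmd_generate(config, outdir)
  cohort <- gen$cohort
  cls <- cmd_classify(cohort, config, outdir)
  stages <- list()
  stages$cohort <- list(n = nrow(cohort), provenance = "generated",
                        seed = config$seeds[["generate"]])
  stages$classification <- list(
    agreement = cls$agreement,
    cells = as.data.frame(as.table(cls$table))
  )
  X <- as.matrix(as.data.frame(cohort)[, surrogate_input_fields()])
  models <- list(); slope_tabs <- list(); tables <- list()
  for (outc in c("FHR", "FA")) {
    model <- cmd_train(cohort, outc, config, outdir)
    fitstats <- surrogate_fit_stats(model, X, cohort[[outc]])
    slopes <- cmd_sweep(model, cohort, config, outdir)
    tab <- cmd_stats(slopes, cls$labels, config, outdir)
    models[[outc]] <- model
    slope_tabs[[outc]] <- slopes
    tables[[outc]] <- tab
    te <- model$split$test
    agr <- evaluate_agreement(predict(model, X[te, , drop = FALSE]),
                              cohort[[outc]][te])
    stages[[paste0("surrogate_", outc)]] <- list(
      fit = as.data.frame(fitstats), best_epoch = model$best_epoch,
      best_val_mse = model$best_val_mse, converged = model$converged,
      test_agreement = list(r = agr$r, t = agr$t, p = agr$p,
                            mean_diff = agr$mean_diff,
                            loa = c(agr$loa_lower, agr$loa_upper),
                            frac_within = agr$frac_within))
    stages[[paste0("sweep_", outc)]] <- list(
      grand_mean_k = mean(slopes$k), grand_mean_b = mean(slopes$b),
      min_r2 = min(slopes$r2), frac_r2_below_0.95 = mean(slopes$r2 < 0.95))
  }
  rel <- reliability_study(cohort, config, outdir)
  stages$reliability <- list(
    icc_inter_range = range(rel$icc_inter),
    icc_intra_range = range(rel$icc_intra)
  )
  report <- list(
    package_version = as.character(utils::packageVersion("cephsweep")),
    seed = config$seed, seeds = as.list(config$seeds),
    config_hash = rlang::hash(config),
    stages = stages,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(outdir)) {
    files <- list.files(outdir)
    manifest <- c(report[c("package_version", "seed", "seeds", "config_hash")],
                  list(files = files))
    jsonlite::write_json(manifest, .stage_file(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(report = report, cohort = cohort, truth = gen$truth,
                 labels = cls$labels, models = models, slopes = slope_tabs,
                 tables = tables, reliability = rel),
            class = "run_report")
}

#' Simulated reliability study
#'
#' Draws `config$n_reliability` records at random, simulates three raters
#' measuring each record twice ([repeated_measures()] defaults), and
#' reports per-field inter- and intra-operator ICCs.
#'
#' @inheritParams cmd_generate
#' @param cohort A `ceph_cohort`.
#' @return Tibble from [reliability_report()].
#' @export
reliability_study <- function(cohort, config = run_config(), outdir = NULL) {
  seed <- config$seeds[["reliability"]]
  set.seed(seed)
  idx <- sample.int(nrow(cohort), min(config$n_reliability, nrow(cohort)))
  sub <- cohort[idx, ]
  ratings <- repeated_measures(sub, n_raters = 3L, n_sessions = 2L, seed = seed)
  rel <- reliability_report(ratings)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(rel),
                     .stage_file(outdir, "reliability.csv"), row.names = FALSE)
  }
  rel
}
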