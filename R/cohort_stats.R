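#' Normality screening
#'
#' Kolmogorov-Smirnov screening against a normal distribution with moments
#' estimated from the sample. Because the moments are estimated, the
#' Lilliefors-corrected p-value drives the verdict; the uncorrected KS
#' p-value is reported alongside for reference.
#'
#' @param values Numeric vector, n >= 5.
#' @param alpha Significance level for the verdict (default 0.05).
#' @return List with `statistic`, `p_lilliefors`, `p_ks`, `normal`
#'   (logical verdict), `degenerate` (TRUE for a constant sample, which is
#'   ruled non-normal).
#' @export
normality_screen <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("normality screening needs n >= 5", call. = FALSE)
  if (stats::sd(values) == 0) {
    return(list(statistic = NA_real_, p_lilliefors = NA_real_, p_ks = NA_real_,
                normal = FALSE, degenerate = TRUE))
  }
  lt <- nortest::lillie.test(values)
  ks <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  list(statistic = unname(lt$statistic),
       p_lilliefors = lt$p.value, p_ks = ks$p.value,
       normal = lt$p.value >= alpha, degenerate = FALSE)
}

#' Dunn's rank-based post-hoc comparisons
#'
#' Pairwise z statistics on the joint ranks after a Kruskal-Wallis
#' omnibus, with the usual tie correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))`,
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return Tibble with `group1`, `group2`, `z`, `p` (two-sided, unadjusted).
#' @export
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, groups, mean)
  ns <- tapply(rk, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  out <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]]))
    # fully tied data: no rank variance, no evidence of a difference
    z <- if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                 z = out["z", ], p = out["p", ])
}

#' Compare groups with route selection and Bonferroni-family correction
#'
#' Takes the parametric route (one-way ANOVA omnibus, pooled-variance
#' pairwise t tests) when every group passes Lilliefors normality and
#' Levene's median-centered homogeneity test holds; otherwise the
#' non-parametric route (Kruskal-Wallis omnibus, Dunn pairwise z). Either
#' way each pairwise p-value is Bonferroni-adjusted by the number of
#' comparisons in the family, capped at 1.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (>= 2 groups with n >= 3 each; smaller
#'   groups are dropped with a warning).
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `comparison_report` list: `summary` (per-group n/mean/sd),
#'   `route`, `screening` (per-group normality + Levene p), `omnibus`
#'   (statistic, df, p), `pairwise` (raw and adjusted p per pair with
#'   significance flags), `alpha`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  keep_levels <- names(which(table(groups) >= 3))
  if (length(keep_levels) < nlevels(groups)) {
    warning("dropping group(s) with fewer than 3 observations: ",
            paste(setdiff(levels(groups), keep_levels), collapse = ", "),
            call. = FALSE)
  }
  sel <- groups %in% keep_levels
  values <- values[sel]
  groups <- droplevels(groups[sel])
  if (nlevels(groups) < 2) stop("need at least 2 groups with n >= 3", call. = FALSE)
  lev <- levels(groups)
  summary_tab <- tibble::tibble(
    group = lev,
    n = as.integer(table(groups)[lev]),
    mean = as.numeric(tapply(values, groups, mean)[lev]),
    sd = as.numeric(tapply(values, groups, stats::sd)[lev])
  )
  norm <- lapply(lev, function(g) normality_screen(values[groups == g], alpha))
  all_normal <- all(vapply(norm, `[[`, logical(1), "normal"))
  lev_p <- tryCatch({
    lt <- car::leveneTest(values ~ groups, center = stats::median)
    lt[1, "Pr(>F)"]
  }, error = function(e) NA_real_)
  homogeneous <- is.finite(lev_p) && lev_p >= alpha
  parametric <- all_normal && homogeneous
  m <- choose(nlevels(groups), 2)
  if (parametric) {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    omnibus <- list(test = "one-way ANOVA", statistic = an[1, "F value"],
                    df = c(an[1, "Df"], an[2, "Df"]), p = an[1, "Pr(>F)"])
    pt <- stats::pairwise.t.test(values, groups, p.adjust.method = "none",
                                 pool.sd = TRUE)
    pairs <- utils::combn(lev, 2)
    raw <- apply(pairs, 2, function(pr) {
      pm <- pt$p.value
      if (pr[2] %in% rownames(pm) && pr[1] %in% colnames(pm)) {
        pm[pr[2], pr[1]]
      } else {
        pm[pr[1], pr[2]]
      }
    })
    pairwise <- tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ], raw_p = raw)
    route <- "ANOVA+Bonferroni"
  } else {
    kw <- stats::kruskal.test(values, groups)
    omnibus <- list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
                    df = unname(kw$parameter), p = kw$p.value)
    dn <- dunn_test(values, groups)
    pairwise <- tibble::tibble(group1 = dn$group1, group2 = dn$group2,
                               raw_p = dn$p)
    route <- "KruskalWallis+Dunn"
  }
  pairwise$adj_p <- pmin(1, pairwise$raw_p * m)
  pairwise$significant <- pairwise$adj_p < alpha
  structure(list(
    summary = summary_tab, route = route,
    screening = list(normality = norm, levene_p = lev_p,
                     all_normal = all_normal, homogeneous = homogeneous),
    omnibus = omnibus, pairwise = pairwise, alpha = alpha
  ), class = "comparison_report")
}

#' Intraclass correlation coefficient from a subjects x raters matrix
#'
#' Two-way mean-squares decomposition (subjects, raters, residual) with
#' the two single-rater forms used in reliability studies: two-way random
#' effects with absolute agreement, ICC(2,1), for inter-operator
#' comparisons; and two-way mixed effects with consistency, ICC(3,1), for
#' intra-operator (across-session) comparisons.
#'
#' @param ratings Numeric matrix, subjects in rows (>= 5), raters (or
#'   sessions) in columns (>= 2); no missing cells.
#' @param form `"two-way-random-absolute"` (ICC(2,1)) or
#'   `"two-way-mixed-consistency"` (ICC(3,1)).
#' @return List with `value`, `form`, `components` (MSR, MSC, MSE),
#'   `n_subjects`, `n_raters`.
#' @export
icc <- function(ratings, form = c("two-way-random-absolute",
                                  "two-way-mixed-consistency")) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5 || k < 2) stop("icc needs >= 5 subjects and >= 2 raters", call. = FALSE)
  if (anyNA(ratings)) stop("icc does not impute missing cells", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  value <- if (form == "two-way-random-absolute") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  list(value = value, form = form,
       components = list(MSR = msr, MSC = msc, MSE = mse),
       n_subjects = n, n_raters = k)
}

#' Reliability report for a repeated-measures tensor
#'
#' Inter-operator reliability: for each field, the first-session ratings
#' of all raters enter ICC(2,1) (two-way random, absolute agreement).
#' Intra-operator reliability: for each rater and field, the sessions
#' enter ICC(3,1) (two-way mixed, consistency); the per-field value
#' reported is the minimum over raters (the most conservative rater).
#'
#' @param ratings 4-d array `[rater, session, record, field]` from
#'   [repeated_measures()].
#' @return Tibble with columns `field`, `icc_inter`, `icc_intra`.
#' @export
reliability_report <- function(ratings) {
  dn <- dimnames(ratings)
  fields <- dn[[4]]
  n_raters <- dim(ratings)[1]; n_sessions <- dim(ratings)[2]
  out <- lapply(fields, function(f) {
    inter <- icc(t(ratings[, 1, , f]), "two-way-random-absolute")$value
    intra <- min(vapply(seq_len(n_raters), function(r) {
      icc(t(ratings[r, , , f]), "two-way-mixed-consistency")$value
    }, numeric(1)))
    tibble::tibble(field = f, icc_inter = inter, icc_intra = intra)
  })
  do.call(rbind, out)
}

# significance letters for one sagittal class' vertical triple:
# a = hypo vs nor (attached to nor), b = hypo vs hyper, c = nor vs hyper
# (both attached to hyper) — the footnote convention of the summary tables
.intra_letters <- function(report) {
  sig <- function(g1, g2) {
    pw <- report$pairwise
    hit <- (pw$group1 == g1 & pw$group2 == g2) | (pw$group1 == g2 & pw$group2 == g1)
    any(pw$significant[hit])
  }
  list(nor = if (sig("hypo", "nor")) "a" else "",
       hyper = paste0(if (sig("hypo", "hyper")) "b" else "",
                      if (sig("nor", "hyper")) ",c" else ""))
}

.inter_letters <- function(report) {
  sig <- function(g1, g2) {
    pw <- report$pairwise
    hit <- (pw$group1 == g1 & pw$group2 == g2) | (pw$group1 == g2 & pw$group2 == g1)
    any(pw$significant[hit])
  }
  marks <- c(if (sig("I", "II")) "A", if (sig("I", "III")) "B",
             if (sig("II", "III")) "C")
  if (length(marks) == 0) "N.S" else paste(marks, collapse = ",")
}

#' Annotated slope/intercept summary table
#'
#' Reproduces the layout of the published per-cell coefficient tables:
#' for one outcome, a `k` row and a `b` row per sagittal class with
#' "mean +/- SD" cells over the vertical types plus a Total column,
#' superscript-style significance letters from the intra-group (within a
#' sagittal class, across vertical types) comparisons, and a final
#' inter-group block (within each vertical type, across sagittal classes).
#' Each letter family is a triple of pairwise comparisons, Bonferroni
#' m = 3.
#'
#' @param slopes Per-patient slopes from [run_sweep()].
#' @param labels Tibble `id`, `sagittal`, `vertical`.
#' @param alpha Family-wise significance level.
#' @return List with `table` (formatted tibble), `cells` (numeric summary
#'   from [summarize_slopes()]), `intra` and `inter` (named lists of
#'   `comparison_report`s, per measure).
#' @export
build_slope_table <- function(slopes, labels, alpha = 0.05) {
  df <- merge(as.data.frame(slopes), as.data.frame(labels), by = "id")
  n_cells <- length(unique(paste(df$sagittal, df$vertical)))
  if (n_cells < 2) stop("need at least two populated cells", call. = FALSE)
  cells <- summarize_slopes(slopes, labels)
  fmt <- function(m, s, letters = "") {
    if (is.na(m)) return("-")
    paste0(sprintf("%.2f +/- %.2f", m, s),
           if (nzchar(letters)) paste0(" ", sub("^,", "", letters)) else "")
  }
  intra <- list(); inter <- list()
  rows <- list()
  for (measure in c("k", "b")) {
    for (sg in SAGITTAL_LEVELS) {
      sub <- df[df$sagittal == sg, ]
      rep_sg <- compare_groups(sub[[measure]], sub$vertical, alpha)
      intra[[paste(measure, sg, sep = ".")]] <- rep_sg
      let <- .intra_letters(rep_sg)
      vals <- lapply(VERTICAL_LEVELS, function(vt) {
        cc <- cells[cells$sagittal == sg & cells$vertical == vt, ]
        fmt(cc[[paste0(measure, "_mean")]], cc[[paste0(measure, "_sd")]],
            switch(vt, hypo = "", nor = let$nor, hyper = let$hyper))
      })
      tot <- cells[cells$sagittal == sg & cells$vertical == "Total", ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        row = sg, measure = measure,
        hypo = vals[[1]], nor = vals[[2]], hyper = vals[[3]],
        total = fmt(tot[[paste0(measure, "_mean")]], tot[[paste0(measure, "_sd")]]))
    }
  }
  inter_row <- function(measure) {
    marks <- vapply(VERTICAL_LEVELS, function(vt) {
      sub <- df[df$vertical == vt, ]
      rep_vt <- compare_groups(sub[[measure]], sub$sagittal, alpha)
      inter[[paste(measure, vt, sep = ".")]] <<- rep_vt
      .inter_letters(rep_vt)
    }, character(1))
    tibble::tibble(row = "Inter-group comparison", measure = measure,
                   hypo = marks[1], nor = marks[2], hyper = marks[3], total = "")
  }
  rows[[length(rows) + 1L]] <- inter_row("k")
  rows[[length(rows) + 1L]] <- inter_row("b")
  list(table = do.call(rbind, rows), cells = cells, intra = intra, inter = inter)
}
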