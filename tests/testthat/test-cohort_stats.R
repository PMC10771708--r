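test_that("normality screening separates normal, uniform and constant samples", {
  set.seed(14)
  expect_true(normality_screen(rnorm(500))$normal)
  u <- normality_screen(runif(200))
  expect_false(u$normal)
  expect_lt(u$p_lilliefors, 0.05)
  const <- normality_screen(rep(3, 10))
  expect_true(const$degenerate)
  expect_false(const$normal)
  expect_error(normality_screen(1:3), "n >= 5")
})

test_that("group comparison picks the route the screening supports", {
  set.seed(15)
  vals <- c(rnorm(100), rnorm(100), rnorm(100, 3))
  grp <- rep(c("g1", "g2", "g3"), each = 100)
  rep_n <- compare_groups(vals, grp)
  expect_equal(rep_n$route, "ANOVA+Bonferroni")
  expect_lt(rep_n$omnibus$p, 1e-6)
  pw <- rep_n$pairwise
  flag <- function(a, b) pw$significant[(pw$group1 == a & pw$group2 == b) |
                                          (pw$group1 == b & pw$group2 == a)]
  expect_true(flag("g1", "g3"))
  expect_true(flag("g2", "g3"))
  expect_false(flag("g1", "g2"))

  # heavy-tailed data reroute to the rank-based tests
  set.seed(16)
  vals2 <- c(rexp(100), rexp(100), rexp(100) + 2)
  rep_e <- compare_groups(vals2, grp)
  expect_equal(rep_e$route, "KruskalWallis+Dunn")
  expect_lt(rep_e$omnibus$p, 1e-6)
})

test_that("Bonferroni adjustment multiplies by the family size and caps at 1", {
  set.seed(17)
  vals <- c(rnorm(50), rnorm(50), rnorm(50))
  rep0 <- compare_groups(vals, rep(c("a", "b", "c"), each = 50))
  expect_equal(rep0$pairwise$adj_p, pmin(1, rep0$pairwise$raw_p * 3))
  expect_true(all(rep0$pairwise$adj_p >= rep0$pairwise$raw_p))
  # the worked arithmetic: raw 0.02 in a family of 3 is not significant
  expect_equal(min(1, 0.02 * 3), 0.06)
})

test_that("identical groups produce no significance markers", {
  set.seed(18)
  base <- rnorm(40)
  rep0 <- compare_groups(c(base, base + 0), rep(c("x", "y"), each = 40))
  expect_false(any(rep0$pairwise$significant))
  sub_min <- expect_warning(
    compare_groups(c(base, base, 1, 2), c(rep(c("x", "y"), each = 40), "z", "z")),
    "fewer than 3")
})

test_that("Dunn z statistics match a brute-force rank computation", {
  set.seed(19)
  vals <- c(rnorm(7), rnorm(6, 1), round(rnorm(7), 0))  # includes ties
  grp <- rep(c("a", "b", "c"), c(7, 6, 7))
  dn <- dunn_test(vals, grp)
  # independent brute force
  N <- length(vals)
  rk <- rank(vals)
  tie_sizes <- as.numeric(table(vals))
  TT <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  for (i in seq_len(nrow(dn))) {
    g1 <- dn$group1[i]; g2 <- dn$group2[i]
    m1 <- mean(rk[grp == g1]); m2 <- mean(rk[grp == g2])
    n1 <- sum(grp == g1); n2 <- sum(grp == g2)
    z <- (m1 - m2) / sqrt((N * (N + 1) / 12 - TT) * (1 / n1 + 1 / n2))
    expect_equal(dn$z[i], z, tolerance = 1e-10)
    expect_equal(dn$p[i], 2 * pnorm(-abs(z)), tolerance = 1e-10)
  }
})

test_that("ICC recovers variance-component ground truth", {
  # perfect agreement
  m <- matrix(rep(rnorm(30), 3), ncol = 3)
  expect_equal(icc(m, "two-way-mixed-consistency")$value, 1)
  expect_equal(icc(m, "two-way-random-absolute")$value, 1)

  # subject variance 9, error variance 1: consistency ICC -> 0.9
  set.seed(20)
  subj <- rnorm(4000, 0, 3)
  ratings <- sapply(1:3, function(j) subj + rnorm(4000, 0, 1))
  est <- icc(ratings, "two-way-mixed-consistency")
  expect_equal(est$value, 0.9, tolerance = 0.01)

  # pure noise: no subject effect
  noise <- matrix(rnorm(3000), ncol = 3)
  expect_lt(abs(icc(noise, "two-way-mixed-consistency")$value), 0.05)

  # systematic rater shifts depress absolute agreement but not consistency
  shifted <- ratings + matrix(rep(c(-2, 0, 2), each = 4000), ncol = 3)
  abs_icc <- icc(shifted, "two-way-random-absolute")$value
  con_icc <- icc(shifted, "two-way-mixed-consistency")$value
  expect_lt(abs_icc, con_icc)

  expect_error(icc(ratings[1:3, ]), ">= 5 subjects")
})

test_that("ICC mean squares agree with a two-way ANOVA decomposition", {
  set.seed(22)
  ratings <- matrix(rnorm(60, 50, 4), ncol = 3)
  est <- icc(ratings, "two-way-random-absolute")
  df <- data.frame(y = as.vector(ratings),
                   subj = factor(rep(seq_len(20), 3)),
                   rater = factor(rep(1:3, each = 20)))
  an <- anova(stats::lm(y ~ subj + rater, data = df))
  expect_equal(est$components$MSR, an["subj", "Mean Sq"], tolerance = 1e-10)
  expect_equal(est$components$MSC, an["rater", "Mean Sq"], tolerance = 1e-10)
  expect_equal(est$components$MSE, an["Residuals", "Mean Sq"], tolerance = 1e-10)
})

test_that("the simulated reliability study lands in the published ICC range", {
  gen <- default_gen()
  set.seed(23)
  idx <- sample.int(nrow(gen$cohort), 100)
  ratings <- repeated_measures(gen$cohort[idx, ], n_raters = 3, n_sessions = 2,
                               seed = 24)
  rel <- reliability_report(ratings)
  expect_equal(nrow(rel), 16)
  expect_true(all(rel$icc_inter >= 0.90 & rel$icc_inter <= 0.98))
  expect_true(all(rel$icc_intra <= 1))
})

test_that("annotated tables carry the footnote letter conventions", {
  # slopes drawn around the published FA coefficients with small dispersion
  set.seed(25)
  alloc <- allocation_table()
  ref <- slope_calibration("FA")
  rows <- list()
  for (i in seq_len(nrow(alloc))) {
    m <- alloc$total[i]
    rows[[i]] <- tibble::tibble(
      id = sprintf("%s.%s.%03d", alloc$sagittal[i], alloc$vertical[i], seq_len(m)),
      sagittal = alloc$sagittal[i], vertical = alloc$vertical[i],
      k = rnorm(m, ref$k[i], 0.03), b = rnorm(m, ref$b[i], 0.5))
  }
  df <- do.call(rbind, rows)
  slopes <- tibble::tibble(id = df$id, outcome = "FA", k = df$k, b = df$b)
  labels <- df[, c("id", "sagittal", "vertical")]
  tab <- build_slope_table(slopes, labels)
  ktab <- tab$table[tab$table$measure == "k", ]
  # hypodivergent vs hyperdivergent FA slopes differ in Classes I and II
  for (sg in c("I", "II")) {
    expect_match(ktab$hyper[ktab$row == sg], "b,c")
  }
  inter_k <- tab$table[tab$table$row == "Inter-group comparison" &
                         tab$table$measure == "k", ]
  for (col in c("hypo", "nor", "hyper")) {
    expect_match(inter_k[[col]], "B")
    expect_match(inter_k[[col]], "C")
  }
  expect_error(build_slope_table(slopes[1:5, ], labels[1:5, ]), "two populated")
})

test_that("tables with no significant differences print N.S markers", {
  set.seed(26)
  ids <- sprintf("r%03d", 1:180)
  labels <- tibble::tibble(id = ids,
                           sagittal = rep(c("I", "II", "III"), each = 60),
                           vertical = rep(rep(c("hypo", "nor", "hyper"), each = 20), 3))
  # every cell holds the same 20 values: all pairwise differences are exactly 0
  slopes <- tibble::tibble(id = ids, outcome = "FHR",
                           k = rep(rnorm(20, -0.28, 0.04), 9),
                           b = rep(rnorm(20, 70, 2), 9))
  tab <- build_slope_table(slopes, labels)
  inter <- tab$table[tab$table$row == "Inter-group comparison", ]
  expect_true(all(unlist(inter[, c("hypo", "nor", "hyper")]) == "N.S"))
})
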