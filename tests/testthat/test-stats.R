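test_that("Anderson-Darling matches the direct order-statistic formula", {
  x <- c(14.0, 14.2, 13.9, 14.1, 14.05, 13.95, 14.15, 13.85)
  got <- anderson_darling(x)
  # independent brute-force evaluation of the A^2 sum
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  i <- seq_len(n)
  a2_direct <- -n - mean((2 * i - 1) *
                           (log(pnorm(z)) + log(1 - pnorm(rev(z)))))
  expect_equal(got$a2, a2_direct, tolerance = 1e-10)
  expect_equal(got$a2_corrected, a2_direct * (1 + 0.75 / n + 2.25 / n^2),
               tolerance = 1e-10)
  expect_gt(got$p_value, 0.05)  # near-symmetric sample, no rejection

  # independent library oracle
  ref <- nortest::ad.test(x)
  expect_equal(got$a2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  # mirror invariance
  expect_equal(anderson_darling(-x)$a2, got$a2, tolerance = 1e-12)

  expect_error(anderson_darling(rep(1, 8)), "constant")
  expect_error(anderson_darling(1:4), "n >= 5")
})

test_that("Levene's W matches a hand ANOVA on absolute deviations", {
  g1 <- c(1.1, 2.3, 1.9, 2.7)
  g2 <- c(4.5, 3.2, 5.1, 4.0)
  g3 <- c(0.5, 6.1, 3.3, 2.9)
  vals <- c(g1, g2, g3)
  grp <- rep(c("a", "b", "c"), each = 4)
  got <- levene_test(vals, grp)

  dev <- unlist(lapply(list(g1, g2, g3), function(g) abs(g - mean(g))))
  fit <- anova(lm(dev ~ factor(grp)))
  expect_equal(got$statistic, fit[["F value"]][1], tolerance = 1e-9)
  expect_equal(got$p_value, fit[["Pr(>F)"]][1], tolerance = 1e-9)
  expect_equal(got$df1, 2)
  expect_equal(got$df2, 9)

  # identical groups: all deviations equal across groups -> W = 0, p = 1
  same <- levene_test(c(g1, g1), rep(c("a", "b"), each = 4))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  expect_error(levene_test(c(1, 2, 3), c("a", "a", "a")), "2 groups")
  expect_error(levene_test(c(1, 1, 1, 2, 3, 4),
                           rep(c("a", "b"), each = 3)), "degenerate")
})

test_that("repeated-measures ANOVA matches a direct sums-of-squares oracle", {
  vals <- withr::with_seed(5, matrix(rnorm(12, 10, 2), nrow = 4))
  tb <- toy_rm_table(vals)
  fit <- rm_anova(tb, value, condition, specimen)

  # brute-force two-way additive decomposition from raw sums
  y <- vals
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  ss_subj <- k * sum((rowMeans(y) - grand)^2)
  ss_cond <- n * sum((colMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  f_direct <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  expect_equal(fit$f, f_direct, tolerance = 1e-9)
  expect_equal(unname(fit$ss), c(ss_subj, ss_cond, ss_err),
               tolerance = 1e-9)
  expect_equal(fit$df1, 2)
  expect_equal(fit$df2, 6)
  expect_equal(fit$p_value, pf(f_direct, 2, 6, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("degenerate ANOVA decompositions are guarded", {
  # no condition effect, large subject effects -> F = 0, p = 1
  flat <- toy_rm_table(matrix(rep(c(10, 20, 30), each = 3),
                              nrow = 3, byrow = TRUE))
  fit0 <- rm_anova(flat, value, condition, specimen)
  expect_equal(fit0$f, 0)
  expect_equal(fit0$p_value, 1)

  # perfectly additive table -> zero error SS -> F = Inf, p = 0
  add <- toy_rm_table(matrix(c(10, 11, 12, 20, 21, 22, 30, 31, 32),
                             nrow = 3, byrow = TRUE))
  fit1 <- rm_anova(add, value, condition, specimen)
  expect_identical(fit1$f, Inf)
  expect_identical(fit1$p_value, 0)
})

test_that("unbalanced tables are rejected listing the missing cells", {
  tb <- toy_rm_table(matrix(1:9 + 0.5, nrow = 3, byrow = TRUE))
  tb <- tb[-c(2, 9), ]
  expect_error(rm_anova(tb, value, condition, specimen),
               "missing cells.*S1:defect")
})

test_that("Tukey q and p match the hand formula on the RM error term", {
  vals <- withr::with_seed(8, matrix(rnorm(12, 10, 2), nrow = 4))
  tb <- toy_rm_table(vals)
  fit <- rm_anova(tb, value, condition, specimen)
  tk <- tukey_posthoc(fit)
  expect_equal(nrow(tk), 3)
  means <- colMeans(vals)
  names(means) <- c("intact", "defect", "treated")
  for (i in seq_len(3)) {
    pair <- strsplit(tk$contrast[i], " - ")[[1]]
    q_hand <- abs(means[pair[1]] - means[pair[2]]) /
      sqrt(fit$ms_error / 4)
    expect_equal(tk$q[i], unname(q_hand), tolerance = 1e-9)
    expect_equal(tk$adj_p_value[i],
                 ptukey(unname(q_hand), 3, 6, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("Tukey separates distant means and spares equal ones", {
  base <- c(5, 5.2, 4.9, 5.05)
  eps <- withr::with_seed(13, matrix(rnorm(12, 0, 1e-3), 4, 3))
  eps <- sweep(eps, 2, colMeans(eps))  # equalise the condition means exactly
  vals <- cbind(base, base, base + 10) + eps
  tb <- toy_rm_table(vals)
  tk <- tukey_posthoc(rm_anova(tb, value, condition, specimen))
  p <- setNames(tk$adj_p_value, tk$contrast)
  expect_gt(p[["defect - intact"]], 0.99)
  expect_lt(p[["treated - intact"]], 1e-6)
  expect_lt(p[["treated - defect"]], 1e-6)

  # identical means in all conditions -> all adjusted p = 1
  eq <- toy_rm_table(matrix(rep(c(3, 7, 11), 3), nrow = 3))
  tke <- tukey_posthoc(rm_anova(eq, value, condition, specimen))
  expect_equal(tke$adj_p_value, rep(1, 3), tolerance = 1e-9)
})

test_that("one-sample t matches hand arithmetic and quadrature", {
  t0 <- one_sample_t(c(4, 5, 6), 5)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)

  t1 <- one_sample_t(c(1, 2, 3), 0)
  expect_equal(t1$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(t1$df, 2)
  # p by numerical integration of the t density
  p_quad <- 2 * integrate(function(u) dt(u, 2), lower = 2 * sqrt(3),
                          upper = Inf)$value
  expect_equal(t1$p_value, p_quad, tolerance = 1e-8)

  expect_error(one_sample_t(c(2, 2, 2), 1), "constant")
  expect_error(one_sample_t(c(1, 2), 0), "n >= 3")
})

test_that("percent change follows the reporting convention", {
  expect_equal(percent_change(12.32, 9.57), 28.7, tolerance = 0.002)
  expect_equal(percent_change(8.86, 8.15), 8.7, tolerance = 0.006)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(1, 0), "zero reference")
})

test_that("comparison battery flags every cell for a separated degenerate cohort", {
  # three conditions with distinct means, tiny within-specimen error
  measures <- withr::with_seed(3, {
    tidyr::expand_grid(specimen_id = sprintf("S%d", 1:6),
                       condition = c("intact", "defect", "treated"),
                       modality = c("flexion_extension", "lateral_bending"),
                       measure = c("rom", "nz_stiffness")) |>
      dplyr::mutate(value = 10 +
                      5 * match(condition, c("intact", "defect", "treated")) +
                      rnorm(dplyr::n(), 0, 1e-4))
  })
  report <- compare_groups(measures)
  expect_equal(nrow(report), 4)
  expect_true(all(report$p_defect_intact < 1e-6))
  counts <- significance_summary(report)
  expect_equal(counts$n_significant, c(4, 4, 4))
  expect_equal(counts$n_cells, rep(4L, 3))

  # percent change conventions agree for a location-shift cohort
  expect_equal(report$pct_defect,
               rep(100 * 5 / (10 + 5), 4), tolerance = 1e-3)
  rep_paired <- compare_groups(measures, percent_method = "paired")
  expect_equal(rep_paired$pct_defect, report$pct_defect, tolerance = 1e-3)

  # all-null report counts zero
  null_rep <- report
  null_rep$p_defect_intact <- 1
  null_rep$p_treated_intact <- 1
  null_rep$p_treated_defect <- 1
  expect_equal(significance_summary(null_rep)$n_significant, c(0, 0, 0))
})

test_that("power: lateral-bending ROM separates defect from intact at n = 8", {
  cells <- reference_kinetics()
  rejections <- withr::with_seed(21, {
    vapply(1:200, function(i) {
      spec <- cohort_spec(cells = cells, n_specimens = 8,
                          seed = sample.int(1e6, 1))
      truth <- sample_cohort_params(spec)
      lb <- dplyr::filter(truth, modality == "lateral_bending")
      fit <- rm_anova(lb, rom, condition, specimen_id)
      tk <- tukey_posthoc(fit)
      tk$adj_p_value[tk$contrast == "defect - intact"] < 0.05
    }, logical(1))
  })
  expect_gt(mean(rejections), 0.5)
})
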