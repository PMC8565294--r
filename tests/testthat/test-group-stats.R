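table1 <- clinical_summary_table()
triple <- function(row, grp) {
  c(mean = row[[paste0("mean_", grp)]], sd = row[[paste0("sd_", grp)]],
    n = row[[paste0("n_", grp)]])
}
t_from_table <- function(characteristic, variant = "welch") {
  row <- table1[table1$characteristic == characteristic, ]
  two_sample_t(triple(row, "patient"), triple(row, "control"), variant)
}

test_that("published clinical group t-values are reproduced from summaries", {
  # Welch reproduces the printed MMSE, auditory, naming, language rows
  expect_equal(t_from_table("mmse")$statistic, -10.43, tolerance = 0.005)
  expect_equal(t_from_table("abc_auditory")$statistic, -6.43,
               tolerance = 0.005)
  expect_equal(t_from_table("abc_naming")$statistic, -7.81, tolerance = 0.02)
  expect_equal(t_from_table("language_ability")$statistic, -8.96,
               tolerance = 0.005)
  # the age row reproduces under the pooled Student variant
  expect_equal(t_from_table("age", "student")$statistic, -1.71,
               tolerance = 0.005)
  expect_gt(t_from_table("age", "student")$p_value, 0.05)
  # the spontaneous-speech row also reproduces under pooled Student
  expect_equal(t_from_table("abc_spontaneous", "student")$statistic, -10.46,
               tolerance = 0.005)
})

test_that("composite language ability equals the mean of the ABC sub-scores", {
  subs <- c("abc_spontaneous", "abc_auditory", "abc_repetition", "abc_naming")
  sub_rows <- table1[match(subs, table1$characteristic), ]
  lang <- table1[table1$characteristic == "language_ability", ]
  expect_equal(mean(sub_rows$mean_patient), lang$mean_patient,
               tolerance = 0.005)
  expect_equal(mean(sub_rows$mean_control), lang$mean_control,
               tolerance = 0.005)
})

test_that("two-sample t handles raw samples, matches t.test, and errors on degeneracy", {
  set.seed(10)
  a <- rnorm(15, 1)
  b <- rnorm(12)
  for (v in c("welch", "student")) {
    mine <- two_sample_t(a, b, v)
    ref <- t.test(a, b, var.equal = v == "student")
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  same <- c(1, 2, 3, 4)
  res <- two_sample_t(same, same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero variance")
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})

test_that("chi-square on 2x2 tables matches the formula and chisq.test", {
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$p_value, 1)
  expect_equal(chi_square_2x2(matrix(c(20, 0, 0, 20), 2))$statistic, 40)
  # the study's sex table 16:8 vs 10:9: uncorrected 0.873, Yates 0.385
  sex <- matrix(c(16, 10, 8, 9), 2)
  expect_equal(chi_square_2x2(sex)$statistic, 0.873, tolerance = 0.001)
  expect_equal(chi_square_2x2(sex, yates = TRUE)$statistic, 0.385,
               tolerance = 0.001)
  ref <- suppressWarnings(chisq.test(sex, correct = FALSE))
  expect_equal(chi_square_2x2(sex)$statistic, unname(ref$statistic),
               tolerance = 1e-10)
  expect_equal(chi_square_2x2(sex)$p_value, ref$p.value, tolerance = 1e-10)
  refy <- suppressWarnings(chisq.test(sex, correct = TRUE))
  expect_equal(chi_square_2x2(sex, yates = TRUE)$statistic,
               unname(refy$statistic), tolerance = 1e-10)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margins")
})

test_that("Mann-Whitney U: separation, symmetry, enumeration, wilcox agreement", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  x <- c(1, 2, 3, 4)
  expect_equal(mann_whitney_u(x, x)$statistic, length(x)^2 / 2)
  expect_equal(mann_whitney_u(c(1, 3), c(2, 4))$statistic, 1)
  # exact p agrees with full enumeration over the 6 label assignments:
  # U* = 1,0,2,2,4,3 so 4 of 6 are at least as far from n_a n_b / 2 = 2
  res <- mann_whitney_u(c(1, 3), c(2, 4))
  expect_equal(res$p_value, 4 / 6)
  # agreement with wilcox.test (exact, no ties)
  set.seed(20)
  a <- rnorm(6); b <- rnorm(5, 0.5)
  expect_equal(mann_whitney_u(a, b)$statistic,
               unname(wilcox.test(a, b, exact = TRUE)$statistic))
  expect_equal(mann_whitney_u(a, b)$p_value,
               wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-10)
  # large samples: normal approximation close to wilcox.test's
  a2 <- rnorm(30); b2 <- rnorm(25, 0.6)
  expect_equal(mann_whitney_u(a2, b2)$p_value,
               wilcox.test(a2, b2, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-6)
})

test_that("permutation test: exact enumeration, add-one bound, sampled accuracy", {
  # toy case: 6 relabelings, 2 as extreme as observed
  res <- permutation_two_sample(c(1, 2), c(10, 11))
  expect_true(res$exhaustive)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  # identical multisets: p = 1
  expect_equal(permutation_two_sample(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # sampled p respects the add-one lower bound
  set.seed(30)
  a <- rnorm(10, 5); b <- rnorm(9)
  res2 <- permutation_two_sample(a, b, n_perm = 200, seed = 7,
                                 exhaustive_limit = 10)
  expect_false(res2$exhaustive)
  expect_gte(res2$p_value, 1 / 201)
  # sampled p close to exact p on an enumerable design
  set.seed(31)
  x <- rnorm(5, 1); y <- rnorm(5)
  exact <- permutation_two_sample(x, y)  # choose(10,5)=252, exhaustive
  expect_true(exact$exhaustive)
  sampled <- permutation_two_sample(x, y, n_perm = 5000, seed = 3,
                                    exhaustive_limit = 10)
  expect_lt(abs(sampled$p_value - exact$p_value), 0.02)
})

test_that("Pearson correlation matches cor.test and handles edge cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson_correlation(x, c(1, 3, 2, 4))$statistic, 0.8)
  set.seed(40)
  u <- rnorm(25); v <- 0.5 * u + rnorm(25)
  ref <- cor.test(u, v)
  mine <- pearson_correlation(u, v)
  expect_equal(mine$statistic, unname(ref$estimate), tolerance = 1e-10)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("partial correlation projects out covariates correctly", {
  set.seed(50)
  # empty covariate set reduces to Pearson
  x <- rnorm(20); y <- 0.6 * x + rnorm(20)
  expect_equal(partial_correlation(x, y)$statistic,
               pearson_correlation(x, y)$statistic)
  # y = x + c with x independent of c: controlling for c recovers r ~ 1
  n <- 500
  cvar <- rnorm(n)
  x2 <- rnorm(n)
  y2 <- x2 + 3 * cvar
  pc <- partial_correlation(x2, y2, data.frame(c = cvar))
  expect_gt(pc$statistic, 0.99)
  expect_equal(pc$df, n - 3)
  # sex-style factor covariates are encoded 0/1
  sex <- sample(c("M", "F"), 40, replace = TRUE)
  x3 <- rnorm(40); y3 <- rnorm(40)
  res <- partial_correlation(x3, y3, data.frame(sex = sex))
  expect_true(is.finite(res$statistic))
  # rank-deficient design errors
  expect_error(partial_correlation(x3, y3,
                                   data.frame(a = x3 * 0 + 1, b = 2)),
               "rank-deficient")
  # x fully explained by covariates: degenerate
  expect_error(partial_correlation(cvar, y2, data.frame(c = cvar)),
               "zero residual variance")
  # agreement with lm-residual reference
  set.seed(51)
  z1 <- rnorm(60); z2 <- rnorm(60)
  xa <- rnorm(60) + z1; ya <- rnorm(60) + z1 - z2
  r_ref <- cor(resid(lm(xa ~ z1 + z2)), resid(lm(ya ~ z1 + z2)))
  expect_equal(partial_correlation(xa, ya, data.frame(z1, z2))$statistic,
               r_ref, tolerance = 1e-10)
})

test_that("Bonferroni levels reproduce the 264-node thresholds", {
  lev <- bonferroni_levels(0.05, 264)
  expect_equal(lev$strict, 0.05 / 264)
  expect_equal(lev$liberal, 1 / 264)
  # at the precision the thresholds are conventionally printed
  expect_equal(round(lev$strict, 6), 0.000189)
  expect_equal(round(lev$liberal, 4), 0.0038)
  expect_equal(bonferroni_levels(0.05, 1)$strict, 0.05)
})

test_that("compare_groups detects the lesion effect with the right direction", {
  cfg <- strong_lesion_config(seed = 71, n_nodes = 30,
                              module_sizes = rep(5, 6),
                              lesion_nodes = 1:10, n_timepoints = 100,
                              n_patients = 10, n_controls = 8)
  co <- generate_cohort(cfg)
  profiles <- profile_cohort(co$series, grid = threshold_grid(),
                             n_nulls = 10, seed = 4)
  cmp <- compare_groups(profiles, co$clinical, n_perm = 500, seed = 9)
  glob <- cmp$global
  eloc <- glob[glob$metric == "Eloc", ]
  expect_lt(eloc$mean_patient, eloc$mean_control)
  expect_lt(eloc$t, 0)
  # parametric and permutation p agree in significance here
  expect_identical(eloc$p_t < 0.05, eloc$p_perm < 0.05)
  # nodal table covers every node x metric with both flags
  expect_identical(nrow(cmp$nodal), 30L * 4L)
  expect_identical(cmp$nodal$flag_strict,
                   cmp$nodal$p < 0.05 / 30)
  expect_identical(cmp$nodal$flag_liberal, cmp$nodal$p < 1 / 30)
  # flagged nodes should be enriched in the lesioned set for DC
  dc <- cmp$nodal[cmp$nodal$metric == "DC" & cmp$nodal$flag_liberal, ]
  if (nrow(dc) > 0)
    expect_gt(mean(dc$node_id <= 10), 0.5)
  # behavior table exists only for significant global metrics
  if (!is.null(cmp$behavior))
    expect_true(all(cmp$behavior$metric %in%
                      glob$metric[glob$significant]))
})

test_that("compare_groups guards against missing groups and subjects", {
  cfg <- cohort_config(seed = 72, n_nodes = 12, module_sizes = c(6, 6),
                       n_timepoints = 50, n_patients = 3, n_controls = 3)
  co <- generate_cohort(cfg)
  profiles <- profile_cohort(co$series, grid = threshold_grid(),
                             global_metrics = c("Cp", "Eloc"),
                             nodal_metrics = "DC")
  clin_bad <- co$clinical[co$clinical$group == "patient", ]
  expect_error(compare_groups(profiles, clin_bad), "missing subjects")
})
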