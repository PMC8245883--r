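test_that("pearson test matches cor.test and handles perfect correlation", {
  set.seed(101)
  x <- rnorm(25)
  y <- 0.5 * x + rnorm(25)
  mine <- pearson_test(x, y)
  ref <- cor.test(x, y)
  expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-12)

  exact <- pearson_test(x, 2 * x + 1)
  expect_equal(exact$r, 1)
  expect_equal(exact$p_two_sided, 0)

  expect_error(pearson_test(1:3, 2:4), "n >= 4")
  expect_error(pearson_test(rep(1, 5), 1:5), "constant")
  expect_error(pearson_test(1:5, 1:4), "equal length")
})

test_that("printed worked-example correlation p-values reproduce", {
  expect_equal(pearson_p(0.48, 20)$p_two_sided, 0.03220232, tolerance = 1e-6)
  expect_equal(round(pearson_p(0.48, 20)$p_two_sided, 2), 0.03)
  # resolves the 0.03-vs-0.003 discrepancy in favour of the closed form
  expect_equal(pearson_p(-0.64, 20)$p_two_sided, 0.002371762,
               tolerance = 1e-6)
})

test_that("the analytic correlation p agrees with a permutation oracle", {
  set.seed(57)
  x <- rnorm(12)
  y <- 0.6 * x + rnorm(12)
  r_obs <- cor(x, y)
  perm <- replicate(10000, abs(cor(x, sample(y))) >= abs(r_obs))
  expect_lt(abs(mean(perm) - pearson_test(x, y)$p_two_sided), 0.02)
})

test_that("fisher z transform: values, odd symmetry, inverse, domain", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.90), 1.472219, tolerance = 1e-6)
  expect_equal(fisher_z(-0.48), -fisher_z(0.48))
  expect_equal(fisher_z_inverse(fisher_z(0.7)), 0.7, tolerance = 1e-12)
  expect_error(fisher_z(1), "< 1")
  expect_error(fisher_z(-1.3), "< 1")
})

test_that("the Fisher z comparison reproduces the printed z statistics and is antisymmetric", {
  a <- compare_correlations(0.90, 20, 0.48, 20)
  expect_equal(round(a$z_statistic, 2), 2.77)
  expect_lt(a$p_two_sided, 0.01)

  b <- compare_correlations(-0.64, 20, -0.06, 20)
  expect_equal(round(abs(b$z_statistic), 2), 2.04)
  expect_equal(round(b$p_two_sided, 2), 0.04)

  swapped <- compare_correlations(0.48, 20, 0.90, 20)
  expect_identical(swapped$z_statistic, -a$z_statistic)

  null <- compare_correlations(0.5, 20, 0.5, 20)
  expect_equal(null$z_statistic, 0)
  expect_equal(null$p_two_sided, 1)
})

test_that("one-sample t matches hand computations, the published statistic, and t.test", {
  # symmetric values about the null mean
  sym <- one_sample_t(c(-1, 0, 1), mu0 = 0)
  expect_equal(sym$t_statistic, 0)
  expect_equal(sym$p_two_sided, 1)

  expect_equal(one_sample_t(c(-0.2, -0.19, -0.18))$t_statistic, -32.90897,
               tolerance = 1e-6)

  # any series with mean -0.19 kb and sd 0.16826 kb at n = 20 gives t = -5.05
  set.seed(3)
  x <- as.numeric(scale(rnorm(20))) * 0.16826 - 0.19
  res <- one_sample_t(x)
  expect_equal(round(res$t_statistic, 2), -5.05)
  expect_lt(res$p_two_sided, 0.001)
  ref <- t.test(x, mu = 0)
  expect_equal(res$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_two_sided, ref$p.value, tolerance = 1e-12)
  expect_error(one_sample_t(1), "n >= 2")
})

test_that("one-way ICC: boundary cases and exact agreement with the ANOVA decomposition", {
  # identical replicates within subjects, subjects differ -> perfect reliability
  perfect <- icc_oneway(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(perfect$icc, 1)

  # pure noise, no subject effect
  set.seed(71)
  noise <- matrix(rnorm(10000 * 2), ncol = 2)
  expect_lt(abs(icc_oneway(noise)$icc), 0.02)

  # mean squares agree with stats::aov on a random balanced table
  tab <- matrix(rnorm(60, mean = rep(rnorm(20), each = 3)), ncol = 3,
                byrow = TRUE)
  long <- data.frame(y = as.vector(t(tab)),
                     subject = factor(rep(1:20, each = 3)))
  ms <- anova(aov(y ~ subject, data = long))
  mine <- icc_oneway(tab)
  expect_equal(mine$ms_between, ms["subject", "Mean Sq"], tolerance = 1e-10)
  expect_equal(mine$ms_within, ms["Residuals", "Mean Sq"], tolerance = 1e-10)

  expect_error(icc_oneway(cbind(c(1, NA), c(2, 3))), "unbalanced")
  expect_error(icc_oneway(cbind(1, 2)), ">= 2 subjects")
})

test_that("the dependent-correlation comparison is null at equality and signed correctly", {
  eq <- compare_correlations_dependent(0.5, 0.5, 0.3, 20)
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$p_two_sided, 1)
  gt <- compare_correlations_dependent(0.9, 0.48, 0.5, 20)
  expect_gt(gt$t_statistic, 0)
  expect_lt(gt$p_two_sided, 0.05)
})
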