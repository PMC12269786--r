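# The statistical battery, checked against hand computations and
# independent-formula oracles.

test_that("pearson correlation matches the hand-computed example", {
  r <- pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$estimate, 0.8)
  expect_equal(r$statistic, 0.8 * sqrt(2 / (1 - 0.64)), tolerance = 1e-6)
  expect_equal(r$df, 2)
  # perfect linearity
  expect_equal(pearson_cor(1:10, 1:10)$estimate, 1)
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6))$estimate, 1)
  expect_error(pearson_cor(rep(1, 5), 1:5), "variance")
})

test_that("two-sample lm equals the textbook pooled t", {
  r <- two_sample_lm(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(abs(r$statistic), 3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  # identical groups: t = 0, p = 1
  same <- two_sample_lm(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # df with the study's period sample sizes
  set.seed(5)
  r2 <- two_sample_lm(rnorm(74), rep(c("p1", "p2"), c(38, 36)))
  expect_equal(r2$df, 72)
  # oracle sweep on random instances
  for (i in 1:20) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    y1 <- rnorm(n1); y2 <- rnorm(n2, 0.5)
    got <- two_sample_lm(c(y1, y2), rep(c("a", "b"), c(n1, n2)))
    want <- pooled_t_oracle(y1, y2)
    expect_equal(got$statistic, want$t, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
  expect_error(two_sample_lm(1:3, c("a", "a", "b")), "n >= 2")
})

test_that("the Poisson GLM satisfies its score equations", {
  # constant response: intercept log(mean), zero group effect
  fit <- poisson_glm(rep(4L, 20), rep(c("a", "b"), 10))
  expect_equal(unname(coef(fit)[1]), log(4), tolerance = 1e-8)
  expect_equal(unname(coef(fit)[2]), 0, tolerance = 1e-8)
  # fitted group means equal sample means
  set.seed(6)
  y <- rpois(40, 5); g <- rep(c("a", "b"), each = 20)
  fit2 <- poisson_glm(y, g)
  expect_equal(unique(fitted(fit2)[g == "a"]), mean(y[g == "a"]), tolerance = 1e-8)
  # estimator consistency for a log-rate difference of 0.5
  set.seed(7)
  y3 <- rpois(400, rep(c(5, 5 * exp(0.5)), each = 200))
  fit3 <- poisson_glm(y3, rep(c("a", "b"), each = 200))
  expect_equal(unname(coef(fit3)[2]), 0.5, tolerance = 0.15)
  expect_error(poisson_glm(c(1, -2, 3), factor(c("a", "b", "a"))), "non-negative")
  expect_error(poisson_glm(c(1.5, 2), factor(c("a", "b"))), "integer")
})

test_that("the dispersion ratio is Pearson chi-square over residual df", {
  set.seed(8)
  y <- rpois(19, 4); g <- rep(c("a", "b"), c(8, 11))
  fit <- poisson_glm(y, g)
  od <- overdispersion_check(fit)
  chi2 <- sum(residuals(fit, "pearson")^2)
  expect_equal(od$statistic, chi2)
  expect_equal(od$df, 17)                 # 19 observations, 2 parameters
  expect_equal(od$estimate, chi2 / 17)
  expect_equal(od$p_value, pchisq(chi2, 17, lower.tail = FALSE))
  # equidispersed data: ratio near 1
  set.seed(9)
  fit_eq <- poisson_glm(rpois(100, 6), rep(c("a", "b"), 50))
  expect_equal(overdispersion_check(fit_eq)$estimate, 1, tolerance = 0.3)
  # variance four times the mean: ratio > 1, p < 0.05 at n = 200
  set.seed(10)
  y_od <- rnbinom(200, mu = 5, size = 5 / 3)
  fit_od <- poisson_glm(y_od, rep(c("a", "b"), 100))
  od2 <- overdispersion_check(fit_od)
  expect_gt(od2$estimate, 1)
  expect_lt(od2$p_value, 0.05)
})

test_that("the Type-II deviance test reduces to the LR test for one predictor", {
  set.seed(11)
  y <- rpois(30, 4); g <- rep(c("a", "b"), 15)
  fit <- poisson_glm(y, g)
  got <- type2_deviance_test(fit)
  null_fit <- glm(y ~ 1, family = poisson())
  want <- anova(null_fit, fit, test = "Chisq")
  expect_equal(got$statistic, want$Deviance[2], tolerance = 1e-10)
  expect_equal(got$df, want$Df[2])
  expect_equal(got$p_value, want$`Pr(>Chi)`[2], tolerance = 1e-10)
  # aliased (duplicated) predictors are rejected
  x <- rnorm(30)
  fit_dup <- suppressWarnings(glm(y ~ x + I(x * 1), family = poisson()))
  expect_error(type2_deviance_test(fit_dup), "rank")
})

test_that("Type-II deviance p-values are uniform under the null", {
  set.seed(12)
  p <- replicate(200, {
    y <- rpois(40, 5)
    type2_deviance_test(poisson_glm(y, rep(c("a", "b"), 20)))$p_value
  })
  # count data can tie; the KS p-value is still a valid calibration check
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("the permutation test is seeded, bounded and add-one corrected", {
  y <- c(1, 2, 3, 10, 11, 12); g <- rep(c("a", "b"), each = 3)
  r1 <- lm_permutation_test(y, factor(g), B = 1000, seed = 42)
  r2 <- lm_permutation_test(y, factor(g), B = 1000, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 1001)
  # a clean monotone relation beats every permutation: p = 1/(B+1)
  strong <- lm_permutation_test(1:20, 1:20 + 0, B = 1000, seed = 1)
  expect_equal(strong$p_value, 1 / 1001)
  # observed F agrees with lm
  f_lm <- summary(lm(y ~ g))$fstatistic[1]
  expect_equal(unname(r1$statistic), unname(f_lm), tolerance = 1e-10)
  expect_error(lm_permutation_test(y, g, B = 0), "at least 1")
  expect_error(lm_permutation_test(1:3, 1:3), "n >= 5")
})

test_that("Holm adjustment matches the step-down definition", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.2, 0.2, 0.2)), c(0.6, 0.6, 0.6))
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, holm_oracle(p))          # independent step-down loop
    expect_true(all(adj >= p))
    perm <- sample(length(p))
    expect_equal(holm_adjust(p[perm]), adj[perm])  # order invariance
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("pairwise contrasts flag only truly shifted groups after Holm", {
  # four behaviours give six pairwise cells
  set.seed(14)
  y <- rnorm(80, 1000, 100); g <- rep(c("w", "x", "y", "z"), each = 20)
  pm <- pairwise_behaviour_test(y, g)
  expect_equal(nrow(pm), 6L)
  expect_true(all(pm$p_adj >= pm$p))
  expect_equal(pm$F, pm$t^2, tolerance = 1e-10)
  # identical group values: p about 1 everywhere
  pm_same <- pairwise_behaviour_test(rep(rnorm(20), 4), rep(letters[1:4], each = 20))
  expect_true(all(pm_same$p_adj > 0.99))
  # one group shifted +300 m (sigma 100): its three pairs are significant
  # and dominate every null pair after Holm
  set.seed(15)
  y2 <- c(rnorm(20, 1300, 100), rnorm(20, 1000, 100),
          rnorm(20, 1000, 100), rnorm(20, 1000, 100))
  pm2 <- pairwise_behaviour_test(y2, rep(c("deep", "a", "b", "c"), each = 20))
  hit <- pm2$group1 == "deep" | pm2$group2 == "deep"
  expect_true(all(pm2$significant[hit]))
  expect_lt(max(pm2$p_adj[hit]), min(pm2$p_adj[!hit]))
  expect_warning(pairwise_behaviour_test(c(1, 2, 3, 4, 5), c("a", "a", "b", "b", "c")),
                 "n < 2")
})

test_that("the Shapiro-Wilk wrapper detects heavy tails and rejects bad input", {
  set.seed(16)
  sw <- normality_check(rnorm(100))
  expect_true(sw$statistic > 0 && sw$statistic <= 1)
  expect_gt(sw$p_value, 0.01)
  # power: t1-distributed samples are flagged (median p over 50 seeds)
  p_heavy <- replicate(50, normality_check(rt(100, df = 1))$p_value)
  expect_lt(median(p_heavy), 0.01)
  expect_error(normality_check(rep(1, 10)), "constant")
  expect_error(normality_check(rnorm(2)), "3 <= n")
})
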