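test_that("severity trend recovers a perfect monotone relation", {
  grade <- rep(0:3, each = 10)
  set.seed(1)
  tr <- suppressWarnings(severity_trend(-grade + 1e-9 * rnorm(40), grade))
  expect_lt(tr$t_statistic, -1e5)
  expect_lt(tr$p_value, 1e-30)
  expect_lt(tr$estimate, 0)
})

test_that("severity trend matches normal-equation OLS with covariates", {
  set.seed(41)
  n <- 50
  grade <- sample(0:3, n, replace = TRUE)
  age <- rnorm(n, 55, 8)
  sex <- rbinom(n, 1, 0.6)
  y <- 0.3 - 0.05 * grade + 0.01 * age + rnorm(n, 0, 0.1)
  tr <- severity_trend(y, grade, age, sex)
  x <- cbind(1, grade, age, sex)
  beta <- solve(t(x) %*% x, t(x) %*% y)
  resid <- y - x %*% beta
  sigma2 <- sum(resid^2) / (n - 4)
  se <- sqrt(sigma2 * solve(t(x) %*% x)[2, 2])
  expect_equal(tr$estimate, beta[2], tolerance = 1e-10)
  expect_equal(tr$t_statistic, beta[2] / se, tolerance = 1e-10)
  expect_equal(tr$df, n - 4)
})

test_that("severity trend is invariant to affine covariate rescaling", {
  set.seed(43)
  n <- 60
  grade <- sample(0:3, n, replace = TRUE)
  age <- rnorm(n, 55, 8)
  sex <- rbinom(n, 1, 0.5)
  y <- -0.04 * grade + 0.005 * age + rnorm(n, 0, 0.05)
  t1 <- severity_trend(y, grade, age, sex)$t_statistic
  t2 <- severity_trend(y, grade, (age - 50) / 10, 2 * sex - 1)$t_statistic
  expect_equal(t1, t2, tolerance = 1e-10)
})

test_that("trend p-values are uniform under the null", {
  set.seed(47)
  n <- 70
  grade <- rep(0:3, c(35, 17, 9, 9))
  p <- vapply(1:400, function(i)
    severity_trend(rnorm(n), grade)$p_value, numeric(1))
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("two-group ANOVA reduces to the squared t test", {
  set.seed(53)
  for (i in 1:5) {
    y <- rnorm(30)
    g <- factor(rep(c("a", "b"), 15))
    age <- rnorm(30, 50, 5)
    sex <- rbinom(30, 1, 0.5)
    an <- group_anova(y, g, age, sex)
    dat <- data.frame(y, g, age, sex)
    tt <- summary(lm(y ~ age + sex + g, dat))$coefficients["gb", 3]
    expect_equal(an$F_statistic, tt^2, tolerance = 1e-9)
  }
})

test_that("ANOVA type-I error is nominal and post hoc is Bonferroni-capped", {
  set.seed(59)
  group <- factor(rep(c("control", "noHE", "MHE", "OHE"), c(35, 17, 9, 9)),
                  levels = c("control", "noHE", "MHE", "OHE"))
  rej <- vapply(1:300, function(i)
    group_anova(rnorm(70), group)$p_value < 0.05, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
  an <- group_anova(rnorm(70), group)
  expect_equal(nrow(an$posthoc), 6)
  expect_true(all(an$posthoc$p_bonferroni <= 1))
  expect_equal(an$posthoc$p_bonferroni,
               pmin(1, an$posthoc$p_raw * 6))
  expect_equal(an$df, c(3, 66))
})

test_that("a strongly shifted group is detected with high power", {
  set.seed(61)
  group <- factor(rep(c("a", "b", "c", "d"), each = 9))
  hits <- vapply(1:50, function(i) {
    y <- rnorm(36)
    y[group == "d"] <- y[group == "d"] + 3
    group_anova(y, group)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("ammonia association recovers linear relations", {
  am <- seq(80, 250, length.out = 20)
  eff <- 0.5 - 0.001 * am
  res <- suppressWarnings(ammonia_association(eff, am))
  expect_equal(res$r_squared, 1)
  expect_lt(res$slope, 0)
  # NA ammonia (controls) dropped
  res2 <- suppressWarnings(ammonia_association(c(eff, 0.4), c(am, NA)))
  expect_equal(res2$n, 20L)
  expect_error(ammonia_association(rnorm(5), rep(100, 5)), "constant")
})

test_that("null R-squared has mean about 1/(n-1)", {
  set.seed(67)
  n <- 25
  r2 <- vapply(1:1000, function(i)
    ammonia_association(rnorm(n), rlnorm(n, 4.7, 0.4))$r_squared,
    numeric(1))
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 0.012)
})

test_that("regional trend table flags the disrupted regions", {
  set.seed(71)
  n <- 40
  grade <- rep(0:3, each = 10)
  nodal <- cbind(hit = 0.5 - 0.08 * grade + rnorm(n, 0, 0.05),
                 null1 = rnorm(n, 0.5, 0.05),
                 null2 = rnorm(n, 0.5, 0.05))
  tab <- regional_trend_table(nodal, grade, fdr = TRUE)
  expect_equal(tab$region[1], "hit")
  expect_lt(tab$t[1], 0)
  expect_lt(tab$p_fdr[1], 0.01)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})

test_that("degenerate stat inputs are refused", {
  expect_error(severity_trend(rnorm(3), c(0, 1, 2)), "at least 5")
  expect_error(severity_trend(rnorm(10), rep(1, 10)), "2 levels")
  expect_error(group_anova(rnorm(4), factor(c("a", "a", "a", "b"))),
               "at least 2 subjects")
})
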