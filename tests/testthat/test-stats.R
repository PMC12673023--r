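# Statistics stage: ANOVA, gate, Tukey, regression, Pearson, chi-square.

toy_groups <- function() {
  tibble::tibble(value = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                 group = rep(c("a", "b", "c"), each = 3))
}

test_that("one-way ANOVA matches a brute-force sums-of-squares oracle", {
  df <- toy_groups()
  res <- anova_oneway(df, value, group)
  # independent oracle: explicit between/within sums of squares
  gm <- mean(df$value)
  ms <- tapply(df$value, df$group, mean)
  ns <- tapply(df$value, df$group, length)
  ssb <- sum(ns * (ms - gm)^2)
  ssw <- sum((df$value - ms[df$group])^2)
  Fo <- (ssb / 2) / (ssw / 6)
  expect_equal(res$statistic, Fo, tolerance = 1e-10)
  expect_equal(res$p_value, pf(Fo, 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
})

test_that("identical groups give F = 0 and p = 1", {
  df <- tibble::tibble(value = rep(c(1, 2, 3), 3),
                       group = rep(c("a", "b", "c"), each = 3))
  res <- anova_oneway(df, value, group)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_error(anova_oneway(df[1:3, ], value, group), "2 groups")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(5)
  df <- tibble::tibble(value = c(rnorm(8), rnorm(9, 1)),
                       group = rep(c("a", "b"), c(8, 9)))
  res <- anova_oneway(df, value, group)
  tt <- t.test(value ~ group, data = df, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("the significance gate uses a strict threshold", {
  expect_identical(bonferroni_gate(c(0.0049, 0.005, 0.1, 1)),
                   c(TRUE, FALSE, FALSE, FALSE))
  expect_false(any(bonferroni_gate(rep(1, 5))))
  expect_error(bonferroni_gate(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("Tukey HSD agrees with the pooled t-test for two groups", {
  set.seed(9)
  df <- tibble::tibble(value = c(rnorm(10), rnorm(12, 0.8)),
                       group = rep(c("a", "b"), c(10, 12)))
  tk <- tukey_hsd(df, value, group)
  tt <- t.test(value ~ group, data = df, var.equal = TRUE)
  expect_equal(tk$p_value, tt$p.value, tolerance = 1e-8)

  same <- tibble::tibble(value = rep(c(1, 2, 3, 4), 3),
                         group = rep(c("a", "b", "c"), each = 4))
  tks <- tukey_hsd(same, value, group)
  expect_true(all(abs(tks$p_value - 1) < 1e-9))
  expect_equal(nrow(tks), 3)
})

test_that("Tukey pairwise p-values are not smaller than unadjusted t-tests", {
  set.seed(13)
  df <- tibble::tibble(value = c(rnorm(9), rnorm(9, 0.7), rnorm(9, 1.2)),
                       group = rep(c("a", "b", "c"), each = 9))
  tk <- tukey_hsd(df, value, group)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    sub <- df[df$group %in% pair, ]
    p_t <- t.test(value ~ group, data = sub, var.equal = TRUE)$p.value
    p_tk <- tk$p_value[tk$contrast == paste(pair[2], pair[1], sep = "-")]
    expect_gte(p_tk + 1e-12, p_t * 0.999)
  }
})

test_that("Pearson correlation matches the closed form", {
  df <- tibble::tibble(x = c(1, 2, 4, 7, 8), y = 3 * c(1, 2, 4, 7, 8) + 1)
  expect_equal(pearson_cor(df, x, y)$estimate, 1, tolerance = 1e-12)
  df$y2 <- -df$x
  expect_equal(pearson_cor(df, x, y2)$estimate, -1, tolerance = 1e-12)
  set.seed(3)
  df2 <- tibble::tibble(x = rnorm(20), y = rnorm(20))
  res <- pearson_cor(df2, x, y)
  r <- sum((df2$x - mean(df2$x)) * (df2$y - mean(df2$y))) /
    sqrt(sum((df2$x - mean(df2$x))^2) * sum((df2$y - mean(df2$y))^2))
  tstat <- r * sqrt(18 / (1 - r^2))
  expect_equal(res$estimate, r, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 18), tolerance = 1e-10)
  expect_error(pearson_cor(df2[1:2, ], x, y), "n >= 3")
  df2$z <- 1
  expect_error(pearson_cor(df2, x, z), "variance")
})

test_that("Pearson estimate is unbiased at the calibrated correlation", {
  # sampling-distribution check near the strongest published association
  rho <- 0.81
  set.seed(17)
  rs <- replicate(1000, {
    z <- matrix(rnorm(2 * 47), ncol = 2)
    x <- z[, 1]
    y <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
    cor(x, y)
  })
  expect_lt(abs(mean(rs) - rho), 0.02)
})

test_that("regression recovers exact coefficients and matches lm algebra", {
  df <- tibble::tibble(x = seq(0, 10, by = 0.5))
  df$y <- 2 * df$x
  res <- suppressWarnings(regress(df, "y", "x"))
  expect_equal(res$univariate$estimate, 2, tolerance = 1e-10)
  expect_lt(res$univariate$p_value, 1e-12)
  expect_lt(res$multivariate$conf.high - res$multivariate$conf.low, 1e-8)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)

  # algebraic oracle: closed-form OLS slope on a noisy fit
  set.seed(21)
  df$y2 <- 1.5 * df$x + rnorm(nrow(df))
  r2 <- regress(df, "y2", "x")
  bhat <- cov(df$x, df$y2) / var(df$x)
  expect_equal(r2$univariate$estimate, bhat, tolerance = 1e-10)
})

test_that("collinear predictors are flagged and dropped by VIF", {
  set.seed(8)
  n <- 60
  df <- tibble::tibble(x1 = rnorm(n))
  df$x2 <- df$x1 + rnorm(n, sd = 0.01)   # r ~ 0.999
  df$x3 <- rnorm(n)
  df$y <- df$x1 + 0.5 * df$x3 + rnorm(n, sd = 0.5)
  res <- regress(df, "y", c("x1", "x2", "x3"))
  expect_gte(nrow(res$dropped), 1)
  expect_true(all(res$dropped$vif > 5))
  expect_true(all(res$multivariate$vif <= 5))
  expect_false(all(c("x1", "x2") %in% res$multivariate$term))
})

test_that("regression is scale-equivariant in its predictors", {
  set.seed(31)
  df <- tibble::tibble(x = rnorm(40), z = rnorm(40))
  df$y <- 0.8 * df$x - 0.4 * df$z + rnorm(40, sd = 0.3)
  r1 <- regress(df, "y", c("x", "z"))
  df2 <- dplyr::mutate(df, x = x * 10)
  r2 <- regress(df2, "y", c("x", "z"))
  b1 <- r1$univariate$estimate[r1$univariate$term == "x"]
  b2 <- r2$univariate$estimate[r2$univariate$term == "x"]
  expect_equal(b2, b1 / 10, tolerance = 1e-8)
})

test_that("regression demands complete cases and enough rows", {
  df <- tibble::tibble(x = c(1, 2, NA, 4, 5, 6), y = 1:6)
  expect_error(regress(df, "y", "x"), "complete cases")
  clean <- tibble::tibble(x = c(1, 2, 3), z = c(2, 1, 4), y = c(1, 5, 3))
  expect_error(regress(clean, "y", c("x", "z")), "n >")
  expect_error(regress(df, "y", "nope"), "not in data")
})

test_that("simulated regression CIs cover the generating coefficient", {
  # coverage of the 95% CI for the age effect used by the cohort generator
  beta_age <- -0.06
  beta_root <- -0.10
  set.seed(29)
  hits <- replicate(1000, {
    age <- runif(51, 19, 50)
    root <- rnorm(51, 43, 5)
    y <- 3.6 + beta_age * (age - mean(age)) + beta_root * (root - mean(root)) +
      rnorm(51, sd = 1.0)
    fit <- lm(y ~ age + root)
    ci <- confint(fit)["age", ]
    ci[1] <= beta_age && beta_age <= ci[2]
  })
  cover <- mean(hits)
  # binomial 99.7% band around 0.95 at 1000 reps
  expect_gt(cover, 0.95 - 3 * sqrt(0.95 * 0.05 / 1000))
  expect_lt(cover, 0.95 + 3 * sqrt(0.95 * 0.05 / 1000))
})

test_that("ANOVA + gate pipeline holds its type-I error on null data", {
  set.seed(41)
  reps <- 2000
  p <- replicate(reps, {
    df <- tibble::tibble(value = rnorm(30),
                         group = rep(c("a", "b", "c"), each = 10))
    anova_oneway(df, value, group)$p_value
  })
  alpha <- mean(bonferroni_gate(p, 0.05))
  expect_lt(abs(alpha - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("the gated ANOVA detects the calibrated group separation", {
  # power check: simulated AAo 3D distensibility cohorts at published group
  # means/SDs and sizes should clear the 0.005 gate essentially always
  set.seed(55)
  hit <- replicate(200, {
    df <- tibble::tibble(
      value = c(rnorm(47, 5.1, 1.4), rnorm(51, 3.6, 1.4), rnorm(33, 1.4, 0.7)),
      group = rep(c("h", "n", "r"), c(47, 51, 33)))
    anova_oneway(df, value, group)$p_value < 0.005
  })
  expect_gte(mean(hit), 0.99)
})

test_that("equal-mean groups rarely separate (matched-null check)", {
  # native-vs-RR descending distensibility was reported non-significant;
  # with equal generating means the pairwise test should usually agree
  set.seed(61)
  ps <- replicate(200, {
    df <- tibble::tibble(value = c(rnorm(51, 2.45, 0.95), rnorm(33, 2.45, 1.0)),
                         group = rep(c("n", "r"), c(51, 33)))
    tukey_hsd(df, value, group)$p_value
  })
  expect_gt(mean(ps > 0.05), 0.9)
})

test_that("chi-square helper matches stats::chisq.test without correction", {
  df <- tibble::tibble(flag = rep(c("yes", "no", "yes", "yes"), 10),
                       group = rep(c("a", "a", "b", "b"), 10))
  res <- chisq_categorical(df, flag, group)
  ref <- suppressWarnings(chisq.test(table(df$flag, df$group),
                                     correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("regression tidy/glance expose both model stages", {
  set.seed(2)
  df <- tibble::tibble(x = rnorm(50), z = rnorm(50))
  df$y <- 0.9 * df$x + rnorm(50, sd = 0.4)
  res <- regress(df, "y", c("x", "z"))
  td <- tidy(res)
  expect_setequal(unique(td$model), c("univariate", "multivariate"))
  gl <- glance(res)
  expect_equal(gl$n, 50)
  expect_gte(gl$n_promoted, 1)
})
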