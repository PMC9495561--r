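test_that("paired comparison matches hand computation", {
  pc <- paired_comparison(c(1, 2, 3), c(1, 3, 5))
  expect_equal(pc$mean_diff, -1)
  expect_equal(pc$t, -sqrt(3), tolerance = 1e-12)   # SD(diff) = 1, n = 3
  expect_equal(pc$df, 2)
  expect_equal(pc$p, 0.2254033, tolerance = 1e-6)
  expect_false(pc$degenerate)

  pc <- paired_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_true(pc$degenerate)
  expect_equal(pc$mean_diff, 0)
  expect_true(is.na(pc$p))

  expect_error(paired_comparison(1:4, 1:3), "paired")
})

test_that("paired d uses the mean-of-SDs denominator by default", {
  # summary-statistics check: girls' speed shift 0.11 with condition SDs
  # 0.42 / 0.54 gives 0.23 under mean-of-SDs (0.33 under SD-of-differences)
  expect_equal(round_half_up(cohens_d_paired(0.11, 0.42, 0.54)), 0.23)
  set.seed(5)
  x <- rnorm(40, 10, 2); y <- x - rnorm(40, 0.5, 0.4)
  pc_m <- paired_comparison(x, y)
  pc_s <- paired_comparison(x, y, d_denominator = "sd_diff")
  expect_equal(pc_m$cohens_d, mean(x - y) / ((sd(x) + sd(y)) / 2))
  expect_equal(pc_s$cohens_d, mean(x - y) / sd(x - y))
})

test_that("Hedges' g from summaries reproduces the between-sex effect", {
  expect_equal(round_half_up(hedges_g(46.97, 5.07, 63, 49.69, 6.19, 67)),
               0.48)
  expect_equal(hedges_g(10, 1, 20, 10, 1, 20), 0)
})

test_that("independent comparison: identical groups and known effect", {
  set.seed(8)
  a <- rnorm(30)
  ic <- independent_comparison(a, a)
  expect_equal(ic$t, 0)
  expect_equal(ic$hedges_g, 0)

  # unit-variance normals shifted by 1: g near 1
  a <- rnorm(1e4); b <- rnorm(1e4) + 1
  ic <- independent_comparison(a, b)
  expect_lt(abs(ic$hedges_g - 1), 0.05)
})

test_that("the variance gate switches between pooled and Welch", {
  set.seed(9)
  a <- rnorm(200, sd = 1); b <- rnorm(200, sd = 4)
  expect_identical(independent_comparison(a, b)$method, "welch")
  a <- rnorm(200); b <- rnorm(200)
  expect_identical(independent_comparison(a, b)$method, "pooled")
  # forced Welch has a non-integer Satterthwaite df
  ic <- independent_comparison(rnorm(50, sd = 2), rnorm(80),
                               variance = "welch")
  expect_false(isTRUE(all.equal(ic$df, round(ic$df))))
})

test_that("Hopkins bands use the printed half-open thresholds", {
  expect_identical(hopkins_band(0.2), "trivial")
  expect_identical(hopkins_band(0.21), "small")
  expect_identical(hopkins_band(0.48), "small")
  expect_identical(hopkins_band(0.6), "small")
  expect_identical(hopkins_band(1.2), "moderate")
  expect_identical(hopkins_band(2.0), "large")
  expect_identical(hopkins_band(4.0), "very large")
  expect_identical(hopkins_band(4.5), "nearly perfect")
  expect_identical(hopkins_band(-0.48), "small")   # magnitude
})

test_that("Bland-Altman handles identity, offset and LoA geometry", {
  x <- c(40, 45, 50, 55)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_lower, 0)
  expect_equal(ba$loa_upper, 0)
  expect_equal(ba$ba_slope, 0)

  ba <- bland_altman(x, x - 2)
  expect_equal(ba$bias, 2)
  expect_equal(ba$ba_slope, 0)

  set.seed(10)
  m <- rnorm(100, 48, 5); p <- m + rnorm(100, 1, 2)
  ba <- bland_altman(m, p, k = 1.96)
  expect_equal(ba$loa_upper - ba$loa_lower, 2 * 1.96 * sd(m - p))
  expect_true(ba$loa_lower <= ba$bias && ba$bias <= ba$loa_upper)
  # slope is translation invariant
  ba2 <- bland_altman(m + 100, p + 100)
  expect_equal(ba2$ba_slope, ba$ba_slope, tolerance = 1e-9)
  # k = 2.0 reproduces the "two standard deviations" convention
  ba3 <- bland_altman(m, p, k = 2)
  expect_equal(ba3$loa_upper - ba3$loa_lower, 4 * sd(m - p))
})

test_that("near-constant predictions drive the BA slope toward 2", {
  # when the prediction compresses nearly all the measured variance away,
  # d ~ measured - c and m ~ (measured + c)/2, so the slope of d on m
  # approaches 2: the regime behind large published proportional-bias
  # slopes for weakly-varying equations
  set.seed(12)
  meas <- rnorm(500, 48, 5.8)
  pred <- rnorm(500, 44, 0.5)          # tiny variance, independent
  ba <- bland_altman(meas, pred)
  expect_gt(ba$ba_slope, 1.6)
  expect_lt(ba$ba_slope, 2.1)
  # and it agrees with the OLS oracle
  d <- meas - pred; m <- (meas + pred) / 2
  expect_equal(ba$ba_slope, unname(coef(lm(d ~ m))[2]), tolerance = 1e-9)
})

test_that("validity statistics: identity, independence, known residual SD", {
  x <- c(40, 44, 48, 52)
  v <- validity_stats(x, x)
  expect_equal(v$r, 1)
  expect_equal(v$see, 0)

  set.seed(13)
  m <- rnorm(1e4); p <- rnorm(1e4)
  expect_lt(abs(validity_stats(m, p)$r), 0.03)

  x <- rnorm(1e4); y <- 2 * x + rnorm(1e4)
  expect_lt(abs(validity_stats(y, x)$see - 1), 0.05)

  expect_error(validity_stats(rep(1, 5), rnorm(5)), "variance")
})

test_that("t, r, OLS and SEE agree with the stats-package oracles", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    x <- rnorm(n, 10, 3)
    y <- 0.8 * x + rnorm(n, 0, 2)

    pc <- paired_comparison(x, y)
    tt <- t.test(x, y, paired = TRUE)
    expect_equal(pc$t, unname(tt$statistic), tolerance = 1e-9)
    expect_equal(pc$p, tt$p.value, tolerance = 1e-9)
    expect_equal(pc$ci, as.numeric(tt$conf.int), tolerance = 1e-9)

    ic <- independent_comparison(x, y, variance = "welch")
    tw <- t.test(x, y)
    expect_equal(ic$t, unname(tw$statistic), tolerance = 1e-9)
    expect_equal(ic$df, unname(tw$parameter), tolerance = 1e-9)
    expect_equal(ic$p, tw$p.value, tolerance = 1e-9)

    v <- validity_stats(y, x)
    expect_equal(v$r, cor(x, y), tolerance = 1e-9)
    fit <- lm(y ~ x)
    expect_equal(v$see, summary(fit)$sigma, tolerance = 1e-9)

    ba <- bland_altman(y, x)
    d <- y - x; m <- (y + x) / 2
    expect_equal(ba$ba_slope, unname(coef(lm(d ~ m))[2]), tolerance = 1e-9)
  }
})

test_that("assumption checks behave as diagnostics", {
  set.seed(15)
  x <- rnorm(1e4)
  ac <- assumption_checks(x)
  expect_gt(ac$ks_p, 0.01)
  expect_true(is.na(ac$levene_p))

  # Levene type-I error near nominal for equal-variance groups
  rej <- vapply(1:200, function(i) {
    g <- rep(1:2, each = 100)
    ac <- assumption_checks(rnorm(200), group = g)
    ac$levene_p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.12)

  expect_error(assumption_checks(rep(1, 10)), "constant")
  expect_error(assumption_checks(rnorm(4)), "n >= 5")
})

test_that("the adequacy verdict is strict p < alpha significance", {
  expect_identical(classify_equation(0.243), "adequate")
  expect_identical(classify_equation(0.049), "inadequate")
  expect_identical(classify_equation(0.05), "adequate")
  expect_true(is.na(classify_equation(NA_real_)))
})
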