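test_that("rmse matches hand-evaluated cases and its algebraic properties", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt((9 + 16) / 2))  # 3.5355...
  x <- c(1.2, -0.7, 3.3, 0.1); y <- c(0.4, 0.2, 2.9, -1)
  expect_equal(rmse(x, y), rmse(y, x))
  expect_equal(rmse(y + (x - y), y), rmse(y - (x - y), y))  # residual sign flip
  expect_gte(rmse(x, y), abs(mean(x - y)))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("static summaries reproduce published-style per-point aggregation", {
  u <- field_preset("ultimate")
  rep <- static_summary(c(0.20, 0.16, 0.11, 0.13), u)
  expect_equal(rep$mean, 0.15)
  expect_equal(rep$max, 0.20)
  expect_equal(rep$pct_of_length, 100 * 0.15 / 97.11)  # ~0.15 %
  expect_equal(rep$pct_of_width, 100 * 0.15 / 36.25)   # ~0.41 %
  expect_equal(round(rep$pct_of_length, 2), 0.15)
  expect_equal(round(rep$pct_of_width, 2), 0.41)
})

test_that("static validation is zero on a noiseless scene and flags unknown ids", {
  sc <- make_scene("ultimate", n_players = 1, duration = 1, pixel_noise_sd = 0)
  hs <- calibrate_frames(sc$scene$control_points, sc$field)
  recon <- reconstruct_control_points(sc$scene$control_points, hs,
                                      ids = c("v1", "v2", "v3", "v4"))
  rep <- static_validation(recon, sc$field)
  expect_lt(rep$mean, 1e-9)
  expect_lt(rep$max, 1e-9)
  expect_error(static_validation(data.frame(point_id = "zz", frame = 0, x = 1, y = 1),
                                 sc$field), "zz")
})

test_that("Bland-Altman bias and limits match closed forms", {
  a <- c(3, 5, 9)
  expect_equal(bland_altman(a, a)$bias, 0)
  expect_equal(bland_altman(a, a)$loa_low, 0)
  ba <- bland_altman(a, a + 5)
  expect_equal(ba$bias, -5)
  expect_equal(c(ba$loa_low, ba$loa_high), c(-5, -5))
  # differences {1, 3}: bias 2, loa 2 -/+ 1.96 * sqrt(2)
  ba2 <- bland_altman(c(2, 4), c(1, 1))
  expect_equal(ba2$bias, 2)
  expect_equal(ba2$loa_low, 2 - 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba2$loa_high, 2 + 1.96 * sqrt(2), tolerance = 1e-12)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("swapping systems negates the bias and mirrors the limits", {
  set.seed(8)
  a <- stats::rnorm(30, 100, 10); b <- a + stats::rnorm(30, 3, 4)
  ab <- bland_altman(a, b); ba <- bland_altman(b, a)
  expect_equal(ab$bias, -ba$bias)
  expect_equal(ab$loa_low, -ba$loa_high)
  expect_equal(ab$loa_high, -ba$loa_low)
})

test_that("ICC variants behave definitionally and classify by the usual cut-offs", {
  x <- c(380, 420, 455, 510, 610, 700)
  same <- icc(x, x, "consistency")
  expect_equal(same$icc, 1)
  expect_equal(same$class, "excellent")
  expect_equal(icc(x, x, "absolute")$icc, 1)
  shifted_c <- icc(x, x + 25, "consistency")
  shifted_a <- icc(x, x + 25, "absolute")
  expect_equal(shifted_c$icc, 1)
  expect_lt(shifted_a$icc, 1)
  expect_error(icc(rep(5, 6), rep(5, 6)), "between-subject")
  expect_error(icc(x[1:2], x[1:2]), "at least 3")
})

test_that("ICC consistency is never below absolute agreement under an offset", {
  for (seed in 1:10) {
    set.seed(seed)
    a <- stats::rnorm(12, 50, 8)
    b <- a + 4 + stats::rnorm(12, 0, 2)
    expect_gte(icc(a, b, "consistency")$icc, icc(a, b, "absolute")$icc)
  }
})

test_that("ICC matches an independent two-way ANOVA oracle", {
  a <- c(380.2, 421.7, 455.0, 515.3, 610.8, 701.4)
  b <- c(392.5, 410.1, 470.2, 500.9, 625.3, 718.8)
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  ms <- stats::anova(stats::aov(y ~ subj + rater, data = df))
  msr <- ms["subj", "Mean Sq"]; msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  k <- 2; n <- 6
  icc_c_oracle <- (msr - mse) / (msr + (k - 1) * mse)
  icc_a_oracle <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(icc(a, b, "consistency")$icc, icc_c_oracle, tolerance = 1e-9)
  expect_equal(icc(a, b, "absolute")$icc, icc_a_oracle, tolerance = 1e-9)
})

test_that("Pearson correlation is classified by the printed thresholds", {
  x <- c(1, 2, 3, 4, 5)
  perfect <- pearson_with_class(x, 2 * x + 1)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$class, "large")
  # brute-force covariance formula on a fixture
  y <- c(2.3, 1.9, 3.8, 3.1, 5.2)
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_with_class(x, y)$r, r_brute, tolerance = 1e-12)
  # class boundaries on constructed correlations
  expect_equal(pearson_with_class(c(1, 2, 3, 4), c(1, 4, 1, 2.2))$class, "small")
  expect_error(pearson_with_class(x, rep(1, 5)), "constant")
})

test_that("regression fit matches the closed-form OLS solution", {
  x <- c(1, 2, 4); y <- c(2.1, 3.9, 8.2)
  fit <- regression_fit(x, y)
  # closed form
  bx <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ax <- mean(y) - bx * mean(x)
  res <- y - (ax + bx * x)
  expect_equal(fit$slope, bx, tolerance = 1e-12)
  expect_equal(fit$intercept, ax, tolerance = 1e-12)
  expect_equal(fit$rmse, sqrt(mean(res^2)), tolerance = 1e-12)
  expect_equal(fit$rmse_pct, 100 * fit$rmse / mean(y))
  perfect <- regression_fit(1:5, 2 * (1:5) + 3)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0, tolerance = 1e-12)
  expect_error(regression_fit(rep(2, 4), 1:4), "constant")
})

test_that("coefficient of variation uses the sample sd", {
  expect_equal(cv_percent(c(2, 4)), 100 * sqrt(2) / 3, tolerance = 1e-12)
  expect_equal(cv_percent(rep(7, 5)), 0)
  expect_error(cv_percent(c(-1, 1)), "zero mean")
})

test_that("percentage absolute difference averages per-session ratios", {
  expect_equal(percent_abs_difference(c(100, 200), c(100, 200)), 0)
  expect_equal(percent_abs_difference(103, 100), 3)
  expect_equal(percent_abs_difference(c(110, 95), c(100, 100)), 7.5)
  expect_error(percent_abs_difference(1, 0), "nonzero")
})

test_that("the full agreement report is internally consistent", {
  set.seed(4)
  b <- stats::rnorm(20, 400, 80)
  a <- b * 1.02 + stats::rnorm(20, 0, 10)
  rep <- agreement_report(a, b, names = c("drone", "gps"))
  expect_true(rep$loa_low <= rep$bias && rep$bias <= rep$loa_high)
  expect_true(abs(rep$pearson_r) <= 1)
  expect_true(rep$icc_consistency <= 1 && rep$icc_absolute <= 1)
  expect_equal(rep$bias, mean(a - b))
  expect_equal(rep$pct_abs_difference, mean(100 * abs(a - b) / b))
})
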