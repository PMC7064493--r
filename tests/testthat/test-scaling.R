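test_that("exact lines are recovered exactly", {
  fit <- fit_power_law(c(1, 100, 10000), c(1, 10, 100))
  expect_equal(fit$b, 0.5, tolerance = 1e-12)
  expect_equal(fit$a, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_identical(fit$df, 1L)

  const <- fit_power_law(c(1, 10, 100, 1000), rep(7, 4))
  expect_equal(const$b, 0, tolerance = 1e-12)
  expect_equal(const$r_squared, 0)
})

test_that("invalid inputs are rejected with the offending record named", {
  expect_error(fit_power_law(c(1, -2, 3), c(1, 1, 1)), "record 2")
  expect_error(fit_power_law(c(1, 2, 3), c(1, 0, 1)), "record 2")
  expect_error(fit_power_law(1:2, 1:2), "at least 3")
})

test_that("fit is permutation invariant and slope is unit-free", {
  rec <- generate_records(n = 30, seed = 11)
  f1 <- fit_power_law(rec$area_km2, rec$duration_yr)
  perm <- sample(nrow(rec))
  f2 <- fit_power_law(rec$area_km2[perm], rec$duration_yr[perm])
  expect_equal(f1$b, f2$b, tolerance = 1e-12)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  # rescaling areas (m^2 instead of km^2) changes only the intercept
  f3 <- fit_power_law(rec$area_km2 * 1e6, rec$duration_yr)
  expect_equal(f3$b, f1$b, tolerance = 1e-10)
  expect_equal(f3$a, f1$a - f1$b * 6, tolerance = 1e-10)
})

test_that("classification flags follow their definitions", {
  rec <- generate_records(n = 42, seed = 5)
  fit <- fit_power_law(rec$area_km2, rec$duration_yr)
  fl <- classify_fit(fit, alpha = 0.001)
  expect_identical(unname(fl["positive"]), fit$b > 0)
  expect_identical(unname(fl["sublinear"]), fit$b < 1)
  expect_identical(unname(fl["significant"]), fit$p_slope < 0.001)
})

test_that("prediction back-transforms the t-interval on the log scale", {
  # flat law: 10 years everywhere, at any size
  flat <- power_law_records(n = 8, slope = 0, intercept = 1)
  fit <- fit_power_law(flat$area_km2, flat$duration_yr)
  pr <- predict_duration(fit, size = c(1, 1e6))
  expect_equal(pr$fit, c(10, 10), tolerance = 1e-8)

  rec <- generate_records(n = 42, seed = 9)
  fit <- fit_power_law(rec$area_km2, rec$duration_yr)
  pr <- predict_duration(fit, 5.5e6, interval = "prediction")
  pc <- predict_duration(fit, 5.5e6, interval = "confidence")
  expect_true(pr$lwr < pc$lwr && pc$upr < pr$upr)
  # oracle: hand-computed t-based prediction interval on log10 scale
  x <- log10(rec$area_km2); y <- log10(rec$duration_yr)
  n <- length(x); bx <- cov(x, y) / var(x); ax <- mean(y) - bx * mean(x)
  res <- y - ax - bx * x
  s <- sqrt(sum(res^2) / (n - 2))
  x0 <- log10(5.5e6)
  sepred <- s * sqrt(1 + 1 / n + (x0 - mean(x))^2 / ((n - 1) * var(x)))
  tq <- qt(0.975, n - 2)
  expect_equal(pr$fit, 10^(ax + bx * x0), tolerance = 1e-8)
  expect_equal(pr$lwr, 10^(ax + bx * x0 - tq * sepred), tolerance = 1e-8)
  expect_equal(pr$upr, 10^(ax + bx * x0 + tq * sepred), tolerance = 1e-8)
})

test_that("jackknife refits omit exactly one record each", {
  rec <- generate_records(n = 12, seed = 21)
  jk <- jackknife_fits(rec)
  expect_identical(nrow(jk), 12L)
  expect_true(all(jk$df == 12L - 3L))
  expect_identical(jk$omitted, rec$name)
  # omitting a point that lies exactly on the fitted line leaves b alone
  sub <- fit_power_law(rec$area_km2[-1], rec$duration_yr[-1])
  on_line <- rec
  on_line$area_km2[1] <- 1000
  on_line$duration_yr[1] <- 10^(sub$a + sub$b * 3)
  jk2 <- jackknife_fits(on_line)
  full <- fit_power_law(on_line$area_km2, on_line$duration_yr)
  expect_equal(jk2$slope[1], full$b, tolerance = 1e-10)
  expect_equal(full$b, sub$b, tolerance = 1e-10)
})

test_that("monte carlo perturbs durations only, reproducibly", {
  rec <- generate_records(n = 20, seed = 31)
  # degenerate error range: every replicate equals the base fit
  mc1 <- monte_carlo_fits(rec, n_sims = 25, error_low = 1, error_high = 1,
                          seed = 1)
  base <- fit_power_law(rec$area_km2, rec$duration_yr)
  expect_identical(nrow(mc1), 25L)
  expect_true(all(abs(mc1$slope - base$b) < 1e-12))
  # seeded reproducibility
  mc2 <- monte_carlo_fits(rec, n_sims = 40, seed = 99)
  mc3 <- monte_carlo_fits(rec, n_sims = 40, seed = 99)
  expect_equal(mc2, mc3)
  expect_error(monte_carlo_fits(rec, n_sims = 10, error_low = 0),
               "error_low")
})

test_that("covariates enter additively and are reported", {
  rec <- generate_records(n = 40, seed = 41, residual_sd = 0)
  covar <- data.frame(regrowth = runif(40, 1, 100))
  y <- rec$duration_yr * 10^(0.002 * covar$regrowth)
  fit <- fit_power_law(rec$area_km2, y, covariates = covar)
  expect_equal(unname(fit$covariates["regrowth"]), 0.002, tolerance = 1e-8)
  expect_equal(fit$b, attr(rec, "truth")$slope, tolerance = 1e-8)
  expect_identical(fit$df, 40L - 3L)
})
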