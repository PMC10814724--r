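test_that("degenerate baselines are rejected with actionable errors", {
  base <- tibble::tibble(day = 0L, sqrt_bsa_cm = rep(8.5, 5),
                         coronary_inner_d_mm = rep(0.2, 5))
  expect_error(fit_normative(base, "coronary_inner_d_mm", mode = "mean_sd"),
               "constant")
  expect_error(fit_normative(base, "coronary_inner_d_mm"), "mean_sd")
  base2 <- base[1:2, ]
  expect_error(fit_normative(base2, "coronary_inner_d_mm"), ">= 3")
  base3 <- base
  base3$day <- 7L
  expect_error(fit_normative(base3, "coronary_inner_d_mm"), "day-0")
})

test_that("regression mode recovers the generating slope and residual SD", {
  norms <- default_norms()
  norms$sd[norms$measurement == "coronary_inner_d_mm"] <- 0.02
  cfg <- baseline_config(
    40000, seed = 11,
    weight_mean_g = 25, weight_sd_g = 5, weight_noise_sd_g = 0,
    norms = norms,
    slope_per_sqrt_bsa = c(coronary_inner_d_mm = 0.004)
  )
  d <- derive_measures(generate_cohort(cfg))
  m <- fit_normative(d, "coronary_inner_d_mm", mode = "regression")
  expect_lt(abs(m$slope - 0.004), 0.0005)
  expect_lt(abs(m$residual_sd - 0.02), 0.002)
  expect_equal(m$dof, m$n - 2L)
})

test_that("mean_sd mode on an n = 18 baseline recovers the printed norms", {
  d <- derive_measures(generate_cohort(baseline_config(18, seed = 14)))
  m <- fit_normative(d, "coronary_inner_d_mm", mode = "mean_sd")
  expect_lt(abs(m$intercept - 0.217), 0.020) # 3 sigma of the mean at n = 18
  expect_lt(abs(m$residual_sd - 0.028), 0.015)
  expect_equal(m$slope, 0)
  expect_equal(m$dof, 17L)
})

test_that("Z-scores follow (observed - predicted) / residual SD exactly", {
  m <- normative_model("coronary_inner_d_mm", intercept = 0.217, slope = 0,
                       residual_sd = 0.028, n = 18, mode = "mean_sd")
  expect_equal(z_score(m, 0.217), 0)
  expect_equal(z_score(m, 0.273), 2.0)
  z3 <- z_score(m, 0.301)
  expect_equal(z3, 3.0)
  expect_false(classify_cal(z3))      # strict inequality at the cutoff
  expect_true(classify_cal(3.0001))
  expect_false(classify_cal(-5))
  expect_true(is.na(z_score(m, NA_real_)))
  # sloped model needs the body-size regressor
  ms <- normative_model("coronary_inner_d_mm", 0.12, 0.012, 0.025, 38)
  expect_error(z_score(ms, 0.25), "sqrt_bsa")
  expect_equal(z_score(ms, 0.12 + 0.012 * 8.5, 8.5), 0)
  # z strictly increasing in the observation
  expect_true(all(diff(z_score(ms, seq(0.2, 0.3, 0.01), 8.5)) > 0))
})

test_that("percent_above counts strict exceedances over non-missing scores", {
  expect_equal(percent_above(rep(0, 10)), 0)
  expect_equal(percent_above(c(2, 4, 4, 4)), 75)
  expect_equal(percent_above(rep(10, 4)), 100)
  expect_equal(percent_above(c(3, 3, 4)), 100 / 3) # 3.0 itself is normal
  expect_equal(percent_above(c(NA, 5, NA, 1)), 50)
  expect_error(percent_above(c(NA_real_, NA_real_)), "missing")
})

test_that("training-set residuals obey the OLS closed forms", {
  d <- derive_measures(generate_cohort(kdz_config(seed = 17)))
  base <- d[d$day == 0, ]
  m <- fit_normative(base, "coronary_inner_d_mm", mode = "regression")
  z <- z_score(m, base$coronary_inner_d_mm, base$sqrt_bsa_cm)
  expect_lt(abs(sum(z)), 1e-9)
  n <- m$n
  expect_lt(abs(sd(z) - sqrt((n - 2) / (n - 1))), 1e-9)
})

test_that("Z-scores are invariant under a common rescaling of units", {
  d <- derive_measures(generate_cohort(kdz_config(seed = 19)))
  base <- d[d$day == 0, ]
  m <- fit_normative(base, "coronary_inner_d_mm", mode = "regression")
  z <- z_score(m, d$coronary_inner_d_mm, d$sqrt_bsa_cm)
  k <- 3.7
  mk <- normative_model(m$measurement, k * m$intercept, k * m$slope,
                        k * m$residual_sd, m$n, m$mode)
  zk <- z_score(mk, k * d$coronary_inner_d_mm, d$sqrt_bsa_cm)
  expect_equal(zk, z, tolerance = 1e-12)
})

test_that("OLS fit matches a brute-force normal-equations solution", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    x <- rnorm(n, 8.5, 1)
    y <- 0.1 + 0.015 * x + rnorm(n, 0, 0.03)
    base <- tibble::tibble(day = 0L, sqrt_bsa_cm = x, m = y)
    fit <- fit_normative(base, "m", mode = "regression")
    X <- cbind(1, x)
    beta <- solve(crossprod(X), crossprod(X, y))
    expect_lt(abs(fit$intercept - beta[1]), 1e-10)
    expect_lt(abs(fit$slope - beta[2]), 1e-10)
    sse <- sum((y - X %*% beta)^2)
    expect_lt(abs(fit$residual_sd - sqrt(sse / (n - 2))), 1e-10)
  }
})

test_that("normative models round-trip through JSON bit-exactly", {
  d <- derive_measures(generate_cohort(kdz_config(seed = 29)))
  m <- fit_normative(d[d$day == 0, ], "coronary_inner_d_mm")
  f <- withr::local_tempfile(fileext = ".json")
  write_normative_model(m, f)
  expect_identical(read_normative_model(f), m)
})

test_that("score_cohort appends Z and CAL columns, missing stays missing", {
  cfg <- kdz_config(seed = 31, missingness = 0.1)
  d <- derive_measures(generate_cohort(cfg))
  m <- fit_normative(d[d$day == 0, ], "coronary_inner_d_mm")
  s <- score_cohort(d, m)
  expect_true(all(c("z_coronary_inner_d_mm", "cal_coronary_inner_d_mm")
                  %in% names(s)))
  miss <- is.na(s$coronary_inner_d_mm)
  expect_true(all(is.na(s$z_coronary_inner_d_mm[miss])))
  expect_true(any(miss))
  expect_equal(s$cal_coronary_inner_d_mm[!miss],
               s$z_coronary_inner_d_mm[!miss] > 3)
})
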