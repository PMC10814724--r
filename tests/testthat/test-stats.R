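test_that("group x day summaries report n, mean and SEM per cell", {
  recs <- records_of(list("control@0" = c(1, 2, 3), "high@0" = 5))
  s <- summarize_cohort(recs, "m")
  ctl <- s[s$group == "control", ]
  expect_equal(ctl$n, 3)
  expect_equal(ctl$mean, 2)
  expect_lt(abs(ctl$sem - 0.577), 0.001)
  single <- s[s$group == "high", ]
  expect_equal(single$n, 1)
  expect_true(is.na(single$sem)) # SEM undefined for one value
  # absent cells are absent, not zero
  expect_equal(nrow(s), 2)
})

test_that("zero-noise control cells summarize to the configured norm exactly", {
  norms0 <- default_norms()
  norms0$sd <- 0
  cfg <- kdz_config(norms = norms0, weight_sd_g = 0, weight_noise_sd_g = 0,
                    effects = no_effects(),
                    noise_overrides = default_noise_overrides()[0, ], seed = 2)
  s <- summarize_cohort(generate_cohort(cfg), "coronary_inner_d_mm")
  expect_true(all(s$mean == 0.217))
})

test_that("pooled Student's t matches hand-computed and textbook values", {
  recs <- records_of(list("a@7" = c(1, 2, 3), "b@7" = c(1, 2, 3)))
  same <- two_sample_t(recs, "a", "b", "m", 7)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  recs <- records_of(list("a@7" = c(1, 2, 3), "b@7" = c(4, 5, 6)))
  tt <- two_sample_t(recs, "a", "b", "m", 7)
  expect_lt(abs(tt$t - (-3.674)), 0.001) # pooled sd = 1, se = sqrt(2/3)
  expect_lt(abs(tt$p - 0.0213), 0.001)
  expect_equal(tt$df, 4)
  expect_true(tt$significant)

  expect_error(two_sample_t(records_of(list("a@7" = 1, "b@7" = c(1, 2))),
                            "a", "b", "m", 7), ">= 2")
})

test_that("pooled t equals the textbook formula on random small samples", {
  set.seed(37)
  tried <- 0
  while (tried < 200) {
    a <- sample(0:9, sample(2:8, 1), replace = TRUE)
    b <- sample(0:9, sample(2:8, 1), replace = TRUE)
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    if (sp2 == 0) next
    tried <- tried + 1
    recs <- records_of(list("a@0" = a, "b@0" = b))
    got <- two_sample_t(recs, "a", "b", "m", 0)
    t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    expect_lt(abs(got$t - t_ref), 1e-10)
    expect_equal(got$df, na + nb - 2)
    expect_lt(abs(got$p - 2 * pt(-abs(t_ref), na + nb - 2)), 1e-10)
  }
})

test_that("the Welch option relaxes the equal-variance assumption", {
  recs <- records_of(list("a@0" = c(1, 2, 3, 4), "b@0" = c(10, 30, 50, 90)))
  pooled <- two_sample_t(recs, "a", "b", "m", 0)
  welch <- two_sample_t(recs, "a", "b", "m", 0, welch = TRUE)
  expect_equal(pooled$df, 6)
  expect_lt(welch$df, 6)
})

test_that("Pearson correlation matches the product-moment closed form", {
  lin <- records_of(list("a@0" = 1:6))
  lin$y <- lin$m
  expect_equal(pearson_corr(lin, "m", "y", 0)$r, 1)
  lin$y <- -2 * lin$m + 5
  expect_equal(pearson_corr(lin, "m", "y", 0)$r, -1)

  recs <- records_of(list("a@0" = c(1, 2, 3, 4, 5)))
  recs$y <- c(2, 1, 4, 3, 6)
  got <- pearson_corr(recs, "m", "y", 0)
  r_ref <- 10 / sqrt(10 * 14.8) # sums of centred products by hand
  t_ref <- r_ref * sqrt(3) / sqrt(1 - r_ref^2)
  expect_lt(abs(got$r - r_ref), 1e-12)
  expect_lt(abs(got$p - 2 * pt(-t_ref, 3)), 1e-12)
  expect_equal(got$n, 5)

  const <- recs
  const$y <- 1
  expect_error(pearson_corr(const, "m", "y", 0), "zero variance")
  expect_error(pearson_corr(recs[1:2, ], "m", "y", 0), ">= 3")
})

test_that("Pearson r is affine-invariant up to the sign of the scaling", {
  set.seed(41)
  recs <- records_of(list("a@0" = rnorm(30)))
  recs$y <- 0.5 * recs$m + rnorm(30)
  r0 <- pearson_corr(recs, "m", "y", 0)$r
  shifted <- recs
  shifted$m <- 4.2 * recs$m - 17
  expect_equal(pearson_corr(shifted, "m", "y", 0)$r, r0, tolerance = 1e-12)
  flipped <- recs
  flipped$y <- -0.1 * recs$y + 3
  expect_equal(pearson_corr(flipped, "m", "y", 0)$r, -r0, tolerance = 1e-12)
})

test_that("null group comparisons give uniform p-values", {
  cfg0 <- kdz_config(days = 0L, groups = c(control = 0, low = 1),
                     n_per_group_per_day = 30, n_baseline = 60,
                     effects = no_effects())
  p <- vapply(1:300, function(s) {
    cfg <- cfg0
    cfg$seed <- 5000L + s
    co <- generate_cohort(cfg)
    two_sample_t(co, "control", "low", "coronary_inner_d_mm", 0)$p
  }, numeric(1))
  expect_gt(ks.test(p, punif)$p.value, 0.01)
})

test_that("default effects give a dose-monotone response at late days", {
  cfg <- kdz_config(n_per_group_per_day = 20, n_baseline = 80, seed = 43)
  co <- generate_cohort(cfg)
  dr <- dose_response_table(co, "coronary_inner_d_mm")
  mono <- dr$monotonicity
  expect_true(mono$non_decreasing[mono$day == 21])
  expect_true(mono$non_decreasing[mono$day == 28])
  ordered_means <- dr$summaries$mean[dr$summaries$day == 28]
  expect_true(all(diff(ordered_means) > 0))
})

test_that("a single dose group is vacuously monotone", {
  co <- generate_cohort(baseline_config(10, seed = 3))
  dr <- dose_response_table(co, "coronary_inner_d_mm")
  expect_true(all(dr$monotonicity$non_decreasing))
  expect_equal(dr$monotonicity$n_groups, 1)
})

test_that("with no effects the two-group monotonicity flag is a coin flip", {
  cfg0 <- kdz_config(days = 0L, groups = c(control = 0, low = 1),
                     n_per_group_per_day = 10, n_baseline = 20,
                     effects = no_effects())
  flags <- vapply(1:100, function(s) {
    cfg <- cfg0
    cfg$seed <- 7000L + s
    dr <- dose_response_table(generate_cohort(cfg), "coronary_inner_d_mm",
                              group_order = c("control", "low"))
    dr$monotonicity$non_decreasing[1]
  }, logical(1))
  expect_gt(sum(flags), 35)
  expect_lt(sum(flags), 65)
})

test_that("summaries join the percent of Z above cutoff when scored", {
  d <- derive_measures(generate_cohort(kdz_config(seed = 47)))
  m <- fit_normative(d[d$day == 0, ], "coronary_inner_d_mm")
  s <- score_cohort(d, m)
  summ <- summarize_cohort(s, "coronary_inner_d_mm")
  expect_true("percent_z_gt_cutoff" %in% names(summ))
  expect_true(all(summ$percent_z_gt_cutoff >= 0 &
                    summ$percent_z_gt_cutoff <= 100))
  # high dose at day 28 sits far above control
  high28 <- summ$percent_z_gt_cutoff[summ$group == "high" & summ$day == 28]
  ctl28 <- summ$percent_z_gt_cutoff[summ$group == "control" & summ$day == 28]
  expect_gt(high28, ctl28)
})
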