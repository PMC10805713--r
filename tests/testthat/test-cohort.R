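test_that("cohort generation is deterministic given a seed", {
  a <- simulate_cohort(cohort_config(), seed = 7)
  b <- simulate_cohort(cohort_config(), seed = 7)
  expect_identical(a, b)
  expect_identical(cohort_truth(a), cohort_truth(b))
})

test_that("noise-free degenerate cohort follows the exact line", {
  co <- simulate_cohort(noise_free_config(), seed = 3)
  ctrl <- dplyr::filter(co, group == "control")
  expect_equal(ctrl$pfgcipl, 94.6 - 0.29 * ctrl$visit_time, tolerance = 1e-12)
  pd <- dplyr::filter(co, group == "PD")
  expect_equal(pd$pfgcipl, 93.0 - 0.58 * pd$visit_time, tolerance = 1e-12)
})

test_that("visit schedules are valid and match the design fractions", {
  cfg <- cohort_config(n_control = 1000, n_pd = 1000)
  co <- simulate_cohort(cfg, seed = 21)
  by_subj <- split(co$visit_time, co$subject_id)
  expect_true(all(vapply(by_subj, function(t) t[1] == 0, logical(1))))
  expect_true(all(vapply(by_subj, function(t) {
    length(t) == 1 || all(diff(t) > 0)
  }, logical(1))))
  # baseline-only fraction within 3 binomial SEs of the configured 0.32
  frac <- mean(lengths(by_subj) == 1)
  se <- sqrt(0.32 * 0.68 / 2000)
  expect_lt(abs(frac - 0.32), 3 * se)
  # followed subjects have 2-3 visits spanning 1-5 years
  nv <- lengths(by_subj)[lengths(by_subj) > 1]
  expect_true(all(nv %in% 2:3))
  tmax <- vapply(by_subj, max, 0)
  expect_true(all(tmax[lengths(by_subj) > 1] <= 5.6))
})

test_that("negative intercept-slope correlation shows in simulated subjects", {
  cfg <- cohort_config(n_control = 300, n_pd = 300,
                       true_slope = list(control = -0.29, pd = -0.58),
                       intercept_slope_corr = -0.5, slope_sd = 0.3)
  tr <- cohort_truth(simulate_cohort(cfg, seed = 13))
  expect_lt(cor(tr$intercept_true, tr$slope_true), 0)
})

test_that("per-subject OLS slopes recover the configured true slopes", {
  cfg <- cohort_config(n_control = 1000, n_pd = 1000)
  co <- simulate_cohort(cfg, seed = 17)
  tr <- cohort_truth(co)
  ols <- co |>
    dplyr::group_by(subject_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(slope_hat = {
      tt <- visit_time - mean(visit_time)
      sum(tt * pfgcipl) / sum(tt^2)
    })
  truth <- tr$slope_true[match(ols$subject_id, tr$subject_id)]
  err <- ols$slope_hat - truth
  mc_se <- sd(err) / sqrt(length(err))
  expect_lt(abs(mean(err)), 3 * mc_se)
})

test_that("true subgroup membership reflects the analytic control quartile", {
  cfg <- cohort_config(n_control = 2000, n_pd = 0)
  tr <- cohort_truth(simulate_cohort(cfg, seed = 19))
  # control latent baselines fall below the analytic reference quartile
  # about as often as the percentile dictates (noise in the reference
  # measurement makes this approximate)
  frac_low <- mean(tr$subgroup_true == "low")
  expect_lt(abs(frac_low - 0.25), 0.04)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(p_baseline_only = 1.4), "p_baseline_only")
  expect_error(cohort_config(intercept_slope_corr = -2), "corr")
  expect_error(cohort_config(residual_sd = -1), "SDs")
  expect_error(cohort_config(visit_templates = list(c(0, 2, 1))),
               "increasing")
  expect_error(simulate_cohort(cohort_config(n_control = 0, n_pd = 0)),
               "Empty cohort")
})

test_that("the reference population matches its analytic quartile", {
  cfg <- cohort_config()
  q_analytic <- reference_quartile(cfg)
  big <- simulate_reference(2e5, cfg, seed = 23)
  expect_equal(unname(quantile(big$pfgcipl, 0.25)), q_analytic,
               tolerance = 0.1 / q_analytic)
})

test_that("cohort CSV and ground-truth sidecar round-trip", {
  co <- simulate_cohort(cohort_config(n_control = 10, n_pd = 10), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".truth.json")))
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(co))
  expect_equal(back$pfgcipl, co$pfgcipl, tolerance = 1e-12)
})
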