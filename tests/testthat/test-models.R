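test_that("with zero random-effect variance the fit degenerates to OLS", {
  # deterministic linear data, common line across subjects
  d <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:20),
                          visit_time = c(0, 1, 2))
  set.seed(51)
  d$y <- 5 - 0.29 * d$visit_time
  fit <- fit_lmm(d, "y", fixed = "visit_time")
  beta <- tidy(fit)$estimate[tidy(fit)$term == "visit_time"]
  expect_equal(beta, -0.29, tolerance = 1e-9)
  # noisy common-line data: fixed effects equal the closed-form OLS slope
  d$y <- 5 - 0.29 * d$visit_time + rnorm(nrow(d), 0, 0.4)
  fit2 <- fit_lmm(d, "y", fixed = "visit_time")
  tt <- d$visit_time - mean(d$visit_time)
  ols <- sum(tt * d$y) / sum(tt^2)
  beta2 <- tidy(fit2)$estimate[tidy(fit2)$term == "visit_time"]
  expect_equal(beta2, ols, tolerance = 1e-6)
})

test_that("estimates are equivariant under affine time rescaling", {
  co <- simulate_cohort(recovery_config(), seed = 53)
  f_years <- annualized_rate(co, "pfgcipl", by = "group")
  co_months <- dplyr::mutate(co, visit_time = visit_time * 12)
  f_months <- annualized_rate(co_months, "pfgcipl", by = "group")
  expect_equal(f_months$beta_time, f_years$beta_time / 12, tolerance = 1e-4)
})

test_that("fits are invariant to row permutation", {
  co <- simulate_cohort(recovery_config(), seed = 54)
  set.seed(54)
  shuffled <- co[sample(nrow(co)), ]
  a <- tidy(fit_lmm(co, "pfgcipl"))
  b <- tidy(fit_lmm(shuffled, "pfgcipl"))
  expect_equal(a$estimate, b$estimate, tolerance = 1e-9)
  expect_equal(a$std_error, b$std_error, tolerance = 1e-9)
})

test_that("time reversal flips the sign of the annualized rate", {
  co <- simulate_cohort(recovery_config(), seed = 55)
  fwd <- annualized_rate(co, "pfgcipl")
  rev <- annualized_rate(dplyr::mutate(co, visit_time = -visit_time),
                         "pfgcipl")
  expect_equal(rev$beta_time, -fwd$beta_time, tolerance = 1e-8)
})

test_that("the noise-free interaction equals the slope difference exactly", {
  co <- simulate_cohort(noise_free_config(), seed = 56)
  gi <- group_interaction(co, "pfgcipl", adjust = character(0))
  expect_equal(gi$estimate, -0.58 - (-0.29), tolerance = 1e-9)
  expect_identical(gi$reference, "control")
  expect_identical(gi$contrast, "PD - control")
  # identical slopes give a zero interaction
  co0 <- simulate_cohort(
    noise_free_config(control_slope = -0.3, pd_slope = -0.3), seed = 56
  )
  gi0 <- group_interaction(co0, "pfgcipl", adjust = character(0))
  expect_equal(gi0$estimate, 0, tolerance = 1e-9)
})

test_that("swapping the reference level flips the interaction sign", {
  co <- simulate_cohort(recovery_config(), seed = 57)
  a <- group_interaction(co, "pfgcipl")
  b <- group_interaction(co, "pfgcipl", ref = "PD")
  expect_equal(b$estimate, -a$estimate, tolerance = 1e-6)
  expect_identical(b$contrast, "control - PD")
})

test_that("rate models demand follow-up and both groups", {
  co <- simulate_cohort(cohort_config(n_control = 20, n_pd = 20,
                                      p_baseline_only = 1), seed = 58)
  expect_error(annualized_rate(co, "pfgcipl"), "follow-up")
  co2 <- simulate_cohort(cohort_config(n_control = 20, n_pd = 0), seed = 58)
  expect_error(group_interaction(co2, "pfgcipl"), "two")
})

test_that("education is added for cognitive outcomes by the stated rule", {
  co <- simulate_cohort(cohort_config(n_control = 40, n_pd = 40), seed = 59)
  fit <- fit_lmm(co, "moca",
                 fixed = c("visit_time",
                           retinarate:::rate_adjusters(
                             "moca", c("age_baseline", "sex"), NULL, co
                           )))
  expect_true("education" %in% tidy(fit)$term)
  adj <- retinarate:::rate_adjusters("pfgcipl", c("age_baseline", "sex"),
                                     NULL, co)
  expect_false("education" %in% adj)
})

test_that("AIC of nested random structures obeys the penalty bound", {
  cfg <- cohort_config(
    n_control = 0, n_pd = 100,
    visit_templates = list(c(0, 1, 2)), template_weights = 1,
    p_baseline_only = 0, true_slope = list(control = -0.29, pd = -0.58),
    slope_sd = 0.6, intercept_slope_corr = -0.5
  )
  co <- simulate_cohort(cfg, seed = 60)
  cmp <- compare_random_structures(co, "pfgcipl",
                                   fixed = c("visit_time", "age_baseline",
                                             "sex"))
  # correlated model nests the uncorrelated one with one extra parameter:
  # under ML its AIC can exceed the uncorrelated AIC by at most the +2
  # penalty (the log-likelihood cannot decrease)
  expect_lte(cmp$delta_aic, 2 + 0.01)
  expect_equal(cmp$n_subjects, 100)
  expect_error(
    compare_random_structures(
      simulate_cohort(cohort_config(n_control = 5, n_pd = 5,
                                    p_baseline_only = 1), seed = 1),
      "pfgcipl"
    ),
    "Insufficient"
  )
})

test_that("concurrent-change coefficients rescale with the predictor", {
  co <- simulate_cohort(recovery_config(), seed = 61)
  a <- concurrent_change_model(co, "pfgcipl", "prnfl_mean")
  co2 <- dplyr::mutate(co, prnfl_mean = prnfl_mean * 2)
  b <- concurrent_change_model(co2, "pfgcipl", "prnfl_mean")
  expect_equal(b$estimate, a$estimate / 2, tolerance = 1e-8)
  # independent outcomes: association indistinguishable from zero
  set.seed(61)
  co3 <- dplyr::mutate(co, indep = rnorm(dplyr::n(), 100, 5))
  c3 <- concurrent_change_model(co3, "pfgcipl", "indep")
  expect_lt(abs(c3$estimate), 3 * c3$se)
  expect_error(
    concurrent_change_model(dplyr::mutate(co, prnfl_mean = NA_real_),
                            "pfgcipl", "prnfl_mean"),
    "shared"
  )
})

test_that("baseline comparisons select tests by the stated rules", {
  # identical groups: mean difference is exactly zero, p = 1
  d <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:40),
    visit_time = 0,
    group = factor(rep(c("control", "PD"), each = 20)),
    val = rep(c(1, 2, 3, 4, 5.5, 7, 9.2, 11, 13, 15), 4)
  )
  out <- baseline_comparison(d, "val")
  expect_equal(out$p_value, 1, tolerance = 1e-9)
  # a categorical variable with a rare cell goes to Fisher's exact test
  d$cat <- rep(c("a", "a", "a", "a", "b"), 8)
  out2 <- baseline_comparison(d, c("val", "cat"))
  expect_identical(out2$test[out2$variable == "cat"], "Fisher exact")
  # Bonferroni adjustment across the declared family
  expect_equal(out2$p_adjusted, pmin(out2$p_value * 2, 1))
  # skewed data route to Wilcoxon
  set.seed(62)
  d$skew <- exp(rnorm(40, 0, 1))
  out3 <- baseline_comparison(d, "skew")
  expect_identical(out3$test, "Wilcoxon")
})

test_that("baseline comparisons detect a one-SD shift with high power", {
  set.seed(63)
  rejections <- replicate(40, {
    d <- tibble::tibble(
      subject_id = sprintf("S%03d", 1:220),
      visit_time = 0,
      group = factor(rep(c("control", "PD"), c(70, 150))),
      val = rnorm(220, 90, 8) + ifelse(rep(c(FALSE, TRUE), c(70, 150)), 8, 0)
    )
    baseline_comparison(d, "val")$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.8)
})

test_that("model objects expose tidy, glance and residual diagnostics", {
  co <- simulate_cohort(recovery_config(), seed = 64)
  fit <- fit_lmm(co, "pfgcipl")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "p_value") %in%
                    names(td)))
  expect_true(all(td$std_error > 0))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_gte(gl$n_obs, gl$n_subjects)
  diag <- residual_diagnostics(fit)
  expect_equal(nrow(diag), 2)
  expect_true(all(is.finite(diag$p_value)))
})

test_that("Wald and Satterthwaite p-values agree at large samples", {
  co <- simulate_cohort(recovery_config(), seed = 65)
  w <- annualized_rate(co, "pfgcipl", by = "group")
  s <- annualized_rate(co, "pfgcipl", by = "group",
                       df_method = "satterthwaite")
  expect_equal(s$beta_time, w$beta_time, tolerance = 1e-6)
  expect_lt(max(abs(s$p_value - w$p_value)), 0.01)
})
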