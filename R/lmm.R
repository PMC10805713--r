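#' Fit a linear mixed-effects model for longitudinal retinal outcomes
#'
#' Thin, bookkeeping-heavy wrapper around [lme4::lmer()] implementing the
#' model battery used throughout the pipeline: an outcome measured over
#' repeated visits, fixed effects given as term strings, and subject-level
#' random effects that are either a random intercept, a correlated random
#' intercept and slope on time, or an uncorrelated pair. Estimation is REML
#' by default for coefficient reporting and should be ML (`method = "ML"`)
#' when AICs are compared across random-effects structures.
#'
#' P-values for fixed effects use the large-sample Wald z approximation by
#' default; `df_method = "satterthwaite"` instead refits through
#' \pkg{lmerTest} and reports Satterthwaite denominator degrees of freedom.
#' At the sample sizes this pipeline targets the two agree closely.
#'
#' Rows with missing values in any used variable are dropped
#' (available-case likelihood, missing-at-random assumption).
#' Non-convergence and singular random-effects fits are flagged on the
#' returned object, never silently ignored.
#'
#' @param data Long-format visit tibble.
#' @param outcome Outcome column name.
#' @param fixed Character vector of fixed-effect terms (may include
#'   interactions, e.g. `"visit_time * group"`).
#' @param random Random-effects structure: `"intercept"`,
#'   `"intercept_slope"` (correlated) or `"intercept_slope_uncorrelated"`.
#' @param id Subject identifier column (default `subject_id`).
#' @param time Time column used in random slopes (default `visit_time`).
#' @param method `"REML"` or `"ML"`.
#' @param df_method `"wald"` or `"satterthwaite"`.
#' @return A `retina_lmm` object; see [tidy()] and [glance()] methods.
#' @export
fit_lmm <- function(data, outcome,
                    fixed = c("visit_time", "age_baseline", "sex"),
                    random = c("intercept", "intercept_slope",
                               "intercept_slope_uncorrelated"),
                    id = "subject_id", time = "visit_time",
                    method = c("REML", "ML"),
                    df_method = c("wald", "satterthwaite")) {
  random <- match.arg(random)
  method <- match.arg(method)
  df_method <- match.arg(df_method)
  if (!outcome %in% names(data)) {
    abort(sprintf("Outcome `%s` not found in `data`.", outcome))
  }
  re_term <- switch(random,
    intercept = sprintf("(1 | %s)", id),
    intercept_slope = sprintf("(1 + %s | %s)", time, id),
    intercept_slope_uncorrelated = sprintf("(1 + %s || %s)", time, id)
  )
  rhs <- paste(c(fixed, re_term), collapse = " + ")
  fml <- as.formula(paste(outcome, "~", rhs))
  used <- unique(c(outcome, id, time, all.vars(as.formula(
    paste("~", paste(fixed, collapse = "+"))
  ))))
  used <- intersect(used, names(data))
  dat <- as.data.frame(data)[, used, drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  dat <- droplevels(dat)
  if (!nrow(dat)) abort("No complete-case rows to fit.")
  warnings_seen <- character()
  fit <- withCallingHandlers(
    {
      if (df_method == "satterthwaite") {
        lmerTest::lmer(fml, data = dat, REML = method == "REML")
      } else {
        lme4::lmer(fml, data = dat, REML = method == "REML")
      }
    },
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  converged <- !any(grepl("failed to converge", warnings_seen,
                          ignore.case = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  cf <- lme4::fixef(fit)
  se <- tryCatch(
    sqrt(diag(as.matrix(stats::vcov(fit)))),
    error = function(e) {
      warnings_seen <<- c(warnings_seen,
                          paste("vcov unavailable:", conditionMessage(e)))
      rep(NA_real_, length(cf))
    }
  )
  if (df_method == "satterthwaite") {
    st <- as.data.frame(coef(summary(fit)))
    coefs <- tibble(
      term = rownames(st),
      estimate = st[["Estimate"]],
      std_error = st[["Std. Error"]],
      statistic = st[["t value"]],
      df = st[["df"]],
      p_value = st[["Pr(>|t|)"]]
    )
  } else {
    z <- unname(cf) / se
    coefs <- tibble(
      term = names(cf),
      estimate = unname(cf),
      std_error = unname(se),
      statistic = z,
      df = NA_real_,
      p_value = 2 * pnorm(-abs(z))
    )
  }
  structure(
    list(
      model = fit,
      coefficients = coefs,
      aic = AIC(fit),
      loglik = as.numeric(logLik(fit)),
      method = method,
      df_method = df_method,
      random = random,
      n_obs = nrow(dat),
      n_subjects = length(unique(dat[[id]])),
      converged = converged,
      singular = singular,
      warnings = warnings_seen,
      formula = deparse(fml),
      outcome = outcome
    ),
    class = "retina_lmm"
  )
}

#' @export
print.retina_lmm <- function(x, ...) {
  cat(sprintf(
    "<retina_lmm> %s  [%s, %s p-values]\n", x$formula, x$method, x$df_method
  ))
  cat(sprintf(
    "  n_obs = %d, n_subjects = %d, AIC = %.1f%s%s\n",
    x$n_obs, x$n_subjects, x$aic,
    if (!x$converged) ", NOT CONVERGED" else "",
    if (x$singular) ", singular fit" else ""
  ))
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Tidy the fixed effects of a fitted longitudinal model
#'
#' @param x A `retina_lmm`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std_error`,
#'   `statistic`, `df`, `p_value`.
#' @export
tidy.retina_lmm <- function(x, ...) {
  x$coefficients
}

#' One-row model summary
#'
#' @param x A `retina_lmm`.
#' @param ... Unused.
#' @return One-row tibble: `aic`, `loglik`, `sigma`, `n_obs`, `n_subjects`,
#'   `method`, `converged`, `singular`.
#' @export
glance.retina_lmm <- function(x, ...) {
  tibble(
    aic = x$aic,
    loglik = x$loglik,
    sigma = stats::sigma(x$model),
    n_obs = x$n_obs,
    n_subjects = x$n_subjects,
    method = x$method,
    converged = x$converged,
    singular = x$singular
  )
}

#' Residual diagnostics for a fitted longitudinal model
#'
#' Summarizes the distributional assumptions behind the mixed model:
#' normality of conditional residuals (Shapiro-Wilk, on an evenly-spaced
#' subsample when n exceeds 5000) and homoscedasticity (F-test of a linear
#' trend of squared residuals on fitted values).
#'
#' @param fit A `retina_lmm`.
#' @return Tibble with columns `check`, `statistic`, `p_value`, `note`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "retina_lmm"))
  r <- resid(fit$model)
  f <- fitted(fit$model)
  note <- NA_character_
  rs <- r
  if (length(rs) > 5000) {
    rs <- rs[round(seq(1, length(rs), length.out = 5000))]
    note <- "Shapiro-Wilk on an evenly-spaced subsample of 5000 residuals"
  }
  sw <- shapiro.test(rs)
  bp <- stats::anova(lm(I(r^2) ~ f))
  tibble(
    check = c("residual normality (Shapiro-Wilk)",
              "homoscedasticity (squared residuals ~ fitted, F-test)"),
    statistic = c(unname(sw$statistic), bp$`F value`[1]),
    p_value = c(sw$p.value, bp$`Pr(>F)`[1]),
    note = c(note, NA_character_)
  )
}
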