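# Shared fixtures and independent oracles, built in code at test time.

# A centred, right-eye-oriented grid sampled from f(x, y).
grid_from_function <- function(f, n = 200, extent = 6) {
  ax <- seq(-extent / 2, extent / 2, length.out = n)
  vals <- outer(ax, ax, f)
  thickness_grid(vals, extent = extent, centered = TRUE)
}

# Independent per-pixel membership oracle for sector means: an explicit
# loop over every node, re-deriving radius/angle membership from scratch.
brute_sector_means <- function(grid, scheme) {
  ax <- seq(-grid$extent / 2, grid$extent / 2, length.out = nrow(grid$values))
  sums <- setNames(numeric(nrow(scheme)), scheme$sector)
  counts <- setNames(numeric(nrow(scheme)), scheme$sector)
  for (i in seq_along(ax)) {
    for (j in seq_along(ax)) {
      r <- sqrt(ax[i]^2 + ax[j]^2)
      th <- atan2(ax[j], ax[i]) * 180 / pi
      v <- grid$values[i, j]
      if (is.na(v)) next
      for (s in seq_len(nrow(scheme))) {
        if (r < scheme$r_inner[s] - 1e-12 || r >= scheme$r_outer[s] - 1e-12) next
        if (!is.na(scheme$theta_min[s])) {
          tm <- (th - scheme$theta_min[s]) %% 360
          span <- scheme$theta_max[s] - scheme$theta_min[s]
          if (!(tm < span - 1e-9 || tm >= 360 - 1e-9)) next
        }
        sums[s] <- sums[s] + v
        counts[s] <- counts[s] + 1
      }
    }
  }
  ifelse(counts > 0, sums / counts, NA_real_)
}

# Small noise-free cohort configuration used by degenerate-case tests.
noise_free_config <- function(n_control = 30, n_pd = 30,
                              control_slope = -0.29, pd_slope = -0.58) {
  cohort_config(
    n_control = n_control, n_pd = n_pd,
    true_slope = list(control = control_slope, pd = pd_slope),
    slope_sd = 0, intercept_slope_corr = 0, intercept_sd = 0,
    residual_sd = 0, age_effect = 0, sex_effect = 0,
    p_baseline_only = 0, visit_jitter_sd = 0,
    rings = list(resid_sd = 0)
  )
}

# Recovery-style configuration: 150 PD / 70 controls, subject random
# intercepts only, 2-3 visits over 1-5 years.
recovery_config <- function(control_slope = -0.29, pd_slope = -0.58) {
  cohort_config(
    n_control = 70, n_pd = 150,
    true_slope = list(control = control_slope, pd = pd_slope),
    slope_sd = 0, intercept_slope_corr = 0,
    intercept_sd = 6, residual_sd = 2
  )
}
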