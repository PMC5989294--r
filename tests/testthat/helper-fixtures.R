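# Shared fixtures and independent oracles.

# Tiny hand-built cohort with exactly model-consistent recorded months,
# generated forward from a known coefficient triple (the generator is
# the oracle for calibration round trips).
make_exact_cohort <- function(coeffs = model_coefficients(0.04, 5e8, -2.0),
                              Q = c(55, 72, 90, 64),
                              K = c(3.5, 4.6, 5.8, 4.1),
                              h = c(24, 29, 35, 31),
                              T = c(4, 5, 3.5, 6)) {
  new_cohort(id = paste0("p", seq_along(Q)), mass_kg = Q,
             activity_h_per_day = T, offset_mm = h, K = K,
             months_recorded = predict_months(Q, K, h, T, coeffs))
}

# Loop-based (naive) reimplementation of the metric formulas, kept
# deliberately independent of metric_set()'s vectorized code path.
naive_metrics <- function(p, o) {
  n <- length(o)
  se <- 0; ae <- 0; be <- 0; f2 <- 0
  for (i in seq_len(n)) {
    se <- se + (p[i] - o[i])^2
    ae <- ae + abs(p[i] - o[i])
    be <- be + (p[i] - o[i])
    if (p[i] / o[i] >= 0.5 && p[i] / o[i] <= 2) f2 <- f2 + 1
  }
  mse <- se / n; mbe <- be / n
  obar <- sum(o) / n; pbar <- sum(p) / n
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    num <- num + (p[i] - o[i])^2
    den <- den + (abs(p[i] - obar) + abs(o[i] - obar))^2
  }
  list(mse = mse, rmse = sqrt(mse), relative_rmse = 100 * sqrt(mse) / obar,
       mae = ae / n, mbe = mbe, mape = 100 * (ae / n) / obar,
       r = sum((p - pbar) * (o - obar)) /
         sqrt(sum((p - pbar)^2) * sum((o - obar)^2)),
       sdr = sqrt(mse - mbe^2), fact2_fraction = f2 / n, ia = 1 - num / den)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
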