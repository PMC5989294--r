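ref15 <- reference_cohort("assessment15")

test_that("metric set matches a naive loop oracle on random vectors", {
  set.seed(8)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    o <- runif(n, 100, 300)
    p <- o * exp(rnorm(n, 0, 0.2))
    m <- metric_set(p, o)
    expect_equal(unclass(m)[names(naive_metrics(p, o))], naive_metrics(p, o),
                 tolerance = 1e-12)
    # structural identities
    expect_equal(m$rmse^2, m$mbe^2 + m$sdr^2, tolerance = 1e-9)
    expect_equal(m$fact2_printed, m$r)
  }
})

test_that("metric set handles the degenerate agreement cases", {
  o <- c(100, 150, 200, 250)
  perfect <- metric_set(o, o)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$ia, 1)
  expect_equal(perfect$fact2_fraction, 1)
  shifted <- metric_set(o + 5, o)
  expect_equal(shifted$mbe, 5)
  expect_equal(shifted$sdr, 0)
  expect_equal(shifted$rmse, 5)
  expect_error(metric_set(1:3, 1:4), "equal length")
  expect_error(metric_set(1, 1), "two pairs")
})

test_that("model error on the reference cohort is about 10.4 months", {
  m <- metric_set(ref15$months_predicted, ref15$months_recorded)
  expect_equal(m$rmse, 10.39, tolerance = 0.01 / 10.39)
  expect_gt(m$ia, 0.98)
  expect_equal(m$fact2_fraction, 1)
})

test_that("exact Mann-Whitney reproduces small enumerable nulls", {
  # disjoint samples: U = 0; only 2 of the C(6,3) = 20 rank splits are
  # as extreme, so two-sided p = 0.1
  mw <- mann_whitney(c(1, 2, 3), c(10, 11, 12), method = "exact")
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  # identical samples sit exactly at the null centre
  same <- mann_whitney(c(5, 6, 7), c(5, 6, 7), method = "exact")
  expect_equal(same$U, 4.5)
  expect_equal(same$p, 1)
  expect_gte(mann_whitney(c(5, 6, 7), c(5, 6, 7), method = "normal")$p, 0.99)
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("exact Mann-Whitney agrees with the independent implementation", {
  set.seed(13)
  for (i in 1:20) {
    a <- rnorm(sample(4:9, 1), 0, 1)
    b <- rnorm(sample(4:9, 1), 0.5, 1)   # continuous: no ties
    ours <- mann_whitney(a, b, method = "exact")
    oracle <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$U, unname(oracle$statistic))
    expect_equal(ours$p, oracle$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact null at moderate sizes", {
  set.seed(14)
  for (n in c(7, 8)) {
    for (i in 1:40) {
      a <- round(rnorm(n, 200, 40))
      b <- round(rnorm(n, 210, 40))   # rounding induces occasional ties
      pe <- mann_whitney(a, b, "exact")$p
      pn <- mann_whitney(a, b, "normal")$p
      expect_lt(abs(pe - pn), 0.03)
    }
  }
  # at very small n the Gaussian is coarser but stays within 0.1
  for (i in 1:40) {
    n <- sample(4:6, 1)
    a <- round(rnorm(n, 200, 40)); b <- round(rnorm(n, 210, 40))
    expect_lt(abs(mann_whitney(a, b, "exact")$p -
                    mann_whitney(a, b, "normal")$p), 0.1)
  }
})

test_that("pearson correlation behaves and reproduces the activity link", {
  x <- c(1, 2, 4, 8, 9)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -(2 * x + 1)), -1)
  set.seed(2); y <- rnorm(5)
  expect_equal(pearson_r(x, -y), -pearson_r(x, y))
  expect_error(pearson_r(rep(1, 5), y), "constant")
  expect_equal(pearson_r(ref15$activity_h_per_day, ref15$months_recorded),
               -0.84, tolerance = 0.005 / 0.84)
})

test_that("OLS baseline satisfies the normal equations and known fits", {
  b <- ols_baseline(ref15)
  res <- ref15$months_recorded - b$fitted
  for (col in c("mass_kg", "activity_h_per_day", "offset_mm", "K")) {
    x <- ref15[[col]]
    expect_lt(abs(sum(res * x)) / (sqrt(sum(res^2)) * sqrt(sum(x^2)) + 1e-30),
              1e-8)
  }
  expect_lt(abs(sum(res)), 1e-8)
  # an exactly linear cohort is fitted with zero residual
  set.seed(41)
  lin <- new_cohort(id = letters[1:10], mass_kg = runif(10, 45, 105),
                    activity_h_per_day = runif(10, 3, 6),
                    offset_mm = runif(10, 20, 40),
                    K = runif(10, 2.5, 7))
  lin$months_recorded <- 500 - 2 * lin$mass_kg - 30 * lin$activity_h_per_day -
    1.5 * lin$offset_mm - 10 * lin$K
  class(lin) <- c("hip_cohort", "data.frame")
  bl <- ols_baseline(lin)
  expect_equal(bl$rmse, 0, tolerance = 1e-8)
  expect_equal(bl$coef_Q, -2, tolerance = 1e-8)
  expect_error(ols_baseline(reference_cohort("calibration3")), "at least 6")
})

test_that("validation report aggregates the published summary statistics", {
  rep <- validation_report(ref15)
  # summaries of the recorded column use the sample (n - 1) SD
  expect_equal(unname(rep$recorded_summary),
               c(125, 302, 224.33, 50.08), tolerance = 1e-3)
  expect_equal(rep$correlations[["T"]], -0.84, tolerance = 0.005 / 0.84)
  expect_gt(rep$mann_whitney$p, 0.05)
  expect_lt(rep$metrics$rmse, rep$baseline$rmse)
  # a self-consistent cohort validates perfectly
  exact <- make_exact_cohort()
  coeffs <- model_coefficients(0.04, 5e8, -2.0)
  perfect <- validation_report(exact, coeffs)
  expect_equal(perfect$mann_whitney$p, 1)
  expect_equal(perfect$metrics$rmse, 0, tolerance = 1e-9)
})
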