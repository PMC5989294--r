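pub <- published_coefficients()
ref <- reference_cohort("all")

test_that("months/cycles conversion uses 30-day months and inverts exactly", {
  expect_equal(months_to_cycles(1, 1), 30 * 3600 / 1.11)
  expect_equal(months_to_cycles(0, 4), 0)
  x <- c(12.5, 200, 301.7)
  expect_equal(cycles_to_months(months_to_cycles(x, T = 4.5), T = 4.5), x)
  expect_error(months_to_cycles(10, 0), "positive")
})

test_that("load measure is the offset-amplified weight term", {
  expect_equal(load_measure(70, 4, 30, c1 = 0), 280)
  expect_equal(load_measure(100, 5.06, 35.4, 0.0555886592), 1501.7263,
               tolerance = 1e-7)
  expect_equal(load_measure(2 * 70, 4, 30, 0.05),
               2 * load_measure(70, 4, 30, 0.05))
  expect_equal(load_measure(70, 2 * 4, 30, 0.05),
               2 * load_measure(70, 4, 30, 0.05))
  expect_error(load_measure(70, 4, 30, c1 = -0.1), "positive")
})

test_that("closed-form prediction reproduces the published per-patient months", {
  # the two spot rows with their published tolerances
  expect_equal(predict_months(100, 5.06, 35.4, 6, pub), 118.7,
               tolerance = 0.5 / 118.7)
  expect_equal(predict_months(50, 4.04, 25.6, 4, pub), 297.2,
               tolerance = 1.5 / 297.2)
  # whole cohort within 0.5 % (inputs are rounded to the printed digits)
  p <- predict_months(ref$mass_kg, ref$K, ref$offset_mm,
                      ref$activity_h_per_day, pub)
  expect_lt(max(abs(p - ref$months_predicted) / ref$months_predicted), 0.005)
})

test_that("predicted life scales as 1/T and is scale covariant in mass", {
  base <- predict_months(70, 4, 30, 4, pub)
  expect_equal(predict_months(70, 4, 30, 8, pub), base / 2)
  lam <- 1.37
  scaled <- model_coefficients(pub$c1, lam * pub$c2_bar, pub$c)
  expect_equal(predict_months(lam * 70, 4, 30, 4, scaled), base,
               tolerance = 1e-12)
  expect_error(predict_months(70, 4, 30, 0, pub), "positive")
})

test_that("Basquin consistency: prediction inverts the durability law", {
  set.seed(11)
  Q <- runif(20, 45, 105); K <- runif(20, 2.5, 7)
  h <- runif(20, 20, 40); T <- runif(20, 3, 6)
  NM <- predict_months(Q, K, h, T, pub)
  lhs <- load_measure(Q, K, h, pub$c1)
  rhs <- pub$c2_bar * (T * NM)^pub$c
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("triplet calibration reproduces the published coefficient triple", {
  fit <- calibrate_triplet(ref, ids = c(16, 17, 18))
  expect_rel(fit$c1, 0.0555886592, 0.02)
  expect_rel(fit$c2_bar, 2.61607405e9, 0.02)
  expect_rel(fit$c, -2.187401, 0.02)
  # the defining equations are satisfied essentially exactly
  cal <- reference_cohort("calibration3")
  resid <- load_measure(cal$mass_kg, cal$K, cal$offset_mm, fit$c1) /
    (fit$c2_bar * (cal$activity_h_per_day * cal$months_recorded)^fit$c) - 1
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("calibrate-then-predict returns the triplet's recorded months", {
  set.seed(21)
  for (i in 1:5) {
    ids <- sample(ref$id, 3)
    fit <- tryCatch(calibrate_triplet(ref, ids = ids),
                    error = function(e) NULL)
    if (is.null(fit)) next   # inadmissible random triplet
    trip <- cohort_subset(ref, ids)
    back <- predict_months(trip$mass_kg, trip$K, trip$offset_mm,
                           trip$activity_h_per_day, fit)
    expect_lt(max(abs(back - trip$months_recorded) / trip$months_recorded),
              1e-6)
  }
})

test_that("degenerate calibration systems are rejected", {
  same_TN <- new_cohort(id = c("a", "b", "c"), mass_kg = c(60, 70, 80),
                        activity_h_per_day = c(4, 4, 4),
                        offset_mm = c(25, 30, 35), K = c(4, 4.5, 5),
                        months_recorded = c(200, 200, 200))
  expect_error(calibrate_triplet(same_TN), "pairwise distinct")
  expect_error(calibrate_triplet(ref, ids = c(1, 2)), "three patients")
})

test_that("mass sensitivity matches the exact power-law ratio", {
  expect_equal(round(sensitivity_mass(60, -10, pub), 1), 8.7)
  expect_equal(round(sensitivity_mass(60, 10, pub), 1), -6.8)
  expect_equal(sensitivity_mass(75, 0, pub), 0)
  # a 10 % mass decrease buys about 5 % of life
  expect_true(sensitivity_mass(80, -8, pub) > 4.9 &&
                sensitivity_mass(80, -8, pub) < 5.0)
  expect_error(sensitivity_mass(60, -60, pub), "positive")
})

test_that("activity sensitivity is exponent free", {
  expect_equal(round(sensitivity_activity(4, -1), 1), 33.3)
  expect_equal(sensitivity_activity(3, 1), -25)
  expect_equal(sensitivity_activity(5, 0), 0)
  expect_error(sensitivity_activity(1, -1), "positive")
})

test_that("durability surface decreases along every grid axis", {
  for (pair in list(c("Q", "T"), c("h", "K"), c("Q", "h"))) {
    fixed <- list(Q = 60, K = 4, h = 30, T = 4)
    fixed[pair] <- NULL
    surf <- durability_surface(pub, vary = pair,
                               values1 = seq(50, 100, by = 10),
                               values2 = seq(3, 6, by = 0.5) *
                                 if (pair[2] == "h") 6 else 1,
                               fixed = fixed)
    expect_true(all(apply(surf, 2, diff) < 0))
    expect_true(all(apply(surf, 1, diff) < 0))
  }
  # corner ordering and 1x1 degeneracy
  s <- durability_surface(pub, c("Q", "T"), c(50, 100), c(3, 6),
                          fixed = list(h = 30, K = 4))
  expect_lt(s["100", "6"], s["50", "3"])
  one <- durability_surface(pub, c("Q", "T"), 70, 4,
                            fixed = list(h = 30, K = 4))
  expect_equal(as.numeric(one), predict_months(70, 4, 30, 4, pub))
})

test_that("coefficients survive a JSON round trip", {
  fit <- calibrate_triplet(ref, ids = c(16, 17, 18))
  back <- coefficients_from_json(coefficients_to_json(fit))
  expect_equal(back$c1, fit$c1)
  expect_equal(back$c2_bar, fit$c2_bar)
  expect_equal(back$c, fit$c)
})
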