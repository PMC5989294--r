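# Statistical validation of model predictions against recorded
# durability: the error-metric set, Mann-Whitney U (exact permutation
# null or normal approximation), Pearson correlations, and an
# ordinary-least-squares regression baseline.

#' Error-metric set for predicted vs observed durability
#'
#' Computes the ten evaluation statistics used throughout the package,
#' with `P` predicted and `O` observed months (`n` pairs):
#'
#' * `mse`, `rmse`: mean squared error and its root (denominator `n`);
#' * `relative_rmse`: `100 * rmse / mean(O)` (percent);
#' * `mae`: mean absolute error; `mape`: `100 * mae / mean(O)`;
#' * `mbe`: mean bias error `mean(P) - mean(O)` (positive = model
#'   overestimates life);
#' * `r`: Pearson correlation of `P` and `O`;
#' * `sdr`: standard deviation of residuals, `sqrt(rmse^2 - mbe^2)`;
#' * `fact2_fraction`: fraction of cases with `1/2 <= P_i/O_i <= 2`;
#' * `fact2_printed`: the standardized cross-product form often tabled
#'   under the FACT2 label, which is algebraically the correlation `r`;
#' * `ia`: Willmott's index of agreement,
#'   `1 - sum((P-O)^2) / sum((|P - mean(O)| + |O - mean(O)|)^2)`.
#'
#' The identity `rmse^2 = mbe^2 + sdr^2` holds by construction.
#'
#' @param predicted,observed equal-length numeric vectors (length >= 2)
#'   of months.
#' @return A `metric_set` (named list).
#' @export
metric_set <- function(predicted, observed) {
  n <- length(observed)
  if (length(predicted) != n)
    stop("predicted and observed must have equal length")
  if (n < 2L) stop("at least two pairs are required")
  res <- predicted - observed
  obar <- mean(observed)
  mse <- mean(res^2)
  rmse <- sqrt(mse)
  mbe <- mean(res)
  r <- if (var(predicted) > 0 && var(observed) > 0)
    stats::cor(predicted, observed) else NA_real_
  out <- list(
    mse = mse,
    rmse = rmse,
    relative_rmse = 100 * rmse / obar,
    mae = mean(abs(res)),
    mbe = mbe,
    mape = 100 * mean(abs(res)) / obar,
    r = r,
    sdr = sqrt(pmax(mse - mbe^2, 0)),
    fact2_fraction = mean(predicted / observed >= 0.5 &
                            predicted / observed <= 2),
    fact2_printed = r,
    ia = 1 - sum(res^2) /
      sum((abs(predicted - obar) + abs(observed - obar))^2)
  )
  structure(out, n = n, class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 4, ...) {
  cat(sprintf("<metric_set> n = %d pairs\n", attr(x, "n")))
  v <- unlist(x)
  for (nm in names(v))
    cat(sprintf("  %-14s %s\n", nm, format(v[[nm]], digits = digits)))
  invisible(x)
}

# Exact null distribution of the Wilcoxon rank-sum statistic under the
# permutation null, with midranks for ties.  Doubled midranks are
# integers, so the count of size-n1 subsets attaining each rank sum is
# accumulated by dynamic programming (equivalent to full enumeration of
# all choose(N, n1) assignments, without materializing them).
rank_sum_null <- function(ranks2, n1) {
  N <- length(ranks2)
  maxs <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n1)])
  dp <- matrix(0, n1 + 1L, maxs + 1L)
  dp[1L, 1L] <- 1
  for (v in ranks2) {
    for (k in seq(min(n1, N), 1L)) {
      idx <- (v + 1L):(maxs + 1L)
      dp[k + 1L, idx] <- dp[k + 1L, idx] + dp[k, idx - v]
    }
  }
  counts <- dp[n1 + 1L, ]
  list(sum2 = 0:maxs, prob = counts / choose(N, n1))
}

#' Mann-Whitney U test
#'
#' Two-sided rank test comparing the distributions of two samples.  The
#' exact method evaluates the full permutation null of the rank-sum
#' statistic (midranks for ties) by dynamic programming; the normal
#' method uses the Gaussian approximation with tie correction and a 0.5
#' continuity correction.  `"auto"` picks exact when `n1 * n2 <= 400`.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return List with the U statistic (for `sample_a`), the two-sided
#'   `p` value, and the method used.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(10, 11, 12), method = "exact")  # p = 0.1
mann_whitney <- function(sample_a, sample_b,
                         method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  n1 <- length(sample_a); n2 <- length(sample_b)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  if (method == "auto") method <- if (n1 * n2 <= 400) "exact" else "normal"
  r <- rank(c(sample_a, sample_b))
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  if (method == "exact") {
    null <- rank_sum_null(as.integer(round(2 * r)), n1)
    U_all <- null$sum2 / 2 - n1 * (n1 + 1) / 2
    p_low <- sum(null$prob[U_all <= U + 1e-9])
    p_high <- sum(null$prob[U_all >= U - 1e-9])
    p <- min(1, 2 * min(p_low, p_high))
  } else {
    N <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    dev <- U - n1 * n2 / 2
    z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(U = U, p = p, method = method)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero
#'   variance.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (var(x) == 0 || var(y) == 0)
    stop("correlation undefined: constant input")
  stats::cor(x, y)
}

#' Ordinary-least-squares regression baseline
#'
#' Regresses recorded months on body mass, daily activity, femoral
#' offset and load coefficient (with intercept) -- the conventional
#' linear alternative the fatigue model is compared against.  The RMSE
#' uses denominator `n` (not `n - p`) so it is directly comparable with
#' [metric_set()]'s RMSE for the fatigue model.
#'
#' @param cohort a `hip_cohort` with `months_recorded` and at least six
#'   complete records.
#' @return A `regression_baseline`: named coefficients (`intercept`,
#'   `coef_Q`, `coef_T`, `coef_h`, `coef_K`), `rmse`, fitted values and
#'   the underlying [stats::lm] fit.
#' @export
ols_baseline <- function(cohort) {
  stopifnot(inherits(cohort, "hip_cohort"))
  d <- as.data.frame(cohort)
  d <- d[stats::complete.cases(d[c("mass_kg", "activity_h_per_day",
                                   "offset_mm", "K", "months_recorded")]), ]
  if (nrow(d) < 6L)
    stop("ols_baseline needs at least 6 complete records (5 parameters)")
  fit <- lm(months_recorded ~ mass_kg + activity_h_per_day + offset_mm + K,
            data = d)
  if (fit$rank < 5L)
    stop("singular fit: regressors are rank deficient")
  b <- coef(fit)
  structure(list(intercept = unname(b[["(Intercept)"]]),
                 coef_Q = unname(b[["mass_kg"]]),
                 coef_T = unname(b[["activity_h_per_day"]]),
                 coef_h = unname(b[["offset_mm"]]),
                 coef_K = unname(b[["K"]]),
                 rmse = sqrt(mean(stats::residuals(fit)^2)),
                 fitted = unname(stats::fitted(fit)),
                 fit = fit),
            class = "regression_baseline")
}

#' @export
print.regression_baseline <- function(x, ...) {
  cat("<regression_baseline> months ~ Q + T + h + K\n")
  cat(sprintf("  N_M = %.4f Q %+.4f T %+.4f h %+.4f K %+.4f\n",
              x$coef_Q, x$coef_T, x$coef_h, x$coef_K, x$intercept))
  cat(sprintf("  RMSE (denominator n): %.4f months\n", x$rmse))
  invisible(x)
}

#' Full validation report for a cohort
#'
#' Predicts durability for every patient, then summarises agreement with
#' the recorded values: range/mean/SD of both columns (sample SD,
#' denominator `n - 1`), the Mann-Whitney comparison of the two
#' distributions, Pearson correlations of recorded months with mass,
#' activity and offset, the full [metric_set()], and -- where the cohort
#' is large enough -- the [ols_baseline()] RMSE for comparison.
#'
#' @param cohort a `hip_cohort` with recorded months.
#' @param coeffs a [model_coefficients()] triple.
#' @param mapping an [activity_mapping()] for rows lacking `K`.
#' @param mw_method Mann-Whitney method, see [mann_whitney()].
#' @return A `validation_report` list.
#' @export
validation_report <- function(cohort, coeffs = published_coefficients(),
                              mapping = activity_mapping(),
                              mw_method = "auto") {
  stopifnot(inherits(cohort, "hip_cohort"))
  if (all(is.na(cohort$months_recorded)))
    stop("validation requires recorded months")
  cohort <- predict_cohort(cohort, coeffs, mapping)
  keep <- !is.na(cohort$months_recorded)
  pred <- cohort$months_predicted[keep]
  obs <- cohort$months_recorded[keep]
  summarise <- function(v) c(min = min(v), max = max(v),
                             mean = mean(v), sd = sd(v))
  mw <- mann_whitney(pred, obs, method = mw_method)
  cors <- c(Q = pearson_r(cohort$mass_kg[keep], obs),
            T = pearson_r(cohort$activity_h_per_day[keep], obs),
            h = pearson_r(cohort$offset_mm[keep], obs))
  baseline <- tryCatch(ols_baseline(cohort), error = function(e) NULL)
  structure(list(cohort = cohort,
                 predicted_summary = summarise(pred),
                 recorded_summary = summarise(obs),
                 mann_whitney = mw,
                 correlations = cors,
                 metrics = metric_set(pred, obs),
                 baseline = baseline),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat("  predicted months:",
      paste(sprintf("%s=%.2f", names(x$predicted_summary),
                    x$predicted_summary), collapse = " "), "\n")
  cat("  recorded months: ",
      paste(sprintf("%s=%.2f", names(x$recorded_summary),
                    x$recorded_summary), collapse = " "), "\n")
  cat(sprintf("  Mann-Whitney U = %.1f, two-sided p = %.3f (%s)\n",
              x$mann_whitney$U, x$mann_whitney$p, x$mann_whitney$method))
  cat("  r(recorded months vs):",
      paste(sprintf("%s=%.2f", names(x$correlations), x$correlations),
            collapse = " "), "\n")
  cat(sprintf("  model RMSE = %.2f months", x$metrics$rmse))
  if (!is.null(x$baseline))
    cat(sprintf("; OLS baseline RMSE = %.2f months", x$baseline$rmse))
  cat("\n")
  invisible(x)
}
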