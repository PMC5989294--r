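# The durability law.
#
# Basquin's stress-life relation applied to the equivalent contact
# stress collapses, for one implant type, to
#
#     Q * K * (1 + c1 * h) = c2_bar * (T * N_M)^c
#
# with Q body mass (kg), K load coefficient, h femoral offset (mm),
# T daily activity (h/day) and N_M durability (months).  c1 (per mm)
# carries the section geometry, c2_bar absorbs the material constants
# and the steps-per-month conversion, and c < 0 is the fatigue
# exponent.  One month = 30 days; a step takes T_step seconds.

#' Model coefficient triple
#'
#' @param c1 geometric offset coefficient, per millimeter
#'   (`c1 = y_max / i_x^2` for the contact section).
#' @param c2_bar scale constant absorbing material properties and the
#'   cycles-per-month conversion; must be positive.
#' @param c fatigue exponent (negative for physically meaningful fits:
#'   heavier loading shortens life).
#' @param provenance free-text origin (e.g. the calibration triplet ids).
#' @return A `model_coefficients` object.
#' @seealso [published_coefficients()], [calibrate_triplet()]
#' @export
model_coefficients <- function(c1, c2_bar, c, provenance = "unspecified") {
  stopifnot(is.numeric(c1), length(c1) == 1L,
            is.numeric(c2_bar), length(c2_bar) == 1L, c2_bar > 0,
            is.numeric(c), length(c) == 1L, c != 0)
  structure(list(c1 = c1, c2_bar = c2_bar, c = c, provenance = provenance),
            class = "model_coefficients")
}

#' @export
print.model_coefficients <- function(x, ...) {
  cat("<model_coefficients>\n")
  cat(sprintf("  c1     = %.10g  (per mm)\n", x$c1))
  cat(sprintf("  c2_bar = %.10g\n", x$c2_bar))
  cat(sprintf("  c      = %.10g  (fatigue exponent)\n", x$c))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' The published coefficients for the non-cemented RCM stem
#'
#' The coefficient triple calibrated on the reference cohort's three
#' calibration patients (ids 16--18): `c1 = 0.0555886592` per mm,
#' `c2_bar = 2.61607405e9`, `c = -2.187401`.  Being implant specific,
#' these apply to the hydroxyapatite-coated RCM femoral stem only.
#'
#' @return A [model_coefficients()] object.
#' @export
published_coefficients <- function() {
  model_coefficients(c1 = 0.0555886592, c2_bar = 2.61607405e9,
                     c = -2.187401, provenance = "published (RCM stem)")
}

#' Convert durability in months to load cycles (steps)
#'
#' `N = 30 * N_M * T * 3600 / T_step`: 30 days per month, `T` walking
#' hours per day, one step every `T_step` seconds.
#'
#' @param N_M durability in months (>= 0).
#' @param T daily activity, hours per day (> 0).
#' @param T_step seconds per step.
#' @return Number of steps before failure.
#' @export
months_to_cycles <- function(N_M, T, T_step = 1.11) {
  if (any(N_M < 0)) stop("months N_M must be non-negative")
  if (any(T <= 0) || any(T_step <= 0)) stop("T and T_step must be positive")
  30 * N_M * T * 3600 / T_step
}

#' @rdname months_to_cycles
#' @param N number of steps.
#' @export
cycles_to_months <- function(N, T, T_step = 1.11) {
  if (any(N < 0)) stop("cycle count must be non-negative")
  if (any(T <= 0) || any(T_step <= 0)) stop("T and T_step must be positive")
  N * T_step / (30 * T * 3600)
}

#' Load measure of a patient
#'
#' The left-hand side of the durability law:
#' `L = Q * K * (1 + c1 * h)`, in kg-equivalents.
#'
#' @param Q body mass, kg.
#' @param K load coefficient.
#' @param h femoral offset, mm.
#' @param c1 offset coefficient, per mm; `1 + c1 * h` must stay positive.
#' @return The load measure `L`.
#' @export
load_measure <- function(Q, K, h, c1) {
  f <- 1 + c1 * h
  if (any(f <= 0))
    stop("load measure undefined: 1 + c1 * h must be positive ",
         "(c1 too negative for this offset range)")
  Q * K * f
}

#' Predict durability in months
#'
#' The closed-form durability law
#' `N_M = (1/T) * (c2_bar / (K Q (1 + c1 h)))^(-1/c)`.  With the fitted
#' `c < 0` the inner ratio is raised to the positive power `-1/c`, so
#' predicted life falls as any of `Q`, `K`, `h`, `T` rises.  The formula
#' degrades as `T` approaches zero (life diverges), so `T` must be
#' strictly positive; sensible use is roughly 2--7 h/day of activity and
#' `K` between 2.2 and 7.2.
#'
#' @param Q body mass, kg.
#' @param K load coefficient (dimensionless).
#' @param h femoral offset, mm.
#' @param T daily activity, hours per day (> 0).
#' @param coeffs a [model_coefficients()] triple.
#' @return Predicted months to aseptic loosening (vectorized).
#' @export
#' @examples
#' predict_months(Q = 100, K = 5.06, h = 35.4, T = 6,
#'                coeffs = published_coefficients())  # ~118.7 months
predict_months <- function(Q, K, h, T, coeffs = published_coefficients()) {
  stopifnot(inherits(coeffs, "model_coefficients"))
  if (any(T <= 0)) stop("daily activity T must be strictly positive")
  L <- load_measure(Q, K, h, coeffs$c1)
  (1 / T) * (coeffs$c2_bar / L)^(-1 / coeffs$c)
}

#' Predict durability for every patient of a cohort
#'
#' Fills the `months_predicted` column; `K` is taken from the cohort
#' where present and otherwise derived from the activity score through
#' `mapping`.
#'
#' @param cohort a `hip_cohort`.
#' @param coeffs a [model_coefficients()] triple.
#' @param mapping an [activity_mapping()] used for rows lacking `K`.
#' @return The cohort with `months_predicted` (and any derived `K`)
#'   filled in.
#' @export
predict_cohort <- function(cohort, coeffs = published_coefficients(),
                           mapping = activity_mapping()) {
  stopifnot(inherits(cohort, "hip_cohort"))
  K <- resolve_K(cohort, mapping)
  cohort$K <- K
  cohort$months_predicted <- predict_months(cohort$mass_kg, K,
                                            cohort$offset_mm,
                                            cohort$activity_h_per_day,
                                            coeffs)
  cohort
}

#' Calibrate the coefficient triple from three patients
#'
#' Three patients with known `(Q, K, h, T)` and recorded durability
#' determine `(c1, c2_bar, c)` exactly.  Taking logs of the durability
#' law, the three points `(log(T_i N_i), log(Q_i K_i (1 + c1 h_i)))`
#' must be collinear at the true `c1`; the collinearity defect (the
#' difference of the two pairwise slopes) is a smooth function of `c1`
#' alone, so calibration reduces to a one-dimensional root-find on
#' `c1 > -1 / max(h_i)`, after which `c` is the common slope and
#' `c2_bar` follows from any one equation.  The admissible domain is
#' scanned on a fine grid for sign changes; every root is polished with
#' [stats::uniroot()] at machine tolerance.  A unique solution with
#' `c < 0` is required.
#'
#' @param cohort a `hip_cohort`; either exactly three rows, or any cohort
#'   together with `ids`.
#' @param ids optional three patient ids selecting the triplet.
#' @param mapping an [activity_mapping()] for rows lacking `K`.
#' @param c1_upper upper end of the `c1` scan interval (per mm).
#' @param grid_n number of scan points used to bracket roots.
#' @return A [model_coefficients()] object; residuals of the three
#'   defining equations are below 1e-9 relative.
#' @export
#' @examples
#' calibrate_triplet(reference_cohort(), ids = c(16, 17, 18))
calibrate_triplet <- function(cohort, ids = NULL,
                              mapping = activity_mapping(),
                              c1_upper = 1, grid_n = 4001) {
  stopifnot(inherits(cohort, "hip_cohort"))
  if (!is.null(ids)) cohort <- cohort_subset(cohort, ids)
  if (nrow(cohort) != 3L)
    stop("calibration needs exactly three patients (got ", nrow(cohort), ")")
  if (anyNA(cohort$months_recorded))
    stop("all three calibration patients need recorded months")
  Q <- cohort$mass_kg; h <- cohort$offset_mm
  T <- cohort$activity_h_per_day; N <- cohort$months_recorded
  K <- resolve_K(cohort, mapping)
  x <- log(T * N)
  if (min(stats::dist(x)) < 1e-12)
    stop("degenerate calibration system: the products T_i * N_i must be ",
         "pairwise distinct")
  logL <- function(c1) log(Q * K * (1 + c1 * h))
  defect <- function(c1) {
    l <- logL(c1)
    (l[2] - l[1]) / (x[2] - x[1]) - (l[3] - l[1]) / (x[3] - x[1])
  }
  lo <- -1 / max(h) + 1e-9
  grid <- seq(lo, c1_upper, length.out = grid_n)
  gv <- vapply(grid, defect, numeric(1))
  jumps <- which(diff(sign(gv)) != 0 & is.finite(gv[-1]) &
                   is.finite(gv[-length(gv)]))
  if (!length(jumps))
    stop("no solution: the collinearity defect has no sign change on ",
         sprintf("c1 in (%.4g, %.4g); defect range [%.3g, %.3g]",
                 lo, c1_upper, min(gv, na.rm = TRUE), max(gv, na.rm = TRUE)))
  roots <- vapply(jumps, function(i)
    uniroot(defect, c(grid[i], grid[i + 1]),
            tol = .Machine$double.eps)$root, numeric(1))
  solutions <- lapply(roots, function(c1) {
    l <- logL(c1)
    slope <- (l[2] - l[1]) / (x[2] - x[1])
    list(c1 = c1, c = slope, c2_bar = exp(l[1] - slope * x[1]))
  })
  admissible <- vapply(solutions, function(s)
    s$c < 0 && s$c1 > -1 / max(h), logical(1))
  if (sum(admissible) != 1L)
    stop("calibration is ambiguous or inadmissible: found ",
         length(solutions), " root(s), of which ", sum(admissible),
         " admissible (c < 0). Roots at c1 = ",
         paste(format(roots, digits = 6), collapse = ", "))
  s <- solutions[[which(admissible)]]
  model_coefficients(s$c1, s$c2_bar, s$c,
                     provenance = paste0("triplet: ",
                                         paste(cohort$id, collapse = ", ")))
}

#' Sensitivity of predicted life to body-mass change
#'
#' Durability scales as `Q^(1/c)`, so a mass change from `Q` to
#' `Q + delta_Q` multiplies predicted life by `((Q + delta_Q)/Q)^(1/c)`
#' exactly -- the other factors cancel.
#'
#' @param Q current body mass, kg (> 0).
#' @param delta_Q mass change, kg; `Q + delta_Q` must stay positive.
#' @param coeffs a [model_coefficients()] triple (only `c` is used).
#' @return Percent change in predicted life.
#' @export
#' @examples
#' sensitivity_mass(60, -10)   # ~ +8.7 % after losing 10 kg
sensitivity_mass <- function(Q, delta_Q, coeffs = published_coefficients()) {
  stopifnot(inherits(coeffs, "model_coefficients"))
  if (any(Q <= 0) || any(Q + delta_Q <= 0))
    stop("body mass must remain positive")
  100 * ((Q + delta_Q) / Q)^(1 / coeffs$c) - 100
}

#' Sensitivity of predicted life to activity change
#'
#' Durability scales as `1/T`, independent of the fitted exponent:
#' the percent change is `100 * T / (T + delta_T) - 100`.
#'
#' @param T current daily activity, hours/day (> 0).
#' @param delta_T activity change, hours/day; `T + delta_T` must stay
#'   positive.
#' @return Percent change in predicted life.
#' @export
#' @examples
#' sensitivity_activity(4, -1)  # +33.3 % after one hour less per day
sensitivity_activity <- function(T, delta_T) {
  if (any(T <= 0) || any(T + delta_T <= 0))
    stop("daily activity must remain positive")
  100 * T / (T + delta_T) - 100
}

#' Sensitivity tables for mass and activity
#'
#' Tabulate the exact percent life change after gaining/losing
#' `delta` (kg or hours/day) over a grid of baselines, rounded to one
#' decimal as conventionally reported.
#'
#' @param baselines grid of current masses (kg) or activities (h/day).
#' @param delta magnitude of the change (kg or h/day).
#' @param coeffs a [model_coefficients()] triple (mass table only).
#' @return A data.frame with the baseline, percent gain after a decrease,
#'   and percent loss after an increase.
#' @export
sensitivity_table_mass <- function(baselines = seq(50, 100, by = 10),
                                   delta = 10,
                                   coeffs = published_coefficients()) {
  data.frame(mass_kg = baselines,
             gain_after_loss_pct =
               round(sensitivity_mass(baselines, -delta, coeffs), 1),
             loss_after_gain_pct =
               round(-sensitivity_mass(baselines, delta, coeffs), 1))
}

#' @rdname sensitivity_table_mass
#' @export
sensitivity_table_activity <- function(baselines = seq(3, 6, by = 0.5),
                                       delta = 1) {
  data.frame(activity_h_per_day = baselines,
             gain_after_decrease_pct =
               round(sensitivity_activity(baselines, -delta), 1),
             loss_after_increase_pct =
               round(-sensitivity_activity(baselines, delta), 1))
}

#' Durability over a two-variable grid
#'
#' Evaluates [predict_months()] on the outer grid of two varied inputs
#' with the remaining two fixed, e.g. life as a function of `(Q, T)` at
#' fixed `h` and `K`.  Since `c < 0`, durability decreases monotonically
#' along every axis.
#'
#' @param coeffs a [model_coefficients()] triple.
#' @param vary character vector of the two varied variables, a subset of
#'   `c("Q", "K", "h", "T")`.
#' @param values1,values2 grids for the first and second varied variable.
#' @param fixed named list giving the two fixed variables.
#' @return A matrix of predicted months (`values1` in rows, `values2` in
#'   columns) with a `vars` attribute.
#' @export
#' @examples
#' durability_surface(published_coefficients(), vary = c("Q", "T"),
#'                    values1 = c(50, 100), values2 = c(3, 6),
#'                    fixed = list(h = 30, K = 4))
durability_surface <- function(coeffs, vary, values1, values2, fixed) {
  all_vars <- c("Q", "K", "h", "T")
  stopifnot(length(vary) == 2L, all(vary %in% all_vars))
  need <- setdiff(all_vars, vary)
  if (!all(need %in% names(fixed)))
    stop("fixed must name the remaining variables: ",
         paste(need, collapse = ", "))
  grid <- expand.grid(v1 = values1, v2 = values2)
  args <- list(Q = NULL, K = NULL, h = NULL, T = NULL)
  args[[vary[1]]] <- grid$v1
  args[[vary[2]]] <- grid$v2
  for (v in need) args[[v]] <- fixed[[v]]
  months <- predict_months(args$Q, args$K, args$h, args$T, coeffs)
  out <- matrix(months, nrow = length(values1),
                dimnames = list(as.character(values1), as.character(values2)))
  attr(out, "vars") <- vary
  out
}

#' Serialize / deserialize model coefficients
#'
#' @param coeffs a [model_coefficients()] triple.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @return JSON string (or `path` invisibly); `coefficients_from_json()`
#'   returns a [model_coefficients()] object.
#' @export
coefficients_to_json <- function(coeffs, path = NULL) {
  stopifnot(inherits(coeffs, "model_coefficients"))
  json <- jsonlite::toJSON(unclass(coeffs), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname coefficients_to_json
#' @param json JSON string or path to a JSON file.
#' @export
coefficients_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  model_coefficients(x$c1, x$c2_bar, x$c,
                     provenance = x$provenance %||% "json")
}
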