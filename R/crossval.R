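# Triplet cross-validation: calibrate the three-parameter law on three
# patients, evaluate it on everyone else, repeat over many triplets,
# and summarise error metrics and parameter spread.  This is the
# natural validation scheme for a model whose coefficients are
# identified exactly from three records.

#' Run triplet cross-validation
#'
#' Each run calibrates the coefficient triple on three patients (their
#' recorded months), predicts durability for all remaining patients, and
#' scores the predictions with [metric_set()].  Triplets are either
#' given explicitly (a list of 3-id vectors) or drawn at random: each
#' run samples three distinct patients, independently across runs (the
#' same patient may recur in different runs), reproducibly under `seed`.
#' Runs whose calibration fails (degenerate triplet, no admissible root)
#' are flagged and skipped with a warning; an error is raised only if
#' every run fails.
#'
#' @param cohort a `hip_cohort` with recorded months, at least 4
#'   patients.
#' @param triplets optional list of character/numeric 3-vectors of
#'   patient ids.
#' @param n_runs number of random runs when `triplets` is `NULL`.
#' @param seed RNG seed for random triplet selection.
#' @param mapping an [activity_mapping()] for rows lacking `K`.
#' @return A `cv_runs` list of per-run records: `run`, `triplet_ids`,
#'   `coefficients`, `metrics`, `failed`, `message`.
#' @seealso [summarize_cv()], [published_triplet_cv()]
#' @export
run_cv <- function(cohort, triplets = NULL, n_runs = 10, seed = 1L,
                   mapping = activity_mapping()) {
  stopifnot(inherits(cohort, "hip_cohort"))
  if (nrow(cohort) < 4L)
    stop("cross-validation needs at least 4 patients")
  if (anyNA(cohort$months_recorded))
    stop("cross-validation requires recorded months for every patient")
  if (is.null(triplets)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    triplets <- replicate(n_runs, sample(cohort$id, 3L), simplify = FALSE)
  } else {
    triplets <- lapply(triplets, as.character)
    if (any(vapply(triplets, length, 1L) != 3L))
      stop("each triplet must contain exactly three patient ids")
  }
  runs <- lapply(seq_along(triplets), function(i) {
    ids <- triplets[[i]]
    held_out <- cohort_subset(cohort, setdiff(cohort$id, ids))
    tryCatch({
      coeffs <- calibrate_triplet(cohort, ids = ids, mapping = mapping)
      held_out <- predict_cohort(held_out, coeffs, mapping)
      list(run = i, triplet_ids = ids, coefficients = coeffs,
           metrics = metric_set(held_out$months_predicted,
                                held_out$months_recorded),
           failed = FALSE, message = NA_character_)
    }, error = function(e) {
      warning(sprintf("run %d (triplet %s) failed: %s", i,
                      paste(ids, collapse = ","), conditionMessage(e)),
              call. = FALSE)
      list(run = i, triplet_ids = ids, coefficients = NULL, metrics = NULL,
           failed = TRUE, message = conditionMessage(e))
    })
  })
  if (all(vapply(runs, `[[`, logical(1), "failed")))
    stop("all cross-validation runs failed")
  structure(runs, class = "cv_runs")
}

#' @export
print.cv_runs <- function(x, ...) {
  ok <- !vapply(x, `[[`, logical(1), "failed")
  cat(sprintf("<cv_runs> %d runs (%d failed)\n", length(x), sum(!ok)))
  for (r in x) {
    if (r$failed) {
      cat(sprintf("  run %2d [%s]: FAILED (%s)\n", r$run,
                  paste(r$triplet_ids, collapse = ", "), r$message))
    } else {
      cat(sprintf("  run %2d [%s]: c1=%.6g c2_bar=%.6g c=%.6g RMSE=%.4g\n",
                  r$run, paste(r$triplet_ids, collapse = ", "),
                  r$coefficients$c1, r$coefficients$c2_bar,
                  r$coefficients$c, r$metrics$rmse))
    }
  }
  invisible(x)
}

#' Tabulate cross-validation runs
#'
#' One row per successful run: triplet ids, the three calibrated
#' parameters, and the full metric set.
#'
#' @param runs a `cv_runs` object.
#' @return A data.frame.
#' @export
cv_table <- function(runs) {
  stopifnot(inherits(runs, "cv_runs"))
  ok <- Filter(function(r) !r$failed, runs)
  do.call(rbind, lapply(ok, function(r) {
    data.frame(run = r$run,
               triplet = paste(r$triplet_ids, collapse = ", "),
               c1 = r$coefficients$c1, c2_bar = r$coefficients$c2_bar,
               c = r$coefficients$c,
               as.data.frame(unclass(r$metrics)))
  }))
}

#' Summarise cross-validation runs
#'
#' Mean and sample SD of every metric across successful runs, and for
#' each parameter the mean, SD and a 95% confidence interval
#' `mean +/- t(0.975, runs - 1) * SD / sqrt(runs)`.
#'
#' @param runs a `cv_runs` object with at least 2 successful runs.
#' @return A `cv_summary`: `metrics` (data.frame metric/mean/sd),
#'   `parameters` (data.frame parameter/mean/sd/ci_lower/ci_upper),
#'   `n_runs`, `n_failed`.
#' @export
summarize_cv <- function(runs) {
  stopifnot(inherits(runs, "cv_runs"))
  tab <- cv_table(runs)
  if (nrow(tab) < 2L)
    stop("summary needs at least 2 successful runs")
  metric_cols <- setdiff(names(tab), c("run", "triplet", "c1", "c2_bar", "c"))
  metrics <- data.frame(metric = metric_cols,
                        mean = vapply(tab[metric_cols], mean, 1),
                        sd = vapply(tab[metric_cols], sd, 1),
                        row.names = NULL)
  n <- nrow(tab)
  tq <- qt(0.975, df = n - 1)
  par_cols <- c("c1", "c2_bar", "c")
  parameters <- data.frame(
    parameter = par_cols,
    mean = vapply(tab[par_cols], mean, 1),
    sd = vapply(tab[par_cols], sd, 1),
    row.names = NULL)
  parameters$ci_lower <- parameters$mean - tq * parameters$sd / sqrt(n)
  parameters$ci_upper <- parameters$mean + tq * parameters$sd / sqrt(n)
  structure(list(metrics = metrics, parameters = parameters,
                 n_runs = n, n_failed = length(runs) - n),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("<cv_summary> %d runs (%d failed)\n", x$n_runs + x$n_failed,
              x$n_failed))
  cat("  metrics (mean / sd):\n")
  print(x$metrics, row.names = FALSE, digits = 5)
  cat("  parameters (mean / sd / 95% CI):\n")
  print(x$parameters, row.names = FALSE, digits = 5)
  invisible(x)
}

#' The ten published cross-validation triplets
#'
#' The ten random triplets used in the published cross-validation of the
#' reference cohort.
#'
#' @return A list of ten character 3-vectors of patient ids.
#' @export
published_cv_triplets <- function() {
  lapply(list(c(3, 9, 17), c(1, 5, 18), c(12, 14, 15), c(2, 7, 11),
              c(1, 5, 10), c(4, 11, 17), c(1, 7, 8), c(5, 11, 18),
              c(1, 2, 16), c(3, 13, 16)),
         as.character)
}

#' Re-run the published cross-validation
#'
#' Runs [run_cv()] on the reference cohort (or any 18-patient cohort
#' with the same ids) over the ten published triplets and returns the
#' per-run table.
#'
#' @param cohort a `hip_cohort`; defaults to [reference_cohort()].
#' @return A data.frame, one row per run (see [cv_table()]).
#' @export
published_triplet_cv <- function(cohort = reference_cohort()) {
  cv_table(run_cv(cohort, triplets = published_cv_triplets()))
}
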