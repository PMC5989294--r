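# Cohort container and CSV exchange.
#
# A cohort is a plain data.frame with canonical columns and class
# "hip_cohort"; `provenance` is carried as an attribute so that round
# trips through CSV stay field-for-field identical.

.cohort_columns <- c("id", "age", "sex", "mass_kg", "activity_h_per_day",
                     "offset_mm", "score", "K",
                     "months_recorded", "months_predicted")
.cohort_mandatory <- c("id", "mass_kg", "activity_h_per_day", "offset_mm")
.cohort_numeric <- c("age", "mass_kg", "activity_h_per_day", "offset_mm",
                     "score", "K", "months_recorded", "months_predicted")

#' Construct a patient cohort
#'
#' Assembles (and validates) a cohort from per-patient vectors.  Mandatory
#' fields are `id`, `mass_kg`, `activity_h_per_day` and `offset_mm`; the
#' rest may be `NA`.  Invariants enforced: positive mass, activity and
#' offset; activity scores inside `[0, 1]`; unique, non-missing ids.
#'
#' @param id patient identifiers (coerced to character, must be unique).
#' @param mass_kg body mass `Q` in kilograms.
#' @param activity_h_per_day daily walking activity `T` in hours per day.
#' @param offset_mm femoral offset `h` in millimeters.
#' @param age,sex optional demographics (`sex` in `{"F","M"}`).
#' @param score optional normalized activity score `s` in `[0, 1]`.
#' @param K optional load coefficient (dimensionless multiple of body
#'   weight); if absent it can be derived from `score` at prediction time.
#' @param months_recorded,months_predicted optional durability columns in
#'   months.
#' @param provenance free-text origin tag (file path, `"reference"`,
#'   `"synthetic:<seed>"`).
#' @return A `hip_cohort` data.frame.
#' @seealso [read_cohort()], [reference_cohort()], [synthesize_cohort()]
#' @export
#' @examples
#' new_cohort(id = "a", mass_kg = 70, activity_h_per_day = 4,
#'            offset_mm = 30, K = 4)
new_cohort <- function(id, mass_kg, activity_h_per_day, offset_mm,
                       age = NA_real_, sex = NA_character_,
                       score = NA_real_, K = NA_real_,
                       months_recorded = NA_real_,
                       months_predicted = NA_real_,
                       provenance = "constructed") {
  n <- length(id)
  d <- data.frame(id = as.character(id),
                  age = rep_len(as.numeric(age), n),
                  sex = rep_len(as.character(sex), n),
                  mass_kg = rep_len(as.numeric(mass_kg), n),
                  activity_h_per_day = rep_len(as.numeric(activity_h_per_day), n),
                  offset_mm = rep_len(as.numeric(offset_mm), n),
                  score = rep_len(as.numeric(score), n),
                  K = rep_len(as.numeric(K), n),
                  months_recorded = rep_len(as.numeric(months_recorded), n),
                  months_predicted = rep_len(as.numeric(months_predicted), n),
                  stringsAsFactors = FALSE)
  validate_cohort(d)
  structure(d, provenance = provenance,
            class = c("hip_cohort", "data.frame"))
}

# Row-indexed invariant checks shared by all constructors/readers.
validate_cohort <- function(d) {
  if (nrow(d) == 0L)
    stop("cohort is empty: at least one patient record is required")
  if (anyNA(d$id) || any(!nzchar(d$id)))
    stop("cohort ids must be non-missing and non-empty")
  if (anyDuplicated(d$id))
    stop("cohort ids must be unique; duplicated: ",
         paste(unique(d$id[duplicated(d$id)]), collapse = ", "))
  bad_row <- function(ok, what) {
    if (any(!ok)) stop(sprintf("row(s) %s: %s",
                               paste(which(!ok), collapse = ", "), what))
  }
  bad_row(!is.na(d$mass_kg) & d$mass_kg > 0,
          "mass_kg must be present and > 0")
  bad_row(!is.na(d$activity_h_per_day) & d$activity_h_per_day > 0,
          "activity_h_per_day must be present and > 0")
  bad_row(!is.na(d$offset_mm) & d$offset_mm > 0,
          "offset_mm must be present and > 0")
  bad_row(is.na(d$score) | (d$score >= 0 & d$score <= 1),
          "score must lie in [0, 1]")
  bad_row(is.na(d$sex) | d$sex %in% c("F", "M"),
          "sex must be 'F' or 'M' when present")
  invisible(d)
}

#' @export
print.hip_cohort <- function(x, ...) {
  cat(sprintf("<hip_cohort> %d patients (provenance: %s)\n",
              nrow(x), attr(x, "provenance") %||% "unknown"))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a patient cohort from CSV
#'
#' Expects a comma-separated, UTF-8 file with a header row using the
#' canonical column names `id, age, sex, mass_kg, activity_h_per_day,
#' offset_mm, score, K, months_recorded` (and optionally
#' `months_predicted`); missing optional values are empty cells.  Rows
#' violating the cohort invariants abort with a row-indexed message.
#'
#' @param path CSV file path.
#' @return A `hip_cohort`, provenance set to `path`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  check.names = TRUE, colClasses = "character")
  missing_cols <- setdiff(.cohort_mandatory, names(raw))
  if (length(missing_cols))
    stop("cohort schema error: missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L)
    stop("cohort file has a header but no data rows: ", path)
  for (col in setdiff(.cohort_columns, names(raw)))
    raw[[col]] <- NA_character_
  d <- raw[.cohort_columns]
  for (col in .cohort_numeric) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad))
      stop(sprintf("parse error in column '%s', row(s) %s: non-numeric value",
                   col, paste(bad, collapse = ", ")))
    d[[col]] <- v
  }
  validate_cohort(d)
  structure(d, provenance = path, class = c("hip_cohort", "data.frame"))
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort()]: canonical column order, empty cells for
#' missing optional values, `.` decimal separator.
#'
#' @param cohort a `hip_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "hip_cohort"))
  write.csv(as.data.frame(cohort)[.cohort_columns], path,
            row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' The published 18-patient reference cohort
#'
#' The retrospective cohort of 18 total-hip-arthroplasty patients
#' (non-cemented hydroxyapatite-coated RCM femoral stems, all revised for
#' aseptic loosening) on which the model was calibrated and assessed.
#' Patients 16--18 are the calibration triplet (their recorded and
#' model-calculated durabilities coincide); patients 1--15 are the
#' held-out assessment group.  `months_predicted` holds the published
#' model-calculated durability, `months_recorded` the observed one.
#'
#' @param subset `"all"` (18 patients), `"assessment15"` (patients 1--15)
#'   or `"calibration3"` (patients 16--18).
#' @return A `hip_cohort`, provenance `"reference"`.
#' @export
#' @examples
#' reference_cohort("calibration3")$months_recorded  # 253 192 288
reference_cohort <- function(subset = c("all", "assessment15", "calibration3")) {
  subset <- match.arg(subset)
  path <- system.file("extdata", "reference_cohort.csv", package = "hiplife",
                      mustWork = TRUE)
  cohort <- read_cohort(path)
  attr(cohort, "provenance") <- "reference"
  keep <- switch(subset,
                 all = seq_len(18),
                 assessment15 = 1:15,
                 calibration3 = 16:18)
  sub <- cohort[keep, , drop = FALSE]
  rownames(sub) <- NULL
  attr(sub, "provenance") <- "reference"
  class(sub) <- c("hip_cohort", "data.frame")
  sub
}

#' Select patients by id
#'
#' @param cohort a `hip_cohort`.
#' @param ids character (or coercible) vector of patient ids.
#' @return The sub-cohort in the order of `ids`.
#' @export
cohort_subset <- function(cohort, ids) {
  ids <- as.character(ids)
  idx <- match(ids, cohort$id)
  if (anyNA(idx))
    stop("unknown patient id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  sub <- cohort[idx, , drop = FALSE]
  rownames(sub) <- NULL
  attr(sub, "provenance") <- attr(cohort, "provenance")
  class(sub) <- c("hip_cohort", "data.frame")
  sub
}
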