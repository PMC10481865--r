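#' @keywords internal
"_PACKAGE"

# Canonical cohort CSV column order. Heights are stored in cm throughout the
# package; individual prediction formulas convert units internally.
cohort_columns <- c(
  "id", "sex", "age_years", "weight_kg", "height_cm", "knee_height_cm",
  "tsf_mm", "arm_circumference_cm", "feeding", "bmi_zscore",
  "ree_kcal_day", "rq", "intake_kcal_day"
)

cohort_required_columns <- c("id", "sex", "age_years", "weight_kg")

sex_levels <- c("male", "female")
feeding_levels <- c("oral", "enteral", "mixed")

#' Construct a cohort of subject records
#'
#' A cohort is a data frame with one row per child and a fixed column schema:
#' `id`, `sex` (`"male"`/`"female"`), `age_years`, `weight_kg`, `height_cm`,
#' `knee_height_cm`, `tsf_mm`, `arm_circumference_cm`, `feeding`
#' (`"oral"`/`"enteral"`/`"mixed"`), `bmi_zscore`, `ree_kcal_day` (REE measured
#' by indirect calorimetry), `rq` (respiratory quotient) and `intake_kcal_day`.
#' Optional fields are `NA` when absent. Subject-level invariants (positive
#' weight, age in \[0, 19\], positive skinfold and height where present, RQ in
#' (0.5, 1.3)) are checked on construction.
#'
#' @param subjects data frame holding at least `id`, `sex`, `age_years` and
#'   `weight_kg`; any missing optional columns are added as `NA`.
#' @param provenance character scalar recording where the cohort came from
#'   (source file or generator seed).
#' @return An object of class `cohort` (a data frame).
#' @examples
#' cohort(data.frame(id = "A", sex = "male", age_years = 9, weight_kg = 19.5))
#' @export
cohort <- function(subjects, provenance = "constructed") {
  stopifnot(is.data.frame(subjects))
  missing_req <- setdiff(cohort_required_columns, names(subjects))
  if (length(missing_req) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(cohort_columns, names(subjects))) {
    subjects[[col]] <- rep(if (col %in% c("sex", "feeding")) NA_character_ else NA_real_,
                           nrow(subjects))
  }
  subjects <- subjects[, cohort_columns, drop = FALSE]
  subjects$id <- as.character(subjects$id)
  subjects$sex <- as.character(subjects$sex)
  subjects$feeding <- as.character(subjects$feeding)
  num_cols <- setdiff(cohort_columns, c("id", "sex", "feeding"))
  for (col in num_cols) subjects[[col]] <- as.numeric(subjects[[col]])
  problems <- validate_subjects(subjects)
  if (length(problems) > 0) {
    stop("invalid cohort:\n  ", paste(problems, collapse = "\n  "), call. = FALSE)
  }
  rownames(subjects) <- NULL
  structure(subjects, provenance = provenance,
            class = c("cohort", "data.frame"))
}

# Row-level invariant checks; returns a character vector of problems
# ("row <i>: <message>"), empty when the table is valid.
validate_subjects <- function(df) {
  problems <- character(0)
  note <- function(rows, msg) {
    if (any(rows)) sprintf("row %d: %s", which(rows), msg) else character(0)
  }
  if (anyDuplicated(df$id)) {
    dup <- unique(df$id[duplicated(df$id)])
    problems <- c(problems, paste0("duplicate id(s): ", paste(dup, collapse = ", ")))
  }
  problems <- c(
    problems,
    note(is.na(df$sex) | !(df$sex %in% sex_levels), "sex must be 'male' or 'female'"),
    note(is.na(df$age_years) | df$age_years < 0 | df$age_years > 19,
         "age_years must lie in [0, 19]"),
    note(is.na(df$weight_kg) | df$weight_kg <= 0, "weight_kg must be positive"),
    note(!is.na(df$height_cm) & df$height_cm <= 0, "height_cm must be positive"),
    note(!is.na(df$knee_height_cm) & df$knee_height_cm <= 0,
         "knee_height_cm must be positive"),
    note(!is.na(df$tsf_mm) & df$tsf_mm <= 0, "tsf_mm must be positive"),
    note(!is.na(df$feeding) & !(df$feeding %in% feeding_levels),
         "feeding must be 'oral', 'enteral' or 'mixed'"),
    note(!is.na(df$rq) & (df$rq <= 0.5 | df$rq >= 1.3), "rq must lie in (0.5, 1.3)"),
    note(!is.na(df$ree_kcal_day) & df$ree_kcal_day <= 0,
         "ree_kcal_day must be positive")
  )
  problems
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (provenance: %s)\n",
              nrow(x), attr(x, "provenance") %||% "unknown"))
  print(as.data.frame(x), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort from CSV
#'
#' Reads a comma-separated, UTF-8, `.`-decimal cohort file with a header row
#' (the schema written by [write_cohort_csv()]). Empty cells become `NA`
#' (absent optional fields). All subject invariants are validated; violations
#' are reported with their row numbers.
#'
#' @param path path to an existing CSV file.
#' @return A [cohort()].
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  missing_req <- setdiff(cohort_required_columns, names(df))
  if (length(missing_req) > 0) {
    stop("cohort CSV is missing required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  num_cols <- intersect(setdiff(cohort_columns, c("id", "sex", "feeding")), names(df))
  for (col in num_cols) {
    raw <- df[[col]]
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(parsed)
    if (any(bad)) {
      stop(sprintf("unparseable numeric in column '%s', row(s) %s", col,
                   paste(which(bad), collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- parsed
  }
  cohort(df, provenance = path)
}

#' Write a cohort to CSV
#'
#' Writes the fixed 13-column schema in canonical order; absent optional
#' values become empty cells. Round-trips losslessly through
#' [read_cohort_csv()].
#'
#' @param x a [cohort()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(as.data.frame(x)[, cohort_columns, drop = FALSE],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Estimate standing height from knee height
#'
#' Stature in children who cannot stand is estimated from the knee-height
#' segment as `2.69 * kh + 24.2` (cm).
#'
#' @param kh knee height in cm (positive; vectorised).
#' @return Estimated height in cm.
#' @examples
#' height_from_knee_height(40) # 131.8
#' @export
height_from_knee_height <- function(kh) {
  if (!is.numeric(kh) || any(!is.finite(kh)) || any(kh <= 0)) {
    stop("knee height must be a positive finite number (cm)", call. = FALSE)
  }
  2.69 * kh + 24.2
}

#' Body mass index
#'
#' @param weight weight in kg (positive).
#' @param height height in cm (positive).
#' @return BMI in kg/m^2.
#' @examples
#' bmi(20, 100) # 20
#' @export
bmi <- function(weight, height) {
  if (!is.numeric(weight) || any(!is.finite(weight)) || any(weight <= 0)) {
    stop("weight must be positive (kg)", call. = FALSE)
  }
  if (!is.numeric(height) || any(!is.finite(height)) || any(height <= 0)) {
    stop("height must be positive (cm)", call. = FALSE)
  }
  weight / (height / 100)^2
}

#' Classify nutritional status from a BMI z-score
#'
#' Two groups are contrasted: group 1 pools moderate and severe malnutrition
#' (z-score <= -2); group 2 pools mild malnutrition, normal status and
#' overweight/obesity (z-score >= -1). Scores strictly between -2 and -1 fall
#' in neither published interval and are returned as `"unassigned"`.
#'
#' @param bmi_zscore finite numeric vector of BMI-for-age z-scores.
#' @return Character vector with values `"group1"`, `"group2"`, `"unassigned"`.
#' @examples
#' classify_nutrition_group(c(-2.5, -0.5, -1.5))
#' @export
classify_nutrition_group <- function(bmi_zscore) {
  if (!is.numeric(bmi_zscore) || any(!is.finite(bmi_zscore))) {
    stop("bmi_zscore must be finite numeric", call. = FALSE)
  }
  ifelse(bmi_zscore <= -2, "group1",
         ifelse(bmi_zscore >= -1, "group2", "unassigned"))
}

#' Exclude subjects with implausibly low measured REE
#'
#' Removes subjects whose calorimetry REE falls below `min_ree`; such extreme
#' values (e.g. severe chronic malnutrition) distort the method-comparison
#' conversion equations and the model fit. Subjects without a measured REE are
#' kept. Removals are reported via `message()` with their ids.
#'
#' @param x a [cohort()].
#' @param min_ree exclusion threshold in kcal/day (positive). The default of
#'   300 kcal/day separates physiologically implausible measurements from the
#'   plausible range in this population.
#' @return The filtered [cohort()].
#' @export
exclude_extreme_ree <- function(x, min_ree = 300) {
  stopifnot(inherits(x, "cohort"))
  if (!is.numeric(min_ree) || length(min_ree) != 1 || min_ree <= 0) {
    stop("min_ree must be a positive scalar (kcal/day)", call. = FALSE)
  }
  drop <- !is.na(x$ree_kcal_day) & x$ree_kcal_day < min_ree
  if (any(drop)) {
    message(sprintf("excluding %d subject(s) with REE < %g kcal/day: %s",
                    sum(drop), min_ree, paste(x$id[drop], collapse = ", ")))
  }
  out <- x[!drop, , drop = FALSE]
  if (nrow(out) == 0) warning("all subjects excluded", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(x, "provenance")
  class(out) <- c("cohort", "data.frame")
  out
}
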