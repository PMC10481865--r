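# Age-band coefficient tables for the banded weight (and weight+height)
# equations. Bands are half-open: [0,3), [3,10), [10,18), [18,30); dispatch
# raises beyond 30 years. Columns: wt coefficient, intercept (weight-only
# forms) or wt, ht (metres), intercept (Schofield weight & height).
banded_wt_coefs <- list(
  WHO = list(
    male   = rbind(c(60.9, -54), c(22.7, 495), c(17.5, 651), c(15.3, 679)),
    female = rbind(c(61.0, -51), c(22.5, 499), c(12.2, 746), c(14.7, 496))
  ),
  SCHOFIELD_W = list(
    male   = rbind(c(59.5, -30.4), c(22.7, 504.3), c(17.7, 658.2), c(15.0, 692.1)),
    female = rbind(c(58.3, -31.1), c(20.3, 485.9), c(13.4, 692.6), c(14.8, 486.6))
  ),
  OXFORD = list(
    male   = rbind(c(61.0, -33.7), c(23.3, 514), c(18.4, 581), c(16.0, 545)),
    female = rbind(c(58.9, -23.1), c(20.1, 507), c(11.1, 761), c(13.1, 558))
  )
)

# Schofield weight & height, height in METRES (the ht coefficients are on the
# metre scale). The male <3 y weight coefficient circulates in print as 1.67;
# the original Schofield value is 0.167 and is the default here (`as_printed`
# switches to 1.67).
schofield_wh_coefs <- list(
  male   = rbind(c(0.167, 1517, -618), c(19.6, 130, 415),
                 c(16.2, 137, 516), c(15.0, -10, 706)),
  female = rbind(c(16.2, 1023, -413), c(17.0, 162, 317),
                 c(8.4, 466, 200), c(13.6, 283, 98))
)

#' REE prediction formula identifiers
#'
#' The closed set of supported equations: `WHO`, `SCHOFIELD_W` (weight only),
#' `SCHOFIELD_WH` (weight and height), `HARRIS_BENEDICT`, `OXFORD`, `MIFFLIN`,
#' `CP_PRELIMINARY` (the weight-only population-specific formula
#' `24*weight + 380`) and `CP_FINAL` (the weight + triceps-skinfold model
#' `28.43*weight - 17*tsf + 398.2`).
#'
#' @return Character vector of formula ids.
#' @export
formula_ids <- function() {
  c("WHO", "SCHOFIELD_W", "SCHOFIELD_WH", "HARRIS_BENEDICT", "OXFORD",
    "MIFFLIN", "CP_PRELIMINARY", "CP_FINAL")
}

age_band <- function(age) {
  if (!is.finite(age) || age < 0) stop("age must be a non-negative number", call. = FALSE)
  if (age >= 30) {
    stop("age ", age, " is outside the supported bands [0, 30)", call. = FALSE)
  }
  findInterval(age, c(0, 3, 10, 18))
}

#' Predict resting energy expenditure with a named equation
#'
#' Evaluates one of the equations listed by [formula_ids()]. The banded
#' formulas (WHO, both Schofield forms, Oxford) dispatch on half-open age
#' bands \[0,3), \[3,10), \[10,18), \[18,30) and raise beyond 30 years.
#' Heights are supplied in cm; `SCHOFIELD_WH` converts to metres internally
#' (its height coefficients are on the metre scale) while Harris-Benedict and
#' Mifflin use cm directly. `CP_FINAL` requires the triceps skinfold.
#'
#' @param formula one of [formula_ids()].
#' @param sex `"male"` or `"female"` (ignored by the two CP formulas).
#' @param age age in years (needed by all but the CP formulas).
#' @param weight weight in kg.
#' @param height height in cm (required by `SCHOFIELD_WH`, `HARRIS_BENEDICT`,
#'   `MIFFLIN`).
#' @param tsf triceps skinfold in mm (required by `CP_FINAL`).
#' @param as_printed if `TRUE`, use the widely reprinted 1.67 weight
#'   coefficient for Schofield weight & height, males under 3 years, instead
#'   of the original 0.167.
#' @return Predicted REE in kcal/day.
#' @examples
#' predict_ree("WHO", sex = "male", age = 5, weight = 20) # 949
#' predict_ree("CP_FINAL", weight = 19.7, tsf = 7.8) # 825.67
#' @export
predict_ree <- function(formula, sex = NULL, age = NULL, weight,
                        height = NULL, tsf = NULL, as_printed = FALSE) {
  formula <- match.arg(formula, formula_ids())
  if (!is.numeric(weight) || length(weight) != 1 || !is.finite(weight) || weight <= 0) {
    stop("weight must be a positive scalar (kg)", call. = FALSE)
  }
  if (formula == "CP_PRELIMINARY") return(24 * weight + 380)
  if (formula == "CP_FINAL") {
    if (is.null(tsf)) stop("CP_FINAL requires tsf (mm)", call. = FALSE)
    if (!is.finite(tsf) || tsf <= 0) stop("tsf must be positive (mm)", call. = FALSE)
    return(28.43 * weight - 17 * tsf + 398.2)
  }
  if (is.null(sex) || !(sex %in% sex_levels)) {
    stop(formula, " requires sex ('male' or 'female')", call. = FALSE)
  }
  if (is.null(age) || !is.finite(age)) stop(formula, " requires age (years)", call. = FALSE)
  needs_height <- formula %in% c("SCHOFIELD_WH", "HARRIS_BENEDICT", "MIFFLIN")
  if (needs_height) {
    if (is.null(height) || !is.finite(height) || height <= 0) {
      stop(formula, " requires height (cm)", call. = FALSE)
    }
  }
  switch(formula,
    WHO = , SCHOFIELD_W = , OXFORD = {
      b <- banded_wt_coefs[[formula]][[sex]][age_band(age), ]
      b[1] * weight + b[2]
    },
    SCHOFIELD_WH = {
      b <- schofield_wh_coefs[[sex]][age_band(age), ]
      if (as_printed && sex == "male" && age < 3) b[1] <- 1.67
      b[1] * weight + b[2] * (height / 100) + b[3]
    },
    HARRIS_BENEDICT = {
      if (sex == "male") 66.47 + 13.75 * weight + 5.0 * height - 6.76 * age
      else 655.10 + 9.56 * weight + 1.85 * height - 4.68 * age
    },
    MIFFLIN = {
      base <- 9.99 * weight + 6.25 * height - 4.92 * age
      if (sex == "male") base + 5 else base - 161
    }
  )
}

#' Predict REE for every subject and formula
#'
#' Evaluates each requested formula on each cohort subject. Where a subject
#' lacks a measured height but has a knee height, stature is imputed with
#' [height_from_knee_height()]. Subjects that do not satisfy a formula's
#' requirements get an `NA` prediction with the failure reason in `status`,
#' never a zero.
#'
#' @param x a [cohort()].
#' @param formulas subset of [formula_ids()] (default all eight).
#' @param as_printed passed to [predict_ree()].
#' @return A data frame with columns `id`, `formula`, `ree_kcal_day`,
#'   `status` (`"ok"` or the failure reason), one row per subject-formula
#'   pair, in cohort then formula order.
#' @export
predict_all <- function(x, formulas = formula_ids(), as_printed = FALSE) {
  stopifnot(inherits(x, "cohort"))
  if (length(formulas) == 0) stop("empty formula set", call. = FALSE)
  formulas <- vapply(formulas, function(f) match.arg(f, formula_ids()), "")
  rows <- vector("list", nrow(x) * length(formulas))
  k <- 0
  for (i in seq_len(nrow(x))) {
    s <- x[i, ]
    height <- if (!is.na(s$height_cm)) {
      s$height_cm
    } else if (!is.na(s$knee_height_cm)) {
      height_from_knee_height(s$knee_height_cm)
    } else NULL
    tsf <- if (!is.na(s$tsf_mm)) s$tsf_mm else NULL
    for (f in formulas) {
      k <- k + 1
      res <- tryCatch(
        list(value = predict_ree(f, sex = s$sex, age = s$age_years,
                                 weight = s$weight_kg, height = height,
                                 tsf = tsf, as_printed = as_printed),
             status = "ok"),
        error = function(e) list(value = NA_real_, status = conditionMessage(e))
      )
      rows[[k]] <- data.frame(id = s$id, formula = f,
                              ree_kcal_day = res$value, status = res$status,
                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(id = character(0), formula = character(0),
                      ree_kcal_day = numeric(0), status = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
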