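#' Bland-Altman analysis with a proportional-bias test
#'
#' Differences are oriented as formula minus calorimetry: `D = y1 - y2`,
#' `A = (y1 + y2)/2`. Classic limits of agreement are `mean(D) +/- 1.96 *
#' sd(D)`. Proportional bias is assessed by the Pearson correlation between
#' the differences and the averages with a two-sided test; a significant
#' negative correlation means the formula increasingly underestimates at
#' higher REE.
#'
#' @param y1 numeric vector of formula estimates, kcal/day.
#' @param y2 numeric vector of calorimetry measurements, kcal/day (same
#'   length, n >= 3, no missing values).
#' @param ids optional subject ids (for reporting only).
#' @return A list of class `bland_altman` with `mean_bias`, `classic_loa`
#'   (lower, upper), `pearson_r_bias_vs_mean`, `p_value`, `n`.
#' @export
bland_altman <- function(y1, y2, ids = NULL) {
  check_pairs(y1, y2)
  d <- y1 - y2
  a <- (y1 + y2) / 2
  if (stats::var(a) == 0) stop("zero variance in the averages; correlation undefined",
                               call. = FALSE)
  mean_bias <- mean(d)
  loa <- mean_bias + c(-1.96, 1.96) * stats::sd(d)
  if (stats::var(d) == 0) {
    r <- 0; p <- 1 # identical-difference shortcut: no bias trend to test
  } else {
    ct <- stats::cor.test(a, d, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(mean_bias = mean_bias, classic_loa = loa,
                 pearson_r_bias_vs_mean = r, p_value = p, n = length(y1)),
            class = "bland_altman")
}

check_pairs <- function(y1, y2, min_n = 3) {
  if (length(y1) != length(y2)) stop("y1 and y2 must have equal length", call. = FALSE)
  if (length(y1) < min_n) stop("need at least ", min_n, " pairs", call. = FALSE)
  if (anyNA(y1) || anyNA(y2)) stop("missing values are not allowed", call. = FALSE)
  invisible(TRUE)
}

#' Carstensen regression-based limits of agreement
#'
#' When the Bland-Altman plot shows a slope (proportional bias), the
#' differences are regressed on the averages, `D = a + b*A + e` with
#' `var(e) = tau^2`, and the limits of agreement become the sloped band
#' `a + b*A +/- 2*tau`. `tau` is the residual standard deviation on n - 2
#' degrees of freedom. The multiplier on this path is exactly 2 (the classic
#' Bland-Altman limits in [bland_altman()] use 1.96).
#'
#' @inheritParams bland_altman
#' @return A list of class `carstensen_fit` with `a` (intercept), `b`
#'   (slope), `tau` (residual SD), `n`, and `sloped_loa`, a function mapping
#'   averages A to a two-column matrix of lower/upper limits.
#' @export
carstensen_loa <- function(y1, y2, ids = NULL) {
  check_pairs(y1, y2)
  d <- y1 - y2
  a_vals <- (y1 + y2) / 2
  if (stats::var(a_vals) == 0) {
    stop("degenerate input: averages have zero variance", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, a_vals), d)
  coefs <- fit$coefficients
  n <- length(d)
  tau <- sqrt(sum(fit$residuals^2) / (n - 2))
  a <- unname(coefs[1]); b <- unname(coefs[2])
  structure(list(
    a = a, b = b, tau = tau, n = n,
    sloped_loa = function(A) {
      mid <- a + b * A
      cbind(lower = mid - 2 * tau, upper = mid + 2 * tau)
    }
  ), class = "carstensen_fit")
}

#' @export
print.carstensen_fit <- function(x, ...) {
  cat(sprintf("Carstensen fit: D = %.3f + %.4f * A, tau = %.3f (n = %d)\n",
              x$a, x$b, x$tau, x$n))
  cat(sprintf("sloped LoA: a + b*A +/- 2*tau = %.3f + %.4f*A +/- %.3f\n",
              x$a, x$b, 2 * x$tau))
  invisible(x)
}

#' Construct a conversion equation directly
#'
#' Usually produced by [conversion_equations()]; the direct constructor is
#' useful for applying a published conversion (intercept, slope, optional
#' prediction-interval half-width) to new estimates.
#'
#' @param direction `"y1_from_y2"` (predict the formula value from
#'   calorimetry) or `"y2_from_y1"` (correct a formula estimate towards
#'   calorimetry).
#' @param intercept,slope the conversion line, kcal/day and dimensionless.
#' @param halfwidth half-width of the 95% prediction interval, kcal/day.
#' @return A list of class `conversion_equation`.
#' @export
conversion_equation <- function(direction = c("y2_from_y1", "y1_from_y2"),
                                intercept, slope, halfwidth = 0) {
  direction <- match.arg(direction)
  if (halfwidth < 0) stop("halfwidth must be >= 0", call. = FALSE)
  structure(list(direction = direction, intercept = intercept,
                 slope = slope, halfwidth = halfwidth),
            class = "conversion_equation")
}

#' Bidirectional method-conversion equations from a Carstensen fit
#'
#' From the difference-on-average regression (intercept `a`, slope `b`,
#' residual SD `tau`), the value of one method can be converted into the
#' scale of the other:
#' \deqn{y_{1|2} = a/(1 - b/2) + y_2 (1 + b/2)/(1 - b/2) \pm 2\tau/(1 - b/2)}
#' \deqn{y_{2|1} = -a/(1 + b/2) + y_1 (1 - b/2)/(1 + b/2) \pm 2\tau/(1 + b/2)}
#' The two directions compose to the identity in the point prediction.
#'
#' @param fit a [carstensen_loa()] result (requires `|b| < 2`).
#' @return A list with elements `y1_from_y2` and `y2_from_y1`, each a
#'   [conversion_equation()].
#' @export
conversion_equations <- function(fit) {
  stopifnot(inherits(fit, "carstensen_fit"))
  if (abs(fit$b) >= 2) {
    stop("|b| >= 2: conversion denominators vanish; conversion is degenerate",
         call. = FALSE)
  }
  lo <- 1 - fit$b / 2
  hi <- 1 + fit$b / 2
  list(
    y1_from_y2 = conversion_equation("y1_from_y2",
                                     intercept = fit$a / lo,
                                     slope = hi / lo,
                                     halfwidth = 2 * fit$tau / lo),
    y2_from_y1 = conversion_equation("y2_from_y1",
                                     intercept = -fit$a / hi,
                                     slope = lo / hi,
                                     halfwidth = 2 * fit$tau / hi)
  )
}

#' Apply a conversion equation
#'
#' @param value measurement(s) to convert, kcal/day.
#' @param eq a [conversion_equation()].
#' @return A list with `point` (converted value) and `interval`, a
#'   two-column matrix of prediction limits `point +/- halfwidth`.
#' @examples
#' eq <- conversion_equation("y2_from_y1", intercept = -756.11, slope = 1.70)
#' convert(956, eq)$point # ~869, the calorimetry-scale corrected estimate
#' @export
convert <- function(value, eq) {
  stopifnot(inherits(eq, "conversion_equation"))
  point <- eq$intercept + eq$slope * value
  list(point = point,
       interval = cbind(lower = point - eq$halfwidth,
                        upper = point + eq$halfwidth))
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement with the 45-degree identity line, combining precision
#' (Pearson correlation) and accuracy (location/scale shift):
#' `CCC = 2*s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moments. The 95% CI uses the Fisher z-transform with Lin's (1989)
#' asymptotic standard error.
#'
#' @param x,y numeric vectors of equal length (n >= 3), no missing values.
#' @return A list of class `lin_ccc` with `estimate`, `ci95` (lower, upper),
#'   `n`.
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4))$estimate # 4/7
#' @export
lin_ccc <- function(x, y) {
  check_pairs(x, y)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) stop("zero total variance: CCC undefined", call. = FALSE)
  ccc <- 2 * sxy / denom

  if (sx2 == 0 || sy2 == 0 || abs(ccc) >= 1 - 1e-12) {
    # perfect (or degenerate) concordance: the asymptotic SE collapses
    return(structure(list(estimate = ccc, ci95 = c(ccc, ccc), n = n),
                     class = "lin_ccc"))
  }
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mx - my) / sqrt(sqrt(sx2) * sqrt(sy2))
  z <- atanh(ccc)
  se_z2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
              2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
              ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
  se_z <- sqrt(max(se_z2, 0))
  ci <- tanh(z + c(-1.96, 1.96) * se_z)
  structure(list(estimate = ccc, ci95 = ci, n = n), class = "lin_ccc")
}

#' @export
print.lin_ccc <- function(x, ...) {
  cat(sprintf("Lin's CCC = %.3f (95%% CI %.3f to %.3f, n = %d)\n",
              x$estimate, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Rank prediction formulas by concordance with calorimetry
#'
#' Computes [lin_ccc()] between each formula's predictions and the measured
#' REE, over the subjects where both are available, and ranks formulas by
#' descending concordance.
#'
#' @param predictions the long table produced by [predict_all()] (columns
#'   `id`, `formula`, `ree_kcal_day`, `status`), or any data frame with those
#'   columns.
#' @param measured a data frame with columns `id` and `ree_kcal_day` holding
#'   the calorimetry values (a [cohort()] works directly).
#' @return A data frame with columns `formula`, `ccc`, `ci_lower`,
#'   `ci_upper`, `n`, sorted by `ccc` descending.
#' @export
compare_formulas_ccc <- function(predictions, measured) {
  stopifnot(all(c("id", "formula", "ree_kcal_day") %in% names(predictions)))
  stopifnot(all(c("id", "ree_kcal_day") %in% names(measured)))
  meas <- measured[!is.na(measured$ree_kcal_day), c("id", "ree_kcal_day")]
  if (anyDuplicated(meas$id)) stop("duplicate ids in measured values", call. = FALSE)
  rows <- lapply(unique(predictions$formula), function(f) {
    p <- predictions[predictions$formula == f & !is.na(predictions$ree_kcal_day), ]
    m <- match(p$id, meas$id)
    keep <- !is.na(m)
    if (sum(keep) < 3) {
      return(data.frame(formula = f, ccc = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, n = sum(keep)))
    }
    cc <- lin_ccc(p$ree_kcal_day[keep], meas$ree_kcal_day[m[keep]])
    data.frame(formula = f, ccc = cc$estimate, ci_lower = cc$ci95[1],
               ci_upper = cc$ci95[2], n = cc$n)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$ccc), ]
  rownames(out) <- NULL
  out
}
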