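#' Breath-by-breath gas exchange series
#'
#' Container for an indirect-calorimetry trace: per-breath oxygen uptake
#' (`vo2_ml_min`), carbon-dioxide output (`vco2_ml_min`) and minute
#' ventilation (`ve_l_min`) indexed by time in minutes (`time_min`, strictly
#' increasing). All gas values must be positive.
#'
#' @param data data frame with columns `time_min`, `vo2_ml_min`,
#'   `vco2_ml_min`, `ve_l_min`.
#' @return An object of class `breath_series` (a data frame).
#' @export
breath_series <- function(data) {
  needed <- c("time_min", "vo2_ml_min", "vco2_ml_min", "ve_l_min")
  stopifnot(is.data.frame(data))
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    stop("breath series missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data <- data[, needed]
  if (nrow(data) < 1) stop("breath series must contain at least one breath", call. = FALSE)
  if (any(diff(data$time_min) <= 0)) {
    stop("time_min must be strictly increasing", call. = FALSE)
  }
  if (any(data$vo2_ml_min <= 0) || any(data$vco2_ml_min <= 0) || any(data$ve_l_min <= 0)) {
    stop("vo2, vco2 and ve must all be positive", call. = FALSE)
  }
  structure(data, class = c("breath_series", "data.frame"))
}

#' Read / write a breath series CSV
#'
#' Plain CSV with columns `time_min`, `vo2_ml_min`, `vco2_ml_min`, `ve_l_min`.
#'
#' @param path file path.
#' @return `read_breath_csv()` returns a [breath_series()];
#'   `write_breath_csv()` invisibly returns `path`.
#' @export
read_breath_csv <- function(path) {
  if (!file.exists(path)) stop("breath series file not found: ", path, call. = FALSE)
  breath_series(utils::read.csv(path))
}

#' @rdname read_breath_csv
#' @param x a [breath_series()].
#' @export
write_breath_csv <- function(x, path) {
  stopifnot(inherits(x, "breath_series"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Respiratory quotient
#'
#' @param vo2 oxygen uptake, ml/min (positive).
#' @param vco2 carbon-dioxide output, ml/min.
#' @return VCO2/VO2 (dimensionless).
#' @examples
#' rq(150, 120) # 0.8
#' @export
rq <- function(vo2, vco2) {
  if (any(!is.finite(vo2)) || any(vo2 <= 0)) {
    stop("vo2 must be positive (ml/min)", call. = FALSE)
  }
  vco2 / vo2
}

#' Abbreviated Weir equation
#'
#' Converts gas exchange to energy expenditure without the urinary-nitrogen
#' (protein) term: `REE = 1.44 * (3.941 * VO2 + 1.106 * VCO2)` kcal/day with
#' VO2 and VCO2 in ml/min. The 3.941/1.106 caloric equivalents are the
#' canonical Weir constants; 1.44 converts kcal/min to kcal/day.
#'
#' @param vo2 oxygen uptake, ml/min (positive).
#' @param vco2 carbon-dioxide output, ml/min (positive).
#' @return Energy expenditure in kcal/day.
#' @examples
#' weir_ree(150, 120) # 1042.37
#' @export
weir_ree <- function(vo2, vco2) {
  if (any(!is.finite(vo2)) || any(vo2 <= 0) || any(!is.finite(vco2)) || any(vco2 <= 0)) {
    stop("vo2 and vco2 must be positive (ml/min)", call. = FALSE)
  }
  1.44 * (3.941 * vo2 + 1.106 * vco2)
}

# Coefficient of variation (%) over index windows, from cumulative sums.
window_cv <- function(x, starts, ends) {
  c1 <- c(0, cumsum(x))
  c2 <- c(0, cumsum(x^2))
  m <- ends - starts + 1
  s1 <- c1[ends + 1] - c1[starts]
  s2 <- c2[ends + 1] - c2[starts]
  v <- pmax(0, (s2 - s1^2 / m) / (m - 1))
  100 * sqrt(v) / (s1 / m)
}

#' Detect steady state in a gas-exchange trace
#'
#' Scans breath-by-breath for the earliest contiguous window of at least
#' `window` minutes in which the coefficient of variation (SD/mean, in %) of
#' the respiratory quotient is below `rq_tol`, of VO2 below `vo2_tol`, and of
#' minute ventilation below `ve_tol`. These thresholds implement the usual
#' metabolic-cart criterion of a 5-minute window with <5% RQ variation and
#' <10% VO2 and VE variation. The window slides breath by breath and the
#' earliest qualifying window wins.
#'
#' @param series a [breath_series()] spanning at least `window` minutes.
#' @param window minimum window length, minutes.
#' @param rq_tol,vo2_tol,ve_tol coefficient-of-variation tolerances, %.
#' @return A list of class `steady_state` with elements `found`, `start`,
#'   `end` (minutes), and the window CVs `rq_cv`, `vo2_cv`, `ve_cv` (all `NA`
#'   when no window qualifies).
#' @export
detect_steady_state <- function(series, window = 5, rq_tol = 5,
                                vo2_tol = 10, ve_tol = 10) {
  stopifnot(inherits(series, "breath_series"))
  t <- series$time_min
  n <- length(t)
  if (t[n] - t[1] < window) {
    stop("series shorter than the steady-state window", call. = FALSE)
  }
  # first breath index at or beyond t[i] + window, for each candidate start
  ends <- findInterval(t + window, t, left.open = TRUE) + 1L
  ok <- ends <= n
  starts <- which(ok)
  ends <- ends[ok]

  rq_cv <- window_cv(series$vco2_ml_min / series$vo2_ml_min, starts, ends)
  vo2_cv <- window_cv(series$vo2_ml_min, starts, ends)
  ve_cv <- window_cv(series$ve_l_min, starts, ends)
  hit <- which(rq_cv < rq_tol & vo2_cv < vo2_tol & ve_cv < ve_tol)

  if (length(hit) == 0) {
    return(structure(list(found = FALSE, start = NA_real_, end = NA_real_,
                          rq_cv = NA_real_, vo2_cv = NA_real_, ve_cv = NA_real_),
                     class = "steady_state"))
  }
  k <- hit[1]
  structure(list(found = TRUE, start = t[starts[k]], end = t[ends[k]],
                 rq_cv = rq_cv[k], vo2_cv = vo2_cv[k], ve_cv = ve_cv[k]),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  if (x$found) {
    cat(sprintf("steady state: %.2f-%.2f min (CV%%: RQ %.2f, VO2 %.2f, VE %.2f)\n",
                x$start, x$end, x$rq_cv, x$vo2_cv, x$ve_cv))
  } else {
    cat("no steady state found\n")
  }
  invisible(x)
}

#' Measure REE from a calorimetry trace
#'
#' Locates steady state with [detect_steady_state()], then averages VO2 and
#' VCO2 over the `measurement`-minute window that follows steady-state onset
#' and converts the means with the abbreviated Weir equation. The respiratory
#' quotient is the ratio of the window means.
#'
#' @param series a [breath_series()].
#' @param measurement measurement-window length after steady-state onset,
#'   minutes.
#' @param ... passed to [detect_steady_state()] (`window`, tolerances).
#' @return A list with `ree_kcal_day`, `rq`, and the `steady_state` result.
#' @export
measure_ree <- function(series, measurement = 20, ...) {
  stopifnot(inherits(series, "breath_series"))
  ss <- detect_steady_state(series, ...)
  if (!ss$found) stop("no steady state reached; REE cannot be measured", call. = FALSE)
  t <- series$time_min
  if (max(t) < ss$start + measurement) {
    stop(sprintf(
      "insufficient data after steady-state onset: need %g min, have %.2f",
      measurement, max(t) - ss$start), call. = FALSE)
  }
  idx <- t >= ss$start & t <= ss$start + measurement
  mvo2 <- mean(series$vo2_ml_min[idx])
  mvco2 <- mean(series$vco2_ml_min[idx])
  list(ree_kcal_day = weir_ree(mvo2, mvco2), rq = mvco2 / mvo2, steady_state = ss)
}
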