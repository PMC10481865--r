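#' Build a points-based nomogram from a linear model
#'
#' Converts a strictly linear model into the classic pen-and-paper
#' instrument: each
#' predictor gets an axis mapping its value to points,
#' `points_j(x) = |beta_j| * (x - ref_j) / M * 100` with
#' `M = max_j |beta_j| * range_j`, where `ref_j` is the range end at which
#' the predictor's contribution to the response is smallest (the minimum for
#' positive coefficients, the maximum for negative ones, so points always
#' increase the predicted response). The predictor with the largest
#' `|beta| * range` spans exactly 0-100 points. The total-points axis maps
#' the point sum linearly back to the response, including the intercept, so
#' reading the nomogram reproduces the model prediction exactly (up to
#' floating point).
#'
#' @param model a [fit_linear()] result whose terms are all plain numeric
#'   predictors (no spline or factor terms).
#' @param ranges named list (or 2-row data frame) of `c(min, max)` per
#'   predictor; defaults cover the target population with clinical margin:
#'   weight 5-60 kg, triceps skinfold 2-20 mm.
#' @return A list of class `ree_nomogram` with `axes` (per-predictor list of
#'   `beta`, `range`, `ref`, `max_points`), `scale` (kcal/day per point),
#'   `total_intercept`, and the model `response` name.
#' @export
build_nomogram <- function(model,
                           ranges = list(weight_kg = c(5, 60), tsf_mm = c(2, 20))) {
  stopifnot(inherits(model, "ree_model"))
  terms <- model$terms
  if (any(grepl("rcs|poly|I\\(|:", terms))) {
    stop("nomogram supports strictly linear terms only", call. = FALSE)
  }
  missing_r <- setdiff(terms, names(ranges))
  if (length(missing_r) > 0) {
    stop("no range given for predictor(s): ", paste(missing_r, collapse = ", "),
         call. = FALSE)
  }
  betas <- model$coefficients[terms]
  if (anyNA(betas)) stop("model coefficients missing for some terms", call. = FALSE)
  keep <- betas != 0
  if (any(!keep)) {
    warning("excluding zero-coefficient predictor(s): ",
            paste(terms[!keep], collapse = ", "), call. = FALSE)
    terms <- terms[keep]; betas <- betas[keep]
  }
  if (length(terms) == 0) stop("no usable predictors", call. = FALSE)
  spans <- vapply(terms, function(tm) {
    r <- ranges[[tm]]
    if (!(length(r) == 2 && is.finite(r[1]) && is.finite(r[2]) && r[1] < r[2])) {
      stop("range for ", tm, " must be finite with min < max", call. = FALSE)
    }
    abs(betas[[tm]]) * diff(r)
  }, numeric(1))
  M <- max(spans)
  axes <- lapply(terms, function(tm) {
    r <- ranges[[tm]]
    b <- betas[[tm]]
    ref <- if (b > 0) r[1] else r[2]
    list(predictor = tm, beta = b, range = r, ref = ref,
         max_points = abs(b) * diff(r) / M * 100)
  })
  names(axes) <- terms
  total_intercept <- unname(model$coefficients[1]) +
    sum(vapply(axes, function(ax) ax$beta * ax$ref, numeric(1)))
  structure(list(axes = axes, scale = M / 100,
                 total_intercept = total_intercept,
                 response = model$response),
            class = "ree_nomogram")
}

#' Predict from a nomogram
#'
#' Computes per-predictor points, sums them, and maps the total back to the
#' response scale — the arithmetic a clinician performs graphically. Values
#' outside a predictor's axis range are refused (no clinical extrapolation).
#'
#' @param nomogram a [build_nomogram()] result.
#' @param values named numeric vector or single-row data frame/list of
#'   predictor values (e.g. `c(weight_kg = 19.7, tsf_mm = 7.8)`).
#' @return A list with `points` (per-predictor), `total_points`, and
#'   `prediction` (response units, kcal/day).
#' @examples
#' fit <- fit_linear(ree_kcal_day ~ weight_kg + tsf_mm,
#'                   generate_cohort(generator_config(n = 50, seed = 7)))
#' nom <- build_nomogram(fit)
#' nomogram_predict(nom, c(weight_kg = 19.7, tsf_mm = 7.8))
#' @export
nomogram_predict <- function(nomogram, values) {
  stopifnot(inherits(nomogram, "ree_nomogram"))
  values <- unlist(values)
  pts <- vapply(nomogram$axes, function(ax) {
    x <- if (ax$predictor %in% names(values)) values[[ax$predictor]] else NA_real_
    if (is.na(x)) stop("missing value for ", ax$predictor, call. = FALSE)
    if (x < ax$range[1] || x > ax$range[2]) {
      stop(sprintf("%s = %g outside the nomogram range [%g, %g]",
                   ax$predictor, x, ax$range[1], ax$range[2]), call. = FALSE)
    }
    abs(ax$beta) * abs(x - ax$ref) / (nomogram$scale * 100) * 100
  }, numeric(1))
  total <- sum(pts)
  list(points = pts, total_points = total,
       prediction = nomogram$total_intercept + nomogram$scale * total)
}

#' Tick table for a nomogram
#'
#' The plain-text rendering surface: per-axis tick values with their point
#' equivalents, plus the total-points-to-response axis. Tick positions use
#' [pretty()] within each axis range.
#'
#' @param nomogram a [build_nomogram()] result.
#' @param n suggested ticks per axis.
#' @return A data frame with columns `axis`, `value`, `points`.
#' @export
nomogram_ticks <- function(nomogram, n = 8) {
  stopifnot(inherits(nomogram, "ree_nomogram"))
  rows <- lapply(nomogram$axes, function(ax) {
    v <- pretty(ax$range, n = n)
    v <- v[v >= ax$range[1] & v <= ax$range[2]]
    data.frame(axis = ax$predictor, value = v,
               points = abs(ax$beta) * abs(v - ax$ref) / (nomogram$scale * 100) * 100)
  })
  max_total <- sum(vapply(nomogram$axes, `[[`, numeric(1), "max_points"))
  tp <- pretty(c(0, max_total), n = n)
  tp <- tp[tp >= 0 & tp <= max_total]
  rows$total <- data.frame(axis = "total_points", value = tp,
                           points = tp)
  rows$ree <- data.frame(axis = nomogram$response,
                         value = nomogram$total_intercept + nomogram$scale * tp,
                         points = tp)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a nomogram
#'
#' Writes the plain-text tick table (CSV) that fully describes the
#' instrument; when `plot_path` is given, also draws the familiar
#' aligned-axes figure (points scale on top, one axis per predictor, total
#' points and response at the bottom).
#'
#' @param nomogram a [build_nomogram()] result.
#' @param path output path for the tick-table CSV.
#' @param plot_path optional path for a figure (`.png` or `.pdf`).
#' @return Invisibly, the tick table.
#' @export
render_nomogram <- function(nomogram, path, plot_path = NULL) {
  ticks <- nomogram_ticks(nomogram)
  utils::write.csv(ticks, path, row.names = FALSE)
  if (!is.null(plot_path)) {
    ext <- tolower(tools::file_ext(plot_path))
    if (ext == "png") grDevices::png(plot_path, width = 900, height = 600)
    else grDevices::pdf(plot_path, width = 9, height = 6)
    on.exit(grDevices::dev.off())
    plot_nomogram_canvas(nomogram, ticks)
  }
  invisible(ticks)
}

plot_nomogram_canvas <- function(nomogram, ticks) {
  axes <- c("points", names(nomogram$axes), "total_points", nomogram$response)
  ny <- length(axes)
  max_total <- sum(vapply(nomogram$axes, `[[`, numeric(1), "max_points"))
  graphics::plot.new()
  graphics::plot.window(xlim = c(-0.18, 1.05), ylim = c(0.5, ny + 0.5))
  y_of <- function(i) ny - i + 1
  draw_axis <- function(y, label, at, labels) {
    graphics::segments(min(at), y, max(at), y)
    graphics::segments(at, y - 0.06, at, y + 0.06)
    graphics::text(at, y + 0.22, labels, cex = 0.7)
    graphics::text(-0.17, y, label, adj = 0, cex = 0.8)
  }
  # points reference scale 0..100
  pts <- pretty(c(0, 100))
  draw_axis(y_of(1), "Points", pts / 100, pts)
  for (i in seq_along(nomogram$axes)) {
    ax <- nomogram$axes[[i]]
    tk <- ticks[ticks$axis == ax$predictor, ]
    draw_axis(y_of(1 + i), ax$predictor, tk$points / 100, tk$value)
  }
  tk <- ticks[ticks$axis == "total_points", ]
  draw_axis(y_of(ny - 1), "Total points", tk$value / max_total, tk$value)
  tk <- ticks[ticks$axis == nomogram$response, ]
  draw_axis(y_of(ny), nomogram$response, tk$points / max_total, round(tk$value))
  invisible(NULL)
}
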