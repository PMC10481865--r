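# Restricted cubic term for a 3-knot basis (Harrell's construction): zero
# below the first knot, linear beyond the last, scaled by the squared outer
# knot span so the term is on the scale of x.
rcs_term <- function(x, knots) {
  k1 <- knots[1]; k2 <- knots[2]; k3 <- knots[3]
  p3 <- function(u) pmax(u, 0)^3
  (p3(x - k1) - p3(x - k2) * (k3 - k1) / (k3 - k2) +
     p3(x - k3) * (k2 - k1) / (k3 - k2)) / (k3 - k1)^2
}

#' Restricted cubic spline basis with three knots
#'
#' Builds the two-column basis (linear term plus one restricted cubic term)
#' used to test for a nonlinear predictor effect. The restricted term is zero
#' below the first knot and exactly linear beyond the last, so the fitted
#' curve cannot do anything wild in the tails. Knots default to the 0.10,
#' 0.50 and 0.90 sample quantiles.
#'
#' @param x numeric predictor with at least 10 distinct values.
#' @param probs quantile probabilities for automatic knot placement.
#' @param knots optional explicit knots (3 strictly increasing values);
#'   overrides `probs`.
#' @return A list of class `rcs_basis` with `knots`, `basis` (n x 2 matrix,
#'   columns `x` and `x_rcs`), and `fun(newx)` evaluating the basis at new
#'   values.
#' @export
rcs_basis <- function(x, probs = c(0.10, 0.50, 0.90), knots = NULL) {
  if (is.null(knots)) {
    if (length(unique(x)) < 10) {
      stop("need at least 10 distinct values to place spline knots", call. = FALSE)
    }
    knots <- unname(stats::quantile(x, probs, type = 7))
  }
  if (length(knots) != 3 || any(diff(knots) <= 0)) {
    stop("knots must be 3 strictly increasing values", call. = FALSE)
  }
  fun <- function(newx) cbind(x = newx, x_rcs = rcs_term(newx, knots))
  structure(list(knots = knots, basis = fun(x), fun = fun), class = "rcs_basis")
}

#' Fit a linear REE model by ordinary least squares
#'
#' Thin wrapper around [stats::lm()] that records the fit summaries used
#' throughout model development: adjusted R^2, the mean squared error on the
#' `SSE/n` convention, and the residual SD on `n - p - 1` degrees of freedom
#' (both conventions are kept because they answer different questions).
#'
#' @param formula model formula, e.g. `ree_kcal_day ~ weight_kg + tsf_mm`.
#' @param data data frame (a [cohort()] works directly).
#' @return An object of class `ree_model`: list with `formula`, `terms`,
#'   `coefficients`, `r2adj`, `mse`, `residual_sd`, `sse`, `n`, `loglik`
#'   (Gaussian), and the underlying `lm` fit.
#' @export
fit_linear <- function(formula, data) {
  m <- stats::lm(formula, data = as.data.frame(data))
  if (any(is.na(stats::coef(m)))) {
    stop("rank-deficient design: ", paste(names(stats::coef(m))[is.na(stats::coef(m))],
                                          collapse = ", "), call. = FALSE)
  }
  n <- length(m$residuals)
  p <- length(stats::coef(m)) - 1
  if (n <= p + 2) stop("too few observations for ", p, " predictors", call. = FALSE)
  sse <- sum(m$residuals^2)
  y <- m$model[[1]]
  sst <- sum((y - mean(y))^2)
# a constant response has no variance to explain: R^2 is taken as 0 so
  # the adjusted value is properly negative
  r2 <- if (sst > 0) 1 - sse / sst else 0
  r2adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  sig2_ml <- sse / n
  structure(list(
    formula = formula,
    response = all.vars(formula)[1],
    terms = attr(stats::terms(m), "term.labels"),
    coefficients = stats::coef(m),
    r2adj = r2adj,
    mse = sse / n,
    residual_sd = sqrt(sse / (n - p - 1)),
    sse = sse,
    n = n,
    loglik = -n / 2 * (log(2 * pi * sig2_ml) + 1),
    lm = m
  ), class = "ree_model")
}

#' @export
print.ree_model <- function(x, ...) {
  cat("linear REE model:", deparse(x$formula), "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("n = %d, adj. R^2 = %.4f, MSE = %.2f, residual SD = %.2f\n",
              x$n, x$r2adj, x$mse, x$residual_sd))
  invisible(x)
}

#' @export
predict.ree_model <- function(object, newdata, ...) {
  stats::predict(object$lm, newdata = as.data.frame(newdata), ...)
}

#' Likelihood-ratio test for a nonlinear predictor contribution
#'
#' Compares a linear fit against a nested fit augmented with spline terms for
#' the same predictor, under the Gaussian likelihood implied by least
#' squares: `statistic = n * log(SSE_linear / SSE_spline)`, referred to a
#' chi-square with degrees of freedom equal to the parameter difference.
#'
#' @param linear_fit,spline_fit nested [fit_linear()] results on the same
#'   data (`spline_fit` the larger model).
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
lrt_nonlinearity <- function(linear_fit, spline_fit) {
  stopifnot(inherits(linear_fit, "ree_model"), inherits(spline_fit, "ree_model"))
  if (linear_fit$n != spline_fit$n) {
    stop("models were fitted on different data (n differs)", call. = FALSE)
  }
  df <- length(spline_fit$coefficients) - length(linear_fit$coefficients)
  if (df < 1) stop("spline_fit must extend linear_fit (non-nested input)", call. = FALSE)
  stat <- max(0, linear_fit$n * log(linear_fit$sse / spline_fit$sse))
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Limited backward variable selection with forced terms
#'
#' Starts from the forced predictors plus all candidates and repeatedly drops
#' the candidate with the largest partial-F p-value above `alpha`; forced
#' terms are never considered for removal. With `criterion = "aic"`, the
#' candidate whose removal lowers AIC the most is dropped instead.
#'
#' @param data data frame (a [cohort()] works directly).
#' @param response response column name.
#' @param forced character vector of predictors kept unconditionally.
#' @param candidates character vector of predictors eligible for removal.
#' @param alpha retention threshold for the partial-F criterion.
#' @param criterion `"partial_f"` (default) or `"aic"`.
#' @return The final [fit_linear()] result, with the removal trace in
#'   attribute `"dropped"`.
#' @export
backward_select <- function(data, response = "ree_kcal_day",
                            forced = "weight_kg",
                            candidates = c("height_cm", "age_years", "sex", "tsf_mm"),
                            alpha = 0.05,
                            criterion = c("partial_f", "aic")) {
  criterion <- match.arg(criterion)
  data <- as.data.frame(data)
  missing <- setdiff(c(response, forced, candidates), names(data))
  if (length(missing) > 0) {
    stop("column(s) not in data: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  current <- candidates
  dropped <- character(0)
  repeat {
    fml <- stats::reformulate(c(forced, current), response = response)
    fit <- stats::lm(fml, data = data)
    if (length(current) == 0) break
    if (criterion == "partial_f") {
      scope <- stats::reformulate(current)
      d1 <- stats::drop1(fit, scope = scope, test = "F")
      pvals <- d1[["Pr(>F)"]][-1]
      names(pvals) <- rownames(d1)[-1]
      worst <- names(pvals)[which.max(pvals)]
      if (max(pvals) <= alpha) break
    } else {
      scope <- stats::reformulate(current)
      d1 <- stats::drop1(fit, scope = scope)
      aics <- d1$AIC
      names(aics) <- rownames(d1)
      if (min(aics[-1]) >= aics[1]) break
      worst <- names(aics[-1])[which.min(aics[-1])]
    }
    current <- setdiff(current, worst)
    dropped <- c(dropped, worst)
  }
  out <- fit_linear(stats::reformulate(c(forced, current), response = response), data)
  attr(out, "dropped") <- dropped
  out
}

validation_result <- function(index, original, training, test, n_boot, n_skipped) {
  optimism <- training - test
  structure(list(index = index, original = original, training = training,
                 test = test, optimism = optimism,
                 corrected = original - optimism,
                 n_boot = n_boot, n_skipped = n_skipped),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("%s: original %.4f | training %.4f | test %.4f | optimism %.4f | corrected %.4f (%d resamples)\n",
              x$index, x$original, x$training, x$test, x$optimism, x$corrected,
              x$n_boot))
  invisible(x)
}

# apparent indices of an lm-style fit evaluated on (possibly different) data
index_on <- function(coefs, design_fun, data, response) {
  X <- design_fun(data)
  y <- data[[response]]
  pred <- drop(X %*% coefs)
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  n <- length(y)
  p <- length(coefs) - 1
  r2 <- 1 - sse / sst
  c(r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1), mse = sse / n)
}

#' Bootstrap optimism-corrected model validation
#'
#' Harrell's optimism bootstrap for the adjusted R^2 and the MSE of a linear
#' model specification. For each of `n_boot` resamples (with replacement,
#' size n) the model is refitted; `training` is the mean apparent index on
#' the resamples and `test` the mean index of the resample fits evaluated on
#' the original data. Then `optimism = training - test` and
#' `corrected = original - optimism` — identities that hold exactly for every
#' run, for both indices (for MSE the optimism is negative, so the corrected
#' error is larger than the apparent one). Resamples with a degenerate
#' (rank-deficient) design are skipped and counted.
#'
#' @param data data frame (a [cohort()] works directly).
#' @param formula linear model formula.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer RNG seed.
#' @return A list of class `bootstrap_validation` with elements `r2` and
#'   `mse`, each a `validation_result` (`index`, `original`, `training`,
#'   `test`, `optimism`, `corrected`, `n_boot`, `n_skipped`).
#' @export
bootstrap_validate <- function(data, formula, n_boot = 3000, seed = 1L) {
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  data <- as.data.frame(data)
  mf <- stats::model.frame(formula, data = data)
  response <- names(mf)[1]
  design_fun <- function(d) stats::model.matrix(formula, data = d)
  orig_fit <- fit_linear(formula, data)
  original <- index_on(orig_fit$coefficients, design_fun, data, response)
  n <- nrow(data)
  with_seed(seed, {
    train_idx <- matrix(0, n_boot, 2, dimnames = list(NULL, c("r2", "mse")))
    test_idx <- train_idx
    skipped <- 0
    for (bb in seq_len(n_boot)) {
      take <- sample.int(n, n, replace = TRUE)
      boot <- data[take, , drop = FALSE]
      res <- tryCatch({
        bf <- stats::lm(formula, data = boot)
        if (any(is.na(stats::coef(bf)))) stop("rank deficient")
        list(train = index_on(stats::coef(bf), design_fun, boot, response),
             test = index_on(stats::coef(bf), design_fun, data, response))
      }, error = function(e) NULL)
      if (is.null(res)) {
        skipped <- skipped + 1
        train_idx[bb, ] <- NA
        test_idx[bb, ] <- NA
      } else {
        train_idx[bb, ] <- res$train
        test_idx[bb, ] <- res$test
      }
    }
    tr <- colMeans(train_idx, na.rm = TRUE)
    te <- colMeans(test_idx, na.rm = TRUE)
    used <- n_boot - skipped
    structure(list(
      r2 = validation_result("r2", unname(original["r2"]), unname(tr["r2"]),
                             unname(te["r2"]), used, skipped),
      mse = validation_result("mse", unname(original["mse"]), unname(tr["mse"]),
                              unname(te["mse"]), used, skipped)
    ), class = "bootstrap_validation")
  })
}

#' Historical train/test split validation
#'
#' Fits the model specification on the first `train_n` subjects (cohort
#' order — the split mirrors an earlier study's historical sample rather than
#' a random partition) and predicts the remainder, returning predictions
#' aligned with the measured REE for concordance assessment. An optional
#' seeded shuffle randomises the split.
#'
#' @param x a [cohort()] with measured REE.
#' @param formula linear model formula.
#' @param train_n number of training subjects (need at least 3 test
#'   subjects beyond it).
#' @param shuffle if `TRUE`, permute the cohort first.
#' @param seed seed for the shuffle.
#' @return A list with the fitted `model` ([fit_linear()]) and `test`, a
#'   data frame of `id`, `predicted`, `measured` for the held-out subjects.
#' @export
train_test_split_validate <- function(x, formula, train_n = 54,
                                      shuffle = FALSE, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  data <- as.data.frame(x)
  if (nrow(data) < train_n + 3) {
    stop("cohort too small to split: need at least train_n + 3 subjects",
         call. = FALSE)
  }
  if (shuffle) data <- with_seed(seed, data[sample.int(nrow(data)), , drop = FALSE])
  train <- data[seq_len(train_n), , drop = FALSE]
  test <- data[-seq_len(train_n), , drop = FALSE]
  model <- fit_linear(formula, train)
  response <- all.vars(formula)[1]
  list(model = model,
       test = data.frame(id = test$id,
                         predicted = unname(predict(model, test)),
                         measured = test[[response]],
                         stringsAsFactors = FALSE))
}

#' Group difference of REE quantiles with bootstrap confidence intervals
#'
#' Contrasts the 25th, 50th and 75th percentiles of measured REE between the
#' two nutritional-status groups (group 2 minus group 1) using type-7 sample
#' quantiles, with percentile bootstrap CIs from resampling subjects within
#' each group. Values labelled `"unassigned"` are dropped.
#'
#' @param ree numeric vector of measured REE, kcal/day.
#' @param group character vector of `"group1"`/`"group2"` labels (e.g. from
#'   [classify_nutrition_group()]); same length as `ree`.
#' @param taus quantile probabilities, each in (0, 1).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer RNG seed.
#' @return A data frame of class `quantile_comparison` with columns `tau`,
#'   `difference`, `ci_lower`, `ci_upper`.
#' @export
quantile_group_diff <- function(ree, group, taus = c(0.25, 0.5, 0.75),
                                n_boot = 1000, seed = 1L) {
  stopifnot(length(ree) == length(group))
  if (any(taus <= 0 | taus >= 1)) stop("taus must lie in (0, 1)", call. = FALSE)
  keep <- group %in% c("group1", "group2") & !is.na(ree)
  g1 <- ree[keep & group == "group1"]
  g2 <- ree[keep & group == "group2"]
  if (length(g1) < 5 || length(g2) < 5) {
    stop("need at least 5 subjects per group", call. = FALSE)
  }
  qdiff <- function(a, b) stats::quantile(b, taus, type = 7) -
    stats::quantile(a, taus, type = 7)
  est <- qdiff(g1, g2)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      qdiff(sample(g1, replace = TRUE), sample(g2, replace = TRUE))
    }, numeric(length(taus)))
  })
  boots <- matrix(boots, nrow = length(taus))
  ci <- apply(boots, 1, stats::quantile, probs = c(0.025, 0.975), type = 7)
  out <- data.frame(tau = taus, difference = unname(est),
                    ci_lower = ci[1, ], ci_upper = ci[2, ])
  rownames(out) <- NULL
  class(out) <- c("quantile_comparison", "data.frame")
  out
}

#' Caloric-intake model for measured REE
#'
#' Multivariable linear regression of measured REE on caloric intake and age
#' (optionally sex), on complete cases only. Besides the per-unit
#' coefficients, the clinically readable scaled effects are reported: the REE
#' change per `intake_step` kcal/day of intake (default +388, about one SD of
#' intake in this population) and per `age_step` years (default +4.75, one SD
#' of age).
#'
#' @param ree,intake,age numeric vectors (kcal/day, kcal/day, years).
#' @param sex optional `"male"`/`"female"` vector; when supplied, sex enters
#'   the model (male = 1) and its coefficient is reported too.
#' @param intake_step,age_step scaling steps for the reported effects.
#' @return A list of class `intake_model` with the underlying `fit`
#'   ([fit_linear()]), `scaled_effects` (named vector), `n_complete`.
#' @export
intake_model <- function(ree, intake, age, sex = NULL,
                         intake_step = 388, age_step = 4.75) {
  df <- data.frame(ree = ree, intake = intake, age = age)
  fml <- ree ~ intake + age
  if (!is.null(sex)) {
    df$sex_male <- as.numeric(sex == "male")
    fml <- ree ~ intake + age + sex_male
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 10) stop("fewer than 10 complete cases", call. = FALSE)
  if (stats::var(df$intake) == 0) stop("rank-deficient design: intake is constant",
                                       call. = FALSE)
  fit <- fit_linear(fml, df)
  scaled <- c(intake = unname(fit$coefficients["intake"]) * intake_step,
              age = unname(fit$coefficients["age"]) * age_step)
  structure(list(fit = fit, scaled_effects = scaled,
                 intake_step = intake_step, age_step = age_step,
                 n_complete = nrow(df)),
            class = "intake_model")
}

#' @export
print.intake_model <- function(x, ...) {
  print(x$fit)
  cat(sprintf("scaled effects: +%g kcal/day intake -> %+.1f kcal/day REE; +%g y age -> %+.1f kcal/day REE (n = %d)\n",
              x$intake_step, x$scaled_effects["intake"],
              x$age_step, x$scaled_effects["age"], x$n_complete))
  invisible(x)
}
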