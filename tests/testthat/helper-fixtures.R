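# Small hand-built cohort used across unit tests.
tiny_cohort <- function() {
  cohort(data.frame(
    id = c("A", "B", "C"),
    sex = c("male", "female", "male"),
    age_years = c(5, 9, 12),
    weight_kg = c(20, 19.45, 30),
    height_cm = c(110, 118, NA),
    knee_height_cm = c(NA, NA, 40),
    tsf_mm = c(8, 7.7, 6.5),
    feeding = c("oral", "enteral", "mixed"),
    ree_kcal_day = c(900, 806.5, 1100),
    rq = c(0.72, 0.71, 0.8),
    stringsAsFactors = FALSE
  ), provenance = "test fixture")
}

# Independent OLS oracle: normal equations by hand-coded summation (no lm).
ols_oracle <- function(X, y) {
  p <- ncol(X)
  XtX <- matrix(0, p, p)
  Xty <- numeric(p)
  for (i in seq_len(nrow(X))) {
    xi <- X[i, ]
    XtX <- XtX + tcrossprod(xi)
    Xty <- Xty + xi * y[i]
  }
  solve(XtX, Xty)
}

# Independent CCC oracle from raw moment sums.
ccc_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# Brute-force steady-state scan: for every start breath, grow the window to
# the first breath at/after start + window minutes and test all three CVs
# with plain sd()/mean().
steady_oracle <- function(series, window = 5, rq_tol = 5, vo2_tol = 10, ve_tol = 10) {
  t <- series$time_min
  n <- length(t)
  rqv <- series$vco2_ml_min / series$vo2_ml_min
  cv <- function(z) 100 * stats::sd(z) / mean(z)
  for (i in seq_len(n)) {
    j <- which(t >= t[i] + window)
    if (length(j) == 0) break
    j <- j[1]
    w <- i:j
    if (cv(rqv[w]) < rq_tol && cv(series$vo2_ml_min[w]) < vo2_tol &&
        cv(series$ve_l_min[w]) < ve_tol) {
      return(list(found = TRUE, start = t[i], end = t[j]))
    }
  }
  list(found = FALSE, start = NA_real_, end = NA_real_)
}
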