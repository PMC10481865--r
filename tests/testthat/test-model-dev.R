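test_that("restricted cubic basis is zero below and linear beyond its knots", {
  set.seed(2)
  x <- c(runif(200, 5, 60))
  rb <- rcs_basis(x)
  expect_equal(unname(rb$knots), unname(quantile(x, c(0.1, 0.5, 0.9), type = 7)))
  grid <- seq(min(x) - 5, max(x) + 20, by = 0.05)
  B <- rb$fun(grid)
  below <- grid < rb$knots[1]
  expect_true(all(B[below, "x_rcs"] == 0))
  # second differences vanish beyond the last knot (linearity in the tail)
  beyond <- which(grid > rb$knots[3] + 0.1)
  d2 <- diff(diff(B[beyond, "x_rcs"]))
  expect_lt(max(abs(d2)), 1e-8)
  # continuity at the knots
  expect_lt(max(abs(diff(B[, "x_rcs"]))), 0.2)
  expect_error(rcs_basis(rep(1:3, 10)), "distinct")
  expect_error(rcs_basis(x, knots = c(1, 1, 2)), "increasing")
})

test_that("linear fitting recovers noiseless truth and matches the OLS oracle", {
  set.seed(3)
  d <- data.frame(weight_kg = runif(40, 8, 45), tsf_mm = runif(40, 3, 15))
  d$ree_kcal_day <- 28.43 * d$weight_kg - 17 * d$tsf_mm + 398.2
  f <- fit_linear(ree_kcal_day ~ weight_kg + tsf_mm, d)
  expect_equal(unname(f$coefficients), c(398.2, 28.43, -17), tolerance = 1e-9)
  expect_equal(f$r2adj, 1, tolerance = 1e-9)
  expect_equal(f$mse, 0, tolerance = 1e-6)

  # constant response: no explainable variance
  d2 <- d
  d2$ree_kcal_day <- 700
  f2 <- fit_linear(ree_kcal_day ~ weight_kg + tsf_mm, d2)
  expect_equal(unname(f2$coefficients[2:3]), c(0, 0), tolerance = 1e-9)
  expect_lte(f2$r2adj, 0)

  # brute-force normal equations agree to 1e-9 on small n
  for (n in c(6, 9, 12)) {
    dd <- data.frame(w = runif(n, 10, 40), t = runif(n, 3, 12))
    dd$y <- 400 + 25 * dd$w - 12 * dd$t + rnorm(n, 0, 80)
    ff <- fit_linear(y ~ w + t, dd)
    beta <- ols_oracle(cbind(1, dd$w, dd$t), dd$y)
    expect_equal(unname(ff$coefficients), beta, tolerance = 1e-9)
  }
  expect_error(fit_linear(y ~ w + t, data.frame(w = 1:3, t = 1:3, y = 1:3)),
               "rank|few")
})

test_that("fit summaries expose both error conventions", {
  set.seed(4)
  d <- data.frame(x = runif(30), y = rnorm(30))
  f <- fit_linear(y ~ x, d)
  expect_equal(f$mse, f$sse / 30)
  expect_equal(f$residual_sd, sqrt(f$sse / (30 - 2)))
  expect_lte(f$r2adj, 1)
})

test_that("nonlinearity LRT is null on identical fits and powerful on curvature", {
  set.seed(5)
  d <- data.frame(w = runif(60, 5, 60))
  d$y <- 300 + 20 * d$w + rnorm(60, 0, 50)
  lin <- fit_linear(y ~ w, d)
  same <- fit_linear(y ~ w, d)
  same$coefficients <- c(same$coefficients, dummy = 0) # same data, same SSE
  out <- lrt_nonlinearity(lin, same)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)

  # strong quadratic effect detected at n = 500
  n <- 500
  d2 <- data.frame(w = runif(n, 5, 60))
  d2$y <- 300 + 20 * d2$w + 0.3 * (d2$w - 30)^2 + rnorm(n, 0, 50)
  rb <- rcs_basis(d2$w)
  d2$w_rcs <- rb$basis[, "x_rcs"]
  lrt <- lrt_nonlinearity(fit_linear(y ~ w, d2), fit_linear(y ~ w + w_rcs, d2))
  expect_lt(lrt$p_value, 0.01)
  expect_equal(lrt$df, 1)
})

test_that("limited backward selection keeps forced terms and true effects", {
  set.seed(6)
  n <- 1000
  ch <- generate_cohort(generator_config(n = n, seed = 606))
  sel <- backward_select(ch)
  expect_setequal(sel$terms, c("weight_kg", "tsf_mm"))

  # pure-noise candidates: forced-only model survives (majority over seeds)
  hits <- 0
  for (s in 1:5) {
    d <- data.frame(w = runif(400, 5, 60), h = runif(400, 90, 160),
                    a = runif(400, 1, 18), s2 = sample(0:1, 400, TRUE))
    d$y <- 300 + 25 * d$w + rnorm(400, 0, 100)
    sel2 <- backward_select(d, response = "y", forced = "w",
                            candidates = c("h", "a", "s2"))
    if (identical(sel2$terms, "w")) hits <- hits + 1
  }
  expect_gte(hits, 3)

  # no candidates: forced model returned unchanged
  d <- data.frame(w = runif(50, 5, 60))
  d$y <- 300 + 25 * d$w + rnorm(50, 0, 50)
  sel3 <- backward_select(d, response = "y", forced = "w", candidates = character(0))
  expect_equal(sel3$terms, "w")
  expect_error(backward_select(d, response = "y", forced = "w",
                               candidates = "nope"), "not in data")
})

test_that("bootstrap validation satisfies the optimism identities", {
  ch <- generate_cohort(generator_config(n = 54, seed = 77))
  bv <- bootstrap_validate(ch, ree_kcal_day ~ weight_kg + tsf_mm,
                           n_boot = 300, seed = 8)
  for (v in list(bv$r2, bv$mse)) {
    expect_equal(v$optimism, v$training - v$test, tolerance = 1e-12)
    expect_equal(v$corrected, v$original - v$optimism, tolerance = 1e-12)
  }
  # r2 optimism is positive (overfitting), mse optimism negative
  expect_gt(bv$r2$optimism, 0)
  expect_lt(bv$mse$optimism, 0)
  # determinism under a fixed seed
  bv2 <- bootstrap_validate(ch, ree_kcal_day ~ weight_kg + tsf_mm,
                            n_boot = 300, seed = 8)
  expect_equal(bv$r2$corrected, bv2$r2$corrected)

  # noiseless data: apparent fit is perfect and optimism is negligible
  d <- data.frame(w = runif(54, 5, 60), t = runif(54, 3, 15))
  d$y <- 28.43 * d$w - 17 * d$t + 398.2
  bn <- bootstrap_validate(d, y ~ w + t, n_boot = 100, seed = 9)
  expect_equal(bn$r2$original, 1, tolerance = 1e-9)
  expect_equal(bn$r2$corrected, 1, tolerance = 1e-6)
})

test_that("historical train/test split fits first, predicts the rest", {
  ch <- generate_cohort(generator_config(n = 95, seed = 10))
  out <- train_test_split_validate(ch, ree_kcal_day ~ weight_kg + tsf_mm,
                                   train_n = 54)
  expect_equal(out$model$n, 54)
  expect_equal(nrow(out$test), 41)
  expect_equal(out$test$id, ch$id[55:95])

  # noiseless generating model gives perfect held-out concordance
  d <- as.data.frame(ch)
  d$ree_kcal_day <- 28.43 * d$weight_kg - 17 * d$tsf_mm + 398.2
  out2 <- train_test_split_validate(cohort(d), ree_kcal_day ~ weight_kg + tsf_mm,
                                    train_n = 54)
  expect_equal(lin_ccc(out2$test$predicted, out2$test$measured)$estimate, 1,
               tolerance = 1e-9)

  # seeded shuffle is reproducible
  s1 <- train_test_split_validate(ch, ree_kcal_day ~ weight_kg + tsf_mm,
                                  train_n = 54, shuffle = TRUE, seed = 4)
  s2 <- train_test_split_validate(ch, ree_kcal_day ~ weight_kg + tsf_mm,
                                  train_n = 54, shuffle = TRUE, seed = 4)
  expect_equal(s1$test$id, s2$test$id)
  expect_error(train_test_split_validate(ch, ree_kcal_day ~ weight_kg,
                                         train_n = 94), "too small")
})

test_that("quantile group differences match direct sample quantiles", {
  g1 <- c(700, 800, 900, 650, 720)
  g2 <- c(800, 900, 1000, 750, 820)
  qc <- quantile_group_diff(c(g1, g2), rep(c("group1", "group2"), each = 5),
                            taus = 0.5, n_boot = 200, seed = 1)
  expect_equal(qc$difference, median(g2) - median(g1))

  # identical groups: zero differences, CIs cover zero
  same <- c(700, 750, 800, 850, 900, 950)
  qc2 <- quantile_group_diff(rep(same, 2), rep(c("group1", "group2"), each = 6),
                             n_boot = 200, seed = 2)
  expect_true(all(qc2$difference == 0))
  expect_true(all(qc2$ci_lower <= 0 & qc2$ci_upper >= 0))

  # a known 120 kcal/day location shift is recovered within the bootstrap CI
  set.seed(3)
  a <- rlnorm(200, log(800), 0.25)
  b <- a * 0 + rlnorm(200, log(920), 0.25)
  qc3 <- quantile_group_diff(c(a, b), rep(c("group1", "group2"), each = 200),
                             taus = 0.5, n_boot = 500, seed = 4)
  expect_true(qc3$ci_lower <= 120 && 120 <= qc3$ci_upper)
  expect_error(quantile_group_diff(1:8, rep(c("group1", "group2"), 4),
                                   taus = 0.5), "at least 5")
  expect_error(quantile_group_diff(1:10, rep(c("group1", "group2"), 5),
                                   taus = c(0.5, 1.2)), "taus")
})

test_that("the intake model reports per-unit and scaled effects consistently", {
  set.seed(13)
  n <- 1000
  intake <- runif(n, 600, 2000)
  age <- runif(n, 1, 18)
  ree <- 200 + (163 / 388) * intake + (102 / 4.75) * age + rnorm(n, 0, 120)
  im <- intake_model(ree, intake, age)
  expect_equal(unname(im$scaled_effects["intake"]), 163, tolerance = 0.1)
  expect_equal(unname(im$scaled_effects["age"]), 102, tolerance = 0.1)
  # scaled effect is exactly coefficient times step
  expect_equal(unname(im$scaled_effects["intake"]),
               unname(im$fit$coefficients["intake"]) * 388, tolerance = 1e-12)

  # incomplete cases are dropped before fitting
  intake[1:100] <- NA
  im2 <- intake_model(ree, intake, age)
  expect_equal(im2$n_complete, 900)

  expect_error(intake_model(ree, rep(1000, n), age), "constant")
  expect_error(intake_model(ree[1:5], intake[1:5], age[1:5]), "complete cases")
})

test_that("generator cohorts reproduce the intake-model scaled effects", {
  ch <- generate_cohort(generator_config(n = 4000, seed = 19))
  im <- intake_model(ch$ree_kcal_day, ch$intake_kcal_day, ch$age_years)
  expect_equal(unname(im$scaled_effects["intake"]), 163, tolerance = 0.1)
  expect_equal(unname(im$scaled_effects["age"]), 102, tolerance = 0.15)
})
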