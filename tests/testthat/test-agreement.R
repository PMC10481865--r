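test_that("Bland-Altman bias, limits and proportional-bias test behave", {
  y1 <- c(100, 200, 150)
  y2 <- c(110, 190, 150)
  ba <- bland_altman(y1, y2)
  expect_equal(ba$mean_bias, 0)
  expect_equal(ba$classic_loa[1], -1.96 * sd(c(-10, 10, 0)))
  expect_true(ba$classic_loa[1] <= ba$mean_bias &&
                ba$mean_bias <= ba$classic_loa[2])

  # identical methods: zero bias, degenerate limits, no trend to test
  same <- c(100, 150, 210)
  ba2 <- bland_altman(same, same)
  expect_equal(ba2$mean_bias, 0)
  expect_equal(unname(ba2$classic_loa), c(0, 0))
  expect_equal(ba2$pearson_r_bias_vs_mean, 0)
  expect_equal(ba2$p_value, 1)

  expect_error(bland_altman(c(1, 2), c(1, 2)), "at least 3")
  expect_error(bland_altman(c(5, 5, 5), c(5, 5, 5)), "zero variance")

  # a known negative difference-vs-mean slope is detected at n = 200
  set.seed(99)
  a <- runif(200, 500, 1500)
  d <- 50 - 0.4 * a + rnorm(200, 0, 40)
  y1 <- a + d / 2
  y2 <- a - d / 2
  ba3 <- bland_altman(y1, y2)
  expect_lt(ba3$pearson_r_bias_vs_mean, -0.8)
  expect_lt(ba3$p_value, 1e-6)
})

test_that("Carstensen difference-on-average fit matches hand algebra", {
  same <- c(100, 150, 210, 320)
  cf0 <- carstensen_loa(same, same)
  expect_equal(cf0$a, 0)
  expect_equal(cf0$b, 0)
  expect_equal(cf0$tau, 0)
  # at b = 0 the sloped limits reduce to mean +/- 2 tau
  loa <- cf0$sloped_loa(c(100, 500))
  expect_equal(unname(loa[, "lower"]), c(0, 0))

  # y2 = 2 y1 exactly: D = -y1, A = 1.5 y1 => a = 0, b = -2/3, tau = 0
  y1 <- 1:10
  cf <- carstensen_loa(y1, 2 * y1)
  expect_equal(cf$a, 0, tolerance = 1e-9)
  expect_equal(cf$b, -2 / 3, tolerance = 1e-9)
  expect_equal(cf$tau, 0, tolerance = 1e-9)

  expect_error(carstensen_loa(c(5, 5, 5), c(5, 5, 5)), "degenerate")
})

test_that("Carstensen fit recovers known generating parameters by simulation", {
  set.seed(7)
  n <- 1000
  A <- runif(n, 500, 1500)
  D <- 560 - 0.52 * A + rnorm(n, 0, 60)
  y1 <- A + D / 2
  y2 <- A - D / 2
  cf <- carstensen_loa(y1, y2)
  expect_equal(cf$a, 560, tolerance = 0.05)
  expect_equal(cf$b, -0.52, tolerance = 0.05)
  expect_equal(cf$tau, 60, tolerance = 0.05)
})

test_that("OLS of differences on averages matches a brute-force oracle", {
  set.seed(11)
  for (n in c(5, 8, 12)) {
    y1 <- runif(n, 600, 1200)
    y2 <- y1 + rnorm(n, 30, 50)
    cf <- carstensen_loa(y1, y2)
    beta <- ols_oracle(cbind(1, (y1 + y2) / 2), y1 - y2)
    expect_equal(cf$a, beta[1], tolerance = 1e-9)
    expect_equal(cf$b, beta[2], tolerance = 1e-9)
  }
})

test_that("conversion equations carry the published orientation and invert", {
  # degenerate fit: both directions are the identity
  same <- c(100, 150, 210, 320)
  ce0 <- conversion_equations(carstensen_loa(same, same))
  expect_equal(ce0$y1_from_y2$slope, 1)
  expect_equal(ce0$y1_from_y2$intercept, 0)
  expect_equal(ce0$y2_from_y1$halfwidth, 0)
  expect_equal(convert(123.4, ce0$y2_from_y1)$point, 123.4)

  # the y2 = 2 y1 case: correcting y1 towards y2 doubles it
  ce <- conversion_equations(carstensen_loa(1:10, 2 * (1:10)))
  expect_equal(ce$y2_from_y1$slope, 2, tolerance = 1e-9)
  expect_equal(ce$y2_from_y1$intercept, 0, tolerance = 1e-9)

  # a fit with (a, b) = (560, -0.5185) back-solves the published
  # Harris-Benedict correction of -756.1 + 1.70 x
  fit <- structure(list(a = 560, b = -0.5185, tau = 0, n = 99), class = "carstensen_fit")
  eq <- conversion_equations(fit)$y2_from_y1
  expect_equal(eq$intercept, -756.1, tolerance = 1e-3)
  expect_equal(eq$slope, 1.70, tolerance = 1e-3)

  # interval arithmetic
  eq2 <- conversion_equation("y2_from_y1", 0, 2, halfwidth = 10)
  out <- convert(100, eq2)
  expect_equal(out$point, 200)
  expect_equal(unname(out$interval[1, ]), c(190, 210))

  expect_error(conversion_equations(structure(list(a = 0, b = 2.1, tau = 1),
                                              class = "carstensen_fit")),
               "degenerate")
})

test_that("the two conversion directions compose to the identity", {
  set.seed(5)
  for (i in 1:1000) {
    fit <- structure(list(a = runif(1, -800, 800), b = runif(1, -1.9, 1.9),
                          tau = runif(1, 0, 120)),
                     class = "carstensen_fit")
    ce <- conversion_equations(fit)
    s <- ce$y1_from_y2$slope * ce$y2_from_y1$slope
    icpt <- ce$y1_from_y2$intercept + ce$y1_from_y2$slope * ce$y2_from_y1$intercept
    expect_equal(s, 1, tolerance = 1e-9)
    expect_equal(icpt, 0, tolerance = 1e-6)
  }
})

test_that("Lin's CCC matches its moment formula, oracle and sign properties", {
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4))$estimate, 4 / 7, tolerance = 1e-12)
  x <- c(3, 7, 11, 2)
  expect_equal(lin_ccc(x, x)$estimate, 1)
  expect_lt(lin_ccc(x, -x + 10)$estimate, 0)
  expect_error(lin_ccc(c(2, 2, 2), c(2, 2, 2)), "zero total variance")

  set.seed(21)
  for (n in c(5, 9, 12)) {
    a <- rnorm(n, 800, 150)
    b <- a + rnorm(n, 40, 80)
    cc <- lin_ccc(a, b)
    expect_equal(cc$estimate, ccc_oracle(a, b), tolerance = 1e-9)
    # precision-accuracy decomposition: |CCC| <= |r|
    expect_lte(abs(cc$estimate), abs(cor(a, b)) + 1e-12)
    expect_true(cc$ci95[1] <= cc$estimate && cc$estimate <= cc$ci95[2])
  }
  # equality when means and variances match exactly
  a <- c(1, 2, 3, 4)
  b <- c(2, 1, 4, 3)
  expect_equal(lin_ccc(a, b)$estimate, cor(a, b), tolerance = 1e-12)
})

test_that("formula ranking by concordance is consistent and ordered", {
  ch <- generate_cohort(generator_config(n = 120, seed = 14))
  preds <- predict_all(ch)
  tab <- compare_formulas_ccc(preds, as.data.frame(ch))
  expect_equal(nrow(tab), 8)
  expect_true(all(diff(tab$ccc) <= 0))
  # each row matches a standalone computation
  for (i in seq_len(nrow(tab))) {
    f <- tab$formula[i]
    p <- preds[preds$formula == f & preds$status == "ok", ]
    m <- match(p$id, ch$id)
    expect_equal(tab$ccc[i], lin_ccc(p$ree_kcal_day, ch$ree_kcal_day[m])$estimate)
  }
  # an exact predictor ranks first with CCC 1
  fake <- rbind(preds,
                data.frame(id = ch$id, formula = "EXACT",
                           ree_kcal_day = ch$ree_kcal_day, status = "ok"))
  tab2 <- compare_formulas_ccc(fake, as.data.frame(ch))
  expect_equal(tab2$formula[1], "EXACT")
  expect_equal(tab2$ccc[1], 1)
  # the population-specific weight+TSF formula wins on generator cohorts
  expect_equal(tab$formula[1], "CP_FINAL")
})
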