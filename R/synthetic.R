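# Run code with a locally seeded Mersenne-Twister stream, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

# Log-normal parameters matched to a (median, IQR) pair: mu from the median,
# sigma from the quartile ratio. Only the ratio q3/q1 is identifiable; the
# implied quartiles then sit symmetrically around the median on log scale.
lognormal_params <- function(median, iqr, what = "variable") {
  if (!(is.numeric(iqr) && length(iqr) == 2 && all(iqr > 0) && iqr[1] < iqr[2])) {
    stop(what, ": iqr must be two positive increasing values", call. = FALSE)
  }
  if (!(is.numeric(median) && median > 0)) {
    stop(what, ": median must be positive", call. = FALSE)
  }
  list(mu = log(median), sigma = log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75)))
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the clinical population the package targets: n = 100
#' children with spastic quadriplegic cerebral palsy, 65% male, with median
#' (IQR) age 9 (6, 14) years, weight 19.45 (14.43, 26.05) kg, height 118
#' (107.55, 135.25) cm, triceps skinfold 7.7 (5.4, 9.2) mm and median RQ
#' 0.7144. Measured REE follows the population-specific linear structure
#' `REE = ree_intercept + ree_coeff_weight * weight + ree_coeff_tsf * tsf`
#' plus Gaussian noise (sd 200 kcal/day, the residual scale of the validated
#' model), truncated below at 250 kcal/day. Caloric intake is generated so
#' that a multivariable regression of REE on intake and age recovers, in
#' expectation, an REE increase of 163 kcal/day per +388 kcal/day intake and
#' 102 kcal/day per +4.75 years of age.
#'
#' @param n number of subjects.
#' @param seed integer RNG seed.
#' @param male_fraction proportion of boys.
#' @param weight_median,weight_iqr weight distribution, kg (median and
#'   c(q1, q3) of a log-normal).
#' @param tsf_median,tsf_iqr triceps skinfold, mm.
#' @param age_median,age_iqr age, years (truncated above at 19).
#' @param height_median,height_iqr height, cm.
#' @param ree_coeff_weight,ree_coeff_tsf,ree_intercept coefficients of the
#'   REE-generating linear model (kcal/day per kg, per mm, and kcal/day).
#' @param ree_noise_sd residual sd of measured REE, kcal/day.
#' @param ree_floor lower truncation for measured REE, kcal/day.
#' @param intake_slope REE change per kcal/day of caloric intake.
#' @param intake_age_slope REE change per year of age (at fixed intake).
#' @param intake_median median caloric intake anchoring the intake scale,
#'   kcal/day.
#' @param intake_noise_sd sd of the intake noise, kcal/day.
#' @param rq_median centre of the respiratory-quotient distribution; draws
#'   are kept inside (0.6, 0.9).
#' @param weight_tsf_spearman rank correlation between weight and skinfold
#'   (Gaussian copula). The remaining dependence structure (age-height 0.8,
#'   age-weight 0.6, height-weight 0.7 on the latent normal scale) is fixed:
#'   it only enforces anthropometric plausibility.
#' @param zscore_mean,zscore_sd BMI-for-age z-scores are generated from the
#'   weight latent normal with this location and scale, so heavier-for-cohort
#'   children get better nutritional-status scores.
#' @param feeding_probs probabilities of oral/enteral/mixed feeding.
#' @param inject_outlier if `TRUE`, the lightest subject is turned into a
#'   severe-malnutrition outlier (REE 209 kcal/day, z-score -4.63) to exercise
#'   [exclude_extreme_ree()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n = 100,
                             seed = 1L,
                             male_fraction = 0.65,
                             weight_median = 19.45, weight_iqr = c(14.43, 26.05),
                             tsf_median = 7.70, tsf_iqr = c(5.40, 9.20),
                             age_median = 9, age_iqr = c(6, 14),
                             height_median = 118, height_iqr = c(107.55, 135.25),
                             ree_coeff_weight = 28.43,
                             ree_coeff_tsf = -17,
                             ree_intercept = 398.2,
                             ree_noise_sd = 200,
                             ree_floor = 250,
                             intake_slope = 163 / 388,
                             intake_age_slope = 102 / 4.75,
                             intake_median = 1146,
                             intake_noise_sd = 150,
                             rq_median = 0.7144,
                             weight_tsf_spearman = 0.3,
                             zscore_mean = -2.05, zscore_sd = 1.3,
                             feeding_probs = c(oral = 0.64, enteral = 0.29, mixed = 0.07),
                             inject_outlier = FALSE) {
  cfg <- as.list(environment())
  if (!(is.numeric(cfg$n) && length(cfg$n) == 1 && cfg$n >= 0 && cfg$n == floor(cfg$n))) {
    stop("n must be a non-negative integer", call. = FALSE)
  }
  if (cfg$ree_noise_sd < 0) stop("ree_noise_sd must be >= 0", call. = FALSE)
  if (cfg$male_fraction < 0 || cfg$male_fraction > 1) {
    stop("male_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$intake_slope <= 0) stop("intake_slope must be positive", call. = FALSE)
  # fail fast on unsatisfiable median/IQR pairs
  lognormal_params(cfg$weight_median, cfg$weight_iqr, "weight")
  lognormal_params(cfg$tsf_median, cfg$tsf_iqr, "tsf")
  lognormal_params(cfg$age_median, cfg$age_iqr, "age")
  lognormal_params(cfg$height_median, cfg$height_iqr, "height")
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic cohort
#'
#' Draws `config$n` subjects whose anthropometry has log-normal marginals
#' matched to the configured medians and IQRs, correlated through a Gaussian
#' copula, and whose measured REE, caloric intake, RQ, feeding mode and BMI
#' z-score follow the structure described in [generator_config()].
#' Deterministic under a fixed seed.
#'
#' @param config a [generator_config()].
#' @return A [cohort()] with provenance `"generator seed <seed>"`.
#' @examples
#' generate_cohort(generator_config(n = 5, seed = 42))
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- as.integer(config$n)
  prov <- sprintf("generator seed %d", as.integer(config$seed))
  if (n == 0) {
    empty <- data.frame(id = character(0), sex = character(0),
                        age_years = numeric(0), weight_kg = numeric(0))
    return(cohort(empty, provenance = prov))
  }
  with_seed(config$seed, {
    wp <- lognormal_params(config$weight_median, config$weight_iqr, "weight")
    tp <- lognormal_params(config$tsf_median, config$tsf_iqr, "tsf")
    ap <- lognormal_params(config$age_median, config$age_iqr, "age")
    hp <- lognormal_params(config$height_median, config$height_iqr, "height")

    # latent-normal correlation: order (age, height, weight, tsf); the
    # weight-tsf entry converts the configured Spearman rho to Pearson on
    # the normal scale.
    r_wt <- 2 * sin(pi * config$weight_tsf_spearman / 6)
    R <- matrix(c(
      1.00, 0.80, 0.60, 0.15,
      0.80, 1.00, 0.70, 0.15,
      0.60, 0.70, 1.00, r_wt,
      0.15, 0.15, r_wt, 1.00), 4, 4)
    L <- chol(R)
    Z <- matrix(stats::rnorm(n * 4), n, 4) %*% L

    age <- pmin(exp(ap$mu + ap$sigma * Z[, 1]), 19)
    height <- exp(hp$mu + hp$sigma * Z[, 2])
    weight <- exp(wp$mu + wp$sigma * Z[, 3])
    tsf <- exp(tp$mu + tp$sigma * Z[, 4])

    sex <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")
    feeding <- sample(names(config$feeding_probs), n, replace = TRUE,
                      prob = config$feeding_probs)
    zscore <- config$zscore_mean + config$zscore_sd * Z[, 3]

    ac_z <- 0.6 * Z[, 3] + sqrt(1 - 0.36) * stats::rnorm(n)
    acp <- lognormal_params(18, c(15.2, 20.0), "arm circumference")
    arm_circ <- exp(acp$mu + acp$sigma * ac_z)

    # measured REE: linear weight+TSF structure with Gaussian noise and a
    # physiological floor; the floor clamp distorts the conditional mean far
    # less than resampling the residual would, keeping coefficient recovery
    # honest for all but the most extreme low-weight/high-TSF subjects.
    mu_ree <- config$ree_intercept + config$ree_coeff_weight * weight +
      config$ree_coeff_tsf * tsf
    ree <- pmax(mu_ree + stats::rnorm(n, 0, config$ree_noise_sd), config$ree_floor)

    # caloric intake: invert the target multivariable relation
    # REE = c0 + intake_slope * intake + intake_age_slope * age, anchored so
    # the median-subject intake equals intake_median, plus independent noise.
    med_ree <- config$ree_intercept + config$ree_coeff_weight * config$weight_median +
      config$ree_coeff_tsf * config$tsf_median
    intake <- config$intake_median +
      ((ree - config$intake_age_slope * age) - (med_ree - config$intake_age_slope * config$age_median)) /
        config$intake_slope +
      stats::rnorm(n, 0, config$intake_noise_sd)
    intake <- pmax(intake, 100)

    rq <- stats::rnorm(n, config$rq_median, 0.09)
    for (iter in seq_len(100)) {
      bad <- rq <= 0.6 | rq >= 0.9
      if (!any(bad)) break
      rq[bad] <- stats::rnorm(sum(bad), config$rq_median, 0.09)
    }
    rq <- pmin(pmax(rq, 0.601), 0.899)

    df <- data.frame(
      id = sprintf("S%0*d", max(3L, nchar(n)), seq_len(n)),
      sex = sex,
      age_years = age,
      weight_kg = weight,
      height_cm = height,
      knee_height_cm = (height - 24.2) / 2.69,
      tsf_mm = tsf,
      arm_circumference_cm = arm_circ,
      feeding = feeding,
      bmi_zscore = zscore,
      ree_kcal_day = ree,
      rq = rq,
      intake_kcal_day = intake,
      stringsAsFactors = FALSE
    )
    if (isTRUE(config$inject_outlier)) {
      i <- which.min(df$weight_kg)
      df$ree_kcal_day[i] <- 209
      df$bmi_zscore[i] <- -4.63
    }
    cohort(df, provenance = prov)
  })
}

#' Generate a synthetic breath-by-breath calorimetry trace
#'
#' Produces a gas-exchange series whose stationary segment is constructed so
#' that the abbreviated Weir equation applied to its mean VO2/VCO2 returns
#' `ree_true` and the VCO2/VO2 ratio returns `rq_true`. The first
#' `unsteady_lead` minutes carry a large (+/-50%) slow oscillation in VO2 (and
#' proportionally in VCO2 and minute ventilation) so that no steady-state
#' window overlapping the lead by more than a fraction of a minute can satisfy
#' the variation criteria; the remainder has breath-level noise with
#' coefficients of variation of roughly 2% (VO2, VE) and 1.2% (RQ), well under
#' the steady-state tolerances. Breaths arrive about every 2 seconds.
#' Deterministic under a fixed seed.
#'
#' @param ree_true target resting energy expenditure, kcal/day.
#' @param rq_true target respiratory quotient (in \[0.6, 1.2\]).
#' @param duration total trace length, minutes.
#' @param unsteady_lead length of the initial unsteady segment, minutes
#'   (`0 <= unsteady_lead < duration`).
#' @param seed integer RNG seed.
#' @return A `breath_series` data frame with columns `time_min`,
#'   `vo2_ml_min`, `vco2_ml_min`, `ve_l_min`.
#' @export
generate_breath_series <- function(ree_true = 800, rq_true = 0.75,
                                   duration = 30, unsteady_lead = 0,
                                   seed = 1L) {
  if (!(rq_true >= 0.6 && rq_true <= 1.2)) {
    stop("rq_true must lie in [0.6, 1.2]", call. = FALSE)
  }
  if (!(duration > unsteady_lead && unsteady_lead >= 0)) {
    stop("need duration > unsteady_lead >= 0", call. = FALSE)
  }
  with_seed(seed, {
    dt <- 2 / 60 # nominal breath interval, minutes
    gaps <- dt * stats::runif(ceiling(duration / dt) + 10, 0.9, 1.1)
    t <- cumsum(gaps)
    t <- t[t <= duration]
    nb <- length(t)
    # invert abbreviated Weir for the target VO2 (ml/min)
    vo2_target <- ree_true / (1.44 * (3.941 + 1.106 * rq_true))
    drift <- ifelse(t < unsteady_lead, 1 + 0.5 * cos(2 * pi * t / 2), 1)
    vo2 <- vo2_target * drift * (1 + stats::rnorm(nb, 0, 0.02))
    vco2 <- rq_true * vo2 * (1 + stats::rnorm(nb, 0, 0.012))
    ve <- 0.028 * vo2 * (1 + stats::rnorm(nb, 0, 0.02))
    breath_series(data.frame(time_min = t, vo2_ml_min = vo2,
                             vco2_ml_min = vco2, ve_l_min = ve))
  })
}
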