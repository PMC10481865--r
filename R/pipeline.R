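#' Configuration for a full pipeline run
#'
#' @param input either a path to a cohort CSV or a [generator_config()] (the
#'   default simulates the target population).
#' @param formulas prediction formulas to evaluate ([formula_ids()]).
#' @param min_ree exclusion threshold for implausible calorimetry values,
#'   kcal/day (see [exclude_extreme_ree()]).
#' @param train_n training-set size for the historical split validation.
#' @param n_boot bootstrap resamples for the optimism correction.
#' @param seed master seed; per-stage substreams are derived from it so
#'   stages can be re-run in isolation.
#' @param output_dir directory for the report bundle.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = generator_config(),
                       formulas = formula_ids(),
                       min_ree = 300,
                       train_n = 54,
                       n_boot = 3000,
                       seed = 1L,
                       output_dir = "cpree-run") {
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  if (train_n < 10) stop("train_n must be >= 10", call. = FALSE)
  structure(list(input = input, formulas = formulas, min_ree = min_ree,
                 train_n = train_n, n_boot = n_boot, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 97 + k) %% .Machine$integer.max)
}

drop_functions <- function(x) {
  if (is.list(x)) lapply(Filter(function(e) !is.function(e), unclass(x)), drop_functions)
  else x
}

#' Run the full REE analysis pipeline
#'
#' Orchestrates: cohort ingestion or simulation, exclusion of implausible
#' calorimetry values, prediction with all requested formulas, agreement
#' analysis per formula (Bland-Altman, Carstensen limits, conversion
#' equations), model development (final weight + TSF fit, spline
#' nonlinearity test, backward selection, bootstrap optimism correction,
#' historical train/test split with CCC ranking) and nomogram construction.
#' Each stage's result is written under `output_dir` (`cohort.csv`,
#' `predictions.csv`, `agreement/<formula>.json`, `model.json`,
#' `validation.json`, `ccc_table.csv`, `nomogram_ticks.csv`, `run.log`).
#' Stage failures are recorded and later independent stages still run;
#' identical config and seed give identical reports.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results and an `errors`
#'   character vector (empty on full success).
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  errors <- character(0)
  note_error <- function(stage, e) {
    errors <<- c(errors, sprintf("%s: %s", stage, conditionMessage(e)))
    NULL
  }
  write_json <- function(x, file) {
    jsonlite::write_json(drop_functions(x), file.path(config$output_dir, file),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out <- list()

  # -- cohort ---------------------------------------------------------------
  out$cohort <- tryCatch({
    ch <- if (inherits(config$input, "generator_config")) {
      cfg <- config$input
      cfg$seed <- stage_seed(config$seed, 1)
      generate_cohort(cfg)
    } else {
      read_cohort_csv(config$input)
    }
    ch <- suppressMessages(exclude_extreme_ree(ch, config$min_ree))
    write_cohort_csv(ch, file.path(config$output_dir, "cohort.csv"))
    ch
  }, error = function(e) note_error("cohort", e))
  if (is.null(out$cohort)) {
    writeLines(errors, file.path(config$output_dir, "run.log"))
    return(invisible(structure(out, errors = errors)))
  }

  # -- predictions ----------------------------------------------------------
  out$predictions <- tryCatch({
    p <- predict_all(out$cohort, config$formulas)
    utils::write.csv(p, file.path(config$output_dir, "predictions.csv"),
                     row.names = FALSE)
    p
  }, error = function(e) note_error("predictions", e))

  # -- agreement ------------------------------------------------------------
  if (!is.null(out$predictions)) {
    dir.create(file.path(config$output_dir, "agreement"), showWarnings = FALSE)
    out$agreement <- list()
    for (f in unique(out$predictions$formula)) {
      out$agreement[[f]] <- tryCatch({
        p <- out$predictions[out$predictions$formula == f, ]
        m <- match(p$id, out$cohort$id)
        keep <- !is.na(p$ree_kcal_day) & !is.na(out$cohort$ree_kcal_day[m])
        y1 <- p$ree_kcal_day[keep]
        y2 <- out$cohort$ree_kcal_day[m][keep]
        ba <- bland_altman(y1, y2)
        cf <- carstensen_loa(y1, y2)
        conv <- conversion_equations(cf)
        rep <- list(formula = f, n = length(y1),
                    bland_altman = ba, carstensen = cf,
                    conversion = conv)
        write_json(rep, file.path("agreement", paste0(f, ".json")))
        rep
      }, error = function(e) note_error(paste0("agreement/", f), e))
    }
  }

  # -- model development ----------------------------------------------------
  out$model <- tryCatch({
    ch <- out$cohort
    final <- fit_linear(ree_kcal_day ~ weight_kg + tsf_mm, ch)
    rb <- rcs_basis(ch$weight_kg)
    spl_df <- as.data.frame(ch)
    spl_df$weight_rcs <- rb$basis[, "x_rcs"]
    spline_fit <- fit_linear(ree_kcal_day ~ weight_kg + weight_rcs + tsf_mm, spl_df)
    lrt <- lrt_nonlinearity(final, spline_fit)
    selected <- backward_select(ch)
    rep <- list(final = list(terms = final$terms,
                             coefficients = as.list(final$coefficients),
                             r2adj = final$r2adj, mse = final$mse,
                             residual_sd = final$residual_sd, n = final$n),
                spline_knots = rb$knots,
                lrt_nonlinearity = lrt,
                backward_selected_terms = selected$terms)
    write_json(rep, "model.json")
    list(final = final, spline = spline_fit, lrt = lrt, selected = selected,
         report = rep)
  }, error = function(e) note_error("model", e))

  # -- validation -----------------------------------------------------------
  out$validation <- tryCatch({
    bv <- bootstrap_validate(out$cohort, ree_kcal_day ~ weight_kg + tsf_mm,
                             n_boot = config$n_boot,
                             seed = stage_seed(config$seed, 2))
    write_json(list(r2 = bv$r2, mse = bv$mse), "validation.json")
    bv
  }, error = function(e) note_error("validation", e))

  # -- CCC comparison on the held-out split ---------------------------------
  out$ccc <- tryCatch({
    split <- train_test_split_validate(out$cohort,
                                       ree_kcal_day ~ weight_kg + tsf_mm,
                                       train_n = config$train_n)
    test_ids <- split$test$id
    preds <- out$predictions[out$predictions$id %in% test_ids, ]
    preds <- rbind(preds,
                   data.frame(id = split$test$id, formula = "NEW_MODEL",
                              ree_kcal_day = split$test$predicted,
                              status = "ok", stringsAsFactors = FALSE))
    tab <- compare_formulas_ccc(preds, as.data.frame(out$cohort))
    utils::write.csv(tab, file.path(config$output_dir, "ccc_table.csv"),
                     row.names = FALSE)
    list(split = split, table = tab)
  }, error = function(e) note_error("ccc", e))

  # -- nomogram -------------------------------------------------------------
  out$nomogram <- tryCatch({
    fit <- if (!is.null(out$ccc)) out$ccc$split$model else out$model$final
    nom <- build_nomogram(fit)
    render_nomogram(nom, file.path(config$output_dir, "nomogram_ticks.csv"))
    nom
  }, error = function(e) note_error("nomogram", e))

  writeLines(c(sprintf("cpree %s", as.character(utils::packageVersion("cpree"))),
               sprintf("seed %d", config$seed),
               sprintf("n_boot %d", config$n_boot),
               sprintf("train_n %d", config$train_n),
               if (length(errors)) paste("ERROR", errors) else "status ok"),
             file.path(config$output_dir, "run.log"))
  invisible(structure(out, errors = errors))
}
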