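#' Configuration for an end-to-end pipeline run
#'
#' Bundles every knob of the simulate -> fuse -> features -> fit ->
#' predict -> evaluate chain. All randomness flows from the single
#' `seed`, expanded per stage by fixed offsets, so a config re-runs
#' bit-identically.
#'
#' @param params [sim_params()] for the simulated cohort (or `NULL` when
#'   `cohort` is supplied to [run_pipeline()]).
#' @param scheme A `ptml_scheme`.
#' @param level Data level preset for [pt_config()].
#' @param task `"classification"` or `"regression"`.
#' @param algorithm `"LDA"` (linear discriminant scoring) or any
#'   [ml_spec()] algorithm.
#' @param split_fraction,split_mode Split settings, see
#'   [split_train_validation()].
#' @param seed Master seed (mandatory).
#' @param ... Extra algorithm settings forwarded to [ml_spec()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(params = sim_params(), scheme = default_scheme(),
                       level = c("ma", "raw", "ed"),
                       task = c("classification", "regression"),
                       algorithm = "LDA",
                       split_fraction = 0.75,
                       split_mode = c("case", "patient"),
                       seed, ...) {
  level <- match.arg(level)
  task <- match.arg(task)
  split_mode <- match.arg(split_mode)
  if (missing(seed)) rlang::abort("`seed` is mandatory.")
  structure(list(params = params, scheme = scheme, level = level,
                 task = task, algorithm = algorithm,
                 split_fraction = split_fraction, split_mode = split_mode,
                 seed = as.integer(seed), settings = list(...)),
            class = "run_config")
}

#' Run the full IFPTML pipeline
#'
#' Simulates (or accepts) a cohort, builds and imputes the case table,
#' splits it, fits the group means and reference prior on the training
#' side only, builds the level's features for both sides, fits the model,
#' and evaluates both sides. Per-stage row counts and the fitted-model
#' summary are logged via `message()`; the returned manifest (seeds,
#' sizes, config hash) is sufficient to reproduce the run bit-identically.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-built `ptml_cohort` (skips simulation).
#' @return A list of class `ptml_run`: `cohort`, `cases`, `split`,
#'   `means`, `features` (train/validation), `model`, `predictions`,
#'   `metrics` (train/validation), `manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  cohort <- cohort %||% simulate_cohort(config$params, seed = seed)
  message(sprintf("cohort: %d patients, %d visits",
                  nrow(cohort$patients), nrow(cohort$visits)))
  cases <- build_case_table(cohort, config$scheme)
  cases <- impute_missing(cases)
  message(sprintf("cases: %d rows, prevalence(Within) = %.3f",
                  nrow(cases), mean(cases$output_class == "Within")))
  split <- split_train_validation(cases, config$split_fraction,
                                  config$split_mode, seed = seed + 1L)
  cfg <- pt_config(config$level)
  means <- fit_group_means(split$train)
  feats <- list(
    train = build_features(split$train, means, split$train, cfg),
    validation = build_features(split$validation, means, split$train, cfg)
  )
  pred <- list()
  metrics <- list()
  if (config$task == "classification" && config$algorithm == "LDA") {
    model <- fit_lda(feats$train,
                     lambda = config$settings$lambda %||% 1e-6)
    for (set in names(feats)) {
      sc <- score_linear(feats[[set]], model)
      pred[[set]] <- sc
      metrics[[set]] <- classification_metrics(
        feats[[set]]$output_class, sc$class, sc$score)
    }
  } else {
    spec <- do.call(ml_spec, c(list(task = config$task,
                                    algorithm = config$algorithm,
                                    seed = seed + 2L),
                               config$settings))
    model <- fit_ml(feats$train, spec)
    for (set in names(feats)) {
      p <- stats::predict(model, feats[[set]])
      pred[[set]] <- tibble::tibble(case_id = feats[[set]]$case_id,
                                    prediction = p)
      metrics[[set]] <- if (config$task == "regression") {
        dplyr::bind_cols(regression_metrics(feats[[set]]$inr, p),
                         pb_bins(feats[[set]]$inr, p))
      } else {
        classification_metrics(feats[[set]]$output_class, p)
      }
    }
  }
  message(sprintf("model: %s %s on %s features",
                  config$algorithm, config$task, config$level))
  manifest <- list(
    seed = seed,
    config_hash = rlang::hash(config),
    n_patients = nrow(cohort$patients),
    n_cases = nrow(cases),
    n_train = nrow(split$train),
    n_validation = nrow(split$validation),
    level = config$level, task = config$task,
    algorithm = config$algorithm,
    package_version = as.character(utils::packageVersion("ifptml"))
  )
  structure(list(cohort = cohort, cases = cases, split = split,
                 means = means, features = feats, model = model,
                 predictions = pred, metrics = metrics,
                 manifest = manifest),
            class = "ptml_run")
}

#' @export
print.ptml_run <- function(x, ...) {
  cat(sprintf("<ptml_run> %s %s, level %s | train %d / validation %d cases\n",
              x$manifest$algorithm, x$manifest$task, x$manifest$level,
              x$manifest$n_train, x$manifest$n_validation))
  invisible(x)
}

#' Predict new cases with a frozen transform and fitted model
#'
#' Applies the training-time group means and reference prior to a new
#' case table, scores it with a fitted linear model, and returns score,
#' posterior probability (when a calibration is supplied) and predicted
#' class per case. This is the batch-prediction entry point that replaces
#' an interactive spreadsheet template: feed it any case file in the
#' scheme's column roster.
#'
#' @param cases A `ptml_cases` table (e.g. from [read_cases()]).
#' @param model A `ptml_linear_model`.
#' @param means The frozen `ptml_group_means` from training.
#' @param train Labelled training table for the reference prior.
#' @param cfg [pt_config()]; its level must match the model's.
#' @param calibration Optional `ptml_calibration` for posterior output.
#' @return Tibble: `case_id`, `score`, `probability`, `class`.
#' @export
predict_cases <- function(cases, model, means, train,
                          cfg = pt_config(model$level),
                          calibration = NULL) {
  if (cfg$level != model$level) {
    rlang::abort(sprintf("model level `%s` does not match pt_config level `%s`.",
                         model$level, cfg$level))
  }
  if (nrow(cases) == 0) {
    rlang::warn("empty case table: returning empty predictions.")
    return(tibble::tibble(case_id = character(), score = numeric(),
                          probability = numeric(), class = character()))
  }
  feats <- build_features(cases, means, train, cfg)
  sc <- score_linear(feats, model)
  sc$probability <- if (!is.null(calibration)) {
    posterior_probability(calibration, sc$score)
  } else {
    NA_real_
  }
  sc[c("case_id", "score", "probability", "class")]
}
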