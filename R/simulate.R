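#' INR response to a recent dosing history
#'
#' The generator's dose-response model. Effective exposure is an
#' exponentially weighted sum of the doses administered on the `window`
#' days preceding the measurement, E = sum_d w_d * dose(t - d) with
#' w_d = 2^(-d / halflife) normalised over the full window, so a freshly
#' started regimen approaches its steady-state effect over a few
#' half-lives. The INR is then
#' `baseline + beta * G * E / weight + noise`, floored at 0.8, where G is
#' the product of the patient's genotype sensitivity multipliers.
#'
#' @param dose_history Numeric vector of daily doses (mg/d) on the days
#'   preceding the measurement, most recent day first (element `d` is the
#'   dose `d` days before the INR). Shorter histories are padded with 0.
#' @param weight Patient weight (kg), > 0.
#' @param genotypes Named character vector or list, SNP -> genotype
#'   category, matched against `params$genotype_multipliers`.
#' @param params A [sim_params()] object.
#' @param noise_draw Additive noise (INR units), default 0.
#' @param window Length of the exposure window in days.
#'
#' @return A single INR value (dimensionless), >= 0.8.
#' @export
#' @examples
#' p <- sim_params()
#' inr_response(rep(2.5, 10), weight = 64,
#'              genotypes = c(CYP2C9 = "*1/*1", VKORC1 = "AA"), params = p)
inr_response <- function(dose_history, weight, genotypes, params,
                         noise_draw = 0, window = 63L) {
  if (length(dose_history) == 0) {
    rlang::abort("`dose_history` must cover at least one day.")
  }
  if (any(dose_history < 0)) {
    rlang::abort("`dose_history` contains a negative dose.")
  }
  stopifnot(weight > 0)
  doses <- c(dose_history, rep(0, max(0L, window - length(dose_history))))
  doses <- doses[seq_len(window)]
  w <- 2^(-(seq_len(window)) / params$exposure_halflife_days)
  w <- w / sum(w)
  exposure <- sum(w * doses)
  g <- genotype_multiplier(genotypes, params$genotype_multipliers)
  max(0.8, params$baseline_inr +
        params$sensitivity_beta * g * exposure / weight + noise_draw)
}

genotype_multiplier <- function(genotypes, multipliers) {
  g <- 1
  genotypes <- as.list(genotypes)
  for (snp in names(multipliers)) {
    cat_i <- genotypes[[snp]]
    if (!is.null(cat_i) && !is.na(cat_i) &&
        cat_i %in% names(multipliers[[snp]])) {
      g <- g * multipliers[[snp]][[cat_i]]
    }
  }
  g
}

#' Simulate a longitudinal warfarin cohort
#'
#' Draws per-patient covariates, then walks each patient through a
#' titration loop: visits occur at rounded positive-normal gaps; at each
#' visit the INR is computed with [inr_response()] from the doses actually
#' administered; the clinician-feedback rule then adjusts the daily dose by
#' one `dose_step` towards the target range (below range: +step, above:
#' -step, inside: hold), the new level taking effect the day after the
#' visit. Day 1 is the first dosed day. Labs are measured at every
#' in-hospital visit and with probability `outpatient_lab_prob` afterwards
#' (unmeasured values are `NA`); acute co-medications run only over the
#' in-hospital window, chronic ones over the whole follow-up.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; the cohort is bit-identical for a given seed.
#'
#' @return An object of class `ptml_cohort`: a list with tibbles
#'   `patients` (one row per patient: demographics, surgery, genotypes)
#'   and `visits` (patient_id, day, inr, dose_mg = level administered up
#'   to the visit, dose_next = level prescribed from the next day, lab and
#'   co-medication columns), plus the `params` used.
#' @seealso [build_case_table()], [write_cohort()]
#' @export
simulate_cohort <- function(params = sim_params(), seed = params$rng_seed) {
  validate_sim_params(params)
  withr::with_seed(seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(params) {
  n <- params$n_patients
  gf <- params$genotype_freqs
  patients <- tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    sex = ifelse(stats::runif(n) < params$sex_male_frac, "male", "female"),
    age = round(stats::rnorm(n, params$age_mean, params$age_sd), 1),
    height = round(stats::rnorm(n, params$height_mean, params$height_sd), 1),
    weight = round(pmax(35, stats::rnorm(n, params$weight_mean,
                                         params$weight_sd)), 1),
    surgery_type = sample(names(params$surgery_freqs), n, TRUE,
                          prob = params$surgery_freqs),
    valve_type = sample(names(params$valve_freqs), n, TRUE,
                        prob = params$valve_freqs),
    smoking = ifelse(stats::runif(n) < params$smoking_frac, "yes", "no")
  )
  for (snp in names(gf)) {
    patients[[snp]] <- sample(names(gf[[snp]]), n, TRUE, prob = gf[[snp]])
  }

  cs <- params$comedication_spec
  ls <- params$lab_spec
  visits <- vector("list", n)
  for (i in seq_len(n)) {
    fu_range <- seq(params$follow_up_days[1], params$follow_up_days[2])
    follow_up <- fu_range[sample.int(length(fu_range), 1L)]
    vdays <- integer(0)
    t <- 1L
    repeat {
      gap <- max(1L, as.integer(round(stats::rnorm(1, params$visit_gap_mean,
                                                   params$visit_gap_sd))))
      t <- t + gap
      if (t > follow_up) break
      vdays <- c(vdays, t)
    }
    if (length(vdays) == 0L) vdays <- as.integer(follow_up)

    genos <- as.list(patients[i, names(gf), drop = FALSE])
    # per-patient co-medication assignment and lab baselines
    on_drug <- stats::runif(nrow(cs)) < cs$prevalence
    drug_dose <- round(stats::runif(nrow(cs), cs$dose_min, cs$dose_max), 1)
    lab_base <- stats::rnorm(nrow(ls), ls$mean, ls$sd)

    dose_level <- params$dose_init
    daily <- rep(params$dose_init, max(vdays))
    rows <- vector("list", length(vdays))
    for (j in seq_along(vdays)) {
      d <- vdays[j]
      hist <- rev(daily[seq_len(d - 1L)])  # most recent day first
      noise <- if (params$noise_sd > 0) {
        stats::rnorm(1, 0, params$noise_sd)
      } else 0
      inr <- inr_response(hist, patients$weight[i], genos, params, noise)
      inr <- round(inr, 2)
      new_level <- dose_level
      if (inr < params$target_inr[1]) {
        new_level <- dose_level + params$dose_step
      } else if (inr > params$target_inr[2]) {
        new_level <- max(0, dose_level - params$dose_step)
      }
      measured <- d <= params$inpatient_days ||
        stats::runif(1) < params$outpatient_lab_prob
      labs <- if (measured) {
        round(pmax(0, lab_base + stats::rnorm(nrow(ls), 0, ls$noise_sd)), 3)
      } else {
        rep(NA_real_, nrow(ls))
      }
      active <- on_drug & (cs$chronic | d <= params$inpatient_days)
      comeds <- ifelse(active, drug_dose, 0)
      row <- c(list(patient_id = patients$patient_id[i], day = d,
                    inr = inr, dose_mg = dose_level, dose_next = new_level),
               stats::setNames(as.list(labs), ls$lab),
               stats::setNames(as.list(comeds), cs$drug))
      rows[[j]] <- tibble::as_tibble(row)
      if (d < max(vdays)) {
        daily[(d + 1L):max(vdays)] <- new_level
      }
      dose_level <- new_level
    }
    visits[[i]] <- dplyr::bind_rows(rows)
  }
  out <- list(patients = patients,
              visits = dplyr::bind_rows(visits),
              params = params)
  class(out) <- "ptml_cohort"
  out
}

#' @export
print.ptml_cohort <- function(x, ...) {
  cat(sprintf("<ptml_cohort> %d patients, %d visits (INR measurements)\n",
              nrow(x$patients), nrow(x$visits)))
  cat(sprintf("  mean dose %.2f mg/d, mean INR %.2f, follow-up %d-%d d\n",
              mean(x$visits$dose_mg), mean(x$visits$inr),
              min(x$visits$day), max(x$visits$day)))
  invisible(x)
}

#' Reconstruct the daily dose series of one patient
#'
#' The dose level is piecewise constant: `dose_init` up to and including
#' the first visit, then the level prescribed at each visit from the day
#' after that visit.
#'
#' @param cohort A `ptml_cohort`.
#' @param patient_id Patient identifier.
#' @param until Last day required (defaults to the last visit day).
#' @return Numeric vector `dose[1..until]` of administered daily doses.
#' @export
daily_doses <- function(cohort, patient_id, until = NULL) {
  v <- cohort$visits[cohort$visits$patient_id == patient_id, , drop = FALSE]
  if (nrow(v) == 0) rlang::abort(sprintf("unknown patient `%s`.", patient_id))
  v <- v[order(v$day), ]
  until <- until %||% max(v$day)
  daily <- rep(cohort$params$dose_init, until)
  for (j in seq_len(nrow(v))) {
    d <- v$day[j]
    if (d < until) daily[(d + 1L):until] <- v$dose_next[j]
  }
  daily
}

#' Write / read a cohort as plain-text files
#'
#' `write_cohort()` writes `patients.csv`, `visits.csv` and a
#' `params.json` sidecar into `dir`; `read_cohort()` restores the
#' `ptml_cohort` from them.
#'
#' @param cohort A `ptml_cohort`.
#' @param dir Directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `ptml_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"))
  readr::write_csv(cohort$visits, file.path(dir, "visits.csv"))
  p <- cohort$params
  p$comedication_spec <- as.data.frame(p$comedication_spec)
  p$lab_spec <- as.data.frame(p$lab_spec)
  # named vectors must become JSON objects, not bare arrays
  p$genotype_freqs <- lapply(p$genotype_freqs, as.list)
  p$genotype_multipliers <- lapply(p$genotype_multipliers, as.list)
  p$surgery_freqs <- as.list(p$surgery_freqs)
  p$valve_freqs <- as.list(p$valve_freqs)
  jsonlite::write_json(unclass(p), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  p <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  p$genotype_freqs <- lapply(p$genotype_freqs, unlist)
  p$genotype_multipliers <- lapply(p$genotype_multipliers, unlist)
  p$surgery_freqs <- unlist(p$surgery_freqs)
  p$valve_freqs <- unlist(p$valve_freqs)
  params <- do.call(sim_params, p[setdiff(names(p), "rng_seed")])
  params$rng_seed <- as.integer(p$rng_seed)
  out <- list(
    patients = readr::read_csv(file.path(dir, "patients.csv"),
                               show_col_types = FALSE),
    visits = readr::read_csv(file.path(dir, "visits.csv"),
                             show_col_types = FALSE),
    params = params
  )
  class(out) <- "ptml_cohort"
  out
}
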