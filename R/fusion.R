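#' Label an INR observation as Within or Out of the target range
#'
#' The target interval is closed on both ends: a boundary INR is
#' clinically in range.
#'
#' @param inr Numeric vector of INR values, all > 0.
#' @param target Length-2 numeric interval.
#' @return Character vector of `"Within"` / `"Out"`.
#' @export
#' @examples
#' label_output(c(1.7, 1.8, 2.0, 2.5, 3.0))
label_output <- function(inr, target = c(1.8, 2.5)) {
  if (any(inr <= 0)) rlang::abort("INR values must be positive.")
  ifelse(inr >= target[1] & inr <= target[2], "Within", "Out")
}

#' Encode the dose and treatment-day windows for one visit
#'
#' `DoseK` is the dose administered `K` days before the visit (0 for days
#' before the first dose); `TreatDayK` is the number of consecutive days
#' that dose level had been held as of that day (0 before treatment
#' start). The output always has arity `2 * window`, padding early-course
#' visits with zeros so every case has a fixed-width encoding.
#'
#' @param cohort A `ptml_cohort`.
#' @param patient_id Patient identifier.
#' @param visit_day Day of the INR measurement (must be a visit day, >= 2).
#' @param window Window length in days.
#' @return Named numeric vector `Dose01..DoseNN, TreatDay01..TreatDayNN`.
#' @export
encode_dose_history <- function(cohort, patient_id, visit_day,
                                window = 63L) {
  if (visit_day < 2L) {
    rlang::abort("`visit_day` precedes any dosing (day 1 is the first dosed day).")
  }
  daily <- daily_doses(cohort, patient_id, until = visit_day)
  encode_window(daily, visit_day, window)
}

# daily: administered dose on days 1..(>= visit_day - 1)
encode_window <- function(daily, visit_day, window = 63L) {
  past <- daily[seq_len(visit_day - 1L)]
  runs <- rle(past)
  hold <- sequence(runs$lengths)  # consecutive days the level has been held
  idx <- visit_day - seq_len(window)  # day of lag K
  dose <- ifelse(idx >= 1L, past[pmax(idx, 1L)], 0)
  treat <- ifelse(idx >= 1L, hold[pmax(idx, 1L)], 0)
  stats::setNames(c(dose, treat), c(dose_cols(window), treatday_cols(window)))
}

#' Build the information-fusion case table
#'
#' The horizontal fusion step assembles, for every INR measurement, one
#' row holding the output (`inr`, `output_class`), the continuous inputs
#' (dose and treatment-day windows, demographics, postoperative day, labs,
#' co-medication daily doses) and the categorical label vector named by
#' the scheme's partitions; the vertical step stacks all patients. Rows
#' are ordered by (patient, day) and carry a stable `case_id`.
#'
#' @param cohort A `ptml_cohort`.
#' @param scheme A `ptml_scheme`; its `window` sets the encoding width.
#' @return A tibble of class `ptml_cases` with attribute `scheme`.
#' @export
#' @examples
#' co <- simulate_cohort(sim_params(n_patients = 4), seed = 1)
#' cases <- build_case_table(co, default_scheme())
#' nrow(cases) == nrow(co$visits)
build_case_table <- function(cohort, scheme = default_scheme()) {
  stopifnot(inherits(cohort, "ptml_cohort"), inherits(scheme, "ptml_scheme"))
  v <- cohort$visits
  dup <- duplicated(v[c("patient_id", "day")])
  if (any(dup)) {
    bad <- v[dup, c("patient_id", "day")]
    rlang::abort(sprintf(
      "duplicate INR entries for: %s",
      paste(sprintf("%s day %d", bad$patient_id, bad$day), collapse = ", ")))
  }
  v <- v[order(v$patient_id, v$day), ]
  window <- scheme$window
  label_cols <- unname(scheme$partitions)
  missing_lab <- setdiff(label_cols, names(cohort$patients))
  if (length(missing_lab)) {
    rlang::abort(sprintf("label column(s) missing from patients table: %s",
                         paste(missing_lab, collapse = ", ")))
  }

  # per-patient window encoding (vectorised over that patient's visits)
  enc <- vector("list", nrow(cohort$patients))
  split_v <- split(v, v$patient_id)
  for (k in seq_along(split_v)) {
    vi <- split_v[[k]]
    daily <- daily_doses(cohort, vi$patient_id[1])
    enc[[k]] <- do.call(rbind, lapply(vi$day, function(d) {
      encode_window(daily, d, window)
    }))
  }
  enc <- tibble::as_tibble(do.call(rbind, enc))
  v <- dplyr::bind_rows(split_v)

  static <- cohort$patients[match(v$patient_id, cohort$patients$patient_id), ]
  carried <- setdiff(names(v), c("patient_id", "day", "inr", "dose_mg",
                                 "dose_next"))
  cases <- dplyr::bind_cols(
    tibble::tibble(
      case_id = sprintf("%s_d%03d", v$patient_id, v$day),
      patient_id = v$patient_id,
      visit_day = v$day,
      inr = v$inr,
      output_class = label_output(v$inr, scheme$target_interval)
    ),
    enc,
    tibble::tibble(age = static$age, height = static$height,
                   weight = static$weight, pod = as.numeric(v$day)),
    v[carried],
    static[setdiff(label_cols, "pod")]
  )
  new_cases(cases, scheme)
}

new_cases <- function(df, scheme) {
  df <- tibble::as_tibble(df)
  attr(df, "scheme") <- scheme
  class(df) <- c("ptml_cases", class(df))
  df
}

cases_scheme <- function(cases) {
  sc <- attr(cases, "scheme")
  if (is.null(sc)) rlang::abort("case table carries no scheme attribute.")
  sc
}

#' Impute missing continuous values in a case table
#'
#' Within each patient, missing laboratory (and any other continuous)
#' values are last-observation-carried-forward along visit day; values
#' still missing afterwards are replaced by the mean of the variable over
#' the reference table (by default the table itself; pass the training
#' table via `reference` to transform validation data without leakage).
#' The number of imputed values per variable is reported with a message.
#'
#' @param cases A `ptml_cases` table.
#' @param reference Optional table supplying the fill-in means.
#' @return The imputed `ptml_cases` table, with an `imputation_counts`
#'   attribute.
#' @export
impute_missing <- function(cases, reference = cases) {
  scheme <- cases_scheme(cases)
  vars <- intersect(registered_continuous(scheme), names(cases))
  counts <- integer(0)
  out <- cases
  for (vn in vars) {
    x <- out[[vn]]
    if (!anyNA(x)) next
    n_missing <- sum(is.na(x))
    # LOCF within patient (rows are ordered by patient, day)
    filled <- stats::ave(x, out$patient_id, FUN = locf)
    if (anyNA(filled)) {
      m <- mean(reference[[vn]], na.rm = TRUE)
      if (is.nan(m)) {
        rlang::abort(sprintf("variable `%s` has no observed values.", vn))
      }
      filled[is.na(filled)] <- m
    }
    out[[vn]] <- filled
    counts[vn] <- n_missing
  }
  if (length(counts)) {
    message("imputed values per variable: ",
            paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  }
  attr(out, "imputation_counts") <- counts
  out
}

locf <- function(x) {
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  out <- x
  out[idx > 0L] <- x[idx[idx > 0L]]
  out[idx == 0L] <- NA
  out
}

#' Write / read a case table as CSV
#'
#' The file starts with a `#` manifest line naming the scheme so that a
#' table can be matched to the configuration that produced it. The round
#' trip is lossless: numeric columns are written with shortest
#' round-trippable decimal representation.
#'
#' @param cases A `ptml_cases` table.
#' @param path CSV path.
#' @param scheme Scheme used to re-attach metadata on read (defaults to
#'   [default_scheme()] at the manifest's window).
#' @return `read_cases()` returns a `ptml_cases` tibble.
#' @export
write_cases <- function(cases, path) {
  scheme <- cases_scheme(cases)
  manifest <- sprintf("# ifptml cases scheme=%s window=%d target=%g,%g",
                      scheme$name, scheme$window,
                      scheme$target_interval[1], scheme$target_interval[2])
  writeLines(manifest, path)
  readr::write_csv(cases, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_cases
#' @export
read_cases <- function(path, scheme = NULL) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# ifptml cases")) {
    rlang::abort("not an ifptml case file (missing manifest line).")
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  mandatory <- c("case_id", "patient_id", "visit_day", "inr", "output_class")
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    rlang::abort(sprintf("missing mandatory column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$case_id)) {
    rlang::abort("duplicate case_id values in file.")
  }
  if (is.null(scheme)) {
    window <- as.integer(sub(".*window=(\\d+).*", "\\1", first))
    scheme <- default_scheme(window = window)
  }
  new_cases(df, scheme)
}
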