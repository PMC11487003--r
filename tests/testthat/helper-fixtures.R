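# Small in-code fixtures shared across tests.

# A hand-built two-patient cohort with known dose histories.
# P1: dose 2.0 from day 1; the day-7 visit raises it to 2.5 (effective
#     day 8), so days 8..10 are 2.5; second visit on day 10.
# P2: constant 2.0 throughout; single visit on day 11.
manual_cohort <- function(params = sim_params(dose_init = 2.0)) {
  patients <- tibble::tibble(
    patient_id = c("P1", "P2"),
    sex = c("male", "female"),
    age = c(60, 55), height = c(170, 160), weight = c(70, 60),
    surgery_type = c("MVR", "AVR"),
    valve_type = c("mechanical", "bioprosthetic"),
    smoking = c("no", "yes"),
    CYP2C9 = c("*1/*1", "*1/*3"),
    VKORC1 = c("AA", "AG"),
    CYP4F2 = c("CC", "CT"),
    GGCX = c("AA", "AG"),
    EPHX1 = c("TT", "TC")
  )
  visits <- tibble::tibble(
    patient_id = c("P1", "P1", "P2"),
    day = c(7L, 10L, 11L),
    inr = c(1.5, 2.1, 3.0),
    dose_mg = c(2.0, 2.5, 2.0),
    dose_next = c(2.5, 2.5, 2.0),
    neutrophil = c(65, NA, 70),
    albumin = c(38, NA, NA)
  )
  structure(list(patients = patients, visits = visits, params = params),
            class = "ptml_cohort")
}

mini_scheme <- function(window = 5L) {
  partition_scheme(
    partitions = c(TypeCat = "surgery_type", PKGeneCat = "CYP2C9"),
    variable_groups = list(
      Dose = sprintf("Dose%02d", seq_len(window)),
      DEMO = c("age", "weight")
    ),
    extra_continuous = "pod",
    window = window,
    name = "mini"
  )
}

small_cohort <- function(n = 12, seed = 42, ...) {
  simulate_cohort(sim_params(n_patients = n, ...), seed = seed)
}

# deterministically labelled case table for operator tests
fixture_cases <- function(n = 30, seed = 11, window = 3L) {
  withr::with_seed(seed, {
    scheme <- partition_scheme(
      partitions = c(TypeCat = "surgery_type", PKGeneCat = "CYP2C9"),
      variable_groups = list(Dose = sprintf("Dose%02d", seq_len(window)),
                             DEMO = c("age", "weight")),
      window = window, name = "fixture"
    )
    df <- tibble::tibble(
      case_id = sprintf("C%02d", seq_len(n)),
      patient_id = sprintf("P%02d", seq_len(n)),
      visit_day = rep(5L, n),
      inr = round(stats::runif(n, 1.0, 3.5), 2),
      surgery_type = sample(c("MVR", "AVR", "DVR"), n, TRUE),
      CYP2C9 = sample(c("*1/*1", "*1/*3"), n, TRUE),
      age = round(stats::rnorm(n, 58, 13), 1),
      weight = round(stats::rnorm(n, 64, 12), 1)
    )
    for (v in sprintf("Dose%02d", seq_len(window))) {
      df[[v]] <- round(stats::runif(n, 0, 5), 2)
    }
    df$output_class <- label_output(df$inr, scheme$target_interval)
    attr(df, "scheme") <- scheme
    class(df) <- c("ptml_cases", class(df))
    df
  })
}
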