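#' Simulation parameters for a longitudinal warfarin cohort
#'
#' Builds the full parameter set controlling [simulate_cohort()]. The
#' defaults reproduce the marginal structure of a cardiac-surgery
#' anticoagulation cohort: 246 patients, ~3.3k INR measurements, a median
#' follow-up around three months, visit gaps of 6.7 +/- 7.8 days, sex
#' 63.8% male, CYP2C9 *1/*1 92.3% / *1/*3 7.7%, VKORC1 AA/AG/GG
#' 85.5/13.8/1.2%, age 58 +/- 13 y, height 164.7 +/- 8.8 cm, weight
#' 63.9 +/- 11.8 kg, and a mean daily warfarin dose near 2.12 mg/d under
#' the titration policy.
#'
#' The INR response model (exponentially weighted dose exposure scaled by
#' multiplicative genotype sensitivity plus additive Gaussian noise, see
#' [inr_response()]) is a generator design choice, not an estimate from any
#' real cohort; all of its constants live here so that recovery experiments
#' state their own ground truth.
#'
#' @param n_patients Number of patients to simulate.
#' @param follow_up_days Integer range (length 2) of per-patient follow-up,
#'   in days; follow-up is drawn uniformly on this range.
#' @param visit_gap_mean,visit_gap_sd Mean and SD (days) of the normal from
#'   which inter-visit gaps are drawn; gaps are rounded and floored at 1 day.
#' @param sex_male_frac Probability a patient is male.
#' @param genotype_freqs Named list: SNP -> named probability vector over
#'   genotype categories. Each vector is renormalised to sum to 1.
#' @param age_mean,age_sd,weight_mean,weight_sd,height_mean,height_sd
#'   Moments of the demographic normals (years, kg, cm).
#' @param surgery_freqs,valve_freqs Named probability vectors for surgery
#'   type and prosthetic valve type.
#' @param smoking_frac Probability a patient smokes.
#' @param dose_init Starting daily warfarin dose (mg/d).
#' @param dose_step Titration step (mg/d) applied after each visit.
#' @param target_inr Length-2 numeric, the closed target INR interval.
#' @param baseline_inr INR with zero warfarin exposure.
#' @param sensitivity_beta INR increase per unit of weight-normalised
#'   effective exposure (INR * kg / (mg/d)).
#' @param genotype_multipliers Named list: SNP -> named multiplier vector;
#'   a patient's sensitivity multiplier is the product over their genotypes.
#'   Genes or categories absent from the list multiply by 1.
#' @param exposure_halflife_days Half-life (days) of the exponential dose
#'   weighting in the effective-exposure sum.
#' @param noise_sd SD (INR units) of the additive measurement/biology noise.
#' @param comedication_spec Data frame with columns `drug`, `prevalence`,
#'   `dose_min`, `dose_max`, `chronic` describing co-medications; acute
#'   drugs are given only during the in-hospital window.
#' @param lab_spec Data frame with columns `lab`, `mean`, `sd`, `noise_sd`
#'   describing laboratory analytes (per-patient baseline draw + visit
#'   noise).
#' @param inpatient_days Days after surgery during which labs are always
#'   measured and acute co-medication is given.
#' @param outpatient_lab_prob Probability a lab is measured at an
#'   outpatient visit.
#' @param rng_seed Default seed used by [simulate_cohort()].
#'
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [simulate_cohort()], [inr_response()]
#' @export
#' @examples
#' p <- sim_params(n_patients = 10)
#' p$genotype_freqs$VKORC1
sim_params <- function(n_patients = 246,
                       follow_up_days = c(30L, 168L),
                       visit_gap_mean = 6.7,
                       visit_gap_sd = 7.8,
                       sex_male_frac = 0.638,
                       genotype_freqs = list(
                         CYP2C9 = c("*1/*1" = 0.923, "*1/*3" = 0.077),
                         VKORC1 = c(AA = 0.855, AG = 0.138, GG = 0.012),
                         CYP4F2 = c(CC = 0.50, CT = 0.40, TT = 0.10),
                         GGCX   = c(AA = 0.60, AG = 0.35, GG = 0.05),
                         EPHX1  = c(TT = 0.55, TC = 0.35, CC = 0.10)
                       ),
                       age_mean = 58, age_sd = 13,
                       weight_mean = 63.9, weight_sd = 11.8,
                       height_mean = 164.7, height_sd = 8.8,
                       surgery_freqs = c(DVR = 0.102, AVR = 0.146,
                                         MVR = 0.394, TVR = 0.012,
                                         other = 0.346),
                       valve_freqs = c(mechanical = 0.35,
                                       bioprosthetic = 0.50,
                                       none = 0.15),
                       smoking_frac = 0.28,
                       dose_init = 2.5,
                       dose_step = 0.25,
                       target_inr = c(1.8, 2.5),
                       baseline_inr = 1.0,
                       sensitivity_beta = 35,
                       genotype_multipliers = list(
                         CYP2C9 = c("*1/*1" = 1.0, "*1/*3" = 1.35),
                         VKORC1 = c(AA = 1.25, AG = 1.0, GG = 0.8)
                       ),
                       exposure_halflife_days = 2,
                       noise_sd = 0.25,
                       comedication_spec = default_comedication_spec(),
                       lab_spec = default_lab_spec(),
                       inpatient_days = 14L,
                       outpatient_lab_prob = 0.2,
                       rng_seed = 1L) {
  genotype_freqs <- lapply(genotype_freqs, function(p) p / sum(p))
  params <- list(
    n_patients = as.integer(n_patients),
    follow_up_days = as.integer(follow_up_days),
    visit_gap_mean = visit_gap_mean,
    visit_gap_sd = visit_gap_sd,
    sex_male_frac = sex_male_frac,
    genotype_freqs = genotype_freqs,
    age_mean = age_mean, age_sd = age_sd,
    weight_mean = weight_mean, weight_sd = weight_sd,
    height_mean = height_mean, height_sd = height_sd,
    surgery_freqs = surgery_freqs / sum(surgery_freqs),
    valve_freqs = valve_freqs / sum(valve_freqs),
    smoking_frac = smoking_frac,
    dose_init = dose_init,
    dose_step = dose_step,
    target_inr = as.numeric(target_inr),
    baseline_inr = baseline_inr,
    sensitivity_beta = sensitivity_beta,
    genotype_multipliers = genotype_multipliers,
    exposure_halflife_days = exposure_halflife_days,
    noise_sd = noise_sd,
    comedication_spec = tibble::as_tibble(comedication_spec),
    lab_spec = tibble::as_tibble(lab_spec),
    inpatient_days = as.integer(inpatient_days),
    outpatient_lab_prob = outpatient_lab_prob,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_params(structure(params, class = "sim_params"))
}

#' @rdname sim_params
#' @export
default_params <- function() sim_params()

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$n_patients < 1L) {
    rlang::abort("`n_patients` must be >= 1.")
  }
  probs <- c(p$sex_male_frac, p$smoking_frac, p$outpatient_lab_prob,
             p$comedication_spec$prevalence)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("all probabilities must lie in [0, 1].")
  }
  for (snp in names(p$genotype_freqs)) {
    f <- p$genotype_freqs[[snp]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-12) {
      rlang::abort(sprintf(
        "genotype frequencies for %s must be a distribution summing to 1.",
        snp))
    }
  }
  if (p$noise_sd < 0) rlang::abort("`noise_sd` must be >= 0.")
  if (p$dose_step <= 0) rlang::abort("`dose_step` must be > 0.")
  if (length(p$target_inr) != 2L || p$target_inr[1] >= p$target_inr[2]) {
    rlang::abort("`target_inr` must be an interval with lower < upper.")
  }
  if (length(p$follow_up_days) != 2L ||
      p$follow_up_days[1] < 2L ||
      p$follow_up_days[1] > p$follow_up_days[2]) {
    rlang::abort("`follow_up_days` must be an increasing range of days >= 2.")
  }
  if (p$exposure_halflife_days <= 0) {
    rlang::abort("`exposure_halflife_days` must be > 0.")
  }
  p
}

default_comedication_spec <- function() {
  tibble::tribble(
    ~drug,            ~prevalence, ~dose_min, ~dose_max, ~chronic,
    "cefoperazone",    0.15,        2000,      4000,      FALSE,
    "ceftriaxone",     0.10,        1000,      2000,      FALSE,
    "cefuroxime",      0.20,        1500,      3000,      FALSE,
    "ticarcillin",     0.05,        3000,      6000,      FALSE,
    "tigecycline",     0.03,          50,       100,      FALSE,
    "spironolactone",  0.25,          20,        40,      TRUE,
    "aspirin",         0.10,          75,       100,      TRUE,
    "diclofenac",      0.05,          50,       100,      FALSE,
    "bifidobacterium", 0.10,           1,         3,      TRUE
  )
}

default_lab_spec <- function() {
  tibble::tribble(
    ~lab,           ~mean, ~sd,  ~noise_sd,
    "neutrophil",    65,    8,    4,      # %
    "plateletcrit",  0.23,  0.05, 0.02,   # %
    "pdw",           13,    2,    0.8,    # %
    "albumin",       38,    4,    1.5,    # g/L
    "hdl_chol",      1.1,   0.3,  0.1     # mmol/L
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  patients: %d, follow-up %d-%d d, visit gap %.1f +/- %.1f d\n",
              x$n_patients, x$follow_up_days[1], x$follow_up_days[2],
              x$visit_gap_mean, x$visit_gap_sd))
  cat(sprintf("  dose: init %.2f mg/d, step %.2f, target INR [%.1f, %.1f]\n",
              x$dose_init, x$dose_step, x$target_inr[1], x$target_inr[2]))
  cat(sprintf("  response: baseline %.2f, beta %.1f, halflife %.1f d, noise sd %.2f\n",
              x$baseline_inr, x$sensitivity_beta, x$exposure_halflife_days,
              x$noise_sd))
  cat(sprintf("  genes: %s\n", paste(names(x$genotype_freqs), collapse = ", ")))
  invisible(x)
}
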