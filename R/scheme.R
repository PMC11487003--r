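#' Partition scheme: categorical partitions and continuous variable groups
#'
#' A partition scheme drives both the information-fusion stage and the
#' perturbation-theory operators. It registers (i) the categorical
#' partitions (`s`-groups): named mappings from a partition name such as
#' `PKGeneCat` to the label column that realises it (e.g. the CYP2C9
#' genotype), (ii) named groups of continuous variables (`c`-groups) used
#' by the second-order Euclidean-distance operators, (iii) any extra
#' continuous variables that belong to no group, and (iv) the target INR
#' interval that defines the Within/Out output class.
#'
#' @param partitions Named character vector: partition name -> label
#'   column.
#' @param variable_groups Named list of character vectors: group name ->
#'   continuous-variable names. Groups must be disjoint.
#' @param extra_continuous Continuous variables registered but in no group.
#' @param target_interval Closed INR interval labelled `Within`.
#' @param window Dose/treatment-day window length in days; registers
#'   `Dose01..DoseNN` and `TreatDay01..TreatDayNN` columns.
#' @param name Scheme name recorded in file manifests.
#'
#' @return An object of class `ptml_scheme`.
#' @seealso [default_scheme()], [build_case_table()]
#' @export
partition_scheme <- function(partitions,
                             variable_groups = list(),
                             extra_continuous = character(),
                             target_interval = c(1.8, 2.5),
                             window = 63L,
                             name = "custom") {
  stopifnot(is.character(partitions), !is.null(names(partitions)),
            length(target_interval) == 2L,
            target_interval[1] < target_interval[2], window >= 1L)
  all_grouped <- unlist(variable_groups, use.names = FALSE)
  if (anyDuplicated(all_grouped)) {
    rlang::abort("`variable_groups` must be disjoint sets.")
  }
  scheme <- list(
    partitions = partitions,
    variable_groups = variable_groups,
    extra_continuous = extra_continuous,
    target_interval = as.numeric(target_interval),
    window = as.integer(window),
    name = name
  )
  class(scheme) <- "ptml_scheme"
  scheme
}

#' Default scheme for the simulated warfarin cohort
#'
#' Partitions: `DemoCat` (sex), `TypeCat` (surgery type), `ValveCat`
#' (valve type), `PKGeneCat` (CYP2C9), `PDGeneCat` (VKORC1), `NRGeneCat`
#' (CYP4F2), `ClotGeneCat` (GGCX), `VKPKGeneCat` (EPHX1) and `SmokeCat`.
#' Variable groups: the 63-day dose and treatment-day windows, `DEMO`
#' (age/height/weight), `Blood_cell_count`, `Chemistry`, `Antibiotics`,
#' `Diuretic`, `Aspirin`, `Diclofenac` and `Probiotics`; postoperative day
#' (`pod`) is registered ungrouped.
#'
#' @param window Window length in days.
#' @return A `ptml_scheme`.
#' @export
default_scheme <- function(window = 63L) {
  partition_scheme(
    partitions = c(DemoCat = "sex", TypeCat = "surgery_type",
                   ValveCat = "valve_type", PKGeneCat = "CYP2C9",
                   PDGeneCat = "VKORC1", NRGeneCat = "CYP4F2",
                   ClotGeneCat = "GGCX", VKPKGeneCat = "EPHX1",
                   SmokeCat = "smoking"),
    variable_groups = list(
      Dose = dose_cols(window),
      TreatDay = treatday_cols(window),
      DEMO = c("age", "height", "weight"),
      Blood_cell_count = c("neutrophil", "plateletcrit", "pdw"),
      Chemistry = c("albumin", "hdl_chol"),
      Antibiotics = c("cefoperazone", "ceftriaxone", "cefuroxime",
                      "ticarcillin", "tigecycline"),
      Diuretic = "spironolactone",
      Aspirin = "aspirin",
      Diclofenac = "diclofenac",
      Probiotics = "bifidobacterium"
    ),
    extra_continuous = "pod",
    window = window,
    name = "warfarin-default"
  )
}

dose_cols <- function(window) sprintf("Dose%02d", seq_len(window))
treatday_cols <- function(window) sprintf("TreatDay%02d", seq_len(window))

#' Continuous variables registered in a scheme
#' @param scheme A `ptml_scheme`.
#' @return Character vector of variable names, group-major order.
#' @export
registered_continuous <- function(scheme) {
  c(unlist(scheme$variable_groups, use.names = FALSE),
    scheme$extra_continuous)
}

#' @export
print.ptml_scheme <- function(x, ...) {
  cat(sprintf("<ptml_scheme> \"%s\": %d partitions, %d variable groups, %d continuous variables\n",
              x$name, length(x$partitions), length(x$variable_groups),
              length(registered_continuous(x))))
  cat(sprintf("  target INR [%g, %g], window %d d\n",
              x$target_interval[1], x$target_interval[2], x$window))
  invisible(x)
}

#' Write / read a scheme as JSON
#' @param scheme A `ptml_scheme`.
#' @param path File path.
#' @return `read_scheme()` returns a `ptml_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  x <- unclass(scheme)
  x$partitions <- as.list(x$partitions)  # keep names through JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  partition_scheme(
    partitions = unlist(x$partitions),
    variable_groups = lapply(x$variable_groups, unlist),
    extra_continuous = unlist(x$extra_continuous) %||% character(),
    target_interval = x$target_interval,
    window = x$window,
    name = x$name
  )
}
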