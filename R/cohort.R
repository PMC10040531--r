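# Synthetic subject cohorts standing in for a clinical CT cohort.
#
# Each subject carries a cardiac output (CO), heart rate (HR), hematocrit
# and an idealized appendage geometry. Default ranges reproduce the study
# population the package emulates: CO 1.9-6.8 L/min, HR 44-84 bpm,
# hematocrit 35-49%.

#' Stroke volume and cardiac output from the Teichholz formula
#'
#' Converts echocardiographic left-ventricular end-diastolic and
#' end-systolic diameters to volumes with the Teichholz cubic
#' `V = 7.0 D^3 / (2.4 + D)` (D in cm, V in mL) and returns the cardiac
#' output `(EDV - ESV) * HR / 1000` in L/min.
#'
#' @param edd End-diastolic diameter, cm.
#' @param esd End-systolic diameter, cm (must be < `edd`).
#' @param hr Heart rate, bpm.
#' @return Cardiac output, L/min.
#' @examples
#' teichholz_cardiac_output(5.0, 3.0, 60)
#' @export
teichholz_cardiac_output <- function(edd, esd, hr) {
  stopifnot(all(edd > 0), all(hr > 0))
  if (any(esd >= edd) || any(esd <= 0))
    stop("invalid measurement: require 0 < ESD < EDD")
  teich <- function(d) 7.0 * d^3 / (2.4 + d)
  (teich(edd) - teich(esd)) * hr / 1000
}

#' Default parameter bounds for cohort generation
#'
#' Physiologic ranges (CO, HR, hematocrit) follow the emulated study
#' population; geometry bounds define the desk-scale pouch variability
#' (depth, neck width, bend, lobe count) that stands in for patient-specific
#' appendage morphology.
#'
#' @return A named list of bounds usable as the `ranges` argument of
#'   [generate_cohort()].
#' @export
cohort_ranges <- function() {
  list(
    co = c(1.9, 6.8),          # L/min
    hr = c(44, 84),            # bpm
    hct = c(0.35, 0.49),       # fraction
    pouch_depth = c(0.004, 0.009),      # m
    pouch_neck_width = c(0.004, 0.006), # m
    pouch_bend_angle = c(0, 40),        # degrees
    p_two_lobes = 0.2,
    channel_length = 0.03, channel_height = 0.01,
    outlet_extension_length = 0.03, h = 0.01 / 12
  )
}

#' Generate a synthetic subject cohort
#'
#' Draws `n` subjects with independent uniform CO, HR and hematocrit within
#' the configured bounds, plus a subject-specific appendage geometry
#' (pouch depth, neck width, bend angle, 1 or 2 lobes). Bit-reproducible
#' for a fixed seed; the caller's RNG state is restored on exit.
#'
#' @param n Number of subjects.
#' @param seed Integer RNG seed.
#' @param ranges Parameter bounds, see [cohort_ranges()].
#' @return A list of `subject_record` objects (also of class
#'   `laa_cohort`), each with `subject_id`, `co`, `hr`, `hct` and a
#'   [geometry_spec()] in `$geometry`.
#' @examples
#' cohort <- generate_cohort(3, seed = 1)
#' cohort_table(cohort)
#' @export
generate_cohort <- function(n, seed = 1L, ranges = cohort_ranges()) {
  stopifnot(n >= 1)
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  set.seed(seed)
  runif_in <- function(b) runif(1, b[1], b[2])
  cohort <- lapply(seq_len(n), function(i) {
    geom <- geometry_spec(
      channel_length = ranges$channel_length,
      channel_height = ranges$channel_height,
      pouch_depth = runif_in(ranges$pouch_depth),
      pouch_neck_width = runif_in(ranges$pouch_neck_width),
      pouch_bend_angle = runif_in(ranges$pouch_bend_angle),
      n_lobes = 1L + rbinom(1, 1, ranges$p_two_lobes),
      outlet_extension_length = ranges$outlet_extension_length,
      h = ranges$h)
    rec <- list(subject_id = sprintf("S%02d", i),
                co = runif_in(ranges$co),
                hr = runif_in(ranges$hr),
                hct = runif_in(ranges$hct),
                geometry = geom)
    stopifnot(rec$co > 0, rec$hct > 0, rec$hct < 0.65, rec$hr > 0)
    structure(rec, class = "subject_record")
  })
  structure(cohort, class = "laa_cohort")
}

#' Flatten a cohort to a data frame (one row per subject)
#'
#' @param cohort An `laa_cohort`.
#' @return A data frame with subject id, CO, HR, hematocrit and the main
#'   geometry parameters.
#' @export
cohort_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) data.frame(
    subject_id = s$subject_id, co = s$co, hr = s$hr, hct = s$hct,
    pouch_depth = s$geometry$pouch_depth,
    pouch_neck_width = s$geometry$pouch_neck_width,
    pouch_bend_angle = s$geometry$pouch_bend_angle,
    n_lobes = s$geometry$n_lobes)))
}

#' Write / read a cohort as CSV
#'
#' @param cohort An `laa_cohort`.
#' @param file CSV path.
#' @return `file` (write) or a data frame (read).
#' @export
write_cohort_csv <- function(cohort, file) {
  write.csv(cohort_table(cohort), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(file) read.csv(file)

#' Read a plain-text `key: value` configuration file
#'
#' Configuration files are YAML-compatible `key: value` text; nested keys
#' and lists are supported.
#'
#' @param file Path to the config file.
#' @return A named list.
#' @export
read_config <- function(file) yaml::read_yaml(file)
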