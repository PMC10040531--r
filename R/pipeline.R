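# Desk-scale orchestration of the three confounder studies:
#   1. waveform sweep  — 3 cardiac outputs x 3 pulmonary-vein waveform
#      types per subject; effects-coded regression of t_m / C_inf on CO,
#      SysP, RevP.
#   2. rheology factorial — {Newtonian, Quemada} x 3 hematocrit levels per
#      subject at a steady CO of 4.4 L/min; regression on Hct, rheology
#      dummy and their interaction.
#   3. truncation study — one long washout per subject, refitted on prefix
#      windows; Spearman rank stability of the indices versus the longest
#      window.

#' Experiment configuration for the confounder studies
#'
#' Defaults define the desk-scale study conditions: an 8-subject synthetic
#' cohort, the tabulated cardiac-output levels 3.3/4.4/5.5 L/min, the
#' three hematocrit levels 27.4/45.5/60.4%, a 40 s washout horizon, and a
#' truncation ladder expressed as fractions of the horizon that mirrors a
#' 625-to-30,000 s geometric ladder.
#'
#' @param n_subjects Cohort size.
#' @param seed Cohort RNG seed.
#' @param co_levels Cardiac-output levels for the waveform sweep, L/min.
#' @param wave_types Waveform types for the sweep.
#' @param hct_levels Hematocrit levels (fractions) for the factorial.
#' @param rheologies Rheology models for the factorial.
#' @param co_factorial Steady cardiac output used in the factorial and
#'   truncation study, L/min.
#' @param washout_horizon Washout integration horizon, s.
#' @param sample_interval Washout sampling interval, s (default
#'   horizon/2000).
#' @param truncation_fracs Truncation window lengths as fractions of the
#'   horizon.
#' @param ranges Cohort parameter bounds, see [cohort_ranges()].
#' @param solver A [solver_config()]; the default uses 4 spin-up cycles
#'   and a 1e-7 m/s steady tolerance as the desk-scale settings.
#' @param outdir Optional output directory for CSV/JSON artifacts.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 8L, seed = 1L,
                              co_levels = c(3.3, 4.4, 5.5),
                              wave_types = c("normal", "af", "steady"),
                              hct_levels = c(0.274, 0.455, 0.604),
                              rheologies = c("newtonian", "quemada"),
                              co_factorial = 4.4,
                              washout_horizon = 300,
                              sample_interval = NULL,
                              truncation_fracs = c(625, 1250, 2500, 5000,
                                                   10000, 20000, 30000) /
                                30000,
                              ranges = cohort_ranges(),
                              solver = solver_config(spin_up_cycles = 4L,
                                                     tol_velocity = 1e-7),
                              outdir = NULL) {
  structure(as.list(environment()), class = "experiment_config")
}

subject_rheology <- function(subject) {
  rheology_params("quemada", hct = subject$hct)
}

# one flow + washout + fit; returns t_m, c_inf and diagnostics
run_case <- function(grid, rheology, waveform, config) {
  flow <- solve_flow(grid, rheology, waveform, config$solver)
  series <- run_washout(grid, flow, t_max = config$washout_horizon,
                        sample_interval = config$sample_interval)
  fit <- fit_concentration(series)
  list(flow = flow, series = series, fit = fit,
       t_m = mean_residence_time(fit), c_inf = asymptotic_concentration(fit))
}

#' Waveform-pulsatility sweep over a cohort
#'
#' For every subject and every (CO level, waveform type) pair: solve the
#' flow, wash the tracer out, fit the RTD model, and record `t_m`, `C_inf`
#' and the measured pulsatility indices. Case failures are logged in the
#' `status` column and excluded from the regression, never aborting the
#' cohort.
#'
#' @param cohort An `laa_cohort` (default: generated from the config).
#' @param config An [experiment_config()].
#' @param execute If `FALSE`, return only the design table (the planned
#'   observations) without running any simulation.
#' @return A list with the observation `table`, regressions `reg_tm` and
#'   `reg_cinf` ([fit_waveform_model()]) and the per-case `fits`.
#' @export
run_waveform_sweep <- function(cohort = NULL, config = experiment_config(),
                               execute = TRUE) {
  if (is.null(cohort))
    cohort <- generate_cohort(config$n_subjects, config$seed, config$ranges)
  design <- expand.grid(wave_type = config$wave_types,
                        co = config$co_levels,
                        subject_id = vapply(cohort, `[[`, "", "subject_id"),
                        stringsAsFactors = FALSE)
  design <- design[order(design$subject_id, design$co), ]
  rownames(design) <- NULL
  if (!execute) return(list(table = design))

  grids <- lapply(cohort, function(s) build_geometry(s$geometry))
  names(grids) <- vapply(cohort, `[[`, "", "subject_id")
  subjects <- stats::setNames(cohort, names(grids))

  rows <- vector("list", nrow(design))
  fits <- vector("list", nrow(design))
  for (r in seq_len(nrow(design))) {
    sid <- design$subject_id[r]
    s <- subjects[[sid]]
    w <- make_waveform(design$wave_type[r], co = design$co[r], hr = s$hr)
    pidx <- pulsatility_indices(w)
    res <- try(run_case(grids[[sid]], subject_rheology(s), w, config),
               silent = TRUE)
    ok <- !inherits(res, "try-error")
    rows[[r]] <- data.frame(
      subject_id = sid, co = design$co[r],
      wave_type = design$wave_type[r], sysp = pidx$sysp, revp = pidx$revp,
      hct = s$hct,
      t_m = if (ok) res$t_m else NA_real_,
      c_inf = if (ok) res$c_inf else NA_real_,
      status = if (ok) "ok" else paste("failed:",
                                       trimws(attr(res, "condition")$message)))
    if (ok) fits[[r]] <- res$fit
  }
  table <- do.call(rbind, rows)
  okrows <- table[table$status == "ok", ]
  can_reg <- length(unique(okrows$co)) >= 2 &&
    length(unique(okrows$sysp)) >= 2
  out <- list(table = table, fits = fits,
              reg_tm = if (can_reg) fit_waveform_model(okrows, "t_m"),
              reg_cinf = if (can_reg) fit_waveform_model(okrows, "c_inf"))
  maybe_write_study(out, config, "waveform_sweep")
  out
}

#' Hematocrit-by-rheology factorial over a cohort
#'
#' For every subject: {Newtonian at the equivalent viscosity, Quemada} x
#' hematocrit levels, steady inflow at `co_factorial`. The Newtonian
#' comparator of each hematocrit uses [equivalent_newtonian_viscosity()],
#' so both arms see identical inflow and differ only in the constitutive
#' law.
#'
#' @inheritParams run_waveform_sweep
#' @return A list with the observation `table`, regressions `reg_tm`,
#'   `reg_cinf` ([fit_rheology_model()]) and the Newtonian-vs-Quemada rank
#'   correlations `spearman_tm`, `spearman_cinf`.
#' @export
run_rheology_factorial <- function(cohort = NULL,
                                   config = experiment_config(),
                                   execute = TRUE) {
  if (is.null(cohort))
    cohort <- generate_cohort(config$n_subjects, config$seed, config$ranges)
  design <- expand.grid(rheology = config$rheologies,
                        hct = config$hct_levels,
                        subject_id = vapply(cohort, `[[`, "", "subject_id"),
                        stringsAsFactors = FALSE)
  design <- design[order(design$subject_id, design$hct), ]
  rownames(design) <- NULL
  if (!execute) return(list(table = design))

  grids <- lapply(cohort, function(s) build_geometry(s$geometry))
  names(grids) <- vapply(cohort, `[[`, "", "subject_id")
  w <- make_waveform("steady", co = config$co_factorial)

  rows <- vector("list", nrow(design))
  for (r in seq_len(nrow(design))) {
    sid <- design$subject_id[r]
    hct <- design$hct[r]
    rheo <- if (design$rheology[r] == "newtonian") {
      rheology_params("newtonian", mu = equivalent_newtonian_viscosity(hct))
    } else rheology_params("quemada", hct = hct)
    res <- try(run_case(grids[[sid]], rheo, w, config), silent = TRUE)
    ok <- !inherits(res, "try-error")
    rows[[r]] <- data.frame(
      subject_id = sid, hct = hct, rheology = design$rheology[r],
      t_m = if (ok) res$t_m else NA_real_,
      c_inf = if (ok) res$c_inf else NA_real_,
      status = if (ok) "ok" else paste("failed:",
                                       trimws(attr(res, "condition")$message)))
  }
  table <- do.call(rbind, rows)
  okrows <- table[table$status == "ok", ]
  # rank correlation of matched Newtonian vs Quemada observations
  key <- paste(okrows$subject_id, okrows$hct)
  newt <- okrows[okrows$rheology == "newtonian", ]
  quem <- okrows[okrows$rheology == "quemada", ]
  m <- merge(newt, quem, by = c("subject_id", "hct"),
             suffixes = c("_n", "_q"))
  out <- list(table = table,
              reg_tm = fit_rheology_model(okrows, "t_m"),
              reg_cinf = fit_rheology_model(okrows, "c_inf"),
              spearman_tm = spearman(m$t_m_n, m$t_m_q),
              spearman_cinf = spearman(m$c_inf_n, m$c_inf_q))
  maybe_write_study(out, config, "rheology_factorial")
  out
}

#' Simulation-length truncation study over a cohort
#'
#' One long washout per subject (steady inflow at `co_factorial`, Quemada
#' rheology at the subject hematocrit); the RTD model is refitted on each
#' prefix window of the truncation ladder, and the Spearman rank
#' correlation of the per-subject indices against the longest window is
#' reported per window length.
#'
#' @inheritParams run_waveform_sweep
#' @return A list with the per-subject-by-length `table`, and rank
#'   stability data frames `stability_tm`, `stability_cinf` (columns
#'   `length`, `rho`, `p`).
#' @export
run_truncation_study <- function(cohort = NULL,
                                 config = experiment_config()) {
  if (is.null(cohort))
    cohort <- generate_cohort(config$n_subjects, config$seed, config$ranges)
  lengths <- sort(config$truncation_fracs) * config$washout_horizon
  # prefix refits need >= 50 samples even in the shortest window
  si <- config$sample_interval %||% min(config$washout_horizon / 2000,
                                        min(lengths) / 60)
  w <- make_waveform("steady", co = config$co_factorial)
  rows <- list()
  for (s in cohort) {
    grid <- build_geometry(s$geometry)
    flow <- solve_flow(grid, subject_rheology(s), w, config$solver)
    series <- run_washout(grid, flow, t_max = config$washout_horizon,
                          sample_interval = si)
    tb <- truncation_study(series, lengths)
    tb$subject_id <- s$subject_id
    rows[[length(rows) + 1]] <- tb
  }
  table <- do.call(rbind, rows)
  wide <- function(col) {
    m <- sapply(split(table[[col]], table$subject_id), identity)
    m <- t(m)   # subjects x lengths
    colnames(m) <- signif(lengths, 6)
    m
  }
  out <- list(table = table,
              stability_tm = rank_stability(wide("t_m")),
              stability_cinf = rank_stability(wide("c_inf")),
              lengths = lengths)
  maybe_write_study(out, config, "truncation_study")
  out
}

# write study outputs if an output directory is configured
maybe_write_study <- function(out, config, name) {
  if (is.null(config$outdir)) return(invisible(NULL))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write.csv(out$table, file.path(config$outdir, paste0(name, ".csv")),
            row.names = FALSE)
  for (nm in intersect(c("reg_tm", "reg_cinf"), names(out)))
    if (!is.null(out[[nm]]))
      write_regression_json(out[[nm]],
                            file.path(config$outdir,
                                      paste0(name, "_", nm, ".json")))
  invisible(NULL)
}
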