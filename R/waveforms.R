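# Pulmonary-vein inflow waveforms and their pulsatility indices.
#
# Three template types are supported: the normal pulsatile waveform
# (systolic S wave, diastolic D wave, late atrial-reversal dip), the
# atrial-fibrillation waveform (blunted systolic wave, smaller reversal)
# and a steady (zero-pulsatility) waveform. Template shapes are built from
# raised-cosine lobes over fixed phase fractions of the cycle; the lobe
# amplitudes are solved so that (a) the cycle mean equals the requested
# cardiac output and (b) the normalized systolic peak (SysP) and reversal
# peak (RevP) match the tabulated template values, interpolated linearly
# in cardiac output between the tabulated levels 3.3, 4.4 and 5.5 L/min.

# tabulated template pulsatility indices by waveform type and CO (L/min)
.wave_templates <- list(
  co = c(3.3, 4.4, 5.5),
  normal = list(sysp = c(2.25, 2.18, 2.27), revp = c(0.64, 0.91, 0.91),
                fractions = c(systole = 0.40, diastole = 0.45,
                              reversal = 0.15)),
  af = list(sysp = c(1.55, 1.25, 1.54), revp = c(0.61, 0.18, 0.21),
            fractions = c(systole = 0.35, diastole = 0.45, reversal = 0.20))
)

#' Template pulsatility indices for a waveform type and cardiac output
#'
#' Linear interpolation of the tabulated SysP / RevP template values in
#' cardiac output (clamped to the tabulated range 3.3-5.5 L/min). The
#' steady waveform reports both indices as 1 by convention (see
#' [pulsatility_indices()]).
#'
#' @param wave_type `"normal"`, `"af"` or `"steady"`.
#' @param co Cardiac output, L/min.
#' @return A list with `sysp` and `revp`.
#' @export
template_indices <- function(wave_type = c("normal", "af", "steady"), co) {
  wave_type <- match.arg(wave_type)
  if (wave_type == "steady") return(list(sysp = 1, revp = 1))
  tmpl <- .wave_templates[[wave_type]]
  co_tab <- .wave_templates$co
  list(sysp = stats::approx(co_tab, tmpl$sysp, co, rule = 2)$y,
       revp = stats::approx(co_tab, tmpl$revp, co, rule = 2)$y)
}

#' Synthesize one cardiac cycle of pulmonary-vein inflow
#'
#' @param wave_type `"normal"`, `"af"` or `"steady"`.
#' @param co Cardiac output (cycle-mean flow), L/min.
#' @param hr Heart rate, bpm; the period is `60 / hr` s.
#' @param samples_per_cycle Number of time samples over one period
#'   (>= 64).
#' @return An object of class `waveform`: time grid `t` (s, `n + 1` points
#'   closing the period), flow `q_lpm` (L/min), the phase boundaries, the
#'   cardiac output and period, and the amplitudes used.
#' @examples
#' w <- make_waveform("normal", co = 4.4, hr = 60)
#' pulsatility_indices(w)
#' @export
make_waveform <- function(wave_type = c("normal", "af", "steady"),
                          co, hr = 60, samples_per_cycle = 256L) {
  wave_type <- match.arg(wave_type)
  stopifnot(co > 0, hr > 0, samples_per_cycle >= 64)
  T <- 60 / hr
  t <- seq(0, T, length.out = samples_per_cycle + 1L)
  if (wave_type == "steady") {
    w <- list(wave_type = wave_type, co = co, hr = hr, period = T, t = t,
              q_lpm = rep(co, length(t)), phases = NULL,
              amplitudes = c(systole = co, diastole = co, reversal = 0))
    return(structure(w, class = "waveform"))
  }
  fr <- .wave_templates[[wave_type]]$fractions
  ti <- template_indices(wave_type, co)
  a_s <- ti$sysp * co
  a_r <- ti$revp * co
  # cycle mean of each raised-cosine lobe is amplitude * fraction / 2:
  #   mean Q = (a_s f_s + a_d f_d - a_r f_r) / 2 = co
  a_d <- (2 * co - a_s * fr["systole"] + a_r * fr["reversal"]) /
    fr["diastole"]
  if (a_d < 0)
    stop("waveform-construction error: negative diastolic amplitude")
  bounds <- cumsum(c(0, fr)) * T    # systole / diastole / reversal spans
  hump <- function(x) 0.5 * (1 - cos(2 * pi * x))   # 0 at ends, 1 mid-lobe
  q <- numeric(length(t))
  seg <- function(lo, hi) t >= lo & t < hi
  i1 <- seg(bounds[1], bounds[2]); i2 <- seg(bounds[2], bounds[3])
  i3 <- t >= bounds[3]
  q[i1] <- a_s * hump((t[i1] - bounds[1]) / (fr["systole"] * T))
  q[i2] <- a_d * hump((t[i2] - bounds[2]) / (fr["diastole"] * T))
  q[i3] <- -a_r * hump((t[i3] - bounds[3]) / (fr["reversal"] * T))
  q[length(q)] <- q[1]   # exact periodic closure
  structure(list(wave_type = wave_type, co = co, hr = hr, period = T, t = t,
                 q_lpm = q, phases = bounds,
                 amplitudes = c(systole = a_s, diastole = unname(a_d),
                                reversal = a_r)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  pi_ <- pulsatility_indices(x)
  cat("<waveform> ", x$wave_type, ", CO = ", signif(x$co, 3),
      " L/min, HR = ", signif(x$hr, 3), " bpm, SysP = ",
      round(pi_$sysp, 2), ", RevP = ", round(pi_$revp, 2), "\n", sep = "")
  invisible(x)
}

#' Cycle-mean flow of a waveform (trapezoidal), L/min
#' @param w A `waveform`.
#' @return Mean flow in L/min.
#' @export
waveform_mean <- function(w) {
  pracma::trapz(w$t, w$q_lpm) / w$period
}

#' Pulsatility indices of a waveform
#'
#' `SysP` is the systolic-phase peak flow normalized by cardiac output and
#' `RevP` the absolute reversal (most negative) flow normalized by cardiac
#' output. For a waveform without phase annotation, the systolic peak is
#' taken as the global maximum. Zero-variance (steady) waveforms report
#' both indices as 1 by convention, matching the tabulated template value
#' for the no-pulsatility waveform; this convention lives only here.
#'
#' @param w A `waveform`.
#' @return A list with `sysp` and `revp` (dimensionless).
#' @export
pulsatility_indices <- function(w) {
  stopifnot(inherits(w, "waveform"))
  co <- w$co
  if (co == 0) stop("division error: zero cardiac output")
  if (diff(range(w$q_lpm)) == 0) return(list(sysp = 1, revp = 1))
  sys_q <- if (!is.null(w$phases)) {
    w$q_lpm[w$t >= w$phases[1] & w$t < w$phases[2]]
  } else w$q_lpm
  qmin <- min(w$q_lpm)
  list(sysp = max(sys_q) / co, revp = if (qmin < 0) abs(qmin) / co else 0)
}

#' Split a total inflow across inlets at equal velocity
#'
#' The total flow is distributed among the inlets in proportion to their
#' cross-sectional areas, i.e. a single uniform velocity
#' `v = Q_total / sum(area)` is applied at every inlet.
#'
#' @param q_total Total volumetric inflow (m^3/s in 3D; m^2/s per unit
#'   depth in 2D).
#' @param inlet_areas Inlet cross-sectional areas (m^2, or widths in m for
#'   2D).
#' @return A list with the common `velocity` and the per-inlet `flows`.
#' @export
distribute_inlets <- function(q_total, inlet_areas) {
  stopifnot(all(inlet_areas > 0))
  a <- sum(inlet_areas)
  if (a <= 0) stop("configuration error: zero total inlet area")
  v <- q_total / a
  list(velocity = v, flows = v * inlet_areas)
}

#' Write a waveform as two-column CSV (time s, flow L/min)
#' @param w A `waveform`.
#' @param file Output path.
#' @export
write_waveform_csv <- function(w, file) {
  write.csv(data.frame(time_s = w$t, flow_lpm = w$q_lpm), file,
            row.names = FALSE)
  invisible(file)
}
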