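# Eulerian passive-tracer transport: conservative donor-cell advection of
# a source-free scalar on the face velocities of a flow solution. The
# tracer is initialized to 1 inside the appendage and 0 elsewhere; the
# appendage-averaged concentration C(t) is the washout curve that the RTD
# analysis fits. Pure advection (no molecular diffusion term) is used; the
# numerical diffusion of the donor-cell scheme is characterized in the
# test suite rather than modeled.

#' Initialize the tracer field
#'
#' Concentration 1 on every appendage cell, 0 on all other fluid cells.
#'
#' @param grid An `laa_grid` with a nonempty appendage mask.
#' @return An `nx x ny` concentration matrix.
#' @export
init_tracer <- function(grid) {
  stopifnot(inherits(grid, "laa_grid"))
  if (!any(grid$laa))
    stop("configuration error: empty appendage (no cells to initialize)")
  matrix(as.numeric(grid$laa), grid$nx, grid$ny)
}

# normalize a flow argument to frames + period
flow_frames <- function(flow) {
  if (inherits(flow, "flow_solution")) {
    list(fu = flow$frames_u, fv = flow$frames_v,
         nf = length(flow$frames_u),
         period = if (is.na(flow$period)) 1 else flow$period)
  } else {
    stopifnot(is.list(flow), !is.null(flow$u), !is.null(flow$v))
    list(fu = list(flow$u), fv = list(flow$v), nf = 1L, period = 1)
  }
}

tracer_dt <- function(frames, h, cfl = 0.45) {
  umax <- max(vapply(frames$fu, function(m) max(abs(m)), 0),
              vapply(frames$fv, function(m) max(abs(m)), 0), 1e-12)
  cfl * h / umax
}

#' Advance a tracer field by a number of donor-cell steps
#'
#' Low-level single-field update used for scheme verification; most
#' analyses use [run_washout()].
#'
#' @param field Concentration matrix (see [init_tracer()]).
#' @param flow A `flow_solution` or a list with staggered `u`, `v`.
#' @param grid The `laa_grid`.
#' @param dt Time step, s (must satisfy the advective CFL condition).
#' @param nsteps Number of steps (default 1).
#' @return The updated concentration matrix, with attributes `mass` and
#'   `outflux_cum` (final values).
#' @export
advance_tracer <- function(field, flow, grid, dt, nsteps = 1L) {
  fr <- flow_frames(flow)
  out <- cpp_tracer_run(grid$lab, grid$laa, grid$h,
                        unlist(fr$fu), unlist(fr$fv), fr$nf, fr$period,
                        dt, 0, nsteps * dt, as.integer(nsteps), field)
  if (out$c_min < -1e-10 || out$c_max > 1 + 1e-10)
    stop("scheme error: tracer boundedness violated (min ", out$c_min,
         ", max ", out$c_max, ")")
  res <- out$c_final
  attr(res, "mass") <- tail(out$mass, 1)
  attr(res, "outflux_cum") <- tail(out$outflux_cum, 1)
  res
}

#' Integrate the washout of the appendage tracer
#'
#' Runs donor-cell tracer transport to `t_max` over a frozen (steady) or
#' cyclically replayed (pulsatile) velocity field, sampling the
#' appendage-averaged concentration. Supports continuing a previous run
#' (`resume`) so a truncation study can reuse one long integration.
#'
#' @param grid An `laa_grid`.
#' @param flow A `flow_solution` (steady => frozen field, cyclic => cycle
#'   replay) or a list with `u`, `v`.
#' @param t_max Washout horizon, s.
#' @param sample_interval Sampling interval, s; default `t_max / 2000`,
#'   which conditions the exponential fits well.
#' @param cfl Advective CFL number of the tracer step (default 0.45).
#' @param resume A previous `concentration_series` to continue from.
#' @return A `concentration_series`: data frame columns `t`, `c_laa`,
#'   `mass`, `outflux_cum`, with the final concentration field, cell size
#'   and appendage area in attributes.
#' @export
run_washout <- function(grid, flow, t_max, sample_interval = NULL,
                        cfl = 0.45, resume = NULL) {
  stopifnot(inherits(grid, "laa_grid"))
  fr <- flow_frames(flow)
  if (fr$nf > 1 && t_max < fr$period)
    stop("configuration error: t_max shorter than one cycle in cyclic mode")
  if (is.null(sample_interval)) sample_interval <- t_max / 2000
  dt <- min(tracer_dt(fr, grid$h, cfl), sample_interval)
  sample_every <- max(1L, as.integer(round(sample_interval / dt)))
  if (is.null(resume)) {
    c0 <- init_tracer(grid)
    t0 <- 0
    base <- NULL
  } else {
    c0 <- attr(resume, "c_final")
    t0 <- max(resume$t)
    base <- resume
    stopifnot(!is.null(c0), t_max > t0)
  }
  out <- cpp_tracer_run(grid$lab, grid$laa, grid$h,
                        unlist(fr$fu), unlist(fr$fv), fr$nf, fr$period,
                        dt, t0, t_max, sample_every, c0)
  if (out$c_min < -1e-10 || out$c_max > 1 + 1e-10)
    stop("scheme error: tracer boundedness violated")
  df <- data.frame(t = out$t, c_laa = out$c_laa, mass = out$mass,
                   outflux_cum = out$outflux_cum)
  if (!is.null(base)) {
    prev_out <- tail(base$outflux_cum, 1)
    df$outflux_cum <- df$outflux_cum + prev_out
    df <- rbind(base[base$t < t0, c("t", "c_laa", "mass", "outflux_cum")],
                df)
  }
  structure(df, class = c("concentration_series", "data.frame"),
            c_final = out$c_final, h = grid$h, area = laa_area(grid),
            dt = dt, c_min = out$c_min, c_max = out$c_max)
}

#' @export
print.concentration_series <- function(x, ...) {
  cat("<concentration_series> ", nrow(x), " samples over ",
      signif(max(x$t), 4), " s; C_LAA(end) = ",
      signif(tail(x$c_laa, 1), 4), "\n", sep = "")
  invisible(x)
}
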