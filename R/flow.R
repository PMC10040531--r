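# R interface to the masked staggered-grid flow solver (src/solver.cpp).
#
# Cardiac output in L/min is mapped to a channel velocity by Reynolds
# matching: Re = re_per_lpm * CO with Re = rho * U * H / mu_ref, using a
# fixed reference viscosity so that changing the rheology model changes
# only the constitutive law, never the imposed inflow. The mapping keeps
# the physiologic rank ordering of cardiac outputs while keeping the toy
# domain laminar and the time step practical.

#' Solver configuration
#'
#' @param dt Time step, s, or `NA` (default) to choose it from the
#'   advective CFL condition; diffusion is implicit so advection sets the
#'   stability limit. The run halves dt and restarts whenever the CFL
#'   ceiling is hit (logged in the diagnostics).
#' @param spin_up_cycles Pulsatile spin-up cycles before one cycle is
#'   recorded (default 25, matching the convention of running tracer
#'   transport only after the flow is periodic).
#' @param tol_velocity Steady-state criterion: maximum velocity change per
#'   step, m/s.
#' @param tol_div Post-projection divergence tolerance, s^-1.
#' @param max_pressure_iterations Iteration cap for the pressure (and
#'   momentum) conjugate-gradient solves.
#' @param cfl_max Advective CFL ceiling.
#' @param max_steps Step budget for steady solves.
#' @param frames_per_cycle Velocity snapshots stored per cycle for cyclic
#'   tracer replay.
#' @param re_per_lpm Reynolds number assigned per L/min of cardiac output.
#' @param mu_ref Reference viscosity for the CO-to-velocity mapping, Pa s.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(dt = NA_real_, spin_up_cycles = 25L,
                          tol_velocity = 1e-8, tol_div = 1e-8,
                          max_pressure_iterations = 20000L,
                          cfl_max = 0.9, max_steps = 60000L,
                          frames_per_cycle = 24L,
                          re_per_lpm = 20, mu_ref = 0.00371) {
  stopifnot(is.na(dt) || dt > 0, tol_velocity > 0, tol_div > 0,
            cfl_max > 0)
  structure(as.list(environment()), class = "solver_config")
}

#' Channel mean velocity for a cardiac output
#'
#' `U = Re * mu_ref / (rho * H)` with `Re = re_per_lpm * CO`.
#'
#' @param co_lpm Cardiac output (or instantaneous flow), L/min.
#' @param grid An `laa_grid` (for the channel height).
#' @param config A [solver_config()].
#' @param rho Density, kg/m^3.
#' @return Mean channel velocity, m/s.
#' @export
co_to_velocity <- function(co_lpm, grid, config = solver_config(),
                           rho = 1060) {
  config$re_per_lpm * co_lpm * config$mu_ref /
    (rho * grid$spec$channel_height)
}

# uniform inlet velocity for an instantaneous flow (L/min equivalent):
# channel flux U*H split over the total inlet width at equal velocity
inlet_velocity <- function(q_lpm, grid, config, rho) {
  u_mean <- co_to_velocity(q_lpm, grid, config, rho)
  q2d <- u_mean * grid$spec$channel_height        # m^2/s per unit depth
  widths <- grid$h * tabulate(grid$lab[grid$lab >= .CELL_INLET0] -
                                .CELL_INLET0 + 1L)
  distribute_inlets(q2d, widths)$velocity
}

rheo_args <- function(rheology) {
  if (rheology$model == "newtonian") {
    list(mode = 0L, mu = rheology$mu, mu_p = rheology$mu_p, hct = 0,
         k0 = 1, kinf = 1, gc = 1, gmin = 0)
  } else {
    co <- quemada_coefficients(rheology$hct)
    list(mode = 1L, mu = rheology$mu, mu_p = rheology$mu_p,
         hct = rheology$hct, k0 = co$k0, kinf = co$k_inf, gc = co$gamma_c,
         gmin = rheology$gamma_min)
  }
}

run_chunk <- function(grid, rheology, vin, dt, state, config,
                      record_every = 0L) {
  ra <- rheo_args(rheology)
  cpp_flow_run(grid$lab, grid$h, rheology$rho, ra$mode, ra$mu, ra$mu_p,
               ra$hct, ra$k0, ra$kinf, ra$gc, ra$gmin, vin, dt,
               state$u, state$v, config$cfl_max, config$tol_div,
               as.integer(config$max_pressure_iterations),
               as.integer(record_every))
}

zero_state <- function(grid) {
  list(u = matrix(0, grid$nx + 1, grid$ny), v = matrix(0, grid$nx,
                                                       grid$ny + 1))
}

# pick a stable dt for a given peak inlet velocity (advective CFL with a
# margin for in-domain acceleration through the narrow neck); the runtime
# CFL guard halves it further if the margin proves too small
auto_dt <- function(config, grid, u_in_peak, margin = 2.5) {
  u_cap <- max(abs(u_in_peak)) * margin + 1e-12
  dt <- 0.35 * grid$h / u_cap
  if (!is.na(config$dt)) dt <- min(config$dt, dt)
  dt
}

#' Solve for a steady or time-periodic flow field
#'
#' Steady inflow: time-marches until the maximum velocity change per step
#' drops below `tol_velocity` (or the step budget is exhausted, with a
#' warning). Pulsatile inflow: runs `spin_up_cycles` cardiac cycles, then
#' records one cycle of velocity snapshots for cyclic tracer replay; the
#' cycle-to-cycle L2 velocity difference is reported as the periodicity
#' residual. The time step is halved and the run restarted whenever the
#' CFL ceiling is hit.
#'
#' @param grid An `laa_grid`.
#' @param rheology A [rheology_params()].
#' @param waveform A [make_waveform()] result, or a single number taken as
#'   a steady cardiac output in L/min.
#' @param config A [solver_config()].
#' @return An object of class `flow_solution` with the final staggered
#'   fields `u`, `v`, pressure `p`, apparent viscosity `mu`, mode
#'   (`"steady"`/`"cyclic"`), stored cycle frames (cyclic), and
#'   diagnostics (divergence, CFL, convergence history).
#' @export
solve_flow <- function(grid, rheology, waveform, config = solver_config()) {
  stopifnot(inherits(grid, "laa_grid"), inherits(rheology, "rheology_params"))
  if (is.numeric(waveform) && length(waveform) == 1)
    waveform <- make_waveform("steady", co = waveform)
  steady <- diff(range(waveform$q_lpm)) == 0
  rho <- rheology$rho
  dt_halvings <- 0L

  if (steady) {
    v_in <- inlet_velocity(waveform$co, grid, config, rho)
    dt <- auto_dt(config, grid, v_in)
    state <- zero_state(grid)
    steps_done <- 0L
    res <- NULL
    repeat {
      chunk <- min(400L, config$max_steps - steps_done)
      if (chunk <= 0) {
        warning("steady solve did not reach tol_velocity within max_steps")
        break
      }
      res <- run_chunk(grid, rheology, rep(v_in, chunk), dt, state, config)
      if (res$diverged) stop("solver divergence (NaN velocity)")
      if (res$cfl_exceeded_at >= 0) {
        dt <- dt / 2; dt_halvings <- dt_halvings + 1L
        if (dt_halvings > 12) stop("solver error: CFL unreachable")
        state <- zero_state(grid); steps_done <- 0L
        next
      }
      state <- list(u = res$u, v = res$v)
      steps_done <- steps_done + chunk
      if (res$max_du < config$tol_velocity) break
    }
    # tight final projection so the tracer sees a divergence-free field
    pr <- cpp_project(grid$lab, grid$h, res$u, res$v, rho, dt, 1e-13,
                      as.integer(config$max_pressure_iterations))
    res$u <- pr$u; res$v <- pr$v; res$div_max <- pr$div_max
    return(structure(list(
      mode = "steady", u = res$u, v = res$v, p = res$p, mu = res$mu,
      frames_u = list(res$u), frames_v = list(res$v), period = NA_real_,
      dt = dt, steps = steps_done, max_du = res$max_du,
      div_max = res$div_max, dt_halvings = dt_halvings,
      waveform = waveform, grid_dim = c(grid$nx, grid$ny)),
      class = "flow_solution"))
  }

  # pulsatile: spin up, then record one cycle
  T_ <- waveform$period
  peak <- max(abs(range(waveform$q_lpm)))
  dt0 <- auto_dt(config, grid, inlet_velocity(peak, grid, config, rho))
  repeat {
    nsc <- ceiling(T_ / dt0)
    nsc <- as.integer(ceiling(nsc / config$frames_per_cycle) *
                        config$frames_per_cycle)
    dt <- T_ / nsc
    tq <- (seq_len(nsc) - 0.5) * dt
    q_t <- stats::approx(waveform$t, waveform$q_lpm, xout = tq)$y
    vin_cycle <- vapply(q_t, inlet_velocity, 0, grid = grid,
                        config = config, rho = rho)
    state <- zero_state(grid)
    residuals <- numeric(0)
    ok <- TRUE
    for (cyc in seq_len(config$spin_up_cycles)) {
      res <- run_chunk(grid, rheology, vin_cycle, dt, state, config)
      if (res$diverged) stop("solver divergence (NaN velocity)")
      if (res$cfl_exceeded_at >= 0) { ok <- FALSE; break }
      resid <- sqrt(sum((res$u - state$u)^2) + sum((res$v - state$v)^2))
      residuals <- c(residuals, resid)
      state <- list(u = res$u, v = res$v)
    }
    if (!ok) {
      dt0 <- dt0 / 2; dt_halvings <- dt_halvings + 1L
      if (dt_halvings > 12) stop("solver error: CFL unreachable")
      next
    }
    rec <- run_chunk(grid, rheology, vin_cycle, dt, state, config,
                     record_every = nsc %/% config$frames_per_cycle)
    if (rec$cfl_exceeded_at >= 0) {
      dt0 <- dt0 / 2; dt_halvings <- dt_halvings + 1L
      if (dt_halvings > 12) stop("solver error: CFL unreachable")
      next
    }
    frames_u <- as.list(rec$frames_u)
    frames_v <- as.list(rec$frames_v)
    for (k in seq_along(frames_u)) {   # divergence-free frames for replay
      pr <- cpp_project(grid$lab, grid$h, frames_u[[k]], frames_v[[k]],
                        rho, dt, 1e-13,
                        as.integer(config$max_pressure_iterations))
      frames_u[[k]] <- pr$u; frames_v[[k]] <- pr$v
    }
    return(structure(list(
      mode = "cyclic", u = rec$u, v = rec$v, p = rec$p, mu = rec$mu,
      frames_u = frames_u, frames_v = frames_v,
      period = T_, dt = dt, steps = config$spin_up_cycles * nsc,
      periodicity_residuals = residuals, div_max = rec$div_max,
      dt_halvings = dt_halvings, waveform = waveform,
      grid_dim = c(grid$nx, grid$ny)),
      class = "flow_solution"))
  }
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution> mode =", x$mode, " dt =", signif(x$dt, 3),
      "s, steps =", x$steps, "\n  max divergence:", signif(x$div_max, 3),
      "1/s")
  if (x$mode == "cyclic")
    cat("  periodicity residual:",
        signif(tail(x$periodicity_residuals, 1), 3))
  cat("\n")
  invisible(x)
}

#' Global mass balance of a flow field
#'
#' @param flow A `flow_solution` (steady mode).
#' @param grid The `laa_grid` it was solved on.
#' @return A list with `inflow`, `outflow` (m^2/s) and the relative
#'   imbalance.
#' @export
flow_mass_balance <- function(flow, grid) {
  u <- flow$u
  h <- grid$h
  inflow <- 0; outflow <- 0
  for (j in seq_len(grid$ny)) {
    for (i in seq_len(grid$nx + 1)) {
      L <- if (i >= 2) grid$lab[i - 1, j] else .CELL_WALL
      R <- if (i <= grid$nx) grid$lab[i, j] else .CELL_WALL
      if (L >= .CELL_INLET0 && R == .CELL_FLUID) inflow <- inflow + u[i, j] * h
      if (L == .CELL_FLUID && R == .CELL_OUTLET) outflow <- outflow + u[i, j] * h
    }
  }
  list(inflow = inflow, outflow = outflow,
       rel_imbalance = abs(inflow - outflow) / max(abs(inflow), 1e-300))
}

#' Write a flow snapshot as a legacy VTK structured file
#'
#' Exports cell-centered velocity components and magnitude, pressure and
#' apparent viscosity alongside the grid labels.
#'
#' @param flow A `flow_solution`.
#' @param grid The `laa_grid` it was solved on.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_flow_vtk <- function(flow, grid, file) {
  nx <- grid$nx; ny <- grid$ny
  uc <- 0.5 * (flow$u[1:nx, ] + flow$u[2:(nx + 1), ])
  vc <- 0.5 * (flow$v[, 1:ny] + flow$v[, 2:(ny + 1)])
  write_vtk_grid(grid, file, fields = list(
    u = uc, v = vc, speed = sqrt(uc^2 + vc^2), p = flow$p, mu = flow$mu))
}

#' Cell-centered velocity magnitude of a flow solution
#' @param flow A `flow_solution`.
#' @param grid The grid.
#' @return An `nx x ny` matrix (NA outside fluid).
#' @export
velocity_magnitude <- function(flow, grid) {
  nx <- grid$nx; ny <- grid$ny
  uc <- 0.5 * (flow$u[1:nx, ] + flow$u[2:(nx + 1), ])
  vc <- 0.5 * (flow$v[, 1:ny] + flow$v[, 2:(ny + 1)])
  m <- sqrt(uc^2 + vc^2)
  m[grid$lab != .CELL_FLUID] <- NA_real_
  m
}
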