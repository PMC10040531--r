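# Flow solver verification beyond the headline benchmarks (which live in
# test-acceptance.R): fixed points, projection quality, self-consistency,
# time-step and grid sensitivity, rheology mechanism.

test_that("zero inflow from rest is a fixed point", {
  g <- build_geometry(test_geometry())
  ra <- laawash:::rheo_args(rheology_params("newtonian"))
  out <- laawash:::cpp_flow_run(g$lab, g$h, 1060, ra$mode, ra$mu, ra$mu_p,
                                ra$hct, ra$k0, ra$kinf, ra$gc, ra$gmin,
                                rep(0, 5), 1e-3,
                                matrix(0, g$nx + 1, g$ny),
                                matrix(0, g$nx, g$ny + 1),
                                0.9, 1e-8, 10000L, 0L)
  expect_equal(max(abs(out$u)), 0)
  expect_equal(max(abs(out$v)), 0)
  expect_equal(max(abs(out$p)), 0)
})

test_that("post-projection divergence and global mass balance hold", {
  s <- shared_steady()
  expect_lt(s$flow$div_max, 1e-8)
  mb <- flow_mass_balance(s$flow, s$grid)
  expect_gt(mb$inflow, 0)
  expect_lt(mb$rel_imbalance, 1e-6)
})

test_that("steady state is independent of the initial condition", {
  s <- shared_steady()
  g <- s$grid
  cfg <- solver_config(tol_velocity = 1e-7)
  v_in <- laawash:::inlet_velocity(4.4, g, cfg, 1060)
  dt <- s$flow$dt
  # restart from a plug-flow initial guess and march the same number of
  # chunks the converged run used
  state <- list(u = matrix(laawash:::co_to_velocity(4.4, g, cfg),
                           g$nx + 1, g$ny),
                v = matrix(0, g$nx, g$ny + 1))
  for (it in 1:80) {
    res <- laawash:::run_chunk(g, s$rheology, rep(v_in, 200), dt, state, cfg)
    state <- list(u = res$u, v = res$v)
    if (res$max_du < 1e-7) break
  }
  expect_lt(res$max_du, 1e-7)
  # same attractor from both initial conditions
  scale <- max(abs(s$flow$u))
  expect_lt(max(abs(state$u - s$flow$u)) / scale, 5e-3)
})

test_that("the solution is insensitive to halving the time step", {
  g <- build_geometry(test_geometry())
  rh <- rheology_params("newtonian")
  f1 <- solve_flow(g, rh, 4.4, solver_config(tol_velocity = 1e-8))
  f2 <- solve_flow(g, rh, 4.4, solver_config(dt = f1$dt / 2,
                                             tol_velocity = 1e-8))
  scale <- max(abs(f1$u))
  expect_lt(max(abs(f1$u - f2$u)) / scale, 1e-3)
})

test_that("grid refinement changes the pouch-mean speed by < 5 percent", {
  spec <- test_geometry(h = 0.01 / 16)
  rh <- rheology_params("newtonian")
  pouch_speed <- function(spec) {
    g <- build_geometry(spec)
    fl <- solve_flow(g, rh, 4.4, solver_config(tol_velocity = 1e-7))
    mean(velocity_magnitude(fl, g)[g$laa])
  }
  v1 <- pouch_speed(spec)
  spec$h <- spec$h / 2
  v2 <- pouch_speed(spec)
  expect_lt(abs(v1 - v2) / v2, 0.05)
})

test_that("pulsatile spin-up approaches a periodic orbit monotonically", {
  g <- build_geometry(test_geometry(h = 0.01 / 8, pouch_neck_width = 0.0052))
  w <- make_waveform("af", co = 4.4, hr = 75)
  fl <- solve_flow(g, rheology_params("newtonian"), w,
                   solver_config(spin_up_cycles = 7L))
  r <- fl$periodicity_residuals
  expect_gte(length(r), 6)
  last5 <- tail(r, 5)
  expect_true(all(diff(last5) < 0))
  expect_lt(tail(last5, 1), r[1] * 1e-2)
})

test_that("Quemada and matched Newtonian agree in the channel core but
          diverge inside the pouch", {
  s <- shared_steady()
  g <- s$grid
  # Newtonian comparator matched at the channel's developed shear level
  u_mean <- laawash:::co_to_velocity(4.4, g, solver_config())
  gd_core <- 6 * u_mean / g$spec$channel_height
  mu_eq <- apparent_viscosity(gd_core, s$rheology)
  fl_n <- solve_flow(g, rheology_params("newtonian", mu = mu_eq), 4.4,
                     solver_config(tol_velocity = 1e-7))
  vq <- velocity_magnitude(s$flow, g)
  vn <- velocity_magnitude(fl_n, g)
  core <- !g$laa & g$lab == 1L &
    matrix(g$yc, g$nx, g$ny, byrow = TRUE) > 0.3 * g$spec$channel_height &
    matrix(g$yc, g$nx, g$ny, byrow = TRUE) < 0.7 * g$spec$channel_height
  core_diff <- mean(abs(vq[core] - vn[core])) / mean(vn[core])
  pouch_diff <- mean(abs(vq[g$laa] - vn[g$laa])) / mean(vn[g$laa])
  expect_lt(core_diff, 0.05)
  expect_gt(pouch_diff, core_diff)
})
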