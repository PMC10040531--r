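# Tracer transport: initialization, conservation, boundedness, and the
# physical orderings washout must respect.

test_that("tracer initialization marks exactly the appendage", {
  g <- build_geometry(test_geometry())
  c0 <- init_tracer(g)
  expect_equal(sum(c0), sum(g$laa))
  expect_true(all(c0[g$laa] == 1))
  expect_true(all(c0[!g$laa] == 0))
  g2 <- build_geometry(test_geometry(pouch_depth = 0))
  expect_error(init_tracer(g2), "empty appendage")
})

test_that("zero velocity leaves the field unchanged forever", {
  g <- build_geometry(test_geometry())
  flow <- list(u = matrix(0, g$nx + 1, g$ny), v = matrix(0, g$nx, g$ny + 1))
  ser <- run_washout(g, flow, t_max = 5, sample_interval = 0.5)
  expect_true(all(ser$c_laa == 1))
  expect_true(all(ser$outflux_cum == 0))
})

test_that("a marked band in plug flow exits on the advective time scale", {
  pc <- plug_channel()
  g <- pc$grid
  # band between 1/4 and 1/2 of the channel length
  xc <- matrix(g$xc, g$nx, g$ny)
  g$laa[, ] <- g$lab == 1L & xc > 0.005 & xc <= 0.010
  t_exit <- (0.02 - 0.005) / pc$U       # far band edge to outlet
  ser <- run_washout(g, pc$flow, t_max = 2.5 * t_exit,
                     sample_interval = t_exit / 100)
  expect_true(all(diff(ser$c_laa) <= 1e-12))
  expect_lt(tail(ser$c_laa, 1), 1e-6)
  expect_lt(tail(ser$mass, 1), 1e-6 * ser$mass[1])
  # conservation at every sample
  err <- abs(ser$mass + ser$outflux_cum - ser$mass[1]) / ser$mass[1]
  expect_lt(max(err), 1e-8)
})

test_that("washout over a solved pouch flow conserves mass and stays
          bounded", {
  s <- shared_steady()
  ser <- run_washout(s$grid, s$flow, t_max = 60)
  err <- abs(ser$mass + ser$outflux_cum - ser$mass[1]) / ser$mass[1]
  expect_lt(max(err), 1e-6)
  expect_gte(attr(ser, "c_min"), -1e-10)
  expect_lte(attr(ser, "c_max"), 1 + 1e-10)
  expect_equal(ser$c_laa[1], 1)
  expect_true(all(ser$c_laa >= 0 & ser$c_laa <= 1))
})

test_that("a deep narrow pouch retains tracer longer than a shallow wide
          one", {
  rh <- rheology_params("newtonian")
  cfg <- solver_config(tol_velocity = 1e-7)
  wash <- function(spec) {
    g <- build_geometry(spec)
    fl <- solve_flow(g, rh, 4.4, cfg)
    run_washout(g, fl, t_max = 30, sample_interval = 0.5)
  }
  deep <- wash(test_geometry(pouch_depth = 0.008, pouch_neck_width = 0.004))
  shallow <- wash(test_geometry(pouch_depth = 0.004,
                                pouch_neck_width = 0.008))
  expect_true(all(deep$c_laa[-1] > shallow$c_laa[-1]))
})

test_that("doubling a frozen field compresses the washout curve in time", {
  s <- shared_steady()
  g <- s$grid
  slow <- list(u = s$flow$u, v = s$flow$v)
  fast <- list(u = 2 * s$flow$u, v = 2 * s$flow$v)
  ser_s <- run_washout(g, slow, t_max = 40, sample_interval = 0.4)
  ser_f <- run_washout(g, fast, t_max = 20, sample_interval = 0.2)
  # same CFL, halved dt: the discrete dynamics coincide step for step
  n <- min(nrow(ser_s), nrow(ser_f))
  expect_equal(ser_f$c_laa[1:n], ser_s$c_laa[1:n], tolerance = 1e-10)
})

test_that("checkpoint/resume reproduces an uninterrupted run", {
  s <- shared_steady()
  full <- run_washout(s$grid, s$flow, t_max = 30, sample_interval = 0.5)
  part <- run_washout(s$grid, s$flow, t_max = 15, sample_interval = 0.5)
  cont <- run_washout(s$grid, s$flow, t_max = 30, sample_interval = 0.5,
                      resume = part)
  expect_equal(tail(cont$c_laa, 1), tail(full$c_laa, 1), tolerance = 1e-12)
  expect_equal(tail(cont$outflux_cum, 1), tail(full$outflux_cum, 1),
               tolerance = 1e-12)
})
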