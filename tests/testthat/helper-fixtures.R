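# Shared fixtures, built in code. Expensive flow solves are memoized per
# test run so several test files can share one solution.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# small reference pouch geometry used across flow/tracer tests
test_geometry <- function(...) {
  args <- list(channel_length = 0.03, channel_height = 0.01,
               pouch_depth = 0.006, pouch_neck_width = 0.005,
               outlet_extension_length = 0.03, h = 0.01 / 12)
  do.call(geometry_spec, utils::modifyList(args, list(...)))
}

# one steady Quemada solution on the reference geometry, shared
shared_steady <- function() {
  memo("steady", {
    g <- build_geometry(test_geometry())
    rh <- rheology_params("quemada", hct = 0.455)
    fl <- solve_flow(g, rh, 4.4, solver_config(tol_velocity = 1e-7))
    list(grid = g, rheology = rh, flow = fl)
  })
}

# straight-channel grid with a uniform plug-flow field (analytic transport)
plug_channel <- function(U = 0.01, h = 5e-4, L = 0.02, H = 0.005) {
  g <- build_geometry(geometry_spec(
    channel_length = L, channel_height = H, pouch_depth = 0,
    n_inlets = 1, inlet_widths = H - 1e-9,
    outlet_extension_length = 0, h = h))
  flow <- list(u = matrix(U, g$nx + 1, g$ny), v = matrix(0, g$nx, g$ny + 1))
  list(grid = g, flow = flow, U = U)
}

# noiseless multi-exponential washout series
synthetic_series <- function(a, tau, c_inf = 0, t_max = 100, n = 1500) {
  t <- seq(0, t_max, length.out = n)
  c_ <- c_inf + colSums(t(exp(-outer(t, 1 / tau))) * a)
  list(t = t, c_laa = c_)
}
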