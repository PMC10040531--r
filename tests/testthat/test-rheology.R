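# Quemada constitutive model and strain-rate kinematics.

test_that("Quemada coefficients match the published polynomials", {
  co0 <- quemada_coefficients(0)
  expect_equal(co0$k0, exp(3.874))
  expect_equal(co0$k_inf, exp(1.3435))
  expect_equal(co0$gamma_c, exp(-6.1508))
  # independent evaluation at Hct = 0.455
  co <- quemada_coefficients(0.455)
  expect_equal(co$k0, 3.895, tolerance = 5e-4)
  expect_equal(co$k_inf, 1.765, tolerance = 5e-4)
  expect_equal(co$gamma_c, 4.97, tolerance = 1e-3)
  # gamma_c strictly increasing over the physiologic range
  h <- seq(0.1, 0.6, by = 0.005)
  gc <- vapply(h, function(x) quemada_coefficients(x)$gamma_c, 0)
  expect_true(all(diff(gc) > 0))
  expect_error(quemada_coefficients(0.8), "range")
})

test_that("intrinsic viscosity interpolates k0 -> k_inf in sqrt(shear)", {
  co <- quemada_coefficients(0.4)
  expect_equal(intrinsic_viscosity(0, 0.4), co$k0)
  expect_equal(intrinsic_viscosity(co$gamma_c, 0.4),
               (co$k0 + co$k_inf) / 2)
  expect_equal(intrinsic_viscosity(1e12, 0.4), co$k_inf, tolerance = 1e-4)
})

test_that("apparent viscosity is shear-thinning and hematocrit-thickening", {
  g <- 10^seq(-2, 4, by = 0.1)
  for (hct in c(0.2, 0.35, 0.5, 0.6)) {
    mu <- apparent_viscosity(g, rheology_params("quemada", hct = hct))
    expect_true(all(diff(mu) < 0))        # shear-thinning
  }
  for (gd in c(1, 100, 2000)) {
    h <- seq(0.05, 0.6, by = 0.05)
    mu <- vapply(h, function(x)
      apparent_viscosity(gd, rheology_params("quemada", hct = x)), 0)
    expect_true(all(diff(mu) > 0))        # thicker blood at higher Hct
  }
  # Hct = 0 degenerates to plasma viscosity
  expect_equal(apparent_viscosity(123, rheology_params("quemada", hct = 0)),
               0.00123)
  # infinite-shear plateau: mu -> mu_p (1 - k_inf Hct / 2)^-2
  hct <- 0.45
  co <- quemada_coefficients(hct)
  lim <- 0.00123 * (1 - 0.5 * co$k_inf * hct)^-2
  mu6 <- apparent_viscosity(1e6 * co$gamma_c,
                            rheology_params("quemada", hct = hct))
  expect_lt(abs(mu6 - lim) / lim, 0.01)
})

test_that("percent hematocrit is accepted at the interface", {
  expect_equal(equivalent_newtonian_viscosity(45.5),
               equivalent_newtonian_viscosity(0.455))
  h <- seq(0.1, 0.6, by = 0.02)
  mu <- vapply(h, equivalent_newtonian_viscosity, 0)
  expect_true(all(diff(mu) > 0))
})

test_that("strain-rate magnitude matches canonical flows", {
  # simple shear du/dy = g  =>  gamma_dot = g
  expect_equal(strain_rate_magnitude(matrix(c(0, 0, 7, 0), 2, 2)), 7)
  # rigid rotation has no strain
  expect_equal(strain_rate_magnitude(matrix(c(0, 3, -3, 0), 2, 2)), 0)
  # uniaxial extension du/dx = a, dv/dy = -a  =>  gamma_dot = 2a
  expect_equal(strain_rate_magnitude(diag(c(2, -2))), 4)
})

test_that("strain-rate magnitude is frame-invariant", {
  set.seed(5)
  for (i in 1:25) {
    G <- matrix(rnorm(4), 2, 2)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    G2 <- R %*% G %*% t(R)
    expect_equal(strain_rate_magnitude(G2), strain_rate_magnitude(G),
                 tolerance = 1e-12)
  }
})
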