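# Blood rheology: Newtonian and Quemada generalized-Newtonian viscosity.
#
# The Quemada model expresses the apparent viscosity of whole blood as
#   mu_a = mu_p * (1 - 0.5 * k * Hct)^-2
# where mu_p is plasma viscosity, Hct the hematocrit (red-cell volume
# fraction) and k the intrinsic viscosity, which interpolates between a
# zero-shear value k0 and an infinite-shear value k_inf with the square
# root of the shear-rate ratio:
#   k = (k0 + k_inf * sqrt(gdot/gdot_c)) / (1 + sqrt(gdot/gdot_c)).
# k0, k_inf and the critical shear rate gdot_c are exponentials of cubic
# polynomials in Hct fitted to rheometry data.

#' Rheology parameter set
#'
#' Describes the constitutive model used by the flow solver: either a
#' constant-viscosity Newtonian fluid or the Quemada shear-thinning model.
#' Hematocrit may be given as a fraction (0-0.65) or as a percent (> 1 is
#' interpreted as percent and divided by 100).
#'
#' @param model `"newtonian"` or `"quemada"`.
#' @param mu Dynamic viscosity in Pa s (Newtonian only). Default 0.00371,
#'   a standard whole-blood value at normal hematocrit.
#' @param mu_p Plasma viscosity in Pa s (Quemada only). Default 0.00123.
#' @param hct Hematocrit, fraction of 1 (or percent). Required for Quemada.
#' @param rho Density in kg m^-3. Default 1060.
#' @param gamma_min Low-shear cutoff, s^-1 (default 1e-3): the apparent
#'   viscosity is evaluated at `max(gamma_dot, gamma_min)`. The fitted
#'   `k0` law makes the zero-shear viscosity diverge in a band of
#'   low-to-mid hematocrits (a gel-like limit), so a cutoff far below any
#'   hemodynamically relevant shear keeps the constitutive law finite.
#' @return An object of class `rheology_params`.
#' @examples
#' rheology_params("quemada", hct = 0.455)
#' @export
rheology_params <- function(model = c("newtonian", "quemada"),
                            mu = 0.00371, mu_p = 0.00123,
                            hct = NA_real_, rho = 1060,
                            gamma_min = 1e-3) {
  model <- match.arg(model)
  if (!is.na(hct) && hct > 1) hct <- hct / 100
  stopifnot(mu > 0, mu_p > 0, rho > 0, gamma_min >= 0)
  if (model == "quemada") {
    if (is.na(hct)) stop("quemada model requires a hematocrit")
    if (hct < 0 || hct > 0.65)
      stop("hematocrit out of supported range [0, 0.65]")
    k_floor <- intrinsic_viscosity(gamma_min, hct)
    if (0.5 * k_floor * hct >= 1)
      stop("rheology singularity: 0.5*k*Hct >= 1 at the low-shear cutoff")
  }
  structure(list(model = model, mu = mu, mu_p = mu_p, hct = hct, rho = rho,
                 gamma_min = gamma_min),
            class = "rheology_params")
}

#' Quemada model coefficients for a given hematocrit
#'
#' Evaluates the three empirical coefficient laws: the zero-shear and
#' infinite-shear intrinsic viscosities `k0`, `k_inf` (dimensionless) and
#' the critical shear rate `gamma_c` (s^-1), each the exponential of a
#' cubic polynomial in hematocrit.
#'
#' @param hct Hematocrit as a fraction in \[0, 0.65\].
#' @return A list with components `k0`, `k_inf`, `gamma_c`.
#' @examples
#' quemada_coefficients(0.455)
#' @export
quemada_coefficients <- function(hct) {
  if (any(hct < 0 | hct > 0.65))
    stop("hematocrit out of supported range [0, 0.65]")
  list(
    k0      = exp(3.874  - 10.41  * hct + 13.8   * hct^2 - 6.738  * hct^3),
    k_inf   = exp(1.3435 - 2.803  * hct + 2.711  * hct^2 - 0.6479 * hct^3),
    gamma_c = exp(-6.1508 + 27.923 * hct - 25.6   * hct^2 + 3.697  * hct^3)
  )
}

#' Intrinsic viscosity at a given shear rate
#'
#' @param gamma_dot Shear strain-rate magnitude, s^-1 (vectorized, >= 0).
#' @param hct Hematocrit fraction.
#' @return Dimensionless intrinsic viscosity `k`.
#' @export
intrinsic_viscosity <- function(gamma_dot, hct) {
  stopifnot(all(gamma_dot >= 0))
  co <- quemada_coefficients(hct)
  s <- sqrt(gamma_dot / co$gamma_c)
  (co$k0 + co$k_inf * s) / (1 + s)
}

#' Apparent viscosity of blood
#'
#' For a Newtonian parameter set this is the constant `mu`; for Quemada it
#' is `mu_p * (1 - 0.5 * k * Hct)^-2` with `k` the shear-dependent
#' intrinsic viscosity.
#'
#' @param gamma_dot Shear strain-rate magnitude, s^-1 (vectorized).
#' @param params A [rheology_params()] object.
#' @return Apparent viscosity in Pa s.
#' @examples
#' apparent_viscosity(2000, rheology_params("quemada", hct = 0.455))
#' @export
apparent_viscosity <- function(gamma_dot, params) {
  stopifnot(inherits(params, "rheology_params"), all(gamma_dot >= 0))
  if (params$model == "newtonian") return(rep(params$mu, length(gamma_dot)))
  k <- intrinsic_viscosity(pmax(gamma_dot, params$gamma_min), params$hct)
  arg <- 1 - 0.5 * k * params$hct
  if (any(arg <= 0)) stop("rheology singularity: 0.5*k*Hct >= 1")
  params$mu_p * arg^-2
}

#' Equivalent Newtonian viscosity for a hematocrit
#'
#' The Quemada apparent viscosity evaluated at a high reference shear rate
#' (default 2000 s^-1), used to build a Newtonian comparator that matches
#' the shear-thinning model in the high-shear regime.
#'
#' @param hct Hematocrit fraction (or percent if > 1).
#' @param gamma_ref Reference shear rate, s^-1. Default 2000.
#' @param mu_p Plasma viscosity, Pa s.
#' @return Viscosity in Pa s.
#' @examples
#' equivalent_newtonian_viscosity(0.455)
#' @export
equivalent_newtonian_viscosity <- function(hct, gamma_ref = 2000,
                                           mu_p = 0.00123) {
  if (hct > 1) hct <- hct / 100
  apparent_viscosity(gamma_ref, rheology_params("quemada", mu_p = mu_p,
                                                hct = hct))
}

#' Magnitude of the strain-rate tensor
#'
#' For a 2x2 velocity-gradient tensor `G` with entries `G[i, j] =
#' du_i/dx_j`, forms the symmetric strain-rate tensor
#' `e = (G + t(G)) / 2` and returns `sqrt(2 * sum(e * e))`, the scalar
#' shear-rate magnitude used by generalized-Newtonian models (equal to the
#' imposed shear rate in simple shear, and zero for rigid rotation).
#'
#' @param grad_u 2x2 numeric matrix of velocity gradients, s^-1.
#' @return Scalar strain-rate magnitude, s^-1.
#' @examples
#' strain_rate_magnitude(matrix(c(0, 0, 10, 0), 2, 2)) # simple shear, 10/s
#' @export
strain_rate_magnitude <- function(grad_u) {
  stopifnot(is.matrix(grad_u), all(dim(grad_u) == c(2, 2)),
            all(is.finite(grad_u)))
  e <- (grad_u + t(grad_u)) / 2
  sqrt(2 * sum(e * e))
}
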