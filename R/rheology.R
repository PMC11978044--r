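#' Fluid properties for the Williamson model
#'
#' Material constants shared by the flow and energy solvers. The apparent
#' viscosity follows the rational Williamson law
#' `mu(gdot) = mu_inf + (mu0 - mu_inf)/(1 + lambda*gdot)`, which decreases
#' monotonically from the zero-shear plateau `mu0` to the infinite-shear
#' plateau `mu_inf`. `eta0` and `Gamma` parameterize the alternative linear
#' extra-stress form (see [extra_stress_tensor()]); the two forms are kept
#' independent.
#'
#' @param density Fluid density rho (kg/m^3).
#' @param mu0 Zero-shear viscosity (Pa s).
#' @param mu_inf Infinite-shear viscosity (Pa s), `0 < mu_inf <= mu0`.
#' @param lambda Rheological time constant (s), `>= 0`; `0` gives a Newtonian
#'   fluid of viscosity `mu0`.
#' @param k Thermal conductivity (W/m/K).
#' @param cp Specific heat (J/kg/K).
#' @param alpha Viscous-dissipation switch/multiplier (dimensionless;
#'   1 = on, 0 = off).
#' @param eta0 Consistency viscosity of the linear stress form (Pa s);
#'   defaults to `mu0`.
#' @param Gamma Time constant of the linear stress form (s); defaults to
#'   `lambda`.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1060, mu0 = 0.056, mu_inf = 0.00345,
                             lambda = 3.313, k = 0.52, cp = 3617,
                             alpha = 1, eta0 = mu0, Gamma = lambda) {
  stopifnot(density > 0, mu_inf > 0, mu0 >= mu_inf, lambda >= 0,
            k > 0, cp > 0, alpha >= 0, eta0 > 0, Gamma >= 0)
  structure(list(density = density, mu0 = mu0, mu_inf = mu_inf,
                 lambda = lambda, k = k, cp = cp, alpha = alpha,
                 eta0 = eta0, Gamma = Gamma),
            class = "fluid_properties")
}

#' Newtonian limit helper
#'
#' Convenience constructor for a Newtonian fluid (`lambda = 0`,
#' `mu0 = mu_inf = mu`), used throughout the verification battery.
#'
#' @param mu Dynamic viscosity (Pa s).
#' @inheritParams fluid_properties
#' @return A `fluid_properties` object.
#' @export
newtonian_properties <- function(mu = 0.0035, density = 1060, k = 0.52,
                                 cp = 3617, alpha = 1) {
  fluid_properties(density = density, mu0 = mu, mu_inf = mu, lambda = 0,
                   k = k, cp = cp, alpha = alpha, eta0 = mu, Gamma = 0)
}

#' Shear-rate magnitude from a velocity-gradient tensor
#'
#' Second-invariant shear rate: with
#' `gamma_ij = d(u_i)/d(x_j) + d(u_j)/d(x_i)`, returns
#' `gdot = sqrt(0.5 * sum_ij gamma_ij^2)`. The result is non-negative,
#' vanishes for rigid rotation, and is invariant under orthogonal rotation of
#' the coordinate frame.
#'
#' @param grad 3x3 velocity-gradient matrix `G[i, j] = d(u_i)/d(x_j)` (1/s).
#' @return Scalar shear rate (1/s).
#' @export
shear_rate_magnitude <- function(grad) {
  stopifnot(is.matrix(grad), all(dim(grad) == c(3, 3)), all(is.finite(grad)))
  gam <- grad + t(grad)
  sqrt(0.5 * sum(gam^2))
}

#' Williamson apparent viscosity
#'
#' `mu(gdot) = mu_inf + (mu0 - mu_inf)/(1 + lambda*gdot)`. Strictly
#' decreasing in `gdot` when `mu0 > mu_inf`; identically `mu0` when
#' `lambda = 0`.
#'
#' @param gamma_dot Shear rate(s) (1/s), `>= 0`; vectorized.
#' @param props A [fluid_properties()].
#' @return Apparent viscosity (Pa s), same length as `gamma_dot`.
#' @export
williamson_viscosity <- function(gamma_dot, props) {
  stopifnot(inherits(props, "fluid_properties"))
  if (any(gamma_dot < 0)) stop("shear rate must be >= 0", call. = FALSE)
  props$mu_inf + (props$mu0 - props$mu_inf) / (1 + props$lambda * gamma_dot)
}

#' Williamson extra-stress tensor (linear form)
#'
#' The alternative stress closure `delta_ij = eta0*(1 + Gamma*gdot)*gamma_ij`
#' with `gamma_ij` the rate-of-strain doubling and `gdot` from
#' [shear_rate_magnitude()]. Symmetric; traceless for incompressible fields;
#' reduces to the Newtonian stress at `Gamma = 0`. The form is a low-shear
#' expansion: a warning is emitted outside its validity range
#' `Gamma*gdot < 1`.
#'
#' @param grad 3x3 velocity-gradient matrix (1/s).
#' @param eta0 Consistency viscosity (Pa s).
#' @param Gamma Time constant (s).
#' @return 3x3 stress matrix (Pa).
#' @export
extra_stress_tensor <- function(grad, eta0, Gamma) {
  stopifnot(is.matrix(grad), all(dim(grad) == c(3, 3)), all(is.finite(grad)),
            eta0 > 0, Gamma >= 0)
  gdot <- shear_rate_magnitude(grad)
  if (Gamma * gdot >= 1)
    warning("Gamma * gamma_dot >= 1: outside the validity range of the ",
            "linear Williamson stress form", call. = FALSE)
  eta0 * (1 + Gamma * gdot) * (grad + t(grad))
}
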