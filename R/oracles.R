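# Analytic / independent verification oracles.
# These are deliberately independent of the finite-volume discretization:
# closed forms where they exist, pointwise root-finding plus quadrature for
# the shear-thinning pipe flow.

#' Hagen-Poiseuille pipe-flow oracle
#'
#' Exact laminar Newtonian pipe flow at mean speed `U` in a tube of radius
#' `R`: axial velocity `u(r) = 2*U*(1 - (r/R)^2)` (centerline `2U`) and
#' pressure drop `dp = 8*mu*L*U/R^2` over length `L`.
#'
#' @param r Radial positions (m).
#' @param R Tube radius (m).
#' @param U Mean (bulk) axial speed (m/s).
#' @param mu Dynamic viscosity (Pa s).
#' @param L Tube length (m).
#' @return List with `u` (velocity at `r`), `u_center`, `dp`.
#' @export
poiseuille_oracle <- function(r, R, U, mu, L) {
  list(u = 2 * U * (1 - (r / R)^2),
       u_center = 2 * U,
       dp = 8 * mu * L * U / R^2)
}

#' Elliptic-duct Poiseuille oracle
#'
#' Exact laminar Newtonian flow in a straight duct of elliptic cross-section
#' with semi-axes `a`, `b`: `u(x, y) = u_max*(1 - x^2/a^2 - y^2/b^2)`,
#' with `u_max = 2*U` for mean speed `U` (the mean of the elliptic paraboloid
#' over the section is half its peak, as for a circle).
#'
#' @param x,y Transverse coordinates (m).
#' @param a,b Semi-axes (m).
#' @param U Mean axial speed (m/s).
#' @return Velocity values (negative values clipped to zero outside the
#'   lumen).
#' @export
elliptic_poiseuille_oracle <- function(x, y, a, b, U) {
  pmax(2 * U * (1 - x^2 / a^2 - y^2 / b^2), 0)
}

#' One-dimensional generalized-Poiseuille oracle for Williamson pipe flow
#'
#' Independent reference for fully developed shear-thinning pipe flow. For an
#' axial pressure gradient `G = -dp/dz`, the shear stress is `tau(r) = G*r/2`;
#' the local shear rate solves `mu(gdot)*gdot = tau(r)` pointwise (the left
#' side is strictly increasing, solved by bisection via [stats::uniroot()]),
#' and the velocity follows by radial quadrature `u(r) = int_r^R gdot ds`.
#' When a flow rate `Q` is prescribed instead of `G`, the gradient is found
#' by an outer root-find on `Q(G) - Q`.
#'
#' @param R Tube radius (m).
#' @param props A [fluid_properties()].
#' @param G Axial pressure gradient `-dp/dz` (Pa/m), or `NULL` if `Q` given.
#' @param Q Volumetric flow rate (m^3/s), or `NULL` if `G` given.
#' @param n Number of radial quadrature points.
#' @return List with `r` (radial nodes, 0..R), `u`, `gamma_dot`, `G`, `Q`,
#'   `U` (mean speed), `u_center`.
#' @export
williamson_pipe_oracle <- function(R, props, G = NULL, Q = NULL, n = 400) {
  stopifnot(inherits(props, "fluid_properties"), xor(is.null(G), is.null(Q)))
  profile_for <- function(G) {
    r <- seq(0, R, length.out = n + 1)
    tau <- G * r / 2
    gdot <- vapply(tau, function(t) {
      if (t <= 0) return(0)
      hi <- t / props$mu_inf  # mu >= mu_inf so gdot <= tau/mu_inf
      stats::uniroot(function(g) williamson_viscosity(g, props) * g - t,
                     c(0, hi), tol = 1e-14 * max(1, hi))$root
    }, numeric(1))
    # u(r) = int_r^R gdot ds, trapezoid on the fine grid
    h <- r[2] - r[1]
    cum <- c(0, cumsum(0.5 * (gdot[-1] + gdot[-(n + 1)]) * h))
    u <- cum[n + 1] - cum
    Qv <- 2 * pi * sum(0.5 * ((u * r)[-1] + (u * r)[-(n + 1)]) * h)
    list(r = r, u = u, gamma_dot = gdot, G = G, Q = Qv)
  }
  if (is.null(G)) {
    # Newtonian bracketing bounds for the gradient
    G_lo <- 8 * props$mu_inf * Q / (pi * R^4) * 0.5
    G_hi <- 8 * props$mu0 * Q / (pi * R^4) * 2
    G <- stats::uniroot(function(g) profile_for(g)$Q - Q, c(G_lo, G_hi),
                        tol = 1e-12 * G_hi)$root
  }
  out <- profile_for(G)
  out$U <- out$Q / (pi * R^2)
  out$u_center <- out$u[1]
  out
}

#' Couette flow with viscous dissipation oracle
#'
#' Closed-form temperature for plane Couette flow (gap `H`, wall speed `U`,
#' both walls at the reference temperature) with viscous heating: in the
#' dimensionless temperature `theta = (T - Ti)/(Tb - Ti)`,
#' `theta(y) = (mu*U^2 / (2*k*(Tb - Ti))) * eta*(1 - eta)` with `eta = y/H`.
#' The mid-gap value is `mu*U^2 / (8*k*(Tb - Ti))`, i.e. Br/8 for the
#' Brinkman number built on `(Tb - Ti)`.
#'
#' @param y Cross-gap positions (m).
#' @param H Gap height (m).
#' @param U Moving-wall speed (m/s).
#' @param props A [fluid_properties()].
#' @param dT Temperature scale `Tb - Ti` (K).
#' @return theta values at `y`.
#' @export
couette_dissipation_oracle <- function(y, H, U, props, dT) {
  mu <- williamson_viscosity(U / H, props)  # gamma_dot = U/H, uniform in gap
  eta <- y / H
  (mu * U^2 / (2 * props$k * dT)) * eta * (1 - eta)
}

#' Stokes stream function of Poiseuille flow
#'
#' `psi(r) = U*(r^2 - r^4/(2*R^2))` (per-radian convention), the analytic
#' shape reference for streamline checks; the wall value `U*R^2/2` equals
#' `Q/(2*pi)`.
#'
#' @inheritParams poiseuille_oracle
#' @return psi values at `r`.
#' @export
poiseuille_stream_oracle <- function(r, R, U) {
  U * (r^2 - r^4 / (2 * R^2))
}
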