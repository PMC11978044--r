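# Verification problems with independent oracles. Each returns the measured
# errors; tolerances are judged by the caller (validate_suite, tests).

#' Hagen-Poiseuille verification
#'
#' Solves the Newtonian straight tube (axisymmetric) and measures the
#' centerline-velocity error against `2U`, the pressure-drop error against
#' `8*mu*L*U/R0^2`, and the discrete mass-conservation errors (global
#' imbalance and worst per-section deviation from the inlet flow rate).
#'
#' @param resolution `c(nr, nz)` cells.
#' @param U Inlet mean speed (m/s).
#' @param mu Viscosity (Pa s).
#' @param R0,L Tube radius and length (m).
#' @param settings Optional [solver_settings()].
#' @return List of errors and the solved case.
#' @export
verify_poiseuille <- function(resolution = c(64, 256), U = 0.02,
                              mu = 0.0035, R0 = 0.002, L = 0.02,
                              settings = NULL) {
  props <- newtonian_properties(mu = mu)
  if (is.null(settings))
    settings <- solver_settings(max_outer = 4000L)
  case <- make_case("healthy", props = props, U = U,
                    geometry = lumen_geometry(R0, L),
                    resolution = resolution, settings = settings,
                    thermal = list(enabled = FALSE))
  sol <- solve_case(case)
  prof <- extract_line(sol, "velocity-magnitude", "centerline")
  zmask <- sol$grid$z_c >= 0.5 * L & sol$grid$z_c <= 0.95 * L
  u_center <- mean(prof$value[zmask])
  oracle <- poiseuille_oracle(0, R0, U, mu, L)
  pd <- pressure_drop(sol$flow, sol$grid)
  q <- section_flow_rates(sol$flow, sol$grid)
  list(err_centerline = abs(u_center - oracle$u_center) / oracle$u_center,
       err_dp = abs(pd$dp - oracle$dp) / oracle$dp,
       err_mass_global = abs(q[length(q)] - q[1]) / abs(q[1]),
       err_mass_sections = max(abs(q - q[1])) / abs(q[1]),
       u_center = u_center, dp = pd$dp, dp_oracle = oracle$dp,
       converged = sol$history$converged, sol = sol)
}

#' Williamson pipe-flow verification against the 1D quadrature oracle
#'
#' Solves fully developed shear-thinning pipe flow with the axisymmetric
#' engine and compares the radial velocity profile (sampled away from the
#' entrance) against the independent one-dimensional oracle
#' ([williamson_pipe_oracle()]) run at the same discrete flow rate.
#' Also reports the centerline-to-mean velocity ratio, which must fall below
#' the Newtonian value of 2 for a shear-thinning fluid (profile flattening).
#'
#' @param resolution `c(nr, nz)` cells.
#' @param U Inlet mean speed (m/s).
#' @param props A [fluid_properties()] (shear-thinning defaults).
#' @param R0,L Tube radius and length (m).
#' @return List with `err_profile` (max profile deviation relative to the
#'   oracle peak), `ratio_center_mean`, profiles, and the solved case.
#' @export
verify_williamson <- function(resolution = c(48, 144), U = 0.01,
                              props = fluid_properties(),
                              R0 = 0.002, L = 0.02) {
  settings <- solver_settings(max_outer = 6000L)
  case <- make_case("healthy", props = props, U = U,
                    geometry = lumen_geometry(R0, L),
                    resolution = resolution, settings = settings,
                    thermal = list(enabled = FALSE))
  sol <- solve_case(case)
  grid <- sol$grid
  js <- which(grid$z_c >= 0.8 * L & grid$z_c <= 0.9 * L)
  u_sim <- rowMeans(0.5 * (sol$flow$uz[, js, drop = FALSE] +
                             sol$flow$uz[, js + 1, drop = FALSE]))
  Q <- mean(section_flow_rates(sol$flow, grid))
  orc <- williamson_pipe_oracle(R0, props, Q = Q)
  u_orc <- stats::approx(orc$r, orc$u, xout = grid$r_c)$y
  err <- max(abs(u_sim - u_orc)) / max(orc$u)
  ratio <- .to_axis(as.matrix(u_sim))[1] / (Q / (pi * R0^2))
  list(err_profile = err, ratio_center_mean = ratio,
       r = grid$r_c, u_sim = u_sim, u_oracle = u_orc,
       converged = sol$history$converged, sol = sol)
}

#' Couette-with-dissipation verification
#'
#' Prescribes plane Couette flow (linear shear, moving lid) on a planar
#' channel grid, solves the temperature equation with viscous dissipation and
#' both walls at the reference temperature, and compares the cross-gap
#' profile far downstream with the closed form `theta = (Br/2) eta (1-eta)`.
#'
#' @param resolution `c(ny, nx)` cells (gap by length).
#' @param H Gap height (m).
#' @param U_lid Moving-wall speed (m/s).
#' @param Br Brinkman number used to set the temperature scale.
#' @param props A [fluid_properties()] (Newtonian default).
#' @return List with `err_mid` (relative mid-gap error), the profiles, and
#'   the temperature field.
#' @export
verify_couette <- function(resolution = c(32, 64), H = 0.001,
                           U_lid = 5e-4, Br = 1,
                           props = newtonian_properties()) {
  L <- 6 * H
  geom <- lumen_geometry(H, L)
  grid <- build_grid(geom, resolution, mode = "planar")
  mu <- williamson_viscosity(U_lid / H, props)
  dT <- mu * U_lid^2 / (props$k * Br)
  groups <- dimensionless_groups(props, u0 = U_lid, L = H,
                                 Ti = 310, Tb = 310 + dT)
  flow <- structure(list(
    uz = matrix(U_lid * grid$r_c / H, grid$nr, grid$nz + 1),
    ur = matrix(0, grid$nr + 1, grid$nz),
    p = matrix(0, grid$nr, grid$nz),
    mu = matrix(mu, grid$nr, grid$nz),
    mode = "planar",
    wall_uz = list(top = U_lid, bottom = 0)), class = "flow_field")
  temp <- solve_energy(flow, grid, props, groups,
                       bc = list(theta_wall = 0, theta_in = 0,
                                 dissipation = TRUE))
  j <- which.min(abs(grid$z_c - 5 * H))
  th_sim <- temp$theta[, j]
  eta <- grid$r_c / H
  th_exact <- couette_dissipation_oracle(grid$r_c, H, U_lid, props, dT)
  mid <- order(abs(eta - 0.5))[1:2]
  th_mid <- mean(th_sim[mid])
  err_mid <- abs(th_mid - mean(th_exact[mid])) / (Br / 8)
  list(err_mid = err_mid, theta_mid = th_mid,
       theta_mid_exact = mean(th_exact[mid]), eta = eta,
       theta_sim = th_sim, theta_exact = th_exact, temperature = temp,
       Br = Br)
}

#' Elliptic-duct Poiseuille verification (3D masked-cell engine)
#'
#' Solves the Newtonian straight elliptic duct (axis ratio `kappa`) with the
#' Cartesian engine and measures the L-infinity deviation of the axial
#' velocity from the analytic solution `2U(1 - x^2/a^2 - y^2/b^2)`,
#' normalized by the peak `2U`.
#'
#' @param resolution `c(nx, ny, nz)` cells.
#' @param kappa Ellipse axis ratio.
#' @param U Inlet mean speed (m/s).
#' @param mu Viscosity (Pa s).
#' @param R0,L Equivalent radius and duct length (m).
#' @param max_outer Outer-iteration budget.
#' @return List with `err_linf` and the solved case.
#' @export
verify_elliptic <- function(resolution = c(48, 48, 96), kappa = 0.5,
                            U = 0.02, mu = 0.0035, R0 = 0.002, L = 0.02,
                            max_outer = 400L) {
  props <- newtonian_properties(mu = mu)
  geom <- lumen_geometry(R0, L, ellipse_ratio = kappa)
  settings <- solver_settings(tol_mom = 1e-5, tol_cont = 1e-6,
                              max_outer = max_outer, sweeps = 4L,
                              cg_tol = 0.05)
  case <- make_case("healthy", props = props, U = U, geometry = geom,
                    mode = "cart3d", resolution = resolution,
                    settings = settings, thermal = list(enabled = FALSE))
  sol <- solve_steady(case)
  grid <- sol$grid
  ks <- which(grid$z_c >= 0.6 * L & grid$z_c <= 0.9 * L)
  ab <- ellipse_section(0, geom)
  exact2d <- 2 * U * pmax(1 - outer(grid$x_c^2 / ab$a^2,
                                    grid$y_c^2 / ab$b^2, `+`), 0)
  errs <- vapply(ks, function(k) {
    wc <- 0.5 * (sol$flow$w[, , k] + sol$flow$w[, , k + 1])
    fl <- grid$fluid[, , k]
    max(abs(wc[fl] - exact2d[fl]))
  }, numeric(1))
  list(err_linf = mean(errs) / (2 * U),
       converged = sol$history$converged, sol = sol)
}

#' Conservation and throat kinematics of a canonical case
#'
#' Solves one of the four canonical severities and reports the discrete
#' conservation errors (global and worst-section), the total pressure drop,
#' the peak velocity magnitude, and the continuity-forced throat speed-up
#' (throat mean velocity versus inlet mean times the discrete area ratio).
#'
#' @param name Canonical case name.
#' @param resolution `c(nr, nz)`.
#' @param ... Further [make_case()] overrides.
#' @return List of scalars plus the solution.
#' @export
verify_conservation <- function(name, resolution = c(32, 96), ...) {
  case <- make_case(name, resolution = resolution,
                    settings = solver_settings(max_outer = 8000L),
                    thermal = list(enabled = FALSE), ...)
  sol <- solve_case(case)
  grid <- sol$grid
  q <- section_flow_rates(sol$flow, grid)
  A <- section_areas(grid)
  k_throat <- which.min(A)
  u_throat <- q[k_throat] / A[k_throat]
  u_in <- q[1] / A[1]
  pd <- pressure_drop(sol$flow, grid)
  spd <- derived_fields(sol$flow, grid, case$props)$speed
  list(err_mass_global = abs(q[length(q)] - q[1]) / abs(q[1]),
       err_mass_sections = max(abs(q - q[1])) / abs(q[1]),
       dp = pd$dp, p_pre = pd$p_pre, p_post = pd$p_post,
       peak_velocity = max(spd, na.rm = TRUE),
       throat_speedup = u_throat / u_in,
       area_ratio = A[1] / A[k_throat],
       converged = sol$history$converged, sol = sol)
}

#' Grid-independence trend on the Poiseuille oracle case
#'
#' Runs the straight-tube case at successive refinement halves and reports
#' the centerline-velocity error against the analytic value per resolution
#' (which must fall monotonically) and the relative change between the two
#' finest grids.
#'
#' @param base Coarsest radial resolution (axial = 3x radial).
#' @param levels Number of refinement levels (default 3).
#' @param U,mu,R0,L Case parameters as in [verify_poiseuille()].
#' @return List with `table` (per-resolution QoI and errors),
#'   `final_change`, `errors`.
#' @export
verify_grid_trend <- function(base = 16, levels = 3, U = 0.02, mu = 0.0035,
                              R0 = 0.002, L = 0.02) {
  props <- newtonian_properties(mu = mu)
  resolutions <- lapply(seq_len(levels) - 1, function(l)
    c(base * 2^l, 3 * base * 2^l))
  case <- make_case("healthy", props = props, U = U,
                    geometry = lumen_geometry(R0, L),
                    settings = solver_settings(max_outer = 4000L),
                    thermal = list(enabled = FALSE))
  tab <- grid_independence(case, resolutions, qoi = qoi_peak_velocity)
  errors <- abs(tab$qoi - 2 * U) / (2 * U)
  list(table = tab, errors = errors,
       final_change = tab$rel_change[nrow(tab)])
}
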