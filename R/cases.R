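# Study orchestration: canonical cases, dimensionless groups, sweeps and the
# automated verification battery.

#' Dimensionless groups of the flow problem
#'
#' From dimensional properties and scales: `Re = rho*u0*L/mu0` (Reynolds),
#' `Pr = cp*mu0/k` (Prandtl), `Br = mu0*u0^2/(k*(Tb - Ti))` (Brinkman-type
#' dissipation group) and `beta = k/(rho*cp)` (thermal diffusivity, m^2/s).
#' The identity `Re*Pr = u0*L/beta` holds by construction.
#'
#' @param props A [fluid_properties()].
#' @param u0 Reference (inlet mean) speed (m/s), > 0.
#' @param L Reference length (m), > 0.
#' @param Ti Inlet reference temperature (K).
#' @param Tb Wall/bulk reference temperature (K), `Tb != Ti`.
#' @return An object of class `dimensionless_groups` with fields `Re`, `Pr`,
#'   `Br`, `beta`, `dT` and the `scales` used.
#' @export
dimensionless_groups <- function(props, u0, L, Ti = 310, Tb = 313) {
  stopifnot(inherits(props, "fluid_properties"), u0 > 0, L > 0)
  if (Tb == Ti)
    stop("degenerate temperature scale: Tb must differ from Ti",
         call. = FALSE)
  dT <- Tb - Ti
  structure(list(
    Re = props$density * u0 * L / props$mu0,
    Pr = props$cp * props$mu0 / props$k,
    Br = props$mu0 * u0^2 / (props$k * dT),
    beta = props$k / (props$density * props$cp),
    dT = dT,
    scales = list(u0 = u0, L = L, Ti = Ti, Tb = Tb)),
    class = "dimensionless_groups")
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat(sprintf("Re = %.4g  Pr = %.4g  Br = %.4g  beta = %.4g m^2/s\n",
              x$Re, x$Pr, x$Br, x$beta))
  invisible(x)
}

#' Groups of a case configuration
#'
#' @param case A [make_case()] configuration.
#' @return The [dimensionless_groups()] implied by its properties and scales.
#' @export
case_groups <- function(case) {
  dimensionless_groups(case$props, u0 = case$U,
                       L = case$geometry$segment_length,
                       Ti = case$thermal$Ti, Tb = case$thermal$Tb)
}

#' Canonical study cases
#'
#' The four stenosis severities of the study: a healthy artery and 40/60/80%
#' reductions of the lumen diameter at mid-segment. All other parameters are
#' documented fixtures (blood-like fluid, 2 mm base radius, 20 mm segment,
#' stenosis length L/5), overridable through `...`.
#'
#' @param name One of `"healthy"`, `"s40"`, `"s60"`, `"s80"`.
#' @param ... Overrides: any of `geometry`, `props`, `U`, `resolution`,
#'   `mode`, `clustering`, `settings`, `thermal`, `ellipse_ratio`,
#'   `degree`.
#' @return An object of class `case_config`.
#' @export
make_case <- function(name = c("healthy", "s40", "s60", "s80"), ...) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown case '", name[1],
         "'; valid cases: healthy, s40, s60, s80", call. = FALSE))
  degree <- c(healthy = 0, s40 = 0.4, s60 = 0.6, s80 = 0.8)[[name]]
  ov <- list(...)
  if (!is.null(ov$degree)) degree <- ov$degree
  R0 <- 0.002; L <- 0.02
  kappa <- if (!is.null(ov$ellipse_ratio)) ov$ellipse_ratio else 1
  geometry <- if (!is.null(ov$geometry)) ov$geometry else
    lumen_geometry(R0, L, ellipse_ratio = kappa,
                   stenosis = if (degree > 0)
                     stenosis_spec(degree, L / 5, L / 2) else NULL)
  props <- if (!is.null(ov$props)) ov$props else fluid_properties()
  thermal <- utils::modifyList(
    list(enabled = TRUE, Ti = 310, Tb = 313, theta_wall = 1, theta_in = 0,
         dissipation = TRUE),
    if (is.null(ov$thermal)) list() else ov$thermal)
  cfg <- list(
    name = name,
    geometry = geometry,
    props = props,
    U = if (!is.null(ov$U)) ov$U else 0.02,
    mode = if (!is.null(ov$mode)) ov$mode else "axisym",
    resolution = if (!is.null(ov$resolution)) ov$resolution else c(32, 96),
    clustering = if (!is.null(ov$clustering)) ov$clustering else 1,
    settings = if (!is.null(ov$settings)) ov$settings else solver_settings(),
    thermal = thermal)
  structure(cfg, class = "case_config")
}

#' @export
print.case_config <- function(x, ...) {
  st <- x$geometry$stenosis
  cat(sprintf("case '%s': %s, degree %.0f%%, U = %g m/s, mode %s, res %s\n",
              x$name,
              if (is.null(st)) "healthy" else "stenosed",
              100 * (if (is.null(st)) 0 else st$degree),
              x$U, x$mode, paste(x$resolution, collapse = "x")))
  invisible(x)
}

#' Run a case end-to-end and write its outputs
#'
#' Solves the flow and temperature, then writes the full output manifest to
#' `outdir`: a VTK field file, one CSV line profile per plotted quantity
#' (velocity magnitude, radial velocity, static pressure, dynamic pressure,
#' pressure coefficient, cell Reynolds number, temperature), a convergence
#' log, a machine-readable summary (pressure drop, peak velocity,
#' iterations) and an echo of the resolved configuration. The pipeline is
#' deterministic: identical reruns produce identical outputs.
#'
#' @param case A [make_case()] configuration.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` (file paths), `summary`,
#'   `converged`; the summary's `status` is nonzero when unconverged.
#' @export
run_case <- function(case, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sol <- solve_case(case)
  conv <- sol$history$converged
  quantities <- c("velocity-magnitude", "radial-velocity", "static-pressure",
                  "dynamic-pressure", "pressure-coefficient", "cell-reynolds",
                  "temperature")
  manifest <- character(0)
  fields <- file.path(outdir, paste0(case$name, "_fields.vtk"))
  write_vtk(sol, fields)
  manifest <- c(manifest, fields)
  for (q in quantities) {
    if (q == "temperature" && is.null(sol$temperature)) next
    prof <- extract_line(sol, quantity = q, axis = "centerline")
    f <- file.path(outdir, paste0(case$name, "_", gsub("-", "_", q), ".csv"))
    utils::write.csv(prof, f, row.names = FALSE)
    manifest <- c(manifest, f)
  }
  logf <- file.path(outdir, paste0(case$name, "_convergence.csv"))
  utils::write.csv(sol$history$residuals, logf, row.names = FALSE)
  manifest <- c(manifest, logf)
  pd <- pressure_drop(sol$flow, sol$grid)
  q <- section_flow_rates(sol$flow, sol$grid)
  summary <- data.frame(
    case = case$name,
    converged = conv,
    status = as.integer(!conv),
    iterations = sol$history$iterations,
    dp = pd$dp, p_pre = pd$p_pre, p_post = pd$p_post,
    peak_velocity = max(derived_fields(sol$flow, sol$grid,
                                       case$props)$speed, na.rm = TRUE),
    flow_rate = q[1])
  sf <- file.path(outdir, paste0(case$name, "_summary.csv"))
  utils::write.csv(summary, sf, row.names = FALSE)
  cf <- file.path(outdir, paste0(case$name, "_config.yml"))
  write_case_config(case, cf)
  manifest <- c(manifest, sf, cf)
  if (!conv)
    warning("case '", case$name, "' did not converge in ",
            sol$history$iterations, " iterations", call. = FALSE)
  invisible(list(manifest = manifest, summary = summary, converged = conv,
                 solution = sol))
}

#' Parameter sweep over full case runs
#'
#' Re-solves a base case across a list of values for one parameter and
#' collects aligned radial profiles for overlay plots. Supported parameter
#' paths: `"Pr"` (Prandtl number, swept by rescaling the thermal
#' conductivity at fixed flow), `"Br"` (Brinkman group, swept through the
#' temperature scale), `"degree"` (stenosis severity), `"Re"` (inlet speed),
#' or any `$`-path into the configuration (e.g. `"props$mu0"`).
#'
#' @param base A [make_case()] configuration.
#' @param parameter Parameter path (see above).
#' @param values Numeric values to sweep (non-empty).
#' @param axis_at Axial station for the radial profiles (default throat).
#' @return List with `parameter`, `values`, `profiles` (list of
#'   [extract_line()] frames on identical coordinates), and `summary`
#'   (per-value pressure drop, peak velocity, peak temperature,
#'   wall-adjacent temperature gradient).
#' @export
run_sweep <- function(base, parameter, values, axis_at = NULL) {
  if (length(values) == 0) stop("values must be non-empty", call. = FALSE)
  profiles <- vector("list", length(values))
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    v <- values[[i]]
    cfg <- .apply_sweep_value(base, parameter, v)
    sol <- solve_case(cfg)
    qty <- if (parameter %in% c("Pr", "Br")) "temperature"
           else "velocity-magnitude"
    profiles[[i]] <- extract_line(sol, quantity = qty, axis = "radial",
                                  at = axis_at)
    pd <- pressure_drop(sol$flow, sol$grid)
    gw <- .wall_theta_gradient(sol)
    rows[[i]] <- data.frame(
      value = v,
      dp = pd$dp,
      peak_velocity = max(derived_fields(sol$flow, sol$grid,
                                         cfg$props)$speed, na.rm = TRUE),
      peak_theta = if (!is.null(sol$temperature))
        max(sol$temperature$theta, na.rm = TRUE) else NA_real_,
      wall_theta_gradient = gw,
      converged = sol$history$converged)
  }
  list(parameter = parameter, values = values, profiles = profiles,
       summary = do.call(rbind, rows))
}

.apply_sweep_value <- function(base, parameter, v) {
  cfg <- base
  if (parameter == "Pr") {
    # Pr = cp*mu0/k: sweep k at fixed flow (viscosity untouched)
    p <- cfg$props
    cfg$props <- fluid_properties(density = p$density, mu0 = p$mu0,
                                  mu_inf = p$mu_inf, lambda = p$lambda,
                                  k = p$cp * p$mu0 / v, cp = p$cp,
                                  alpha = p$alpha, eta0 = p$eta0,
                                  Gamma = p$Gamma)
  } else if (parameter == "Br") {
    # Br = mu0*u0^2/(k*dT): sweep the temperature scale dT
    p <- cfg$props
    dT <- p$mu0 * cfg$U^2 / (p$k * v)
    cfg$thermal$Tb <- cfg$thermal$Ti + dT
  } else if (parameter == "degree") {
    L <- cfg$geometry$segment_length
    cfg$geometry <- lumen_geometry(
      cfg$geometry$base_radius, L,
      ellipse_ratio = cfg$geometry$ellipse_ratio,
      stenosis = if (v > 0) stenosis_spec(v, L / 5, L / 2) else NULL)
  } else if (parameter == "Re") {
    gr <- case_groups(cfg)
    cfg$U <- cfg$U * v / gr$Re
  } else {
    path <- strsplit(parameter, "$", fixed = TRUE)[[1]]
    node <- cfg
    for (p in path[-length(path)]) {
      if (is.null(node[[p]]))
        stop("unresolvable parameter path '", parameter, "'", call. = FALSE)
      node <- node[[p]]
    }
    if (is.null(node[[path[length(path)]]]))
      stop("unresolvable parameter path '", parameter, "'", call. = FALSE)
    expr <- paste0("cfg$", gsub("$", "$", parameter, fixed = TRUE),
                   " <- v")
    eval(parse(text = expr))
  }
  cfg
}

# magnitude of the wall-adjacent radial temperature gradient, averaged over
# the mid-third of the segment (one-sided difference against the wall value)
.wall_theta_gradient <- function(sol) {
  if (is.null(sol$temperature)) return(NA_real_)
  grid <- sol$grid
  th <- sol$temperature$theta
  thw <- sol$temperature$bc$theta_wall
  nz <- grid$nz
  jmid <- which(grid$z_c > grid$geom$segment_length / 3 &
                  grid$z_c < 2 * grid$geom$segment_length / 3)
  g <- vapply(jmid, function(j) {
    iw <- max(which(grid$fluid[, j]))
    abs(thw - th[iw, j]) / (grid$dr / 2)
  }, numeric(1))
  mean(g)
}

#' Automated verification battery
#'
#' Runs the oracle checks that validate the discretization: Hagen-Poiseuille
#' centerline velocity and pressure drop, global and per-section mass
#' conservation, the one-dimensional generalized-Poiseuille quadrature
#' oracle for Williamson flow, Couette flow with viscous dissipation, the
#' elliptic-duct Poiseuille solution (full tier), and the grid-independence
#' trend. Each check reports its measured error against its tolerance;
#' failures are report rows, not exceptions.
#'
#' @param tier `"quick"` (coarser grids, no 3D) or `"full"`.
#' @param tolerances Named tolerance overrides (forcing a tolerance to zero
#'   fails the check by construction).
#' @return data.frame with `check`, `error`, `tolerance`, `pass`.
#' @export
validate_suite <- function(tier = c("quick", "full"), tolerances = list()) {
  tier <- match.arg(tier)
  tol <- utils::modifyList(list(
    poiseuille_centerline = 0.01, poiseuille_dp = 0.01,
    mass_global = 1e-8, mass_sections = 1e-6,
    williamson_profile = 0.02, couette = 0.01,
    elliptic_linf = 0.05, grid_trend = 0.01), tolerances)
  rows <- list()
  add <- function(check, error, tolerance)
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, error = error, tolerance = tolerance,
      # a degenerate (zero) tolerance fails by construction, even for checks
      # whose measured error is exactly zero
      pass = is.finite(error) && tolerance > 0 && error <= tolerance)
  res2d <- if (tier == "quick") c(24, 72) else c(64, 256)
  v <- verify_poiseuille(resolution = res2d)
  add("poiseuille_centerline", v$err_centerline, tol$poiseuille_centerline)
  add("poiseuille_dp", v$err_dp, tol$poiseuille_dp)
  add("mass_global", v$err_mass_global, tol$mass_global)
  add("mass_sections", v$err_mass_sections, tol$mass_sections)
  vw <- verify_williamson(resolution = if (tier == "quick") c(24, 72)
                          else c(48, 144))
  add("williamson_profile", vw$err_profile, tol$williamson_profile)
  vc <- verify_couette(resolution = if (tier == "quick") c(24, 48)
                       else c(32, 64))
  add("couette", vc$err_mid, tol$couette)
  gs <- verify_grid_trend(base = if (tier == "quick") 8 else 16)
  add("grid_trend", gs$final_change, tol$grid_trend)
  if (tier == "full") {
    ve <- verify_elliptic(resolution = c(48, 48, 96))
    add("elliptic_linf", ve$err_linf, tol$elliptic_linf)
  }
  do.call(rbind, rows)
}
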