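# Declarative case configuration: flat YAML with sections for geometry,
# fluid, thermal, solver and discretization. Round-trips a case_config.

#' Write a case configuration to YAML
#'
#' @param case A [make_case()] configuration.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_case_config <- function(case, path) {
  st <- case$geometry$stenosis
  cfg <- list(
    name = case$name,
    geometry = list(
      base_radius = case$geometry$base_radius,
      segment_length = case$geometry$segment_length,
      ellipse_ratio = case$geometry$ellipse_ratio,
      stenosis = if (is.null(st)) NULL else
        list(degree = st$degree, length = st$length, center = st$center,
             shape = st$shape)),
    fluid = list(
      density = case$props$density, mu0 = case$props$mu0,
      mu_inf = case$props$mu_inf, lambda = case$props$lambda,
      k = case$props$k, cp = case$props$cp, alpha = case$props$alpha,
      eta0 = case$props$eta0, Gamma = case$props$Gamma),
    flow = list(inlet_velocity = case$U),
    thermal = case$thermal,
    grid = list(mode = case$mode, resolution = as.integer(case$resolution),
                clustering = case$clustering),
    solver = unclass(case$settings))
  writeLines(yaml::as.yaml(cfg, precision = 15L), path)
  invisible(path)
}

#' Read a case configuration from YAML
#'
#' @param path A file written by [write_case_config()] (or hand-edited in
#'   the same layout).
#' @return A `case_config`.
#' @export
read_case_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  st <- cfg$geometry$stenosis
  geom <- lumen_geometry(cfg$geometry$base_radius,
                         cfg$geometry$segment_length,
                         ellipse_ratio = cfg$geometry$ellipse_ratio,
                         stenosis = if (is.null(st)) NULL else
                           stenosis_spec(st$degree, st$length, st$center,
                                         st$shape))
  props <- fluid_properties(density = cfg$fluid$density, mu0 = cfg$fluid$mu0,
                            mu_inf = cfg$fluid$mu_inf,
                            lambda = cfg$fluid$lambda, k = cfg$fluid$k,
                            cp = cfg$fluid$cp, alpha = cfg$fluid$alpha,
                            eta0 = cfg$fluid$eta0, Gamma = cfg$fluid$Gamma)
  sv <- cfg$solver
  settings <- solver_settings(
    alpha_u = sv$alpha_u, alpha_p = sv$alpha_p, tol_mom = sv$tol_mom,
    tol_cont = sv$tol_cont, max_outer = sv$max_outer, scheme = sv$scheme,
    stress_form = sv$stress_form, sweeps = sv$sweeps,
    dt_pseudo = if (is.character(sv$dt_pseudo) || is.null(sv$dt_pseudo))
      Inf else sv$dt_pseudo,
    cg_tol = sv$cg_tol, verbose = isTRUE(sv$verbose))
  name <- cfg$name
  known <- name %in% c("healthy", "s40", "s60", "s80")
  cfg_case <- make_case(if (known) name else "healthy",
                        geometry = geom, props = props,
                        U = cfg$flow$inlet_velocity,
                        mode = cfg$grid$mode,
                        resolution = cfg$grid$resolution,
                        clustering = cfg$grid$clustering,
                        settings = settings,
                        thermal = cfg$thermal)
  cfg_case$name <- name
  cfg_case
}
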