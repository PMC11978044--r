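#' Solver controls for the SIMPLE pressure-velocity coupling
#'
#' @param alpha_u Momentum under-relaxation factor in (0, 1].
#' @param alpha_p Pressure under-relaxation factor in (0, 1].
#' @param tol_mom Scaled momentum-residual tolerance (> 0).
#' @param tol_cont Scaled continuity-residual tolerance (> 0); the L1 mass
#'   imbalance over all cells divided by the inlet mass flux.
#' @param max_outer Maximum outer iterations.
#' @param scheme Advection scheme: `"upwind"` (default, robust at the low
#'   Reynolds numbers of interest) or `"central"`.
#' @param stress_form `"full"` adds the transpose/extra viscous-stress terms
#'   of the variable-viscosity stress divergence as an explicit deferred
#'   correction; `"gradient"` keeps only the implicit
#'   `div(mu grad u)` form. The two coincide for constant viscosity.
#' @param alpha_s Under-relaxation of the deferred stress source in (0, 1].
#' @param alpha_mu Under-relaxation of the apparent-viscosity update in
#'   (0, 1].
#' @param pv_coupling `"simplec"` (consistent correction coefficients,
#'   tolerates `alpha_p` near 1) or `"simple"`.
#' @param momentum_solver `"direct"` (sparse LU per outer iteration; 2D
#'   engine) or `"gs"` (red-black Gauss-Seidel sweeps; always used in 3D).
#' @param sweeps Gauss-Seidel sweeps per momentum solve per outer iteration.
#' @param dt_pseudo Pseudo-transient time step (s); `Inf` disables
#'   pseudo-transient continuation.
#' @param cg_tol Relative tolerance of the pressure-correction CG solve
#'   (3D engine only; the 2D engine factorizes directly).
#' @param verbose Print residuals every `verbose_every` outer iterations.
#' @param verbose_every See `verbose`.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(alpha_u = 0.9, alpha_p = 1,
                            tol_mom = 1e-6, tol_cont = 1e-9,
                            max_outer = 3000L,
                            scheme = c("upwind", "central"),
                            stress_form = c("full", "gradient"),
                            alpha_s = 0.3, alpha_mu = 0.15,
                            pv_coupling = c("simplec", "simple"),
                            momentum_solver = c("direct", "gs"),
                            sweeps = 6L, dt_pseudo = Inf,
                            cg_tol = 0.05,
                            verbose = FALSE, verbose_every = 100L) {
  stopifnot(alpha_u > 0, alpha_u <= 1, alpha_p > 0, alpha_p <= 1,
            tol_mom > 0, tol_cont > 0, max_outer >= 1, sweeps >= 1)
  structure(list(alpha_u = alpha_u, alpha_p = alpha_p,
                 tol_mom = tol_mom, tol_cont = tol_cont,
                 max_outer = as.integer(max_outer),
                 scheme = match.arg(scheme),
                 stress_form = match.arg(stress_form), alpha_s = alpha_s,
                 alpha_mu = alpha_mu,
                 pv_coupling = match.arg(pv_coupling),
                 momentum_solver = match.arg(momentum_solver),
                 sweeps = as.integer(sweeps), dt_pseudo = dt_pseudo,
                 cg_tol = cg_tol,
                 verbose = verbose, verbose_every = as.integer(verbose_every)),
            class = "solver_settings")
}

#' Solve the steady flow problem of a case
#'
#' Iterates the SIMPLE outer loop ([simple_iterate()] steps with cached
#' pressure-operator factorization) from a zero-velocity, uniform-pressure
#' start until the scaled momentum and continuity residuals fall below the
#' tolerances in the case's [solver_settings()], or the iteration budget is
#' exhausted. The run is fully deterministic. On non-convergence the history
#' is returned with `converged = FALSE`; callers must branch.
#'
#' @param case A case configuration ([make_case()]).
#' @param grid Optional pre-built grid (else built from the case).
#' @return List with `flow` (a `flow_field`), `grid`, and `history`
#'   (data.frame of per-iteration residual norms plus `converged`,
#'   `iterations`).
#' @export
solve_steady <- function(case, grid = NULL) {
  if (is.null(grid)) grid <- build_grid(case$geometry, case$resolution,
                                        case$mode, case$clustering)
  st <- case$settings
  state <- if (grid$mode == "cart3d") .state3d(case, grid) else
    .state2d(case, grid)
  hist <- matrix(NA_real_, st$max_outer, 3,
                 dimnames = list(NULL, c("mom_uz", "mom_ur", "continuity")))
  iter_fun <- if (grid$mode == "cart3d") .iter3d else .iter2d
  converged <- FALSE
  it <- 0L
  while (it < st$max_outer) {
    it <- it + 1L
    iter_fun(state)
    r <- state$residuals
    hist[it, ] <- c(r[["mom_uz"]], r[["mom_ur"]], r[["continuity"]])
    if (st$verbose && (it %% st$verbose_every == 0L || it == 1L))
      message(sprintf("outer %5d  mom %.3e %.3e  cont %.3e",
                      it, r[["mom_uz"]], r[["mom_ur"]], r[["continuity"]]))
    if (max(r[["mom_uz"]], r[["mom_ur"]]) <= st$tol_mom &&
        r[["continuity"]] <= st$tol_cont) {
      converged <- TRUE
      break
    }
    if (!all(is.finite(r))) break
  }
  history <- as.data.frame(hist[seq_len(it), , drop = FALSE])
  list(flow = state$field, grid = grid,
       history = list(residuals = history, converged = converged,
                      iterations = it))
}

#' Solve a full case: flow, then temperature
#'
#' Runs [solve_steady()] and, if the case has thermal boundary data,
#' [solve_energy()] on the converged flow (one-way coupling).
#'
#' @param case A case configuration from [make_case()].
#' @return List with `flow`, `grid`, `history`, `temperature` (or `NULL`),
#'   and the resolved `case`.
#' @export
solve_case <- function(case) {
  sol <- solve_steady(case)
  temp <- NULL
  if (isTRUE(case$thermal$enabled)) {
    temp <- solve_energy(sol$flow, sol$grid, case$props,
                         groups = case_groups(case),
                         bc = list(theta_wall = case$thermal$theta_wall,
                                   theta_in = case$thermal$theta_in,
                                   dissipation = case$thermal$dissipation))
  }
  list(flow = sol$flow, grid = sol$grid, history = sol$history,
       temperature = temp, case = case)
}
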