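# Derived quantities and profile extraction: everything the study plots.

#' Cell-centred derived fields
#'
#' Computes, per cell: velocity magnitude, static pressure, dynamic pressure
#' `0.5*rho*|u|^2`, pressure coefficient
#' `Cp = (p - p_ref)/(0.5*rho*U_ref^2)` and cell Reynolds number
#' `rho*|u|*Delta/mu` with `Delta` the geometric mean of the local cell
#' spacings and `mu` the local apparent viscosity. By default `p_ref` is the
#' outlet-section mean pressure (so Cp vanishes there by construction) and
#' `U_ref` the inlet mean speed - the only two scales the problem defines.
#'
#' @param flow A `flow_field`.
#' @param grid The matching grid.
#' @param props A [fluid_properties()].
#' @param U_ref Reference speed (m/s); default inlet mean.
#' @param p_ref Reference pressure (Pa); default outlet mean.
#' @return List of matrices/arrays: `speed`, `p_static`, `p_dynamic`, `cp`,
#'   `cell_re` (solid cells `NA`), plus the references used.
#' @export
derived_fields <- function(flow, grid, props, U_ref = NULL, p_ref = NULL) {
  rho <- props$density
  if (grid$mode == "cart3d") {
    nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
    uc <- 0.5 * (flow$u[2:(nx + 1), , , drop = FALSE] +
                   flow$u[1:nx, , , drop = FALSE])
    vc <- 0.5 * (flow$v[, 2:(ny + 1), , drop = FALSE] +
                   flow$v[, 1:ny, , drop = FALSE])
    wc <- 0.5 * (flow$w[, , 2:(nz + 1), drop = FALSE] +
                   flow$w[, , 1:nz, drop = FALSE])
    speed <- sqrt(uc^2 + vc^2 + wc^2)
    DZ <- array(rep(grid$dz, each = nx * ny), c(nx, ny, nz))
    Delta <- (grid$dx * grid$dy * DZ)^(1 / 3)
    fl <- grid$fluid
    if (is.null(U_ref)) {
      w_in <- flow$w[, , 1]
      U_ref <- sum(w_in) / max(sum(fl[, , 1]), 1)
    }
    if (is.null(p_ref)) p_ref <- mean(flow$p[, , nz][fl[, , nz]])
  } else {
    nr <- grid$nr; nz <- grid$nz
    uzc <- 0.5 * (flow$uz[, 1:nz, drop = FALSE] +
                    flow$uz[, 2:(nz + 1), drop = FALSE])
    urc <- 0.5 * (flow$ur[1:nr, , drop = FALSE] +
                    flow$ur[2:(nr + 1), , drop = FALSE])
    speed <- sqrt(uzc^2 + urc^2)
    Delta <- sqrt(grid$dr * .rowmat(grid$dz, nr))
    fl <- grid$fluid
    if (is.null(U_ref)) {
      A <- grid$w_c * grid$dr
      U_ref <- sum(A * flow$uz[, 1]) / sum(A[fl[, 1]])
    }
    if (is.null(p_ref)) {
      A <- grid$w_c * grid$dr
      p_ref <- sum((A * flow$p[, nz])[fl[, nz]]) / sum(A[fl[, nz]])
    }
  }
  if (U_ref <= 0) stop("U_ref must be > 0", call. = FALSE)
  p_dyn <- 0.5 * rho * speed^2
  cp <- (flow$p - p_ref) / (0.5 * rho * U_ref^2)
  cell_re <- rho * speed * Delta / flow$mu
  mask_na <- function(A) { A[!fl] <- NA_real_; A }
  list(speed = mask_na(speed), p_static = mask_na(flow$p + 0),
       p_dynamic = mask_na(p_dyn), cp = mask_na(cp),
       cell_re = mask_na(cell_re), U_ref = U_ref, p_ref = p_ref)
}

#' Stokes stream function (axisymmetric)
#'
#' `psi(r, z) = int_0^r u_z(r', z) r' dr'` (density-free convention) on the
#' grid nodes. `psi = 0` on the axis; the wall value equals `Q/(2*pi)` at
#' every station of a converged flow, and iso-contours of `psi` are
#' streamlines.
#'
#' @param flow A converged axisymmetric `flow_field`.
#' @param grid The matching grid.
#' @return Matrix `(nr+1) x (nz+1)` of `psi` at nodes `(r_f, z_f)`.
#' @export
stream_function <- function(flow, grid) {
  if (grid$mode != "axisym")
    stop("stream_function supports the axisymmetric mode only; ",
         "use pathlines() for 3D fields", call. = FALSE)
  nr <- grid$nr; nz <- grid$nz
  incr <- flow$uz * grid$r_c * grid$dr          # (nr, nz+1)
  psi <- rbind(0, apply(incr, 2, cumsum))
  psi
}

#' Pathlines of a 3D flow field
#'
#' Companion routine to [stream_function()] for Cartesian fields: explicit
#' integration of seed points through the cell-centred velocity field
#' (nearest-cell sampling, fixed step).
#'
#' @param flow A 3D `flow_field`.
#' @param grid The matching `cart3d` grid.
#' @param seeds Matrix with columns x, y, z of seed coordinates.
#' @param n_steps Number of integration steps.
#' @param dt Time step (s); default chosen from the axial CFL.
#' @return List of per-seed coordinate matrices.
#' @export
pathlines <- function(flow, grid, seeds, n_steps = 200, dt = NULL) {
  stopifnot(grid$mode == "cart3d", is.matrix(seeds), ncol(seeds) == 3)
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  uc <- 0.5 * (flow$u[2:(nx + 1), , , drop = FALSE] +
                 flow$u[1:nx, , , drop = FALSE])
  vc <- 0.5 * (flow$v[, 2:(ny + 1), , drop = FALSE] +
                 flow$v[, 1:ny, , drop = FALSE])
  wc <- 0.5 * (flow$w[, , 2:(nz + 1), drop = FALSE] +
                 flow$w[, , 1:nz, drop = FALSE])
  if (is.null(dt)) dt <- 0.25 * min(grid$dz) / max(abs(wc), 1e-12)
  locate <- function(p) {
    i <- findInterval(p[1], grid$x_f, all.inside = TRUE)
    j <- findInterval(p[2], grid$y_f, all.inside = TRUE)
    k <- findInterval(p[3], grid$z_f, all.inside = TRUE)
    c(i, j, k)
  }
  lapply(seq_len(nrow(seeds)), function(s) {
    p <- seeds[s, ]
    out <- matrix(NA_real_, n_steps + 1, 3)
    out[1, ] <- p
    for (n in seq_len(n_steps)) {
      ijk <- locate(p)
      if (!grid$fluid[ijk[1], ijk[2], ijk[3]]) break
      vel <- c(uc[ijk[1], ijk[2], ijk[3]], vc[ijk[1], ijk[2], ijk[3]],
               wc[ijk[1], ijk[2], ijk[3]])
      p <- p + dt * vel
      if (p[3] >= grid$z_f[nz + 1] || p[3] <= 0) break
      out[n + 1, ] <- p
    }
    out[stats::complete.cases(out), , drop = FALSE]
  })
}

# parabolic extrapolation of cell-centred radial data to the axis r = 0
# (second-order for even profiles sampled at dr/2 and 3dr/2)
.to_axis <- function(M) (9 * M[1, ] - M[2, ]) / 8

#' Extract a line profile
#'
#' Samples a scalar quantity along one of the canonical lines plotted in
#' stenosis hemodynamics: the centerline (axis), a radial line at a given
#' axial station, or the wall-adjacent cell row. Velocity-type radial
#' profiles include the no-slip wall point. Centerline values use a
#' parabolic (second-order) extrapolation from the first two radial cell
#' rows to the axis. Extraction is deterministic: repeated calls give
#' identical output.
#'
#' @param sol List with at least `flow` and `grid` (as from [solve_case()]);
#'   `temperature` is needed for the temperature quantity.
#' @param quantity One of `"velocity-magnitude"`, `"radial-velocity"`,
#'   `"static-pressure"`, `"dynamic-pressure"`, `"pressure-coefficient"`,
#'   `"cell-reynolds"`, `"temperature"`.
#' @param axis `"centerline"`, `"radial"` or `"wall"`.
#' @param at Axial station (m) for `"radial"`; defaults to the throat (or
#'   mid-segment).
#' @param props A [fluid_properties()] for the pressure-derived quantities;
#'   taken from `sol$case$props` when present.
#' @param file Optional path: when given, the profile is also written as CSV
#'   (header row: coordinate, value, quantity, units).
#' @return A data.frame of class `line_profile` with columns `coordinate`,
#'   `value`, `quantity`, `units`.
#' @export
extract_line <- function(sol, quantity = "velocity-magnitude",
                         axis = c("centerline", "radial", "wall"),
                         at = NULL, props = NULL, file = NULL) {
  axis <- match.arg(axis)
  grid <- sol$grid
  if (grid$mode == "cart3d")
    stop("extract_line supports the 2D modes; index 3D arrays directly",
         call. = FALSE)
  if (is.null(props)) props <- sol$case$props
  if (is.null(props)) props <- fluid_properties()
  quantity <- match.arg(quantity, c("velocity-magnitude", "radial-velocity",
                                    "static-pressure", "dynamic-pressure",
                                    "pressure-coefficient", "cell-reynolds",
                                    "temperature"))
  nr <- grid$nr; nz <- grid$nz
  df <- derived_fields(sol$flow, grid, props)
  M <- switch(quantity,
    "velocity-magnitude" = df$speed,
    "radial-velocity" = 0.5 * (sol$flow$ur[1:nr, , drop = FALSE] +
                                 sol$flow$ur[2:(nr + 1), , drop = FALSE]),
    "static-pressure" = df$p_static,
    "dynamic-pressure" = df$p_dynamic,
    "pressure-coefficient" = df$cp,
    "cell-reynolds" = df$cell_re,
    "temperature" = {
      if (is.null(sol$temperature))
        stop("no temperature field in this solution", call. = FALSE)
      sol$temperature$theta
    })
  units <- switch(quantity,
    "velocity-magnitude" = "m/s", "radial-velocity" = "m/s",
    "static-pressure" = "Pa", "dynamic-pressure" = "Pa",
    "pressure-coefficient" = "-", "cell-reynolds" = "-",
    "temperature" = "-")
  if (axis == "centerline") {
    val <- .to_axis(M)
    coord <- grid$z_c
    val <- val[seq_along(coord)]
    out <- data.frame(coordinate = coord, value = as.numeric(val))
  } else if (axis == "radial") {
    if (is.null(at)) {
      st <- grid$geom$stenosis
      at <- if (!is.null(st)) st$center else grid$geom$segment_length / 2
    }
    if (at < 0 || at > grid$geom$segment_length)
      stop("radial line outside the domain", call. = FALSE)
    j <- which.min(abs(grid$z_c - at))
    keep <- grid$fluid[, j]
    coord <- grid$r_c[keep]
    val <- M[keep, j]
    if (quantity %in% c("velocity-magnitude", "radial-velocity")) {
      coord <- c(coord, grid$Rc[j])
      val <- c(val, 0)
    }
    out <- data.frame(coordinate = coord, value = as.numeric(val))
  } else {
    iw <- vapply(seq_len(nz), function(j) max(which(grid$fluid[, j])),
                 integer(1))
    out <- data.frame(coordinate = grid$z_c,
                      value = M[cbind(iw, seq_len(nz))])
  }
  out$quantity <- quantity
  out$units <- units
  class(out) <- c("line_profile", "data.frame")
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Inlet-to-outlet pressure drop and pre/post-stenotic means
#'
#' Area-weighted mean pressures at the inlet and outlet planes (linear
#' extrapolation of the two adjacent cell columns onto the boundary faces,
#' second-order for a linear pressure field), their difference, and the mean
#' pressures over the pre-stenotic and post-stenotic thirds of the segment.
#'
#' @param flow A `flow_field` (2D modes).
#' @param grid The matching grid.
#' @return List with `dp`, `p_in`, `p_out`, `p_pre`, `p_post`.
#' @export
pressure_drop <- function(flow, grid) {
  if (grid$mode == "cart3d") {
    nz <- grid$nz
    fl <- grid$fluid
    colmean <- function(k) mean(flow$p[, , k][fl[, , k]])
    p1 <- colmean(1); p2 <- colmean(2)
    pn <- colmean(nz); pn1 <- colmean(nz - 1)
    p_in <- p1 + (p1 - p2) * (grid$z_c[1] - grid$z_f[1]) /
      (grid$z_c[2] - grid$z_c[1])
    p_out <- pn + (pn - pn1) * (grid$z_f[nz + 1] - grid$z_c[nz]) /
      (grid$z_c[nz] - grid$z_c[nz - 1])
    L <- grid$geom$segment_length
    pre <- grid$z_c < L / 3; post <- grid$z_c > 2 * L / 3
    p_pre <- mean(flow$p[, , pre][fl[, , pre]])
    p_post <- mean(flow$p[, , post][fl[, , post]])
    return(list(dp = p_in - p_out, p_in = p_in, p_out = p_out,
                p_pre = p_pre, p_post = p_post))
  }
  nz <- grid$nz
  A <- grid$w_c * grid$dr
  fl <- grid$fluid
  colmean <- function(j) sum((A * flow$p[, j])[fl[, j]]) / sum(A[fl[, j]])
  p1 <- colmean(1); p2 <- colmean(2)
  pn <- colmean(nz); pn1 <- colmean(nz - 1)
  p_in <- p1 + (p1 - p2) * (grid$z_c[1] - grid$z_f[1]) /
    (grid$z_c[2] - grid$z_c[1])
  p_out <- pn + (pn - pn1) * (grid$z_f[nz + 1] - grid$z_c[nz]) /
    (grid$z_c[nz] - grid$z_c[nz - 1])
  L <- grid$geom$segment_length
  pre <- grid$z_c < L / 3; post <- grid$z_c > 2 * L / 3
  wcol <- vapply(seq_len(nz), function(j) sum(A[fl[, j]]), numeric(1))
  pcol <- vapply(seq_len(nz), colmean, numeric(1))
  p_pre <- sum((pcol * wcol * grid$dz)[pre]) / sum((wcol * grid$dz)[pre])
  p_post <- sum((pcol * wcol * grid$dz)[post]) / sum((wcol * grid$dz)[post])
  list(dp = p_in - p_out, p_in = p_in, p_out = p_out,
       p_pre = p_pre, p_post = p_post)
}

#' Discrete flow rate through every cross-section
#'
#' Integrates the axial velocity over each axial-face plane of the grid.
#' For a converged incompressible solve these agree with the inlet flow rate
#' to the continuity tolerance at every station (mass telescopes through the
#' staggered discretization).
#'
#' @param flow A `flow_field`.
#' @param grid The matching grid.
#' @return Numeric vector (length `nz + 1`) of volumetric flow rates; in the
#'   axisymmetric mode the physical `2*pi` factor is included.
#' @export
section_flow_rates <- function(flow, grid) {
  if (grid$mode == "cart3d") {
    apply(flow$w, 3, sum) * grid$dx * grid$dy
  } else {
    fac <- if (grid$mode == "axisym") 2 * pi else 1
    fac * colSums(flow$uz * grid$w_c * grid$dr)
  }
}

#' Discrete cross-section areas at axial faces
#'
#' The open (fluid) area of each axial-face plane, consistent with the mask
#' used by the solver; the ratio `A_inlet/A_throat` governs the
#' continuity-forced speed-up at the throat.
#'
#' @param grid A [build_grid()] grid.
#' @return Numeric vector (length `nz + 1`).
#' @export
section_areas <- function(grid) {
  if (grid$mode == "cart3d") {
    m <- .masks3d(grid)
    apply(m$act_w, 3, sum) * grid$dx * grid$dy
  } else {
    m <- .masks2d(grid)
    fac <- if (grid$mode == "axisym") 2 * pi else 1
    fac * colSums(m$act_uz * grid$w_c * grid$dr)
  }
}
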