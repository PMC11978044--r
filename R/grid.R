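#' Build a structured computational grid for a lumen geometry
#'
#' Discretizes the segment on an orthogonal staggered grid. Three modes:
#' \describe{
#'   \item{`axisym`}{cylindrical `(r, z)` grid on `[0, R0] x [0, L]` with a
#'     fluid mask from the radius profile (stair-step wall representation);
#'     `r = 0` is the symmetry axis.}
#'   \item{`planar`}{Cartesian `(y, x)` channel grid on `[0, R0] x [0, L]`
#'     with solid walls on both transverse boundaries; used for verification
#'     problems such as Couette flow.}
#'   \item{`cart3d`}{Cartesian `(x, y, z)` box grid bounding the widest
#'     elliptic cross-section, with a per-cell lumen mask from the ellipse
#'     containment test.}
#' }
#' Velocity components live on faces (staggered/MAC arrangement), pressure
#' and temperature at cell centers.
#'
#' @param geom A [lumen_geometry()].
#' @param resolution Cells per axis: `c(nr, nz)` for the 2D modes (transverse,
#'   axial) or `c(nx, ny, nz)` for `cart3d`. Each entry must be `>= 4`.
#' @param mode `"axisym"`, `"planar"` or `"cart3d"`.
#' @param clustering Axial refinement factor `>= 1`; values above 1
#'   concentrate axial cells inside the stenotic window (no-op for a healthy
#'   vessel).
#' @return An object of class `flow_grid`.
#' @export
build_grid <- function(geom, resolution, mode = c("axisym", "planar", "cart3d"),
                       clustering = 1) {
  stopifnot(inherits(geom, "lumen_geometry"))
  mode <- match.arg(mode)
  if (!is.numeric(resolution) || any(resolution < 4) ||
      any(resolution != round(resolution)))
    stop("resolution must be integer cell counts >= 4 per axis", call. = FALSE)
  if (!is.numeric(clustering) || clustering < 1)
    stop("clustering must be >= 1", call. = FALSE)
  L <- geom$segment_length
  R0 <- geom$base_radius

  nz <- resolution[length(resolution)]
  z_f <- .axial_faces(geom, nz, clustering)
  z_c <- 0.5 * (z_f[-1] + z_f[-(nz + 1)])
  dz <- diff(z_f)

  if (mode %in% c("axisym", "planar")) {
    if (length(resolution) != 2L)
      stop("2D modes need resolution = c(nr, nz)", call. = FALSE)
    nr <- resolution[1]
    dr <- R0 / nr
    r_f <- seq(0, R0, length.out = nr + 1)
    r_c <- 0.5 * (r_f[-1] + r_f[-(nr + 1)])
    Rc <- radius_profile(z_c, geom)
    Rf <- radius_profile(z_f, geom)
    .check_throat(geom, dr)
    fluid <- outer(r_c, Rc, function(r, R) r < R)
    if (mode == "axisym") {
      w_f <- r_f; w_c <- r_c
    } else {
      w_f <- rep(1, nr + 1); w_c <- rep(1, nr)
    }
    g <- list(mode = mode, nr = nr, nz = nz, dr = dr,
              r_f = r_f, r_c = r_c, z_f = z_f, z_c = z_c, dz = dz,
              w_f = w_f, w_c = w_c, Rc = Rc, Rf = Rf,
              fluid = fluid, n_cells = nr * nz, n_fluid = sum(fluid),
              geom = geom, clustering = clustering)
  } else {
    if (length(resolution) != 3L)
      stop("cart3d mode needs resolution = c(nx, ny, nz)", call. = FALSE)
    nx <- resolution[1]; ny <- resolution[2]
    ab0 <- ellipse_section(0, geom)
    ax <- ab0$a; by <- ab0$b     # widest section is the unnarrowed one
    dx <- 2 * ax / nx; dy <- 2 * by / ny
    x_f <- seq(-ax, ax, length.out = nx + 1)
    y_f <- seq(-by, by, length.out = ny + 1)
    x_c <- 0.5 * (x_f[-1] + x_f[-(nx + 1)])
    y_c <- 0.5 * (y_f[-1] + y_f[-(ny + 1)])
    sec_c <- ellipse_section(z_c, geom)
    sec_f <- ellipse_section(z_f, geom)
    .check_throat(geom, min(dx, dy) *
                    sqrt(max(geom$ellipse_ratio, 1 / geom$ellipse_ratio)))
    fluid <- array(FALSE, c(nx, ny, nz))
    for (k in seq_len(nz)) {
      fluid[, , k] <- outer(x_c^2 / sec_c$a[k]^2, y_c^2 / sec_c$b[k]^2,
                            `+`) <= 1
    }
    if (any(apply(fluid, 3, sum) == 0))
      stop("lumen mask empty in at least one axial slab; refine the grid",
           call. = FALSE)
    g <- list(mode = mode, nx = nx, ny = ny, nz = nz,
              dx = dx, dy = dy, dz = dz,
              x_f = x_f, y_f = y_f, z_f = z_f,
              x_c = x_c, y_c = y_c, z_c = z_c,
              a_c = sec_c$a, b_c = sec_c$b, a_f = sec_f$a, b_f = sec_f$b,
              fluid = fluid, n_cells = nx * ny * nz, n_fluid = sum(fluid),
              geom = geom, clustering = clustering)
  }
  structure(g, class = "flow_grid")
}

#' @export
print.flow_grid <- function(x, ...) {
  if (x$mode == "cart3d") {
    cat(sprintf("flow_grid [cart3d] %d x %d x %d cells (%d in lumen)\n",
                x$nx, x$ny, x$nz, x$n_fluid))
  } else {
    cat(sprintf("flow_grid [%s] %d x %d cells (%d in lumen)\n",
                x$mode, x$nr, x$nz, x$n_fluid))
  }
  invisible(x)
}

# Axial face positions, optionally clustered inside the stenotic window.
.axial_faces <- function(geom, nz, clustering) {
  L <- geom$segment_length
  st <- geom$stenosis
  if (clustering <= 1 || is.null(st) || st$degree == 0)
    return(seq(0, L, length.out = nz + 1))
  zf_fine <- seq(0, L, length.out = 4001)
  zm <- 0.5 * (zf_fine[-1] + zf_fine[-length(zf_fine)])
  inside <- abs(zm - st$center) <= st$length / 2
  dens <- rep(1, length(zm))
  dens[inside] <- 1 + (clustering - 1) *
    0.5 * (1 + cos(2 * pi * (zm[inside] - st$center) / st$length))
  cdf <- c(0, cumsum(dens * diff(zf_fine)))
  cdf <- cdf / cdf[length(cdf)]
  z_f <- stats::approx(cdf, zf_fine, xout = seq(0, 1, length.out = nz + 1),
                       ties = "ordered")$y
  z_f[1] <- 0; z_f[nz + 1] <- L
  z_f
}

.check_throat <- function(geom, h) {
  st <- geom$stenosis
  r_min <- geom$base_radius * (1 - if (is.null(st)) 0 else st$degree)
  if (floor(r_min / h) < 3)
    stop("resolution too coarse to resolve throat: fewer than 3 cells ",
         "across the throat radius (", signif(r_min, 4), " m); ",
         "refine the grid", call. = FALSE)
  invisible(TRUE)
}

#' Analytic lumen volume
#'
#' Volume of the lumen by adaptive quadrature of `pi * r(z)^2 dz`; used as an
#' independent oracle for mask-consistency checks.
#'
#' @param geom A [lumen_geometry()].
#' @return Volume (m^3).
#' @export
lumen_volume <- function(geom) {
  stats::integrate(function(z) pi * radius_profile(z, geom)^2,
                   0, geom$segment_length, rel.tol = 1e-10)$value
}

#' Grid-independence study
#'
#' Re-solves a case at a sequence of increasing resolutions, extracts a scalar
#' quantity of interest per resolution, and reports successive relative
#' changes. The study is flagged converged at the first resolution whose
#' change from the previous one falls below `threshold` (mesh-independence
#' criterion). A non-convergent solve is recorded as a failed row, not an
#' error.
#'
#' @param case A case configuration from [make_case()].
#' @param resolutions List of resolution vectors (each as for [build_grid()]),
#'   in increasing order; at least 3.
#' @param qoi Function mapping a [run_case()]-style result
#'   (`list(flow, grid, history, ...)`) to a scalar. Default: peak centerline
#'   axial velocity.
#' @param threshold Relative-change convergence threshold (default 1%).
#' @return A data.frame with one row per resolution: `cells`, `qoi`,
#'   `rel_change`, `solver_converged`, `grid_converged`.
#' @export
grid_independence <- function(case, resolutions, qoi = qoi_peak_velocity,
                              threshold = 0.01) {
  if (length(resolutions) < 3)
    stop("need at least 3 resolutions", call. = FALSE)
  rows <- vector("list", length(resolutions))
  vals <- rep(NA_real_, length(resolutions))
  for (i in seq_along(resolutions)) {
    ci <- case
    ci$resolution <- resolutions[[i]]
    res <- tryCatch(solve_case(ci), error = function(e) NULL)
    ok <- !is.null(res) && isTRUE(res$history$converged)
    if (ok) vals[i] <- qoi(res)
    rows[[i]] <- data.frame(
      cells = prod(resolutions[[i]]),
      qoi = vals[i],
      solver_converged = ok)
  }
  out <- do.call(rbind, rows)
  out$rel_change <- c(NA, abs(diff(out$qoi)) /
                        pmax(abs(out$qoi[-nrow(out)]), .Machine$double.eps))
  out$grid_converged <- !is.na(out$rel_change) & out$rel_change < threshold
  out
}

#' Quantity of interest: peak centerline axial velocity
#'
#' Default QoI for [grid_independence()]: the maximum of the centerline
#' axial-velocity profile.
#'
#' @param result A solved case as returned by [solve_case()].
#' @return Scalar peak centerline velocity.
#' @export
qoi_peak_velocity <- function(result) {
  prof <- extract_line(list(flow = result$flow, grid = result$grid),
                       quantity = "velocity-magnitude", axis = "centerline")
  max(prof$value)
}
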