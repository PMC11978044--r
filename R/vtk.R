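# Legacy ASCII VTK rectilinear-grid writer for field inspection in ParaView
# or similar. Cell data: pressure, viscosity, velocity magnitude, lumen
# mask, temperature (when present), and the velocity vector. The
# axisymmetric plane is written with r as x and z as y.

.vtk_num <- function(x) formatC(x, format = "g", digits = 9)

#' Write a solved case to a legacy VTK file
#'
#' @param sol A solution list with `flow`, `grid` (and optionally
#'   `temperature`), as from [solve_case()].
#' @param path Output `.vtk` file.
#' @return Invisibly, `path`.
#' @export
write_vtk <- function(sol, path) {
  grid <- sol$grid; flow <- sol$flow
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# vtk DataFile Version 3.0")
  w("stenoflow fields")
  w("ASCII")
  w("DATASET RECTILINEAR_GRID")
  if (grid$mode == "cart3d") {
    nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
    w(sprintf("DIMENSIONS %d %d %d", nx + 1, ny + 1, nz + 1))
    w(sprintf("X_COORDINATES %d float", nx + 1))
    w(paste(.vtk_num(grid$x_f), collapse = " "))
    w(sprintf("Y_COORDINATES %d float", ny + 1))
    w(paste(.vtk_num(grid$y_f), collapse = " "))
    w(sprintf("Z_COORDINATES %d float", nz + 1))
    w(paste(.vtk_num(grid$z_f), collapse = " "))
    ncell <- nx * ny * nz
    uc <- 0.5 * (flow$u[2:(nx + 1), , , drop = FALSE] +
                   flow$u[1:nx, , , drop = FALSE])
    vc <- 0.5 * (flow$v[, 2:(ny + 1), , drop = FALSE] +
                   flow$v[, 1:ny, , drop = FALSE])
    wc <- 0.5 * (flow$w[, , 2:(nz + 1), drop = FALSE] +
                   flow$w[, , 1:nz, drop = FALSE])
    w(sprintf("CELL_DATA %d", ncell))
    .vtk_scalar(w, "pressure", flow$p)
    .vtk_scalar(w, "viscosity", flow$mu)
    .vtk_scalar(w, "speed", sqrt(uc^2 + vc^2 + wc^2))
    .vtk_scalar(w, "mask", grid$fluid * 1)
    if (!is.null(sol$temperature)) {
      th <- sol$temperature$theta; th[is.na(th)] <- 0
      .vtk_scalar(w, "theta", th)
    }
    w("VECTORS velocity float")
    m <- cbind(as.numeric(uc), as.numeric(vc), as.numeric(wc))
    writeLines(paste(.vtk_num(m[, 1]), .vtk_num(m[, 2]), .vtk_num(m[, 3])),
               con)
  } else {
    nr <- grid$nr; nz <- grid$nz
    w(sprintf("DIMENSIONS %d %d %d", nr + 1, nz + 1, 1))
    w(sprintf("X_COORDINATES %d float", nr + 1))
    w(paste(.vtk_num(grid$r_f), collapse = " "))
    w(sprintf("Y_COORDINATES %d float", nz + 1))
    w(paste(.vtk_num(grid$z_f), collapse = " "))
    w("Z_COORDINATES 1 float")
    w("0")
    ncell <- nr * nz
    uzc <- 0.5 * (flow$uz[, 1:nz, drop = FALSE] +
                    flow$uz[, 2:(nz + 1), drop = FALSE])
    urc <- 0.5 * (flow$ur[1:nr, , drop = FALSE] +
                    flow$ur[2:(nr + 1), , drop = FALSE])
    w(sprintf("CELL_DATA %d", ncell))
    .vtk_scalar(w, "pressure", flow$p)
    .vtk_scalar(w, "viscosity", flow$mu)
    .vtk_scalar(w, "speed", sqrt(uzc^2 + urc^2))
    .vtk_scalar(w, "mask", grid$fluid * 1)
    if (!is.null(sol$temperature)) {
      th <- sol$temperature$theta; th[is.na(th)] <- 0
      .vtk_scalar(w, "theta", th)
    }
    w("VECTORS velocity float")
    writeLines(paste(.vtk_num(as.numeric(urc)), .vtk_num(as.numeric(uzc)),
                     .vtk_num(rep(0, ncell))), con)
  }
  invisible(path)
}

.vtk_scalar <- function(w, name, A) {
  w(sprintf("SCALARS %s float 1", name))
  w("LOOKUP_TABLE default")
  w(paste(.vtk_num(as.numeric(A)), collapse = "\n"))
}

#' Write a grid (geometry only) to a legacy VTK file
#'
#' Serializes the structured grid with its lumen mask for inspection.
#'
#' @param grid A [build_grid()] grid.
#' @param path Output `.vtk` file.
#' @return Invisibly, `path`.
#' @export
write_vtk_grid <- function(grid, path) {
  flow <- if (grid$mode == "cart3d") {
    list(u = array(0, c(grid$nx + 1, grid$ny, grid$nz)),
         v = array(0, c(grid$nx, grid$ny + 1, grid$nz)),
         w = array(0, c(grid$nx, grid$ny, grid$nz + 1)),
         p = array(0, c(grid$nx, grid$ny, grid$nz)),
         mu = array(0, c(grid$nx, grid$ny, grid$nz)))
  } else {
    list(uz = matrix(0, grid$nr, grid$nz + 1),
         ur = matrix(0, grid$nr + 1, grid$nz),
         p = matrix(0, grid$nr, grid$nz),
         mu = matrix(0, grid$nr, grid$nz))
  }
  write_vtk(list(flow = flow, grid = grid), path)
}
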