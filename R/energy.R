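# Temperature transport with viscous dissipation (one-way coupling).
#
# Solves the steady advection-diffusion equation for the dimensionless
# temperature theta = (T - Ti)/(Tb - Ti) on a converged flow field:
#   u . grad(theta) = beta * div(grad(theta)) + alpha * mu * Phi / (rho*cp*dT)
# with beta = k/(rho*cp) the thermal diffusivity and Phi the viscous
# dissipation function evaluated from the discrete velocity gradients.
# Upwind convection keeps the discrete maximum principle when the source
# vanishes. Boundary conditions: prescribed theta on walls, theta = theta_in
# at the inlet, zero gradient at the outlet, symmetry on the axis.

#' Viscous dissipation function of a 2D flow field
#'
#' Cell-centred dissipation `Phi` (1/s^2). Two groupings are available:
#' `"printed"` uses `2[(dw/dz)^2 + (du_r/dr)^2] + (dw/dr + du_r/dz)^2`
#' (the grouping of the governing energy equation as published, which in the
#' axisymmetric reduction omits the hoop contribution), `"standard"` adds the
#' hoop term `2*(u_r/r)^2`. Both are pointwise non-negative.
#'
#' @param field A `flow_field` (2D modes).
#' @param grid The matching grid.
#' @param form `"printed"` or `"standard"`.
#' @return Matrix (nr x nz) of dissipation values.
#' @export
dissipation_function <- function(field, grid, form = c("printed", "standard")) {
  form <- match.arg(form)
  g <- .gradients2d(field, grid)
  phi <- 2 * (g$duzdz^2 + g$durdr^2) + g$cross^2
  if (form == "standard" && grid$mode == "axisym") phi <- phi + 2 * g$uor^2
  phi
}

# Cell-centred velocity-gradient components of a 2D staggered field.
# Outer-boundary wall shear uses half-cell one-sided differences against the
# wall velocity (zero for no-slip; `field$wall_uz` allows a moving lid, as in
# Couette verification), which is exact for linear profiles.
.gradients2d <- function(field, grid) {
  nr <- grid$nr; nz <- grid$nz
  uz <- field$uz; ur <- field$ur
  w_top <- if (!is.null(field$wall_uz$top)) field$wall_uz$top else 0
  w_bot <- if (!is.null(field$wall_uz$bottom)) field$wall_uz$bottom else 0
  DZ <- .rowmat(grid$dz, nr)
  duzdz <- (uz[, 2:(nz + 1), drop = FALSE] - uz[, 1:nz, drop = FALSE]) / DZ
  durdr <- (ur[2:(nr + 1), , drop = FALSE] - ur[1:nr, , drop = FALSE]) /
    grid$dr
  uor <- if (grid$mode == "axisym")
    0.5 * (ur[2:(nr + 1), , drop = FALSE] + ur[1:nr, , drop = FALSE]) /
      grid$r_c else 0 * durdr
  duzdr_c <- (rbind(uz, 0) - rbind(0, uz)) / grid$dr
  duzdr_c[nr + 1, ] <- (w_top - uz[nr, ]) / (grid$dr / 2)
  duzdr_c[1, ] <- if (grid$mode == "axisym") 0 else
    (uz[1, ] - w_bot) / (grid$dr / 2)
  dzu <- c(grid$dz[1] / 2, diff(grid$z_c), grid$dz[nz] / 2)
  durdz_c <- (cbind(ur, ur[, nz]) - cbind(0, ur)) / .rowmat(dzu, nr + 1)
  durdz_c[, nz + 1] <- 0
  cross_c <- duzdr_c + durdz_c
  cross <- 0.25 * (cross_c[1:nr, 1:nz] + cross_c[2:(nr + 1), 1:nz] +
                   cross_c[1:nr, 2:(nz + 1)] + cross_c[2:(nr + 1), 2:(nz + 1)])
  list(duzdz = duzdz, durdr = durdr, uor = uor, cross = cross)
}

#' Solve the steady temperature equation on a converged flow
#'
#' One-way coupled scalar solve: the flow field advects heat, conduction
#' diffuses it, and (optionally) viscous dissipation acts as a non-negative
#' volumetric source scaled by the Brinkman group through the temperature
#' scale `dT = Tb - Ti`. With the dissipation off, the discrete solution
#' obeys the maximum principle: theta is bounded by its boundary values.
#'
#' @param flow A converged `flow_field` (2D modes; the 3D engine solves the
#'   same equation with Gauss-Seidel sweeps).
#' @param grid The matching grid.
#' @param props A [fluid_properties()]; `props$alpha` multiplies the
#'   dissipation source.
#' @param groups A [dimensionless_groups()] (supplies the temperature scale
#'   `dT` and reference speed).
#' @param bc List with `theta_wall` (wall value, default 1), `theta_in`
#'   (inlet value, default 0), `dissipation` (logical, default TRUE),
#'   `form` (dissipation grouping, see [dissipation_function()]).
#' @return A `temperature_field`: list with `theta` (matrix, `NA` outside the
#'   lumen), `bc`, `converged`.
#' @export
solve_energy <- function(flow, grid, props, groups, bc = list()) {
  bc <- utils::modifyList(list(theta_wall = 1, theta_in = 0,
                               dissipation = TRUE, form = "printed"), bc)
  stopifnot(inherits(props, "fluid_properties"))
  if (grid$mode == "cart3d") return(.energy3d(flow, grid, props, groups, bc))
  nr <- grid$nr; nz <- grid$nz
  fl <- grid$fluid
  beta <- props$k / (props$density * props$cp)
  uz <- flow$uz; ur <- flow$ur
  A_z <- grid$w_c * grid$dr
  DZ <- .rowmat(grid$dz, nr)
  # convective volumetric face fluxes (no rho: equation is per unit rho*cp)
  Fe <- A_z * uz[, 2:(nz + 1), drop = FALSE]
  Fw <- A_z * uz[, 1:nz, drop = FALSE]
  Fn <- grid$w_f[2:(nr + 1)] * DZ * ur[2:(nr + 1), , drop = FALSE]
  Fs <- grid$w_f[1:nr] * DZ * ur[1:nr, , drop = FALSE]
  # diffusive conductances
  dzc <- diff(grid$z_c)
  De <- beta * A_z / .rowmat(c(dzc, grid$dz[nz]), nr)
  Dw <- beta * A_z / .rowmat(c(grid$dz[1], dzc), nr)
  Dn <- beta * grid$w_f[2:(nr + 1)] * DZ / grid$dr
  Ds <- beta * grid$w_f[1:nr] * DZ / grid$dr
  nbE <- cbind(fl[, -1, drop = FALSE], FALSE)
  nbW <- cbind(FALSE, fl[, -nz, drop = FALSE])
  nbN <- rbind(fl[-1, , drop = FALSE], FALSE)
  nbS <- rbind(FALSE, fl[-nr, , drop = FALSE])
  # boundary closures
  De[, nz] <- 0                                  # outlet: zero gradient
  Dw[, 1] <- 2 * beta * A_z / grid$dz[1]         # inlet: Dirichlet theta_in
  wallE <- !nbE & col(De) < nz                   # stair axial walls
  wallW <- !nbW & col(Dw) > 1
  De[wallE] <- 2 * beta * (A_z * matrix(1, nr, nz))[wallE] / DZ[wallE]
  Dw[wallW] <- 2 * beta * (A_z * matrix(1, nr, nz))[wallW] / DZ[wallW]
  wallN <- !nbN                                  # top/stair walls: half-cell
  Dn[wallN] <- 2 * Dn[wallN]
  if (grid$mode == "planar") {
    wallS <- !nbS
    Ds[wallS] <- 2 * Ds[wallS]
  }                                              # axisym: w_f[1] = 0 -> axis
  aE <- De + pmax(-Fe, 0); aW <- Dw + pmax(Fw, 0)
  aN <- Dn + pmax(-Fn, 0); aS <- Ds + pmax(Fs, 0)
  aE[, nz] <- pmax(-pmin(Fe[, nz], 0), 0)        # outlet backflow guard
  aP <- aE + aW + aN + aS + (Fe - Fw + Fn - Fs)
  # Dirichlet folding
  bfix <- matrix(0, nr, nz)
  bfix <- bfix + aW * ifelse(col(bfix) == 1, bc$theta_in,
                             ifelse(!nbW, bc$theta_wall, 0))
  bfix <- bfix + aE * ifelse(!nbE & col(bfix) < nz, bc$theta_wall, 0)
  bfix <- bfix + aN * ifelse(!nbN, bc$theta_wall, 0)
  if (grid$mode == "planar")
    bfix <- bfix + aS * ifelse(!nbS, bc$theta_wall, 0)
  src <- matrix(0, nr, nz)
  if (isTRUE(bc$dissipation) && props$alpha > 0) {
    phi <- dissipation_function(flow, grid, bc$form)
    V <- (grid$w_c * grid$dr) * DZ
    src <- props$alpha * flow$mu * phi /
      (props$density * props$cp * groups$dT) * V
  }
  rhs_m <- bfix + src
  # sparse assembly over fluid cells
  idx <- matrix(0L, nr, nz); idx[fl] <- seq_len(sum(fl))
  linkE <- fl[, 1:(nz - 1)] & fl[, 2:nz]
  linkN <- fl[1:(nr - 1), ] & fl[2:nr, ]
  ii <- c(idx[fl],
          idx[, 1:(nz - 1)][linkE], idx[, 2:nz][linkE],
          idx[1:(nr - 1), ][linkN], idx[2:nr, ][linkN])
  jj <- c(idx[fl],
          idx[, 2:nz][linkE], idx[, 1:(nz - 1)][linkE],
          idx[2:nr, ][linkN], idx[1:(nr - 1), ][linkN])
  xx <- c(aP[fl],
          -aE[, 1:(nz - 1), drop = FALSE][linkE],
          -aW[, 2:nz, drop = FALSE][linkE],
          -aN[1:(nr - 1), , drop = FALSE][linkN],
          -aS[2:nr, , drop = FALSE][linkN])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = rep(sum(fl), 2))
  th_v <- as.numeric(Matrix::solve(A, rhs_m[fl]))
  theta <- matrix(NA_real_, nr, nz)
  theta[fl] <- th_v
  structure(list(theta = theta, bc = bc, groups = groups,
                 converged = all(is.finite(th_v)), mode = grid$mode),
            class = "temperature_field")
}

# 3D scalar transport by red-black Gauss-Seidel (linear, upwind)
.energy3d <- function(flow, grid, props, groups, bc) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  fl <- grid$fluid
  beta <- props$k / (props$density * props$cp)
  dx <- grid$dx; dy <- grid$dy
  DZ <- array(rep(grid$dz, each = nx * ny), c(nx, ny, nz))
  A_z <- dx * dy
  Fe <- A_z * flow$w[, , 2:(nz + 1), drop = FALSE]
  Fw <- A_z * flow$w[, , 1:nz, drop = FALSE]
  Fxp <- dy * DZ * flow$u[2:(nx + 1), , , drop = FALSE]
  Fxm <- dy * DZ * flow$u[1:nx, , , drop = FALSE]
  Fyp <- dx * DZ * flow$v[, 2:(ny + 1), , drop = FALSE]
  Fym <- dx * DZ * flow$v[, 1:ny, , drop = FALSE]
  dzc <- diff(grid$z_c)
  De <- beta * A_z / array(rep(c(dzc, grid$dz[nz]), each = nx * ny),
                           c(nx, ny, nz))
  Dw <- beta * A_z / array(rep(c(grid$dz[1], dzc), each = nx * ny),
                           c(nx, ny, nz))
  Dxp <- array(beta * dy, c(nx, ny, nz)) * DZ / dx
  Dxm <- Dxp; Dyp <- array(beta * dx, c(nx, ny, nz)) * DZ / dy; Dym <- Dyp
  nbE <- .shzp(fl * 1) > 0; nbW <- .shzm(fl * 1) > 0
  nbXp <- .shxp(fl * 1) > 0; nbXm <- .shxm(fl * 1) > 0
  nbYp <- .shyp(fl * 1) > 0; nbYm <- .shym(fl * 1) > 0
  De[, , nz] <- 0
  Dw[, , 1] <- 2 * beta * A_z / grid$dz[1]
  intE <- array(TRUE, dim(De)); intE[, , nz] <- FALSE
  intW <- array(TRUE, dim(Dw)); intW[, , 1] <- FALSE
  De <- ifelse(!nbE & intE, 2 * De, De)
  Dw <- ifelse(!nbW & intW, 2 * Dw, Dw)
  Dxp <- ifelse(nbXp, Dxp, 2 * Dxp); Dxm <- ifelse(nbXm, Dxm, 2 * Dxm)
  Dyp <- ifelse(nbYp, Dyp, 2 * Dyp); Dym <- ifelse(nbYm, Dym, 2 * Dym)
  aE <- De + pmax(-Fe, 0); aW <- Dw + pmax(Fw, 0)
  aE[, , nz] <- pmax(-pmin(Fe[, , nz], 0), 0)
  aXp <- Dxp + pmax(-Fxp, 0); aXm <- Dxm + pmax(Fxm, 0)
  aYp <- Dyp + pmax(-Fyp, 0); aYm <- Dym + pmax(Fym, 0)
  aP <- aE + aW + aXp + aXm + aYp + aYm +
    (Fe - Fw + Fxp - Fxm + Fyp - Fym)
  bfix <- aW * ifelse(intW & !nbW, bc$theta_wall, 0)
  bfix[, , 1] <- aW[, , 1] * bc$theta_in
  bfix <- bfix + aE * ifelse(intE & !nbE, bc$theta_wall, 0) +
    aXp * ifelse(!nbXp, bc$theta_wall, 0) +
    aXm * ifelse(!nbXm, bc$theta_wall, 0) +
    aYp * ifelse(!nbYp, bc$theta_wall, 0) +
    aYm * ifelse(!nbYm, bc$theta_wall, 0)
  src <- array(0, c(nx, ny, nz))
  if (isTRUE(bc$dissipation) && props$alpha > 0) {
    g <- .dissipation3d(flow, grid, bc$form)
    src <- props$alpha * flow$mu * g /
      (props$density * props$cp * groups$dT) * (dx * dy * DZ)
  }
  b <- bfix + src
  th <- array(0, c(nx, ny, nz))
  colors <- (outer(outer(seq_len(nx), seq_len(ny), `+`), seq_len(nz),
                   `+`) %% 2) == 0
  scale <- max(abs(b)) + max(aP[fl]) * max(abs(bc$theta_wall), abs(bc$theta_in), 1)
  ok <- FALSE
  for (s in seq_len(8000)) {
    for (colr in c(TRUE, FALSE)) {
      rhs <- b + aE * .shzp(th) + aW * .shzm(th) +
        aXp * .shxp(th) + aXm * .shxm(th) +
        aYp * .shyp(th) + aYm * .shym(th)
      sel <- fl & (colors == colr)
      th[sel] <- rhs[sel] / aP[sel]
    }
    if (s %% 25 == 0) {
      r <- aP * th - (aE * .shzp(th) + aW * .shzm(th) +
                      aXp * .shxp(th) + aXm * .shxm(th) +
                      aYp * .shyp(th) + aYm * .shym(th)) - b
      if (sum(abs(r[fl])) <= 1e-10 * scale * sum(fl)) { ok <- TRUE; break }
    }
  }
  th[!fl] <- NA_real_
  structure(list(theta = th, bc = bc, groups = groups, converged = ok,
                 mode = "cart3d"), class = "temperature_field")
}

.dissipation3d <- function(flow, grid, form = "printed") {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  u <- flow$u; v <- flow$v; w <- flow$w
  DZ <- array(rep(grid$dz, each = nx * ny), c(nx, ny, nz))
  dudx <- (u[2:(nx + 1), , , drop = FALSE] - u[1:nx, , , drop = FALSE]) /
    grid$dx
  dvdy <- (v[, 2:(ny + 1), , drop = FALSE] - v[, 1:ny, , drop = FALSE]) /
    grid$dy
  dwdz <- (w[, , 2:(nz + 1), drop = FALSE] - w[, , 1:nz, drop = FALSE]) / DZ
  uc <- 0.5 * (u[2:(nx + 1), , , drop = FALSE] + u[1:nx, , , drop = FALSE])
  vc <- 0.5 * (v[, 2:(ny + 1), , drop = FALSE] + v[, 1:ny, , drop = FALSE])
  wc <- 0.5 * (w[, , 2:(nz + 1), drop = FALSE] + w[, , 1:nz, drop = FALSE])
  dudy <- (.shyp(uc) - .shym(uc)) / (2 * grid$dy)
  dudz <- (.shzp(uc) - .shzm(uc)) / (2 * DZ)
  dvdx <- (.shxp(vc) - .shxm(vc)) / (2 * grid$dx)
  dvdz <- (.shzp(vc) - .shzm(vc)) / (2 * DZ)
  dwdx <- (.shxp(wc) - .shxm(wc)) / (2 * grid$dx)
  dwdy <- (.shyp(wc) - .shym(wc)) / (2 * grid$dy)
  if (identical(form, "standard")) {
    2 * (dudx^2 + dvdy^2 + dwdz^2) + (dudy + dvdx)^2 +
      (dudz + dwdx)^2 + (dvdz + dwdy)^2
  } else {
    2 * (dudx^2 + dvdy^2 + dwdz^2) + (dudy + dvdx + dwdz)^2
  }
}
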