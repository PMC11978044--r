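# Three-dimensional masked-cell Cartesian SIMPLE engine (MAC staggering).
#
# The lumen is embedded in a bounding box; cells whose centre lies outside
# the elliptic section are solid. Wall-normal diffusion of the axial velocity
# uses the true distance to the elliptic wall along the grid axis (sharp
# immersed-boundary treatment, first order in the cut distance), which keeps
# the near-wall axial velocity accurate on the stair-step mask. The 3D
# engine solves momentum by red-black Gauss-Seidel sweeps and the
# pressure-correction equation by Jacobi-preconditioned conjugate gradients
# (matrix-free); it implements the implicit div(mu grad u) diffusion form.

# shifts with zero padding, per axis ("p" = value at index + 1)
.shxp <- function(A) { d <- dim(A); B <- array(0, d)
  B[1:(d[1] - 1), , ] <- A[2:d[1], , , drop = FALSE]; B }
.shxm <- function(A) { d <- dim(A); B <- array(0, d)
  B[2:d[1], , ] <- A[1:(d[1] - 1), , , drop = FALSE]; B }
.shyp <- function(A) { d <- dim(A); B <- array(0, d)
  B[, 1:(d[2] - 1), ] <- A[, 2:d[2], , drop = FALSE]; B }
.shym <- function(A) { d <- dim(A); B <- array(0, d)
  B[, 2:d[2], ] <- A[, 1:(d[2] - 1), , drop = FALSE]; B }
.shzp <- function(A) { d <- dim(A); B <- array(0, d)
  B[, , 1:(d[3] - 1)] <- A[, , 2:d[3], drop = FALSE]; B }
.shzm <- function(A) { d <- dim(A); B <- array(0, d)
  B[, , 2:d[3]] <- A[, , 1:(d[3] - 1), drop = FALSE]; B }

.masks3d <- function(grid) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz; fl <- grid$fluid
  act_w <- array(FALSE, c(nx, ny, nz + 1))
  act_w[, , 1] <- fl[, , 1]
  if (nz > 1) act_w[, , 2:nz] <- fl[, , 1:(nz - 1), drop = FALSE] &
      fl[, , 2:nz, drop = FALSE]
  act_w[, , nz + 1] <- fl[, , nz]
  unk_w <- act_w; unk_w[, , 1] <- FALSE
  act_u <- array(FALSE, c(nx + 1, ny, nz))
  act_u[2:nx, , ] <- fl[1:(nx - 1), , , drop = FALSE] &
    fl[2:nx, , , drop = FALSE]
  act_v <- array(FALSE, c(nx, ny + 1, nz))
  act_v[, 2:ny, ] <- fl[, 1:(ny - 1), , drop = FALSE] &
    fl[, 2:ny, , drop = FALSE]
  list(act_w = act_w, unk_w = unk_w, act_u = act_u, act_v = act_v)
}

.inlet_profile3d <- function(grid, U) {
  fl_in <- grid$fluid[, , 1]
  a <- grid$a_f[1]; b <- grid$b_f[1]
  prof <- outer(grid$x_c^2 / a^2, grid$y_c^2 / b^2, `+`)
  prof <- 2 * U * pmax(1 - prof, 0)
  prof[!fl_in] <- 0
  flux <- sum(prof); area <- sum(fl_in)
  if (flux > 0) prof <- prof * (U * area / flux)
  prof
}

.bc3d <- function(field, grid, case) {
  m <- .masks3d(grid)
  field$w[!m$act_w] <- 0
  field$u[!m$act_u] <- 0
  field$v[!m$act_v] <- 0
  field$w[, , 1] <- .inlet_profile3d(grid, case$U)
  field
}

.flow_init3d <- function(grid, case) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  # deterministic initialization: the inlet profile replicated axially
  # (zero transverse velocity, uniform pressure); far cheaper to converge
  # than a zero-velocity start on large 3D grids, and bitwise reproducible
  w0 <- array(.inlet_profile3d(grid, case$U), c(nx, ny, nz + 1))
  field <- structure(list(
    u = array(0, c(nx + 1, ny, nz)),
    v = array(0, c(nx, ny + 1, nz)),
    w = w0,
    p = array(0, c(nx, ny, nz)),
    mu = array(case$props$mu0, c(nx, ny, nz)),
    mode = "cart3d"), class = "flow_field")
  .bc3d(field, grid, case)
}

# wall distances along x and y for the axial-velocity stencil, per z-face
.wall_dist3d <- function(grid) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  dx <- grid$dx; dy <- grid$dy
  dXp <- array(dx, c(nx, ny, nz + 1)); dXm <- dXp
  dYp <- array(dy, c(nx, ny, nz + 1)); dYm <- dYp
  for (k in seq_len(nz + 1)) {
    a <- grid$a_f[k]; b <- grid$b_f[k]
    xw <- a * sqrt(pmax(0, 1 - (grid$y_c / b)^2))     # ny
    yw <- b * sqrt(pmax(0, 1 - (grid$x_c / a)^2))     # nx
    XW <- matrix(xw, nx, ny, byrow = TRUE)
    YW <- matrix(yw, nx, ny)
    XC <- matrix(grid$x_c, nx, ny); YC <- matrix(grid$y_c, nx, ny, byrow = TRUE)
    dXp[, , k] <- pmin(pmax(XW - XC, 0.2 * dx), dx)
    dXm[, , k] <- pmin(pmax(XW + XC, 0.2 * dx), dx)
    dYp[, , k] <- pmin(pmax(YW - YC, 0.2 * dy), dy)
    dYm[, , k] <- pmin(pmax(YW + YC, 0.2 * dy), dy)
  }
  list(dXp = dXp, dXm = dXm, dYp = dYp, dYm = dYm)
}

.gamma_dot_3d <- function(field, grid) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  u <- field$u; v <- field$v; w <- field$w
  DZ <- array(rep(grid$dz, each = nx * ny), c(nx, ny, nz))
  dudx <- (u[2:(nx + 1), , , drop = FALSE] - u[1:nx, , , drop = FALSE]) /
    grid$dx
  dvdy <- (v[, 2:(ny + 1), , drop = FALSE] - v[, 1:ny, , drop = FALSE]) /
    grid$dy
  dwdz <- (w[, , 2:(nz + 1), drop = FALSE] - w[, , 1:nz, drop = FALSE]) / DZ
  # cross gradients approximated at centres by central differences of
  # face-averaged components (adequate for the viscosity field)
  uc <- 0.5 * (u[2:(nx + 1), , , drop = FALSE] + u[1:nx, , , drop = FALSE])
  vc <- 0.5 * (v[, 2:(ny + 1), , drop = FALSE] + v[, 1:ny, , drop = FALSE])
  wc <- 0.5 * (w[, , 2:(nz + 1), drop = FALSE] + w[, , 1:nz, drop = FALSE])
  cgrad <- function(A, axis) {
    d <- dim(A)
    switch(axis,
      x = (.shxp(A) - .shxm(A)) / (2 * grid$dx),
      y = (.shyp(A) - .shym(A)) / (2 * grid$dy),
      z = (.shzp(A) - .shzm(A)) / (2 * DZ))
  }
  g12 <- cgrad(uc, "y") + cgrad(vc, "x")
  g13 <- cgrad(uc, "z") + cgrad(wc, "x")
  g23 <- cgrad(vc, "z") + cgrad(wc, "y")
  sqrt(2 * (dudx^2 + dvdy^2 + dwdz^2) + g12^2 + g13^2 + g23^2)
}

# -- axial (w) momentum coefficients -----------------------------------------
.coef_w3 <- function(field, grid, case, settings, m, wd) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  rho <- case$props$density
  dx <- grid$dx; dy <- grid$dy; dz <- grid$dz
  u <- field$u; v <- field$v; w <- field$w; p <- field$p; mu <- field$mu
  A_z <- dx * dy
  dzu <- c(NA, diff(grid$z_c), dz[nz] / 2)
  DZU <- array(rep(dzu, each = nx * ny), c(nx, ny, nz + 1)); DZU[, , 1] <- 0
  muW <- array(0, c(nx, ny, nz + 1)); muW[, , 2:(nz + 1)] <- mu
  muE <- array(0, c(nx, ny, nz + 1)); muE[, , 1:nz] <- mu
  DZW <- array(rep(c(dz[1], dz), each = nx * ny), c(nx, ny, nz + 1))
  DZE <- array(rep(c(dz, dz[nz]), each = nx * ny), c(nx, ny, nz + 1))
  De <- muE * A_z / DZE; De[, , nz + 1] <- 0
  Dw <- muW * A_z / DZW; Dw[, , 1] <- 0
  uface_e <- 0.5 * (w + .shzp(w))
  uface_e[, , nz + 1] <- pmax(w[, , nz + 1], 0)
  Fe <- rho * A_z * uface_e
  Fw <- rho * A_z * 0.5 * (.shzm(w) + w)
  # transverse fluxes: u and v interpolated axially onto z-faces
  tz <- c(0, (grid$z_f[2:nz] - grid$z_c[1:(nz - 1)]) / diff(grid$z_c), 1)
  TZ <- array(rep(tz, each = (nx + 1) * ny), c(nx + 1, ny, nz + 1))
  u_itp <- array(0, c(nx + 1, ny, nz + 1))
  u_itp[, , 2:nz] <- (1 - TZ[, , 2:nz]) * u[, , 1:(nz - 1), drop = FALSE] +
    TZ[, , 2:nz] * u[, , 2:nz, drop = FALSE]
  u_itp[, , nz + 1] <- u[, , nz]
  TZv <- array(rep(tz, each = nx * (ny + 1)), c(nx, ny + 1, nz + 1))
  v_itp <- array(0, c(nx, ny + 1, nz + 1))
  v_itp[, , 2:nz] <- (1 - TZv[, , 2:nz]) * v[, , 1:(nz - 1), drop = FALSE] +
    TZv[, , 2:nz] * v[, , 2:nz, drop = FALSE]
  v_itp[, , nz + 1] <- v[, , nz]
  Fxp <- rho * dy * DZU * u_itp[2:(nx + 1), , , drop = FALSE]
  Fxm <- rho * dy * DZU * u_itp[1:nx, , , drop = FALSE]
  Fyp <- rho * dx * DZU * v_itp[, 2:(ny + 1), , drop = FALSE]
  Fym <- rho * dx * DZU * v_itp[, 1:ny, , drop = FALSE]
  muX <- 0.5 * (muW + muE); muX[, , nz + 1] <- muW[, , nz + 1]
  mu_xp <- 0.5 * (muX + .shxp(muX)); mu_xp[nx, , ] <- muX[nx, , ]
  mu_xm <- 0.5 * (muX + .shxm(muX)); mu_xm[1, , ] <- muX[1, , ]
  mu_yp <- 0.5 * (muX + .shyp(muX)); mu_yp[, ny, ] <- muX[, ny, ]
  mu_ym <- 0.5 * (muX + .shym(muX)); mu_ym[, 1, ] <- muX[, 1, ]
  nbXp <- .shxp(m$act_w * 1) > 0; nbXm <- .shxm(m$act_w * 1) > 0
  nbYp <- .shyp(m$act_w * 1) > 0; nbYm <- .shym(m$act_w * 1) > 0
  Dxp <- mu_xp * dy * DZU / ifelse(nbXp, dx, wd$dXp)
  Dxm <- mu_xm * dy * DZU / ifelse(nbXm, dx, wd$dXm)
  Dyp <- mu_yp * dx * DZU / ifelse(nbYp, dy, wd$dYp)
  Dym <- mu_ym * dx * DZU / ifelse(nbYm, dy, wd$dYm)
  aE <- De + pmax(-Fe, 0); aW <- Dw + pmax(Fw, 0)
  aE[, , nz + 1] <- 0
  aXp <- Dxp + pmax(-Fxp, 0); aXm <- Dxm + pmax(Fxm, 0)
  aYp <- Dyp + pmax(-Fyp, 0); aYm <- Dym + pmax(Fym, 0)
  dF <- Fe - Fw + Fxp - Fxm + Fyp - Fym
  aP0 <- aE + aW + aXp + aXm + aYp + aYm + dF
  pW <- array(0, c(nx, ny, nz + 1)); pW[, , 2:(nz + 1)] <- p
  pE <- array(0, c(nx, ny, nz + 1)); pE[, , 1:nz] <- p
  b0 <- (pW - pE) * A_z
  b0[, , 1] <- 0
  list(aE = aE, aW = aW, aN = aXp, aS = aXm, aT = aYp, aB = aYm,
       aP0 = aP0, b0 = b0,
       sum_anb = aE + aW + aXp + aXm + aYp + aYm)
}

# The three transverse/axial directions share one generic assembler: we
# permute the arrays so the component's own axis is first, assemble in that
# frame, and permute back. `perm` maps (component axis, t1, t2) -> (x, y, z).
.coef_trans3 <- function(comp, field, grid, case, settings, m) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  rho <- case$props$density
  dx <- grid$dx; dy <- grid$dy
  mu <- field$mu; p <- field$p
  dzv <- grid$dz
  if (comp == "u") {
    U <- field$u                          # (nx+1, ny, nz), own axis x
    own_h <- dx; t1_h <- dy
    act <- m$act_u
    Vt1 <- field$v                        # transverse neighbour along y
    W <- field$w
    n1 <- nx; n2 <- ny
  } else {
    U <- aperm(field$v, c(2, 1, 3))       # (ny+1, nx, nz), own axis y
    own_h <- dy; t1_h <- dx
    act <- aperm(m$act_v, c(2, 1, 3))
    Vt1 <- aperm(field$u, c(2, 1, 3))     # (ny, nx+1, nz)
    W <- aperm(field$w, c(2, 1, 3))
    mu <- aperm(mu, c(2, 1, 3)); p <- aperm(p, c(2, 1, 3))
    n1 <- ny; n2 <- nx
  }
  DZ <- array(rep(dzv, each = (n1 + 1) * n2), c(n1 + 1, n2, nz))
  muOm <- array(0, c(n1 + 1, n2, nz)); muOm[2:(n1 + 1), , ] <- mu
  muOp <- array(0, c(n1 + 1, n2, nz)); muOp[1:n1, , ] <- mu
  Dop <- muOp * t1_h * DZ / own_h
  Dom <- muOm * t1_h * DZ / own_h
  Fop <- rho * t1_h * DZ * 0.5 * (U + .shxp(U))
  Fom <- rho * t1_h * DZ * 0.5 * (.shxm(U) + U)
  # transverse (t1) faces at corners: other transverse comp interp along own
  Vt1e <- array(0, c(n1 + 1, n2 + 1, nz))
  Vt1e[1:n1, , ] <- Vt1
  Vco <- 0.5 * (Vt1e + .shxm(Vt1e))                    # at (o-face, t1-face)
  Ft1p <- rho * own_h * DZ * Vco[1:(n1 + 1), 2:(n2 + 1), , drop = FALSE]
  Ft1m <- rho * own_h * DZ * Vco[1:(n1 + 1), 1:n2, , drop = FALSE]
  muc <- 0.5 * (muOm + muOp)
  mu_t1p <- 0.5 * (muc + .shyp(muc)); mu_t1p[, n2, ] <- muc[, n2, ]
  mu_t1m <- 0.5 * (muc + .shym(muc)); mu_t1m[, 1, ] <- muc[, 1, ]
  nbT1p <- .shyp(act * 1) > 0; nbT1m <- .shym(act * 1) > 0
  Dt1p <- mu_t1p * own_h * DZ / t1_h * ifelse(nbT1p, 1, 2)
  Dt1m <- mu_t1m * own_h * DZ / t1_h * ifelse(nbT1m, 1, 2)
  # axial faces
  We <- array(0, c(n1 + 1, n2, nz + 1)); We[1:n1, , ] <- W
  Wco <- 0.5 * (We + .shxm(We))                        # at (o-face, z-face)
  Fzp <- rho * own_h * t1_h * Wco[, , 2:(nz + 1), drop = FALSE]
  Fzm <- rho * own_h * t1_h * Wco[, , 1:nz, drop = FALSE]
  dzc <- diff(grid$z_c)
  DZP <- array(rep(c(dzc, dzv[nz]), each = (n1 + 1) * n2), c(n1 + 1, n2, nz))
  DZM <- array(rep(c(dzv[1], dzc), each = (n1 + 1) * n2), c(n1 + 1, n2, nz))
  mu_zp <- muc; mu_zm <- muc
  Dzp <- mu_zp * own_h * t1_h / DZP
  Dzm <- mu_zm * own_h * t1_h / DZM
  Dzm[, , 1] <- 2 * muc[, , 1] * own_h * t1_h / dzv[1]   # inlet ghost = 0
  Dzp[, , nz] <- 0                                        # outlet zero-grad
  nbZp <- .shzp(act * 1) > 0
  intZ <- array(TRUE, dim(Dzp)); intZ[, , nz] <- FALSE
  Dzp <- ifelse(!nbZp & intZ, 2 * Dzp, Dzp)
  nbZm <- .shzm(act * 1) > 0
  intZm <- array(TRUE, dim(Dzm)); intZm[, , 1] <- FALSE
  Dzm <- ifelse(!nbZm & intZm, 2 * Dzm, Dzm)
  aOp <- Dop + pmax(-Fop, 0); aOm <- Dom + pmax(Fom, 0)
  aT1p <- Dt1p + pmax(-Ft1p, 0); aT1m <- Dt1m + pmax(Ft1m, 0)
  aZp <- Dzp + pmax(-Fzp, 0); aZm <- Dzm + pmax(Fzm, 0)
  aZp[, , nz] <- 0
  Fzp_cl <- Fzp; Fzp_cl[, , nz] <- pmax(Fzp[, , nz], 0)
  aZp[, , nz] <- 0
  dF <- Fop - Fom + Ft1p - Ft1m + Fzp_cl - Fzm
  aP0 <- aOp + aOm + aT1p + aT1m + aZp + aZm + dF
  pOm <- array(0, c(n1 + 1, n2, nz)); pOm[2:(n1 + 1), , ] <- p
  pOp <- array(0, c(n1 + 1, n2, nz)); pOp[1:n1, , ] <- p
  b0 <- (pOm - pOp) * t1_h * DZ
  list(aE = aZp, aW = aZm, aN = aOp, aS = aOm, aT = aT1p, aB = aT1m,
       aP0 = aP0, b0 = b0,
       sum_anb = aZp + aZm + aOp + aOm + aT1p + aT1m)
  # note: aE/aW are the axial (z) links, aN/aS the own-axis links,
  # aT/aB the other-transverse links, in the permuted frame
}

.gs_sweeps3 <- function(U, cf, aP_rel, b_rel, unk, colors, nsweep) {
  for (s in seq_len(nsweep)) {
    for (colr in c(TRUE, FALSE)) {
      rhs <- b_rel + cf$aE * .shzp(U) + cf$aW * .shzm(U) +
        cf$aN * .shxp(U) + cf$aS * .shxm(U) +
        cf$aT * .shyp(U) + cf$aB * .shym(U)
      sel <- unk & (colors == colr)
      U[sel] <- rhs[sel] / aP_rel[sel]
    }
  }
  U
}

.residual3_l1 <- function(U, cf, unk) {
  r <- cf$aP0 * U - (cf$aE * .shzp(U) + cf$aW * .shzm(U) +
                     cf$aN * .shxp(U) + cf$aS * .shxm(U) +
                     cf$aT * .shyp(U) + cf$aB * .shym(U)) - cf$b0
  sum(abs(r[unk]))
}

.mass_residual3d <- function(field, grid) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  DZ <- array(rep(grid$dz, each = nx * ny), c(nx, ny, nz))
  m <- grid$dy * DZ * (field$u[2:(nx + 1), , , drop = FALSE] -
                         field$u[1:nx, , , drop = FALSE]) +
    grid$dx * DZ * (field$v[, 2:(ny + 1), , drop = FALSE] -
                      field$v[, 1:ny, , drop = FALSE]) +
    grid$dx * grid$dy * (field$w[, , 2:(nz + 1), drop = FALSE] -
                           field$w[, , 1:nz, drop = FALSE])
  m[!grid$fluid] <- 0
  m
}

# Jacobi-preconditioned conjugate gradients on an assembled sparse system
.cg_sparse <- function(A, b, diagc, tol, maxit) {
  x <- numeric(length(b))
  r <- b
  z <- r / diagc
  pvec <- z
  rz <- sum(r * z)
  b_norm <- sqrt(sum(b^2))
  if (b_norm == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% pvec)
    alpha <- rz / sum(pvec * Ap)
    x <- x + alpha * pvec
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * b_norm) break
    z <- r / diagc
    rz_new <- sum(r * z)
    pvec <- z + (rz_new / rz) * pvec
    rz <- rz_new
  }
  x
}

.pressure_correct3 <- function(state) {
  grid <- state$grid; field <- state$field
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  rho <- state$case$props$density
  dx <- grid$dx; dy <- grid$dy
  DZ <- array(rep(grid$dz, each = nx * ny), c(nx, ny, nz))
  A_z <- dx * dy
  m <- state$m
  d_w <- array(0, c(nx, ny, nz + 1))
  d_w[m$unk_w] <- A_z / state$dden_w[m$unk_w]
  d_u <- array(0, c(nx + 1, ny, nz))
  A_x <- dy * array(rep(grid$dz, each = (nx + 1) * ny), c(nx + 1, ny, nz))
  d_u[m$act_u] <- A_x[m$act_u] / state$dden_u[m$act_u]
  d_v <- array(0, c(nx, ny + 1, nz))
  A_y <- dx * array(rep(grid$dz, each = nx * (ny + 1)), c(nx, ny + 1, nz))
  d_v[m$act_v] <- A_y[m$act_v] / state$dden_v[m$act_v]
  aE <- rho * A_z * d_w[, , 2:(nz + 1), drop = FALSE]
  ghost <- aE[, , nz]
  aE[, , nz] <- 0
  aW <- rho * A_z * d_w[, , 1:nz, drop = FALSE]
  aXp <- rho * dy * DZ * d_u[2:(nx + 1), , , drop = FALSE]
  aXm <- rho * dy * DZ * d_u[1:nx, , , drop = FALSE]
  aYp <- rho * dx * DZ * d_v[, 2:(ny + 1), , drop = FALSE]
  aYm <- rho * dx * DZ * d_v[, 1:ny, , drop = FALSE]
  diagc <- aE + aW + aXp + aXm + aYp + aYm
  diagc[, , nz] <- diagc[, , nz] + ghost
  fl <- grid$fluid
  if (is.null(state$p_pattern)) {
    idx <- array(0L, c(nx, ny, nz))
    idx[fl] <- seq_len(sum(fl))
    selE <- fl[, , 1:(nz - 1), drop = FALSE] & fl[, , 2:nz, drop = FALSE]
    selX <- fl[1:(nx - 1), , , drop = FALSE] & fl[2:nx, , , drop = FALSE]
    selY <- fl[, 1:(ny - 1), , drop = FALSE] & fl[, 2:ny, , drop = FALSE]
    state$p_pattern <- list(
      idx = idx, selE = selE, selX = selX, selY = selY,
      ii = c(idx[fl],
             idx[, , 1:(nz - 1)][selE], idx[1:(nx - 1), , ][selX],
             idx[, 1:(ny - 1), ][selY]),
      jj = c(idx[fl],
             idx[, , 2:nz][selE], idx[2:nx, , ][selX],
             idx[, 2:ny, ][selY]))
  }
  pat <- state$p_pattern
  xx <- c(diagc[fl],
          -aE[, , 1:(nz - 1), drop = FALSE][pat$selE],
          -aXp[1:(nx - 1), , , drop = FALSE][pat$selX],
          -aYp[, 1:(ny - 1), , drop = FALSE][pat$selY])
  A <- Matrix::sparseMatrix(i = pat$ii, j = pat$jj, x = xx,
                            dims = rep(sum(fl), 2), symmetric = TRUE)
  mres <- rho * .mass_residual3d(field, grid)
  pc_v <- .cg_sparse(A, -mres[fl], diagc[fl], state$settings$cg_tol, 600)
  pc <- array(0, c(nx, ny, nz))
  pc[fl] <- pc_v
  field$w <- field$w + d_w *
    (.padz_m(pc) - .padz_p(pc))
  field$u <- field$u + d_u * (.padx_m(pc) - .padx_p(pc))
  field$v <- field$v + d_v * (.pady_m(pc) - .pady_p(pc))
  field$p <- field$p + state$settings$alpha_p * pc
  field$w[!m$act_w] <- 0
  field$u[!m$act_u] <- 0
  field$v[!m$act_v] <- 0
  state$field <- field
  invisible(state)
}

# face-padded neighbours of a cell array: value on the minus/plus side of
# each face along an axis (zero outside the domain)
.padz_m <- function(p) { d <- dim(p); B <- array(0, c(d[1], d[2], d[3] + 1))
  B[, , 2:(d[3] + 1)] <- p; B }
.padz_p <- function(p) { d <- dim(p); B <- array(0, c(d[1], d[2], d[3] + 1))
  B[, , 1:d[3]] <- p; B }
.padx_m <- function(p) { d <- dim(p); B <- array(0, c(d[1] + 1, d[2], d[3]))
  B[2:(d[1] + 1), , ] <- p; B }
.padx_p <- function(p) { d <- dim(p); B <- array(0, c(d[1] + 1, d[2], d[3]))
  B[1:d[1], , ] <- p; B }
.pady_m <- function(p) { d <- dim(p); B <- array(0, c(d[1], d[2] + 1, d[3]))
  B[, 2:(d[2] + 1), ] <- p; B }
.pady_p <- function(p) { d <- dim(p); B <- array(0, c(d[1], d[2] + 1, d[3]))
  B[, 1:d[2], ] <- p; B }

.iter3d <- function(state) {
  grid <- state$grid; case <- state$case; st <- state$settings
  m <- state$m
  field <- state$field
  if (case$props$lambda > 0) {
    gd <- .gamma_dot_3d(field, grid)
    field$mu <- array(williamson_viscosity(as.numeric(gd), case$props),
                      dim(gd))
  }
  w_prev <- field$w; u_prev <- field$u; v_prev <- field$v
  cf_w <- .coef_w3(field, grid, case, st, m, state$wd)
  cf_u <- .coef_trans3("u", field, grid, case, st, m)
  cf_v <- .coef_trans3("v", field, grid, case, st, m)
  res_w <- .residual3_l1(field$w, cf_w, m$unk_w)
  vperm <- aperm(field$v, c(2, 1, 3))
  res_u <- .residual3_l1(field$u, cf_u, m$act_u)
  res_v <- .residual3_l1(vperm, cf_v, aperm(m$act_v, c(2, 1, 3)))
  aPrel_w <- cf_w$aP0 / st$alpha_u
  aPrel_u <- cf_u$aP0 / st$alpha_u
  aPrel_v <- cf_v$aP0 / st$alpha_u
  b_w <- cf_w$b0 + (1 - st$alpha_u) * aPrel_w * w_prev
  b_u <- cf_u$b0 + (1 - st$alpha_u) * aPrel_u * u_prev
  b_v <- cf_v$b0 + (1 - st$alpha_u) * aPrel_v * vperm
  field$w <- .gs_sweeps3(field$w, cf_w, aPrel_w, b_w, m$unk_w,
                         state$colors_w, st$sweeps)
  field$u <- .gs_sweeps3(field$u, cf_u, aPrel_u, b_u, m$act_u,
                         state$colors_u, st$sweeps)
  vperm <- .gs_sweeps3(vperm, cf_v, aPrel_v, b_v,
                       aperm(m$act_v, c(2, 1, 3)),
                       state$colors_v, st$sweeps)
  field$v <- aperm(vperm, c(2, 1, 3))
  state$field <- field
  if (identical(st$pv_coupling, "simplec")) {
    state$dden_w <- pmax(aPrel_w - cf_w$sum_anb, 0.02 * aPrel_w)
    state$dden_u <- pmax(aPrel_u - cf_u$sum_anb, 0.02 * aPrel_u)
    dden_v <- pmax(aPrel_v - cf_v$sum_anb, 0.02 * aPrel_v)
  } else {
    state$dden_w <- aPrel_w
    state$dden_u <- aPrel_u
    dden_v <- aPrel_v
  }
  state$dden_v <- aperm(dden_v, c(2, 1, 3))
  .pressure_correct3(state)
  cont <- sum(abs(.mass_residual3d(state$field, grid))) * case$props$density
  state$residuals <- c(mom_uz = res_w / state$mom_ref,
                       mom_ur = max(res_u, res_v) / state$mom_ref,
                       continuity = cont / state$flux_ref)
  invisible(state)
}

.state3d <- function(case, grid, field = NULL) {
  st <- case$settings
  m <- .masks3d(grid)
  if (is.null(field)) field <- .flow_init3d(grid, case)
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  flux_ref <- case$props$density * sum(field$w[, , 1]) * grid$dx * grid$dy
  state <- new.env(parent = emptyenv())
  state$case <- case; state$grid <- grid; state$settings <- st
  state$m <- m; state$field <- field
  state$wd <- .wall_dist3d(grid)
  cols <- function(d1, d2, d3)
    (outer(outer(seq_len(d1), seq_len(d2), `+`), seq_len(d3), `+`) %% 2) == 0
  state$colors_w <- cols(nx, ny, nz + 1)
  state$colors_u <- cols(nx + 1, ny, nz)
  state$colors_v <- cols(ny + 1, nx, nz)   # permuted frame
  state$flux_ref <- max(flux_ref, .Machine$double.xmin)
  state$mom_ref <- max(flux_ref * case$U, .Machine$double.xmin)
  state
}
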