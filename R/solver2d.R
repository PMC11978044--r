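# Two-dimensional staggered finite-volume SIMPLE engine.
#
# Covers the axisymmetric cylindrical (r, z) mode (radial metric weight
# w = r, symmetry axis at r = 0) and the planar (y, x) channel mode (w = 1,
# walls on both transverse boundaries). Arrangement: axial velocity uz on
# axial faces (nr x nz+1), transverse velocity ur on transverse faces
# (nr+1 x nz), pressure at cell centers (nr x nz). The lumen wall is a
# stair-step mask; wall-adjacent diffusion uses half-cell distances with the
# metric weight evaluated at the wall face, which keeps the discrete operator
# conservative (mass telescopes exactly through every cross-section).

# -- small shift helpers (pad with zero) -------------------------------------
.shE <- function(M) cbind(M[, -1, drop = FALSE], 0)   # M[i, k+1]
.shW <- function(M) cbind(0, M[, -ncol(M), drop = FALSE])
.shN <- function(M) rbind(M[-1, , drop = FALSE], 0)   # M[i+1, k]
.shS <- function(M) rbind(0, M[-nrow(M), , drop = FALSE])
.shNc <- function(M) rbind(M[-1, , drop = FALSE], M[nrow(M), ])  # clamp pad
.shSc <- function(M) rbind(M[1, ], M[-nrow(M), , drop = FALSE])
.rowmat <- function(v, nr) matrix(v, nr, length(v), byrow = TRUE)

# -- face-activity masks -----------------------------------------------------
.masks2d <- function(grid) {
  nr <- grid$nr; nz <- grid$nz; fl <- grid$fluid
  act_uz <- matrix(FALSE, nr, nz + 1)
  act_uz[, 1] <- fl[, 1]
  if (nz > 1) act_uz[, 2:nz] <- fl[, 1:(nz - 1)] & fl[, 2:nz]
  act_uz[, nz + 1] <- fl[, nz]
  unk_uz <- act_uz; unk_uz[, 1] <- FALSE
  act_ur <- matrix(FALSE, nr + 1, nz)
  if (nr > 1) act_ur[2:nr, ] <- fl[1:(nr - 1), ] & fl[2:nr, ]
  list(act_uz = act_uz, unk_uz = unk_uz, act_ur = act_ur)
}

# -- discrete inlet profile --------------------------------------------------
# Parabolic profile rescaled so the discrete area-weighted mean equals U
# exactly on the masked inlet section.
.inlet_profile2d <- function(grid, U) {
  nr <- grid$nr
  fl_in <- grid$fluid[, 1]
  R_in <- grid$Rf[1]
  prof <- 2 * U * (1 - (grid$r_c / R_in)^2)
  prof[!fl_in] <- 0
  A <- grid$w_c * grid$dr
  flux <- sum(prof * A); area <- sum(A[fl_in])
  if (flux > 0) prof <- prof * (U * area / flux)
  prof
}

# -- field construction ------------------------------------------------------
.flow_init2d <- function(grid, case) {
  nr <- grid$nr; nz <- grid$nz
  field <- structure(list(
    uz = matrix(0, nr, nz + 1),
    ur = matrix(0, nr + 1, nz),
    p  = matrix(0, nr, nz),
    mu = matrix(case$props$mu0, nr, nz),
    mode = grid$mode), class = "flow_field")
  apply_boundary_conditions(field, grid, case)
}

#' Apply boundary conditions to a flow field
#'
#' Enforces the problem's boundary conditions on a staggered field: no-slip
#' (exact zeros) on every wall face, the parabolic fully developed inlet
#' profile with discrete mean exactly equal to the case's inlet speed, zero
#' transverse velocity at the inlet, and the symmetry condition on the axis
#' (zero normal velocity; the mirrored ghost values of the tangential
#' component are returned in the `ghost` attribute). The outlet is a zero
#' gauge-pressure boundary handled inside the solver; velocities there are
#' left untouched (zero-gradient).
#'
#' @param field A `flow_field` (list with `uz`, `ur`, `p`, `mu`).
#' @param grid A 2D or 3D [build_grid()] object.
#' @param case A case configuration (needs `$U`, the inlet mean speed).
#' @return The field with boundary values imposed.
#' @export
apply_boundary_conditions <- function(field, grid, case) {
  if (grid$mode == "cart3d") return(.bc3d(field, grid, case))
  m <- .masks2d(grid)
  field$uz[!m$act_uz] <- 0
  field$ur[!m$act_ur] <- 0
  field$uz[, 1] <- .inlet_profile2d(grid, case$U)
  field$ur[1, ] <- 0
  field$ur[grid$nr + 1, ] <- 0
  # axis (axisym) / lower-wall (planar) ghosts for the tangential component:
  # symmetric mirror across r = 0, antisymmetric for the normal component
  if (grid$mode == "axisym") {
    attr(field, "ghost") <- list(uz = field$uz[1, ], ur = -field$ur[2, ])
  }
  field
}

# -- cell-centred shear rate (second invariant, standard definition) ---------
.gamma_dot_2d <- function(field, grid) {
  g <- .gradients2d(field, grid)
  sqrt(2 * (g$duzdz^2 + g$durdr^2 + g$uor^2) + g$cross^2)
}

# -- coefficient assembly for the axial momentum equation --------------------
# Returns relaxed and raw coefficient sets for GS sweeps / residuals.
.coef_uz <- function(field, grid, case, settings, m) {
  nr <- grid$nr; nz <- grid$nz
  rho <- case$props$density
  uz <- field$uz; ur <- field$ur; p <- field$p; mu <- field$mu
  A_z <- grid$w_c * grid$dr                       # length nr
  dz <- grid$dz
  dzu <- c(NA, diff(grid$z_c), dz[nz] / 2)        # CV widths, index 1 unused
  DZU <- .rowmat(dzu, nr); DZU[, 1] <- 0
  # viscosity bordering each uz column: west cell k-1, east cell k
  muW <- cbind(0, mu); muE <- cbind(mu, 0)
  DZW <- .rowmat(c(dz[1], dz), nr)                # dz[k-1]; col1 unused
  DZE <- .rowmat(c(dz, dz[nz]), nr)
  De <- muE * A_z / DZE; De[, nz + 1] <- 0
  Dw <- muW * A_z / DZW; Dw[, 1] <- 0
  # convective mass fluxes through CV east/west boundaries (cell centres)
  uface_e <- 0.5 * (uz + .shE(uz)); uface_e[, nz + 1] <- pmax(uz[, nz + 1], 0)
  Fe <- rho * A_z * uface_e
  Fw <- rho * A_z * 0.5 * (.shW(uz) + uz)
  # transverse mass fluxes at the CV corners (r_f[i], z_f[k])
  tz <- c(0, (grid$z_f[2:nz] - grid$z_c[1:(nz - 1)]) / diff(grid$z_c), 1)
  ur_itp <- matrix(0, nr + 1, nz + 1)
  ur_itp[, 2:nz] <- .rowmat(1 - tz[2:nz], nr + 1) * ur[, 1:(nz - 1)] +
    .rowmat(tz[2:nz], nr + 1) * ur[, 2:nz, drop = FALSE]
  ur_itp[, nz + 1] <- ur[, nz]
  WF_n <- grid$w_f[2:(nr + 1)]; WF_s <- grid$w_f[1:nr]
  Fn <- rho * WF_n * DZU * ur_itp[2:(nr + 1), , drop = FALSE]
  Fs <- rho * WF_s * DZU * ur_itp[1:nr, , drop = FALSE]
  muX <- (muW + muE) / 2; muX[, nz + 1] <- muW[, nz + 1]
  mu_n <- 0.5 * (muX + .shNc(muX)); mu_s <- 0.5 * (muX + .shSc(muX))
  # transverse neighbour status: active uz face one radial row up/down
  nbN <- rbind(m$act_uz[-1, , drop = FALSE], FALSE)
  nbS <- rbind(FALSE, m$act_uz[-nr, , drop = FALSE])
  Dn <- mu_n * WF_n * DZU / grid$dr
  Ds <- mu_s * WF_s * DZU / grid$dr
  # wall (or stair-wall) on the transverse side: half-cell distance
  Dn <- ifelse(nbN, Dn, 2 * Dn)
  if (grid$mode == "planar") Ds <- ifelse(nbS, Ds, 2 * Ds)
  # axisym: w_f[1] = 0 makes the axis side vanish automatically
  central <- identical(settings$scheme, "central")
  if (central) {
    aE <- De - 0.5 * Fe; aW <- Dw + 0.5 * Fw
    aN <- Dn - 0.5 * Fn; aS <- Ds + 0.5 * Fs
    aE[, nz + 1] <- 0
  } else {
    aE <- De + pmax(-Fe, 0); aW <- Dw + pmax(Fw, 0)
    aN <- Dn + pmax(-Fn, 0); aS <- Ds + pmax(Fs, 0)
    aE[, nz + 1] <- 0
  }
  dF <- Fe - Fw + Fn - Fs
  aP0 <- aE + aW + aN + aS + dF
  # pressure driving force
  pW <- cbind(0, p); pE <- cbind(p, 0)
  b0 <- (pW - pE) * A_z
  b0[, 1] <- 0
  bs <- NULL
  if (identical(settings$stress_form, "full")) {
    bs <- .stress_extra_uz(field, grid, m, dzu, A_z, mu_n, mu_s,
                           WF_n, WF_s, DZU)
  }
  if (is.finite(settings$dt_pseudo)) {
    apt <- rho * A_z * DZU / settings$dt_pseudo
    aP0 <- aP0 + apt
    b0 <- b0 + apt * uz
  }
  list(aE = aE, aW = aW, aN = aN, aS = aS, aP0 = aP0, b0 = b0, bs = bs,
       sum_anb = aE + aW + aN + aS)
}

# deferred (explicit) transpose-stress terms for uz:
#   (1/w) d/dr (w mu d(ur)/dz)  and the extra  d/dz (mu d(uz)/dz)
.stress_extra_uz <- function(field, grid, m, dzu, A_z, mu_n, mu_s,
                             WF_n, WF_s, DZU) {
  nr <- grid$nr; nz <- grid$nz
  uz <- field$uz; ur <- field$ur; mu <- field$mu
  DZUc <- .rowmat(ifelse(is.na(dzu), 1, dzu), nr + 1)
  durdz_c <- (cbind(ur, ur[, nz]) - cbind(0, ur)) / DZUc
  durdz_c[, nz + 1] <- 0
  fl_n <- WF_n * DZU * mu_n * durdz_c[2:(nr + 1), , drop = FALSE]
  fl_s <- WF_s * DZU * mu_s * durdz_c[1:nr, , drop = FALSE]
  # extra zz-normal stress flux through CV east/west boundaries
  DZ <- .rowmat(grid$dz, nr)
  duzdz <- (uz[, 2:(nz + 1), drop = FALSE] - uz[, 1:nz, drop = FALSE]) / DZ
  tzz <- mu * duzdz * A_z                          # (nr, nz) at cell centres
  tzzE <- cbind(tzz, 0); tzzW <- cbind(0, tzz)
  out <- (fl_n - fl_s) + (tzzE - tzzW)
  out[, 1] <- 0
  out
}

# -- coefficient assembly for the transverse momentum equation ---------------
.coef_ur <- function(field, grid, case, settings, m) {
  nr <- grid$nr; nz <- grid$nz
  rho <- case$props$density
  uz <- field$uz; ur <- field$ur; p <- field$p; mu <- field$mu
  dz <- grid$dz
  DZ <- .rowmat(dz, nr + 1)
  # cell viscosities bordering each ur row: south cell i-1, north cell i
  muS <- rbind(0, mu); muN <- rbind(mu, 0)           # (nr+1, nz)
  WC_n <- c(grid$w_c, grid$w_c[nr]); WC_s <- c(grid$w_c[1], grid$w_c)
  Dn <- muN * WC_n * DZ / grid$dr
  Ds <- muS * WC_s * DZ / grid$dr
  Fn <- rho * WC_n * DZ * 0.5 * (ur + .shN(ur))
  Fs <- rho * WC_s * DZ * 0.5 * (.shS(ur) + ur)
  # axial faces: corner-interpolated uz
  uzc <- 0.5 * (rbind(uz[1, ], uz) + rbind(uz, 0))   # (nr+1, nz+1)
  uzc[nr + 1, ] <- 0
  WF <- grid$w_f
  FE <- rho * WF * grid$dr * uzc[, 2:(nz + 1), drop = FALSE]
  FW <- rho * WF * grid$dr * uzc[, 1:nz, drop = FALSE]
  mu_co <- .corner_mu(mu)                            # (nr+1, nz+1)
  dzc <- diff(grid$z_c)                              # node distances
  DE <- mu_co[, 2:(nz + 1), drop = FALSE] * WF * grid$dr /
    .rowmat(c(dzc, dz[nz]), nr + 1)
  DW <- mu_co[, 1:nz, drop = FALSE] * WF * grid$dr /
    .rowmat(c(dz[1], dzc), nr + 1)
  # boundary adjustments: inlet ghost ur = 0 at half-cell; outlet zero-grad
  DW[, 1] <- 2 * mu_co[, 1] * WF * grid$dr / dz[1]
  DE[, nz] <- 0
  # stair axial walls: inactive axial neighbour -> Dirichlet 0 at half-cell
  nbE <- cbind(m$act_ur[, -1, drop = FALSE], FALSE)
  nbW <- cbind(FALSE, m$act_ur[, -nz, drop = FALSE])
  intE <- col(DE) < nz
  DE <- ifelse(!nbE & intE, 2 * DE, DE)
  DW <- ifelse(!nbW & col(DW) > 1, 2 * DW, DW)
  central <- identical(settings$scheme, "central")
  if (central) {
    aN <- Dn - 0.5 * Fn; aS <- Ds + 0.5 * Fs
    aEc <- DE - 0.5 * FE; aWc <- DW + 0.5 * FW
    aEc[, nz] <- 0
  } else {
    aN <- Dn + pmax(-Fn, 0); aS <- Ds + pmax(Fs, 0)
    aEc <- DE + pmax(-FE, 0); aWc <- DW + pmax(FW, 0)
    aEc[, nz] <- pmax(-pmax(FE[, nz], 0), 0)         # outflow only
  }
  FEcl <- FE; FEcl[, nz] <- pmax(FE[, nz], 0)
  dF <- FEcl - FW + Fn - Fs
  aP0 <- aN + aS + aEc + aWc + dF
  if (grid$mode == "axisym") {
    mu_node <- 0.5 * (muS + muN)
    V <- WF * grid$dr * DZ
    hoop <- mu_node * V / pmax(grid$w_f, grid$dr / 4)^2
    hoop[1, ] <- 0
    aP0 <- aP0 + hoop
  }
  pS <- rbind(0, p); pN <- rbind(p, 0)
  b0 <- (pS - pN) * WF * DZ
  bs <- NULL
  if (identical(settings$stress_form, "full")) {
    bs <- .stress_extra_ur(field, grid, m, mu_co, WC_n, WC_s, DZ)
  }
  if (is.finite(settings$dt_pseudo)) {
    apt <- rho * WF * grid$dr * DZ / settings$dt_pseudo
    aP0 <- aP0 + apt
    b0 <- b0 + apt * ur
  }
  list(aE = aEc, aW = aWc, aN = aN, aS = aS, aP0 = aP0, b0 = b0, bs = bs,
       sum_anb = aEc + aWc + aN + aS)
}

.corner_mu <- function(mu) {
  nr <- nrow(mu); nz <- ncol(mu)
  ext <- rbind(mu[1, ], mu, mu[nr, ])                # clamp rows
  ext <- cbind(ext[, 1], ext, ext[, nz])             # clamp cols
  0.25 * (ext[1:(nr + 1), 1:(nz + 1)] + ext[2:(nr + 2), 1:(nz + 1)] +
          ext[1:(nr + 1), 2:(nz + 2)] + ext[2:(nr + 2), 2:(nz + 2)])
}

# deferred transpose-stress terms for ur:
#   d/dz (mu d(uz)/dr), extra (1/w) d/dr (w mu d(ur)/dr), extra hoop
.stress_extra_ur <- function(field, grid, m, mu_co, WC_n, WC_s, DZ) {
  nr <- grid$nr; nz <- grid$nz
  uz <- field$uz; ur <- field$ur; mu <- field$mu
  duzdr_c <- (rbind(uz, 0) - rbind(0, uz)) / grid$dr # (nr+1, nz+1)
  duzdr_c[1, ] <- 0
  fl <- mu_co * grid$w_f * grid$dr * duzdr_c
  out <- fl[, 2:(nz + 1), drop = FALSE] - fl[, 1:nz, drop = FALSE]
  durdr <- (ur[2:(nr + 1), , drop = FALSE] - ur[1:nr, , drop = FALSE]) /
    grid$dr                                          # (nr, nz) at centres
  trr <- mu * durdr
  trrN <- rbind(trr, 0) * WC_n * DZ                  # north CV face = cell i
  trrS <- rbind(0, trr) * WC_s * DZ
  out <- out + (trrN - trrS)
  if (grid$mode == "axisym") {
    mu_node <- 0.5 * (rbind(0, mu) + rbind(mu, 0))
    V <- grid$w_f * grid$dr * DZ
    rr <- pmax(grid$w_f, grid$dr / 4)
    out <- out - mu_node * ur * V / rr^2
  }
  out
}

# -- direct sparse momentum solve over the unknown mask ----------------------
# Dirichlet neighbours (inlet values, wall zeros) are folded into the RHS
# from the current field matrix; unknown-unknown links become matrix entries.
.mom_direct <- function(u, cf, aP_rel, b_rel, unk, idx) {
  n <- max(idx)
  shifts <- list(E = .shE, W = .shW, N = .shN, S = .shS)
  coefs <- list(E = cf$aE, W = cf$aW, N = cf$aN, S = cf$aS)
  ii <- idx[unk]; jj <- ii; xx <- aP_rel[unk]
  b <- b_rel
  for (d in names(shifts)) {
    nb_idx <- shifts[[d]](idx)        # neighbour unknown index (0 if none)
    nb_val <- shifts[[d]](u)
    link <- unk & nb_idx > 0
    fold <- unk & nb_idx == 0
    ii <- c(ii, idx[link]); jj <- c(jj, nb_idx[link])
    xx <- c(xx, -coefs[[d]][link])
    b[fold] <- b[fold] + coefs[[d]][fold] * nb_val[fold]
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  u[unk] <- as.numeric(Matrix::solve(A, b[unk]))
  u
}

# -- red-black Gauss-Seidel sweeps over the unknown mask ---------------------
.gs_sweeps <- function(u, cf, aP_rel, b_rel, unk, colors, nsweep) {
  for (s in seq_len(nsweep)) {
    for (colr in c(TRUE, FALSE)) {
      rhs <- b_rel + cf$aE * .shE(u) + cf$aW * .shW(u) +
        cf$aN * .shN(u) + cf$aS * .shS(u)
      sel <- unk & (colors == colr)
      u[sel] <- rhs[sel] / aP_rel[sel]
    }
  }
  u
}

.residual_l1 <- function(u, cf, unk) {
  r <- cf$aP0 * u - (cf$aE * .shE(u) + cf$aW * .shW(u) +
                     cf$aN * .shN(u) + cf$aS * .shS(u)) - cf$b0
  sum(abs(r[unk]))
}

# -- pressure-correction system ----------------------------------------------
.mass_residual2d <- function(field, grid) {
  nr <- grid$nr; nz <- grid$nz
  rho_free <- 1  # rho constant: carried outside
  DZ <- .rowmat(grid$dz, nr)
  A_z <- grid$w_c * grid$dr
  m <- grid$w_f[2:(nr + 1)] * DZ * field$ur[2:(nr + 1), , drop = FALSE] -
    grid$w_f[1:nr] * DZ * field$ur[1:nr, , drop = FALSE] +
    A_z * (field$uz[, 2:(nz + 1), drop = FALSE] -
             field$uz[, 1:nz, drop = FALSE])
  m[!grid$fluid] <- 0
  m * rho_free
}

# Build (pattern once) and solve the pressure-correction equation.
.pressure_correct <- function(state) {
  grid <- state$grid; field <- state$field
  nr <- grid$nr; nz <- grid$nz
  rho <- state$case$props$density
  A_z <- grid$w_c * grid$dr
  DZ <- .rowmat(grid$dz, nr)
  d_uz <- matrix(0, nr, nz + 1)
  d_uz[state$m$unk_uz] <- (A_z * matrix(1, nr, nz + 1))[state$m$unk_uz] /
    state$dden_uz[state$m$unk_uz]
  d_ur <- matrix(0, nr + 1, nz)
  A_r <- grid$w_f * .rowmat(grid$dz, nr + 1)
  d_ur[state$m$act_ur] <- A_r[state$m$act_ur] / state$dden_ur[state$m$act_ur]
  aE <- rho * A_z * d_uz[, 2:(nz + 1), drop = FALSE]  # face uz[, j+1]
  ghost <- aE[, nz]                                    # outlet: p' = 0
  aE[, nz] <- 0
  aW <- rho * A_z * d_uz[, 1:nz, drop = FALSE]
  aN <- rho * grid$w_f[2:(nr + 1)] * DZ * d_ur[2:(nr + 1), , drop = FALSE]
  aS <- rho * grid$w_f[1:nr] * DZ * d_ur[1:nr, , drop = FALSE]
  diagc <- aE + aW + aN + aS
  diagc[, nz] <- diagc[, nz] + ghost
  idx <- state$idx_p
  mres <- rho * .mass_residual2d(field, grid)
  fl <- grid$fluid
  if (is.null(state$p_pattern)) {
    # triplets: diagonal + east + north links (upper triangle), symmetric
    ii <- idx[fl]; jj <- idx[fl]
    i2 <- idx[, 1:(nz - 1)][fl[, 1:(nz - 1)] & fl[, 2:nz]]
    j2 <- idx[, 2:nz][fl[, 1:(nz - 1)] & fl[, 2:nz]]
    i3 <- idx[1:(nr - 1), ][fl[1:(nr - 1), ] & fl[2:nr, ]]
    j3 <- idx[2:nr, ][fl[1:(nr - 1), ] & fl[2:nr, ]]
    state$p_pattern <- list(ii = c(ii, i2, i3), jj = c(jj, j2, j3),
                            selE = fl[, 1:(nz - 1)] & fl[, 2:nz],
                            selN = fl[1:(nr - 1), ] & fl[2:nr, ])
  }
  pat <- state$p_pattern
  xE <- -aE[, 1:(nz - 1), drop = FALSE][pat$selE]
  xN <- -aN[1:(nr - 1), , drop = FALSE][pat$selN]
  xx <- c(diagc[fl], xE, xN)
  A <- Matrix::sparseMatrix(i = pat$ii, j = pat$jj, x = xx,
                            dims = c(state$np, state$np), symmetric = TRUE)
  rhs <- -mres[fl]
  if (is.null(state$p_chol)) {
    state$p_chol <- Matrix::Cholesky(A, perm = TRUE, LDL = FALSE)
  } else {
    state$p_chol <- Matrix::update(state$p_chol, A)
  }
  pc_v <- as.numeric(Matrix::solve(state$p_chol, rhs, system = "A"))
  pc <- matrix(0, nr, nz); pc[fl] <- pc_v
  # corrections
  pcW <- cbind(0, pc); pcE <- cbind(pc, 0)
  field$uz <- field$uz + d_uz * (pcW - pcE)
  pcS <- rbind(0, pc); pcN <- rbind(pc, 0)
  field$ur <- field$ur + d_ur * (pcS - pcN)
  field$p <- field$p + state$settings$alpha_p * pc
  field$uz[!state$m$act_uz] <- 0
  field$ur[!state$m$act_ur] <- 0
  state$field <- field
  invisible(state)
}

# -- one outer SIMPLE iteration ----------------------------------------------
.iter2d <- function(state) {
  grid <- state$grid; case <- state$case; st <- state$settings
  m <- state$m
  field <- state$field
  # (i) rheology update (under-relaxed: the apparent viscosity spans an
  # order of magnitude across shear layers and direct substitution can
  # limit-cycle with the momentum solve)
  gd <- .gamma_dot_2d(field, grid)
  mu_new <- matrix(williamson_viscosity(as.numeric(gd), case$props),
                   grid$nr, grid$nz)
  field$mu <- st$alpha_mu * mu_new + (1 - st$alpha_mu) * field$mu
  # (ii) momentum
  uz_prev <- field$uz; ur_prev <- field$ur
  cf_uz <- .coef_uz(field, grid, case, st, m)
  cf_ur <- .coef_ur(field, grid, case, st, m)
  # deferred-correction sources are under-relaxed across outer iterations
  # (plain explicit lagging can limit-cycle in strongly sheared cases)
  if (!is.null(cf_uz$bs)) {
    om <- st$alpha_s
    if (!is.null(state$bs_uz)) cf_uz$bs <- om * cf_uz$bs +
        (1 - om) * state$bs_uz
    if (!is.null(state$bs_ur)) cf_ur$bs <- om * cf_ur$bs +
        (1 - om) * state$bs_ur
    state$bs_uz <- cf_uz$bs; state$bs_ur <- cf_ur$bs
    cf_uz$b0 <- cf_uz$b0 + cf_uz$bs
    cf_ur$b0 <- cf_ur$b0 + cf_ur$bs
  }
  res_uz <- .residual_l1(field$uz, cf_uz, m$unk_uz)
  res_ur <- .residual_l1(field$ur, cf_ur, m$act_ur)
  mom_scale <- sum(abs((cf_uz$aP0 * field$uz)[m$unk_uz])) + state$mom_ref
  aPrel_uz <- cf_uz$aP0 / st$alpha_u
  aPrel_ur <- cf_ur$aP0 / st$alpha_u
  b_uz <- cf_uz$b0 + (1 - st$alpha_u) * aPrel_uz * uz_prev
  b_ur <- cf_ur$b0 + (1 - st$alpha_u) * aPrel_ur * ur_prev
  if (identical(st$momentum_solver, "gs")) {
    field$uz <- .gs_sweeps(field$uz, cf_uz, aPrel_uz, b_uz, m$unk_uz,
                           state$colors_uz, st$sweeps)
    field$ur <- .gs_sweeps(field$ur, cf_ur, aPrel_ur, b_ur, m$act_ur,
                           state$colors_ur, st$sweeps)
  } else {
    field$uz <- .mom_direct(field$uz, cf_uz, aPrel_uz, b_uz, m$unk_uz,
                            state$idx_uz)
    field$ur <- .mom_direct(field$ur, cf_ur, aPrel_ur, b_ur, m$act_ur,
                            state$idx_ur)
  }
  state$field <- field
  if (identical(st$pv_coupling, "simplec")) {
    # clamp: aP - sum(a_nb) can turn slightly negative through the net mass
    # imbalance term while unconverged, which would break the SPD pressure
    # operator
    state$dden_uz <- pmax(aPrel_uz - cf_uz$sum_anb, 0.02 * aPrel_uz)
    state$dden_ur <- pmax(aPrel_ur - cf_ur$sum_anb, 0.02 * aPrel_ur)
  } else {
    state$dden_uz <- aPrel_uz
    state$dden_ur <- aPrel_ur
  }
  cont_pre <- sum(abs(.mass_residual2d(field, grid))) * case$props$density
  # (iii)+(iv) pressure correction
  .pressure_correct(state)
  cont_post <- sum(abs(.mass_residual2d(state$field, grid))) *
    case$props$density
  state$residuals <- c(mom_uz = res_uz / mom_scale,
                       mom_ur = res_ur / mom_scale,
                       continuity = cont_post / state$flux_ref,
                       continuity_pre = cont_pre / state$flux_ref)
  invisible(state)
}

.state2d <- function(case, grid, field = NULL) {
  st <- case$settings
  m <- .masks2d(grid)
  if (is.null(field)) field <- .flow_init2d(grid, case)
  nr <- grid$nr; nz <- grid$nz
  idx_p <- matrix(0L, nr, nz)
  idx_p[grid$fluid] <- seq_len(sum(grid$fluid))
  A_z <- grid$w_c * grid$dr
  flux_ref <- case$props$density * sum(A_z * field$uz[, 1])
  state <- new.env(parent = emptyenv())
  state$case <- case; state$grid <- grid; state$settings <- st
  state$m <- m; state$field <- field
  state$idx_p <- idx_p; state$np <- sum(grid$fluid)
  state$colors_uz <- (outer(seq_len(nr), seq_len(nz + 1), `+`) %% 2) == 0
  state$colors_ur <- (outer(seq_len(nr + 1), seq_len(nz), `+`) %% 2) == 0
  idx_uz <- matrix(0L, nr, nz + 1)
  idx_uz[m$unk_uz] <- seq_len(sum(m$unk_uz))
  idx_ur <- matrix(0L, nr + 1, nz)
  idx_ur[m$act_ur] <- seq_len(sum(m$act_ur))
  state$idx_uz <- idx_uz; state$idx_ur <- idx_ur
  state$flux_ref <- max(flux_ref, .Machine$double.xmin)
  state$mom_ref <- max(flux_ref * case$U, .Machine$double.xmin)
  state$p_pattern <- NULL; state$p_chol <- NULL
  state
}

#' One outer SIMPLE iteration
#'
#' Performs a single pressure-velocity coupling step: recomputes the shear
#' rate and apparent viscosity, solves the under-relaxed momentum equations
#' (upwind convection, variable-viscosity diffusion), solves the
#' pressure-correction equation and corrects velocities and pressure. The
#' continuity imbalance after correction never exceeds the imbalance before.
#'
#' @param field A `flow_field`.
#' @param grid A [build_grid()] grid.
#' @param props A [fluid_properties()].
#' @param settings A [solver_settings()].
#' @param case The case configuration (inlet speed etc.); if missing, a
#'   minimal one is built from `props` and the field's inlet.
#' @return List with `field` (updated) and `residuals` (named: scaled
#'   momentum residuals per component, scaled continuity residual after and
#'   before the correction).
#' @export
simple_iterate <- function(field, grid, props, settings, case = NULL) {
  if (is.null(case)) {
    A_z <- grid$w_c * grid$dr
    U <- sum(A_z * field$uz[, 1]) / sum(A_z[grid$fluid[, 1]])
    case <- list(props = props, U = U, settings = settings)
  }
  case$settings <- settings; case$props <- props
  if (grid$mode == "cart3d") {
    state <- .state3d(case, grid, field)
    .iter3d(state)
  } else {
    state <- .state2d(case, grid, field)
    .iter2d(state)
  }
  list(field = state$field, residuals = state$residuals)
}
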