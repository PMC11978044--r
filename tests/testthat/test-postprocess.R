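test_that("derived fields satisfy their defining identities", {
  v <- cached_solution("poiseuille_24x72",
                       function() verify_poiseuille(resolution = c(24, 72)))
  sol <- v$sol
  df <- derived_fields(sol$flow, sol$grid, sol$case$props)
  rho <- sol$case$props$density
  expect_equal(df$p_dynamic, 0.5 * rho * df$speed^2)
  expect_true(all(df$p_dynamic >= 0, na.rm = TRUE))
  expect_true(all(df$cell_re >= 0, na.rm = TRUE))
  # Cp vanishes at the outlet reference section by construction
  # (area-weighted mean, the solver's own weighting)
  A <- sol$grid$w_c * sol$grid$dr
  expect_lt(abs(sum(A * df$cp[, sol$grid$nz]) / sum(A)), 1e-10)
  # hand arithmetic: |u| = 5, rho = 2 -> p_dyn = 25
  expect_equal(0.5 * 2 * sqrt(3^2 + 4^2)^2, 25)
  expect_error(derived_fields(sol$flow, sol$grid, sol$case$props,
                              U_ref = -1), "U_ref")
})

test_that("pressure coefficient is linear along the centerline of Poiseuille flow", {
  v <- cached_solution("poiseuille_24x72",
                       function() verify_poiseuille(resolution = c(24, 72)))
  prof <- extract_line(v$sol, "pressure-coefficient", "centerline")
  fit <- stats::lm(value ~ coordinate, data = prof)
  expect_lt(max(abs(stats::residuals(fit))) / diff(range(prof$value)), 0.01)
})

test_that("zero-velocity fields give zero dynamic pressure, Cp and pressure drop", {
  grid <- build_grid(lumen_geometry(0.002, 0.02), c(12, 36), "axisym")
  flow <- structure(list(uz = matrix(0, 12, 37), ur = matrix(0, 13, 36),
                         p = matrix(0, 12, 36), mu = matrix(1, 12, 36),
                         mode = "axisym"), class = "flow_field")
  pd <- pressure_drop(flow, grid)
  expect_equal(pd$dp, 0)
  df <- derived_fields(flow, grid, fluid_properties(), U_ref = 1)
  expect_true(all(df$p_dynamic == 0, na.rm = TRUE))
  expect_true(all(df$cp == 0, na.rm = TRUE))
})

test_that("Stokes stream function is zero on the axis and flux-invariant at the wall", {
  v <- cached_solution("poiseuille_24x72",
                       function() verify_poiseuille(resolution = c(24, 72)))
  sol <- v$sol
  psi <- stream_function(sol$flow, sol$grid)
  expect_equal(psi[1, ], rep(0, sol$grid$nz + 1))
  Q <- section_flow_rates(sol$flow, sol$grid)[1]
  expect_equal(psi[sol$grid$nr + 1, ], rep(Q / (2 * pi), sol$grid$nz + 1),
               tolerance = 1e-9)
  # analytic shape: psi = U (r^2 - r^4 / 2R^2) for the parabolic profile
  U <- sol$case$U
  psi_exact <- poiseuille_stream_oracle(sol$grid$r_f, 0.002, U)
  expect_lt(max(abs(psi[, sol$grid$nz] - psi_exact)) / max(psi_exact), 0.01)
  # unsupported mode raises a clear error
  expect_error(stream_function(list(mode = "cart3d"),
                               structure(list(mode = "cart3d"),
                                         class = "flow_grid")),
               "axisymmetric")
})

test_that("line extraction honours the oracle values, no-slip and determinism", {
  v <- cached_solution("poiseuille_24x72",
                       function() verify_poiseuille(resolution = c(24, 72)))
  sol <- v$sol
  center <- extract_line(sol, "velocity-magnitude", "centerline")
  zmask <- center$coordinate > 0.01
  expect_true(all(abs(center$value[zmask] - 2 * sol$case$U) /
                    (2 * sol$case$U) < 0.01))
  rad <- extract_line(sol, "velocity-magnitude", "radial", at = 0.015)
  expect_equal(rad$value[nrow(rad)], 0)              # wall point, no-slip
  expect_true(all(diff(rad$coordinate) > 0))
  rad2 <- extract_line(sol, "velocity-magnitude", "radial", at = 0.015)
  expect_identical(rad, rad2)
  expect_error(extract_line(sol, "velocity-magnitude", "radial", at = 1),
               "outside")
})

test_that("pressure drop matches Hagen-Poiseuille and pre/post means are ordered", {
  v <- cached_solution("poiseuille_24x72",
                       function() verify_poiseuille(resolution = c(24, 72)))
  pd <- pressure_drop(v$sol$flow, v$sol$grid)
  expect_lt(abs(pd$dp - v$dp_oracle) / v$dp_oracle, 0.01)
  expect_gt(pd$p_pre, pd$p_post)    # pressure falls downstream in a tube
})

test_that("pathlines advance seeds through a 3D duct", {
  ve <- cached_solution("elliptic_16",
                        function() verify_elliptic(resolution = c(16, 16, 32),
                                                   max_outer = 200))
  sol <- ve$sol
  seeds <- cbind(0, 0, sol$grid$z_c[2])
  pl <- pathlines(sol$flow, sol$grid, seeds, n_steps = 50)
  expect_gt(nrow(pl[[1]]), 5)
  expect_true(all(diff(pl[[1]][, 3]) > 0))    # moves downstream
})
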