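test_that("boundary conditions impose no-slip, inlet mean and axis mirror", {
  case <- straight_case(c(16, 48))
  grid <- build_grid(case$geometry, case$resolution, case$mode)
  field <- stenoflow:::.flow_init2d(grid, case)
  m <- stenoflow:::.masks2d(grid)
  # wall faces exactly zero
  expect_true(all(field$uz[!m$act_uz] == 0))
  expect_true(all(field$ur[!m$act_ur] == 0))
  expect_equal(field$ur[1, ], rep(0, grid$nz))
  expect_equal(field$ur[grid$nr + 1, ], rep(0, grid$nz))
  # discrete inlet mean equals U exactly
  A <- grid$w_c * grid$dr
  expect_equal(sum(A * field$uz[, 1]) / sum(A), case$U)
  # axis ghost mirrors the interior (zero radial gradient of uz)
  gh <- attr(field, "ghost")
  expect_identical(gh$uz, field$uz[1, ])
  expect_identical(gh$ur, -field$ur[2, ])
})

test_that("solver reproduces Hagen-Poiseuille at coarse resolution", {
  v <- cached_solution("poiseuille_24x72",
                       function() verify_poiseuille(resolution = c(24, 72)))
  expect_true(v$converged)
  expect_lt(v$err_centerline, 0.01)
  expect_lt(v$err_dp, 0.01)
  expect_lt(v$err_mass_global, 1e-10)
  expect_lt(v$err_mass_sections, 1e-10)
})

test_that("an outer iteration leaves a converged state converged and reduces mass imbalance", {
  v <- cached_solution("poiseuille_24x72",
                       function() verify_poiseuille(resolution = c(24, 72)))
  sol <- v$sol
  case <- sol$case
  one <- simple_iterate(sol$flow, sol$grid, case$props, case$settings,
                        case = case)
  expect_lt(one$residuals[["mom_uz"]], case$settings$tol_mom * 2)
  # perturbed (divergent) field: the correction step must not increase the
  # continuity imbalance
  set.seed(7)
  f2 <- sol$flow
  f2$uz <- f2$uz * (1 + 0.05 * matrix(runif(length(f2$uz)), nrow(f2$uz)))
  f2 <- apply_boundary_conditions(f2, sol$grid, case)
  two <- simple_iterate(f2, sol$grid, case$props, case$settings, case = case)
  expect_lte(two$residuals[["continuity"]],
             two$residuals[["continuity_pre"]] + 1e-14)
})

test_that("momentum under-relaxation freezes the field as alpha_u -> 0", {
  v <- cached_solution("poiseuille_24x72",
                       function() verify_poiseuille(resolution = c(24, 72)))
  sol <- v$sol
  case <- sol$case
  st <- quick_settings(alpha_u = 1e-9, alpha_p = 1e-9)
  # perturb the pressure only: the field stays solenoidal, so the iteration
  # can move the velocity only through the (frozen) momentum solve
  f2 <- sol$flow
  f2$p <- f2$p * 1.2 + 5
  out <- simple_iterate(f2, sol$grid, case$props, st, case = case)
  rel <- max(abs(out$field$uz - f2$uz)) / max(abs(f2$uz))
  expect_lt(rel, 1e-6)
})

test_that("Williamson pipe flow matches the 1D quadrature oracle and flattens", {
  vw <- cached_solution("williamson_24x72",
                        function() verify_williamson(resolution = c(24, 72)))
  expect_true(vw$converged)
  expect_lt(vw$err_profile, 0.02)
  expect_lt(vw$ratio_center_mean, 2)
  expect_gt(vw$ratio_center_mean, 1)   # still a maximum on the axis
})

test_that("central advection scheme also recovers Poiseuille", {
  v <- verify_poiseuille(resolution = c(16, 48),
                         settings = quick_settings(scheme = "central"))
  expect_true(v$converged)
  expect_lt(v$err_centerline, 0.01)
})

test_that("stenosed solves conserve mass through every cross-section", {
  for (nm in c("s40", "s60")) {
    v <- canonical_conservation(nm, resolution = c(20, 60))
    expect_true(v$converged)
    expect_lt(v$err_mass_sections, 1e-10)
    expect_equal(v$throat_speedup, v$area_ratio, tolerance = 1e-12)
  }
})

test_that("solver flags non-convergence instead of failing", {
  case <- make_case("s60", resolution = c(16, 48),
                    settings = quick_settings(max_outer = 2L),
                    thermal = list(enabled = FALSE))
  sol <- solve_steady(case)
  expect_false(sol$history$converged)
  expect_equal(sol$history$iterations, 2L)
})

test_that("reruns are bitwise reproducible", {
  case <- straight_case(c(12, 36))
  s1 <- solve_steady(case)
  s2 <- solve_steady(case)
  expect_identical(s1$flow$uz, s2$flow$uz)
  expect_identical(s1$flow$p, s2$flow$p)
})
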