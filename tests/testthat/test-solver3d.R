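test_that("coarse elliptic duct solve stays within 5% of the analytic profile", {
  ve <- cached_solution("elliptic_16",
                        function() verify_elliptic(resolution = c(16, 16, 32),
                                                   max_outer = 200))
  expect_true(ve$converged)
  expect_lt(ve$err_linf, 0.05)
})

test_that("3D boundary conditions zero the wall faces and scale the inlet", {
  geom <- lumen_geometry(0.002, 0.008, ellipse_ratio = 0.5)
  grid <- build_grid(geom, c(12, 12, 16), "cart3d")
  case <- list(U = 0.02, props = newtonian_properties())
  field <- stenoflow:::.flow_init3d(grid, case)
  m <- stenoflow:::.masks3d(grid)
  expect_true(all(field$w[!m$act_w] == 0))
  expect_true(all(field$u[!m$act_u] == 0))
  expect_true(all(field$v[!m$act_v] == 0))
  w_in <- field$w[, , 1]
  expect_equal(sum(w_in) / sum(grid$fluid[, , 1]), case$U)
})

test_that("3D mass conservation improves with convergence of the outer loop", {
  ve <- cached_solution("elliptic_16",
                        function() verify_elliptic(resolution = c(16, 16, 32),
                                                   max_outer = 200))
  q <- section_flow_rates(ve$sol$flow, ve$sol$grid)
  expect_lt(max(abs(q - q[1])) / q[1], 1e-4)
})

test_that("3D temperature solve respects the maximum principle", {
  ve <- cached_solution("elliptic_16",
                        function() verify_elliptic(resolution = c(16, 16, 32),
                                                   max_outer = 200))
  sol <- ve$sol
  props <- newtonian_properties()
  groups <- dimensionless_groups(props, 0.02, 0.02)
  temp <- solve_energy(sol$flow, sol$grid, props, groups,
                       bc = list(theta_wall = 1, theta_in = 0,
                                 dissipation = FALSE))
  expect_true(temp$converged)
  th <- temp$theta[sol$grid$fluid]
  expect_true(all(th >= -1e-9 & th <= 1 + 1e-9))
})
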