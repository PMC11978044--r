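test_that("homogeneous thermal problem yields an identically zero field", {
  case <- straight_case(c(12, 36))
  sol <- solve_steady(case)
  groups <- dimensionless_groups(case$props, case$U, 0.02)
  temp <- solve_energy(sol$flow, sol$grid, case$props, groups,
                       bc = list(theta_wall = 0, theta_in = 0,
                                 dissipation = FALSE))
  expect_true(all(abs(temp$theta) < 1e-12, na.rm = TRUE))
})

test_that("discrete maximum principle holds without dissipation", {
  case <- make_case("s60", resolution = c(16, 48),
                    settings = quick_settings(),
                    thermal = list(enabled = FALSE))
  sol <- solve_steady(case)
  groups <- dimensionless_groups(case$props, case$U, 0.02)
  temp <- solve_energy(sol$flow, sol$grid, case$props, groups,
                       bc = list(theta_wall = 1, theta_in = 0,
                                 dissipation = FALSE))
  th <- temp$theta[sol$grid$fluid]
  expect_true(all(th >= -1e-12 & th <= 1 + 1e-12))
})

test_that("dissipation source is pointwise non-negative in both groupings", {
  vw <- cached_solution("williamson_24x72",
                        function() verify_williamson(resolution = c(24, 72)))
  for (form in c("printed", "standard")) {
    phi <- dissipation_function(vw$sol$flow, vw$sol$grid, form)
    expect_true(all(phi >= 0))
  }
})

test_that("Couette flow with viscous heating matches the closed form", {
  vc <- verify_couette(resolution = c(24, 48))
  expect_lt(vc$err_mid, 0.01)
  # full cross-gap profile shape, not just the mid value
  expect_lt(max(abs(vc$theta_sim - vc$theta_exact)) / (vc$Br / 8), 0.02)
})

test_that("energy balances at Br = 0: wall heat inflow equals advected outflow", {
  case <- straight_case(c(24, 72))
  sol <- solve_steady(case)
  grid <- sol$grid
  props <- case$props
  groups <- dimensionless_groups(props, case$U, 0.02)
  temp <- solve_energy(sol$flow, grid, props, groups,
                       bc = list(theta_wall = 1, theta_in = 0,
                                 dissipation = FALSE))
  beta <- props$k / (props$density * props$cp)
  th <- temp$theta
  nr <- grid$nr; nz <- grid$nz
  # wall diffusive inflow (outer wall, half-cell one-sided gradient)
  q_wall <- sum(beta * grid$w_f[nr + 1] * grid$dz *
                  (1 - th[nr, ]) / (grid$dr / 2))
  # inlet diffusive inflow (theta_in = 0 boundary)
  A <- grid$w_c * grid$dr
  q_inlet_diff <- sum(2 * beta * A * (0 - th[, 1]) / grid$dz[1])
  # net advective enthalpy outflow (theta_in = 0 at the inlet)
  q_adv <- sum(A * sol$flow$uz[, nz + 1] * th[, nz])
  expect_lt(abs(q_wall + q_inlet_diff - q_adv) / q_adv, 0.01)
})

test_that("thermal boundary layers thin as the Prandtl number grows", {
  case <- straight_case(c(24, 72))
  sol <- solve_steady(case)
  props0 <- case$props
  grads <- vapply(c(0.7, 2, 5), function(Pr) {
    k <- props0$cp * props0$mu0 / Pr
    props <- newtonian_properties(mu = props0$mu0, k = k, cp = props0$cp)
    groups <- dimensionless_groups(props, case$U, 0.02)
    temp <- solve_energy(sol$flow, sol$grid, props, groups,
                         bc = list(theta_wall = 1, theta_in = 0,
                                   dissipation = FALSE))
    stenoflow:::.wall_theta_gradient(list(grid = sol$grid,
                                          temperature = temp))
  }, numeric(1))
  expect_true(all(diff(grads) > 0))
})

test_that("temperature field responds to the Brinkman group through the scale", {
  case <- straight_case(c(16, 48))
  sol <- solve_steady(case)
  props <- case$props
  theta_peak <- vapply(c(0.1, 1), function(Br) {
    dT <- props$mu0 * case$U^2 / (props$k * Br)
    groups <- dimensionless_groups(props, case$U, 0.02,
                                   Ti = 310, Tb = 310 + dT)
    temp <- solve_energy(sol$flow, sol$grid, props, groups,
                         bc = list(theta_wall = 0, theta_in = 0,
                                   dissipation = TRUE))
    max(temp$theta, na.rm = TRUE)
  }, numeric(1))
  # linear problem: the dissipation-driven theta scales with Br
  expect_equal(theta_peak[2] / theta_peak[1], 10, tolerance = 1e-6)
})
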