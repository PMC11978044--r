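test_that("shear-rate invariant matches hand-evaluated flows", {
  # simple shear du/dy = kappa: gamma_12 = gamma_21 = kappa
  G <- matrix(0, 3, 3); G[1, 2] <- 2.5
  expect_equal(shear_rate_magnitude(G), 2.5)
  # rigid rotation: antisymmetric gradient, symmetric part vanishes
  W <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 0), 3, 3)
  expect_equal(shear_rate_magnitude(W), 0)
  # incompressible uniaxial extension at rate e: gdot = sqrt(3) e
  e <- 0.7
  expect_equal(shear_rate_magnitude(diag(c(e, -e / 2, -e / 2))),
               sqrt(3) * e)
})

test_that("shear rate and stress invariants are frame-indifferent", {
  set.seed(42)
  for (i in 1:20) {
    G <- matrix(rnorm(9), 3, 3)
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    Gr <- Q %*% G %*% t(Q)
    expect_equal(shear_rate_magnitude(Gr), shear_rate_magnitude(G),
                 tolerance = 1e-12)
    S <- suppressWarnings(extra_stress_tensor(G, 0.01, 0.1))
    Sr <- suppressWarnings(extra_stress_tensor(Gr, 0.01, 0.1))
    expect_equal(sum(Sr^2), sum(S^2), tolerance = 1e-10)
  }
})

test_that("Williamson viscosity has the printed-law limits and monotonicity", {
  props <- fluid_properties(mu0 = 0.056, mu_inf = 0.00345, lambda = 3.313)
  expect_equal(williamson_viscosity(0, props), props$mu0)
  expect_lt(williamson_viscosity(1e9, props) - props$mu_inf, 1e-9)
  # lambda * gdot = 1: halfway between the plateaus
  expect_equal(williamson_viscosity(1 / props$lambda, props),
               props$mu_inf + (props$mu0 - props$mu_inf) / 2)
  gd <- 10^seq(-3, 4, length.out = 60)
  mu <- williamson_viscosity(gd, props)
  expect_true(all(diff(mu) < 0))
  expect_true(all(mu > props$mu_inf & mu <= props$mu0))
  expect_error(williamson_viscosity(-1, props), "shear rate")
  # lambda = 0: Newtonian at mu0 for every shear rate
  newt <- newtonian_properties(mu = 0.004)
  expect_equal(williamson_viscosity(gd, newt), rep(0.004, length(gd)))
})

test_that("linear extra-stress form reduces correctly and warns out of range", {
  expect_equal(extra_stress_tensor(matrix(0, 3, 3), 0.01, 1),
               matrix(0, 3, 3))
  kap <- 3
  G <- matrix(0, 3, 3); G[1, 2] <- kap
  S0 <- extra_stress_tensor(G, 0.01, 0)            # Newtonian limit
  expect_equal(S0[1, 2], 0.01 * kap)
  S <- extra_stress_tensor(G, 0.01, 0.2)
  expect_equal(S[1, 2], 0.01 * (1 + 0.2 * kap) * kap)
  expect_equal(S, t(S))
  # traceless for incompressible gradients
  Gi <- matrix(rnorm(9, sd = 0.1), 3, 3); diag(Gi) <- c(1, 2, -3) * 0.01
  Si <- extra_stress_tensor(Gi, 0.01, 0.5)
  expect_equal(sum(diag(Si)), 0, tolerance = 1e-15)
  expect_warning(extra_stress_tensor(G, 0.01, 1), "validity")
})
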