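test_that("dimensionless groups match their defining arithmetic", {
  props <- fluid_properties(density = 1000, mu0 = 0.001, mu_inf = 0.001,
                            lambda = 0, k = 0.6, cp = 4180)
  g <- dimensionless_groups(props, u0 = 0.01, L = 0.01)
  expect_equal(g$Re, 100)
  props2 <- fluid_properties(mu0 = 0.00345, mu_inf = 0.00345, lambda = 0,
                             k = 0.52, cp = 3617)
  g2 <- dimensionless_groups(props2, u0 = 0.01, L = 0.01)
  expect_equal(signif(g2$Pr, 3), 24.0)
  # Br is quadratic in u0: no dissipation without motion
  g3 <- dimensionless_groups(props2, u0 = 0.001, L = 0.01)
  expect_equal(g3$Br / g2$Br, 0.01)
  expect_error(dimensionless_groups(props, 0.01, 0.01, Ti = 310, Tb = 310),
               "degenerate")
})

test_that("the group identity Re*Pr = u0*L/beta holds for random parameters", {
  set.seed(11)
  for (i in 1:25) {
    props <- fluid_properties(density = runif(1, 800, 1600),
                              mu0 = runif(1, 0.002, 0.08),
                              mu_inf = 0.001, lambda = runif(1, 0, 5),
                              k = runif(1, 0.2, 0.8),
                              cp = runif(1, 1000, 5000))
    u0 <- runif(1, 0.001, 0.5); L <- runif(1, 0.005, 0.1)
    g <- dimensionless_groups(props, u0, L)
    expect_equal(g$Re * g$Pr, u0 * L / g$beta, tolerance = 1e-12)
  }
})

test_that("canonical cases map to the study's stenosis degrees", {
  degs <- vapply(c("healthy", "s40", "s60", "s80"), function(nm) {
    case <- make_case(nm)
    st <- case$geometry$stenosis
    if (is.null(st)) 0 else st$degree
  }, numeric(1))
  expect_equal(unname(degs), c(0, 0.4, 0.6, 0.8))
  expect_error(make_case("s90"), "healthy, s40, s60, s80")
})

test_that("run_case writes the full manifest and flags non-convergence", {
  outdir <- file.path(tempdir(), "sf_case")
  case <- make_case("healthy", resolution = c(12, 36),
                    settings = quick_settings(),
                    U = 0.02, props = newtonian_properties())
  res <- run_case(case, outdir)
  expect_true(res$converged)
  expect_equal(res$summary$status, 0L)
  # 1 field file + 7 profile CSVs + convergence log + summary + config echo
  expect_equal(length(res$manifest), 11L)
  expect_true(all(file.exists(res$manifest)))
  # identical rerun: bitwise-identical outputs
  outdir2 <- file.path(tempdir(), "sf_case2")
  res2 <- run_case(case, outdir2)
  for (i in seq_along(res$manifest)) {
    expect_identical(readLines(res$manifest[i]),
                     readLines(res2$manifest[i]))
  }
  # iteration-starved stenosed case: flagged, nonzero status
  case2 <- make_case("s60", resolution = c(16, 48),
                     settings = quick_settings(max_outer = 1L))
  expect_warning(res3 <- run_case(case2, file.path(tempdir(), "sf_case3")),
                 "did not converge")
  expect_gt(res3$summary$status, 0)
})

test_that("a written config re-runs to bitwise-identical fields", {
  case <- make_case("s40", resolution = c(16, 48),
                    settings = quick_settings(),
                    thermal = list(enabled = FALSE))
  f <- tempfile(fileext = ".yml")
  write_case_config(case, f)
  back <- read_case_config(f)
  s1 <- solve_steady(case)
  s2 <- solve_steady(back)
  expect_identical(s1$flow$uz, s2$flow$uz)
  expect_identical(s1$flow$p, s2$flow$p)
})

test_that("sweeps align profiles and respond monotonically", {
  base <- make_case("healthy", resolution = c(16, 48),
                    settings = quick_settings())
  sw <- run_sweep(base, "Pr", c(0.7, 2, 5))
  expect_length(sw$profiles, 3)
  expect_identical(sw$profiles[[1]]$coordinate, sw$profiles[[2]]$coordinate)
  expect_identical(sw$profiles[[1]]$coordinate, sw$profiles[[3]]$coordinate)
  # thermal boundary layer thins: wall-adjacent gradient grows with Pr
  expect_true(all(diff(sw$summary$wall_theta_gradient) > 0))
  sw2 <- run_sweep(base, "degree", c(0, 0.4, 0.6),
                   axis_at = 0.01)
  expect_true(all(diff(sw2$summary$dp) > 0))
  expect_true(all(diff(sw2$summary$peak_velocity) > 0))
  expect_error(run_sweep(base, "nonsense$path", 1), "unresolvable")
  expect_error(run_sweep(base, "Pr", numeric(0)), "non-empty")
})

test_that("the quick validation tier passes and zero tolerances fail by contract", {
  rep <- cached_solution("validate_quick", function() validate_suite("quick"))
  expect_true(all(rep$pass))
  zeros <- as.list(rep(0, nrow(rep)))
  names(zeros) <- rep$check
  rep0 <- validate_suite("quick", tolerances = zeros)
  expect_false(any(rep0$pass))
})

test_that("VTK export writes a parseable rectilinear grid", {
  v <- cached_solution("poiseuille_24x72",
                       function() verify_poiseuille(resolution = c(24, 72)))
  f <- tempfile(fileext = ".vtk")
  write_vtk(v$sol, f)
  lines <- readLines(f)
  expect_equal(lines[4], "DATASET RECTILINEAR_GRID")
  expect_match(lines[5], "DIMENSIONS 25 73 1")
  expect_true(any(grepl("SCALARS pressure", lines)))
  expect_true(any(grepl("VECTORS velocity", lines)))
})
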