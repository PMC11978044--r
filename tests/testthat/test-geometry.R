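test_that("radius profile narrows by the stenosis degree at the throat and is smooth", {
  R0 <- 1; L <- 10
  for (s in c(0.4, 0.6, 0.8)) {
    g <- lumen_geometry(R0, L, stenosis = stenosis_spec(s, 2, 5))
    # unnarrowed outside the stenotic window
    expect_equal(radius_profile(c(0, 3.9, 6.1, L), g), rep(R0, 4))
    # throat: fractional diameter reduction s
    expect_equal(radius_profile(5, g), R0 * (1 - s))
    # C1 profile: numerically small slope at the window edges
    eps <- 1e-6
    expect_lt(abs(radius_profile(4 + eps, g) - radius_profile(4, g)) / eps,
              1e-4)
  }
  # direct evaluation of the cosine bump: cos(pi/2) = 0 at zc + Ls/4
  g8 <- lumen_geometry(1, 10, stenosis = stenosis_spec(0.8, 2, 5))
  expect_equal(radius_profile(5.5, g8), 0.6)
})

test_that("radius profile is symmetric about the throat", {
  g <- lumen_geometry(1, 10, stenosis = stenosis_spec(0.6, 2.5, 5))
  d <- seq(0, 1.25, length.out = 21)
  expect_equal(radius_profile(5 - d, g), radius_profile(5 + d, g))
})

test_that("geometry constructors enforce their invariants", {
  expect_error(stenosis_spec(1.0, 1, 5), "degree")
  expect_error(stenosis_spec(-0.1, 1, 5), "degree")
  expect_error(stenosis_spec(0.4, -1, 5), "length")
  expect_error(lumen_geometry(1, 10, stenosis = stenosis_spec(0.4, 4, 1)),
               "window")
  expect_error(lumen_geometry(1, 10, ellipse_ratio = 0), "ellipse_ratio")
  g <- lumen_geometry(1, 10)
  expect_error(radius_profile(11, g), "outside")
})

test_that("elliptic sections preserve the cross-sectional area exactly", {
  g <- lumen_geometry(1, 10, ellipse_ratio = 0.5,
                      stenosis = stenosis_spec(0.6, 2, 5))
  ab <- ellipse_section(0, g)
  expect_equal(ab$a, sqrt(2))
  expect_equal(ab$b, 1 / sqrt(2))
  for (kappa in c(1, 0.7, 0.5, 0.25)) {
    gk <- lumen_geometry(1, 10, ellipse_ratio = kappa,
                         stenosis = stenosis_spec(0.8, 2, 5))
    z <- seq(0, 10, length.out = 41)
    ab <- ellipse_section(z, gk)
    expect_equal(pi * ab$a * ab$b, pi * radius_profile(z, gk)^2)
  }
  # circle limit and boundary containment
  ab1 <- ellipse_section(0, lumen_geometry(1, 10))
  expect_equal(c(ab1$a, ab1$b), c(1, 1))
  abg <- ellipse_section(0, g)
  expect_true(ellipse_contains(abg$a, 0, 0, g))          # on the boundary
  expect_false(ellipse_contains(abg$a * (1 + 1e-9), 0, 0, g))
})

test_that("grids honour the cell-count contract and refuse unresolved throats", {
  g <- lumen_geometry(1, 10)
  grid <- build_grid(g, c(4, 8), "axisym")
  expect_equal(grid$n_cells, 32)
  expect_equal(grid$n_fluid, 32)
  expect_error(build_grid(g, c(3, 8), "axisym"), "resolution")
  g8 <- lumen_geometry(1, 10, stenosis = stenosis_spec(0.8, 2, 5))
  expect_error(build_grid(g8, c(8, 24), "axisym"), "throat")
})

test_that("cartesian mask area converges to the analytic ellipse area", {
  g <- lumen_geometry(1, 4)                      # circle, kappa = 1
  grid <- build_grid(g, c(128, 128, 4), "cart3d")
  frac <- sum(grid$fluid[, , 1]) / (grid$nx * grid$ny)
  expect_lt(abs(frac - pi / 4) / (pi / 4), 0.02)
})

test_that("cartesian mask volume matches the quadrature lumen volume", {
  g <- lumen_geometry(1, 10, ellipse_ratio = 0.5,
                      stenosis = stenosis_spec(0.6, 2, 5))
  grid <- build_grid(g, c(96, 96, 96), "cart3d")
  vol_mask <- sum(grid$fluid) * grid$dx * grid$dy * grid$dz[1]
  expect_lt(abs(vol_mask - lumen_volume(g)) / lumen_volume(g), 0.02)
})

test_that("axial clustering concentrates cells in the stenotic window", {
  g <- lumen_geometry(1, 10, stenosis = stenosis_spec(0.6, 2, 5))
  grid <- build_grid(g, c(16, 48), "axisym", clustering = 2)
  j_min <- which.min(grid$dz)
  expect_true(abs(grid$z_c[j_min] - 5) <= 1)
  expect_lt(min(grid$dz), max(grid$dz))
  # mask stays a single axial band per column (connectivity)
  expect_true(all(apply(grid$fluid, 2, function(col) {
    r <- rle(col)$values
    sum(r) == 1 && r[1]
  })))
})

test_that("geometry round-trips through the case config file", {
  case <- make_case("s60", ellipse_ratio = 0.5, resolution = c(12, 36))
  f <- tempfile(fileext = ".yml")
  write_case_config(case, f)
  back <- read_case_config(f)
  expect_equal(back$geometry$base_radius, case$geometry$base_radius)
  expect_equal(back$geometry$stenosis$degree, 0.6)
  expect_equal(back$geometry$ellipse_ratio, 0.5)
  expect_equal(back$props$mu0, case$props$mu0)
  expect_equal(back$U, case$U)
  expect_equal(back$resolution, case$resolution)
})
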