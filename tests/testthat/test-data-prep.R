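test_that("axial rescaling maps poles and midpoints as stated", {
  expect_equal(rescale_axial(10, z_max = 10, z_min = 0, "celegans"), 0)
  expect_equal(rescale_axial(0, z_max = 10, z_min = 0, "celegans"), 55 / 13)
  expect_equal(rescale_axial(5, z_max = 10, z_min = 0, "mouse"), 1.0)
  # affine and order-preserving
  z <- c(2, 4, 7)
  d <- rescale_axial(z, 10, 0, "mouse")
  expect_true(all(diff(d) < 0)) # larger z is closer to the source
  expect_equal(rescale_axial(d * 0 + z, 10, 0, "mouse"), d)
  expect_error(rescale_axial(1, 5, 5), "exceed")
  expect_error(rescale_axial(12, 10, 0, "mouse"), "outside")
})

test_that("radial fitting anchors the outermost points on the boundary", {
  sph <- make_sphere()
  z <- rep(0, 5)
  r_raw <- c(10, 30, 50, 70, 90) # arbitrary image units
  fr <- fit_radial(z, r_raw, sph, n_bins = 10)
  expect_equal(fr$r[1L], -sph$F(0), tolerance = 1e-12)
  expect_equal(fr$r[5L], sph$F(0), tolerance = 1e-12)
  expect_equal(fr$r[3L], 0, tolerance = 1e-12) # midway point maps to the axis
  expect_false(any(fr$flagged))
  # points already spanning [-F, F] are a fixed point of the map
  r_span <- seq(-sph$F(0), sph$F(0), length.out = 7)
  fr2 <- fit_radial(rep(0, 7), r_span, sph, n_bins = 10)
  expect_equal(fr2$r, r_span, tolerance = 1e-12)
  # a lone point in its station is centred and flagged
  fr3 <- fit_radial(c(0, 0.9), c(5, 5), sph, n_bins = 4)
  expect_true(all(fr3$flagged))
  expect_equal(fr3$r, c(0, 0))
})

test_that("cortical projection is the signed tangential component", {
  sph <- make_sphere()
  z0 <- 0.6 # boundary point (0.6, 0.8); tangent towards drain
  d1 <- sph$dF(z0)
  tangent <- -c(1, d1) / sqrt(1 + d1^2)
  v <- tangent # unit velocity along the tangent
  pc <- project_cortical(z0, 0.8, v[1L], v[2L], sph)
  expect_equal(pc$v_t, 1, tolerance = 1e-12)
  normal <- c(-d1, 1) / sqrt(1 + d1^2)
  pc2 <- project_cortical(z0, 0.8, normal[1L], normal[2L], sph)
  expect_equal(pc2$v_t, 0, tolerance = 1e-12)
  diag45 <- (tangent + normal) # magnitude sqrt(2) at 45 degrees
  pc3 <- project_cortical(z0, 0.8, diag45[1L], diag45[2L], sph)
  expect_equal(pc3$v_t, 1, tolerance = 1e-12)
  # lower half-plane mirrors v_r before projecting
  pc4 <- project_cortical(z0, -0.8, v[1L], -v[2L], sph)
  expect_equal(pc4$v_t, 1, tolerance = 1e-12)
})

test_that("observation tables round-trip losslessly through the sheet layout", {
  sph <- make_sphere()
  set.seed(20)
  n <- 25
  z <- runif(n, -0.9, 0.9)
  r <- runif(n, -0.8, 0.8) * sph$F(z)
  obs <- observations(z, r, rnorm(n), rnorm(n), shape = sph)
  path <- file.path(tempdir(), "Mm1.csv")
  on.exit(unlink(path))
  write_observations(obs, path, shape = sph)
  obs2 <- read_observations(path)
  expect_equal(obs2$points$z, obs$points$z, tolerance = 1e-12)
  expect_equal(obs2$points$r, obs$points$r, tolerance = 1e-12)
  expect_equal(obs2$points$v_z, obs$points$v_z, tolerance = 1e-12)
  expect_equal(obs2$points$v_r, obs$points$v_r, tolerance = 1e-12)
  expect_equal(obs2$cell, "Mm1") # label and implied sphere recognised
})

test_that("malformed rows are dropped with a warning and bad files refused", {
  path <- file.path(tempdir(), "Ce2.csv")
  on.exit(unlink(path))
  writeLines(c("D(Sc(z)),Sc(r),v_z,v_r",
               "1.0,0.2,0.05,-0.01",
               "2.0,oops,0.04,0.00",
               "3.0,-0.4,0.03,0.02"), path)
  expect_warning(obs <- read_observations(path), "1 malformed")
  expect_equal(obs$n, 2L)
  expect_equal(obs$cell, "Ce2")
  writeLines(c("a,b", "1,2"), path)
  expect_error(suppressWarnings(read_observations(path)), "missing columns")
  # unrecognised stem needs an explicit shape
  path2 <- file.path(tempdir(), "cellX.csv")
  on.exit(unlink(path2), add = TRUE)
  writeLines(c("D(Sc(z)),Sc(r),v_z,v_r", "1.0,0.2,0.05,-0.01"), path2)
  expect_error(read_observations(path2), "infer")
  expect_s3_class(read_observations(path2, shape = make_sphere()),
                  "observations")
})

test_that("points outside the boundary are rejected on construction", {
  sph <- make_sphere()
  expect_error(observations(0, 1.2, 0, 0, shape = sph), "outside")
  expect_error(observations(c(0, 0.5), c(0.2, NA), c(0, 0), c(0, 0)),
               "missing")
})
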