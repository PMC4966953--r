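test_that("benchmark case pins the analytic stress-slip pairing", {
  bench <- benchmark_case()
  expect_equal(bench$tau0(0), 3)
  expect_equal(bench$u0(c(-1, 1)), c(0, 0))
  expect_equal(bench$u0(0.6), 0.8)
  expect_equal(bench$mu, 1)
  expect_s3_class(bench$stress, "stress_spline")
})

test_that("noiseless synthetic observations equal the solver output", {
  bench <- benchmark_case()
  syn <- synth_observations(bench$shape, bench$stress, n_points = 50,
                            noise_sd = 0, seed = 3, grid_size = c(16, 8))
  v <- interp_velocity(syn$truth$flow, syn$obs$points$z,
                       abs(syn$obs$points$r))
  sgn <- ifelse(syn$obs$points$r < 0, -1, 1)
  expect_equal(syn$obs$points$v_z, v$v_z, tolerance = 1e-12)
  expect_equal(syn$obs$points$v_r, sgn * v$v_r, tolerance = 1e-12)
  expect_true(all(abs(syn$obs$points$r) <= bench$shape$F(syn$obs$points$z)))
})

test_that("observation noise is calibrated and zero-mean", {
  bench <- benchmark_case()
  syn <- synth_observations(bench$shape, bench$stress, n_points = 3000,
                            noise_sd = 0.05, seed = 4, grid_size = c(16, 8))
  clean <- interp_velocity(syn$truth$flow, syn$obs$points$z,
                           abs(syn$obs$points$r))
  sgn <- ifelse(syn$obs$points$r < 0, -1, 1)
  res <- c(syn$obs$points$v_z - clean$v_z,
           syn$obs$points$v_r - sgn * clean$v_r)
  target <- syn$truth$noise_sd_abs
  n <- length(res)
  expect_lt(abs(sd(res) - target), 3 * target / sqrt(2 * n))
  expect_lt(abs(mean(res)), 3 * target / sqrt(n))
})

test_that("synthetic generation is reproducible from its seed", {
  bench <- benchmark_case()
  a <- synth_observations(bench$shape, bench$stress, n_points = 30,
                          noise_sd = 0.1, seed = 11, grid_size = c(16, 8))
  b <- synth_observations(bench$shape, bench$stress, n_points = 30,
                          noise_sd = 0.1, seed = 11, grid_size = c(16, 8))
  expect_identical(a$obs$points, b$obs$points)
  expect_identical(a$seed, 11)
  expect_error(synth_observations(bench$shape, bench$stress,
                                  n_points = 1e6, seed = 1,
                                  grid_size = c(16, 8)), "resolution")
})

test_that("particle pairs advect by the local flow", {
  # zero flow: identical stacks
  p0 <- synth_particle_stacks(c(0, 0, 0), dim_px = c(64, 64, 1),
                              n_particles = 40, dt = 5, seed = 5)
  expect_identical(p0$I1$intensities, p0$I2$intensities)
  # uniform 0.104 um/s over 5 s at 0.26 um voxels = 2.0 px
  pu <- synth_particle_stacks(c(0.104, 0, 0), dim_px = c(110, 110, 1),
                              n_particles = 120, dt = 5, seed = 6)
  vf <- piv_field(pu$I1, pu$I2, dt = 5)
  ok <- vf$flag %in% c("ok", "large")
  expect_gt(sum(ok), 0)
  expect_equal(median(vf$u_px[ok]), 2, tolerance = 0.1)
  expect_equal(median(vf$vx_um_s[ok]), 0.104, tolerance = 0.01)
  # excessive displacement warns
  expect_warning(
    synth_particle_stacks(c(1, 0, 0), dim_px = c(64, 64, 1),
                          n_particles = 10, dt = 5, seed = 7),
    "search range")
})

test_that("PIV on a rendered benchmark flow correlates with the truth", {
  fl <- bench_flow()
  st <- synth_particle_stacks(fl, dim_px = c(140, 140, 1),
                              n_particles = 700, dt = 0.5,
                              voxel_um = c(0.26, 0.26, 1), psf_sd_um = 0.4,
                              seed = 8)
  vf <- piv_field(st$I1, st$I2, dt = 0.5)
  ok <- vf$flag %in% c("ok", "large")
  # true velocity at the interrogation centres
  ext <- c(140, 140, 1) * c(0.26, 0.26, 1)
  vfun <- streamstress:::velocity_function(fl, ext, 15)
  truth <- vfun(cbind(vf$x * 0.26, vf$y * 0.26, vf$z * 1))
  keep <- ok & (abs(truth[, 1L]) + abs(truth[, 2L]) > 1e-6)
  expect_gt(sum(keep), 10)
  expect_gt(cor(vf$vx_um_s[keep], truth[keep, 1L]), 0.9)
})

test_that("species cohorts carry their physical scales and ground truth", {
  syn <- synth_cells("celegans", n_cells = 2, n_points = 40,
                     noise_sd = 0.05, seed = 3, grid_size = c(24, 8))
  expect_length(syn$cells, 2L)
  expect_equal(syn$scale$viscosity_pa_s, 1) # 10 Poise
  expect_equal(syn$cells[[1L]]$obs$cell, "Ce1")
  expect_length(syn$cells[[1L]]$truth$amplitudes, 7L)
  # stored velocities are physical (um/s): peak speed near 0.1 um/s
  speeds <- sqrt(syn$cells[[1L]]$obs$points$v_z^2 +
                   syn$cells[[1L]]$obs$points$v_r^2)
  expect_lt(max(speeds), 0.5)
  expect_gt(max(speeds), 0.01)
})
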