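test_that("autocorrelation peaks at zero shift with zero sub-pixel residual", {
  A <- smooth_texture(96, 96, seed = 1)
  ctr <- c(48L, 48L, 1L)
  ip <- integer_displacement(A, A, ctr)
  expect_equal(ip$shift, c(0L, 0L, 0L))
  expect_equal(ip$flag, "ok")
  sp <- subpixel_displacement(A, A, ctr, ip$shift)
  expect_equal(sp$uvw, c(0, 0, 0))
})

test_that("constructed integer translations are recovered exactly", {
  A <- smooth_texture(96, 96, seed = 2)
  for (sh in list(c(3L, -2L), c(-5L, 4L), c(0L, 1L))) {
    B <- shift_xy(A, sh[1L], sh[2L])
    ip <- integer_displacement(A, B, c(48L, 48L, 1L))
    expect_equal(ip$shift[1:2], sh)
    expect_equal(ip$shift[3L], 0L)
  }
})

test_that("shifts beyond the cumulative search range clip to the boundary", {
  A <- smooth_texture(128, 128, seed = 3, sigma = 4)
  B <- shift_xy(A, 9L, 0L) # cumulative range is 5 + 2 + 1 = 8
  ip <- integer_displacement(A, B, c(64L, 64L, 1L))
  expect_equal(ip$shift[1L], 8L)
  expect_equal(ip$flag, "range")
})

test_that("flat windows and out-of-bounds windows are flagged", {
  Z <- array(1, dim = c(96, 96, 1))
  expect_equal(integer_displacement(Z, Z, c(48L, 48L, 1L))$flag, "flat")
  A <- smooth_texture(96, 96, seed = 4)
  expect_equal(integer_displacement(A, A, c(5L, 48L, 1L))$flag, "oob")
})

test_that("sub-pixel translation of a Gaussian blob is resolved to 0.1 px", {
  xy <- expand.grid(x = 1:64, y = 1:64)
  blob <- function(cx, cy) {
    array(exp(-((xy$x - cx)^2 + (xy$y - cy)^2) / (2 * 3^2)), c(64, 64, 1))
  }
  I1 <- blob(32, 32)
  I2 <- blob(32.4, 32)
  sp <- subpixel_displacement(I1, I2, c(32L, 32L, 1L), c(0L, 0L, 0L))
  expect_equal(sp$flag, "ok")
  expect_lt(abs(sp$uvw[1L] - 0.4), 0.1)
  expect_lt(abs(sp$uvw[2L]), 0.05)
  expect_equal(sp$uvw[3L], 0)
})

test_that("the aperture problem is flagged and the resolvable component kept", {
  # 1D ramp along x: no texture in y, so v is indeterminate
  ramp <- function(offset) {
    array(rep(seq_len(64) + offset, times = 64), c(64, 64, 1))
  }
  sp <- subpixel_displacement(ramp(0), ramp(-0.5), c(32L, 32L, 1L),
                              c(0L, 0L, 0L))
  expect_equal(sp$flag, "singular")
  expect_lt(abs(sp$uvw[1L] - 0.5), 0.05) # gradient says shift +0.5 in x
  expect_equal(sp$uvw[2L], 0, tolerance = 1e-9)
})

test_that("pixel displacements convert to um/s with the anisotropic voxel", {
  A <- smooth_texture(110, 110, seed = 5)
  B <- shift_xy(A, 2L, 0L)
  vf <- piv_field(A, B, dt = 5, voxel_um = c(0.26, 0.26, 1.0))
  ok <- vf$flag == "ok"
  expect_gt(sum(ok), 0)
  expect_equal(vf$u_px[ok], rep(2, sum(ok)), tolerance = 0.05)
  expect_equal(vf$vx_um_s[ok], rep(2 * 0.26 / 5, sum(ok)), tolerance = 0.01)
  expect_equal(vf$w_px[ok], rep(0, sum(ok))) # 2D input: no axial component
  # zero motion gives a zero field
  vf0 <- piv_field(A, A, dt = 5)
  ok0 <- vf0$flag == "ok"
  expect_equal(max(abs(vf0$u_px[ok0])), 0, tolerance = 1e-9)
})

test_that("translation equivariance and pair-reversal antisymmetry hold", {
  A <- smooth_texture(110, 110, seed = 6)
  B <- shift_xy(A, 3L, -1L)
  ctr <- c(55L, 55L, 1L)
  fwd <- integer_displacement(A, B, ctr)$shift
  rev <- integer_displacement(B, A, ctr)$shift
  expect_equal(rev[1:2], -fwd[1:2])
  # translating both stacks identically leaves the estimate unchanged
  A2 <- shift_xy(A, 4L, 4L); B2 <- shift_xy(B, 4L, 4L)
  expect_equal(integer_displacement(A2, B2, ctr)$shift, fwd)
})

test_that("field averaging excludes invalid vectors and is exact arithmetic", {
  A <- smooth_texture(110, 110, seed = 7)
  B <- shift_xy(A, 1L, 0L)
  f1 <- piv_field(A, B, dt = 1)
  valid <- f1$flag %in% c("ok", "large")
  avg11 <- average_fields(list(f1, f1))
  expect_identical(avg11$u_px[valid], f1$u_px[valid])
  expect_true(all(is.na(avg11$u_px[!valid])))
  f2 <- f1
  f2$u_px <- -f1$u_px; f2$v_px <- -f1$v_px; f2$w_px <- -f1$w_px
  f2$vx_um_s <- -f1$vx_um_s; f2$vy_um_s <- -f1$vy_um_s; f2$vz_um_s <- -f1$vz_um_s
  avg <- average_fields(list(f1, f2))
  ok <- avg$flag == "ok"
  expect_equal(max(abs(avg$u_px[ok])), 0)
  # positions with no valid vector stay invalid
  f3 <- f1; f3$flag <- "flat"
  expect_true(all(average_fields(list(f3, f3))$flag == "invalid"))
  expect_error(average_fields(list()), "empty")
})

test_that("noise averages down like 1/sqrt(n) over repeated fields", {
  A <- smooth_texture(110, 110, seed = 8)
  base <- piv_field(A, A, dt = 1)
  set.seed(9)
  sigma <- 0.5
  n_fields <- 50
  fields <- lapply(seq_len(n_fields), function(i) {
    f <- base
    f$u_px <- f$u_px + rnorm(nrow(f), 0, sigma)
    f
  })
  avg <- average_fields(fields)
  emp <- sd(avg$u_px[avg$flag == "ok"])
  expect_lt(emp, 2.5 * sigma / sqrt(n_fields))
  expect_gt(emp, sigma / sqrt(n_fields) / 2.5)
})

test_that("image stacks round-trip through TIFF", {
  A <- smooth_texture(40, 40, seed = 10)
  st <- image_stack(A / max(A))
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(path))
  write_image_stack(st, path)
  st2 <- read_image_stack(path)
  expect_equal(dim(st2$intensities), dim(st$intensities))
  expect_equal(st2$intensities, st$intensities, tolerance = 1e-4) # 16-bit
  expect_error(image_stack(array(-1, c(2, 2, 1))), "non-negative")
})
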