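test_that("zero stress yields identically zero flow", {
  g <- build_grid(make_sphere(), 16, 8)
  fl <- solve_stokes(g, function(z) rep(0, length(z)))
  expect_true(fl$converged)
  expect_equal(max(abs(fl$Psi)), 0)
  expect_equal(max(abs(fl$Omega)), 0)
  expect_equal(max(abs(fl$v_z)), 0)
  expect_equal(max(abs(fl$v_r)), 0)
})

test_that("velocities are recovered from constructed stream functions", {
  g <- build_grid(make_sphere(), 25, 13)
  jj <- 2:25
  # Psi = r^2 / 2 -> uniform stream v_z = 1, v_r = 0 (interior; the wall
  # one-sided stencil only applies where Psi = 0 on the wall, so feed the
  # analytic Psi and check away from the surface)
  v <- velocity_from_stream(g$r^2 / 2, g)
  expect_equal(v$v_z[jj, 1:13], matrix(1, 24, 13), tolerance = 1e-9)
  expect_equal(max(abs(v$v_r[jj, 2:13])), 0, tolerance = 1e-9)
  # Psi = r^2 z -> v_z = 2z, v_r = -r; in (z, s) the stream function is
  # cubic in z through F(z)^2 z, so v_r carries an O(dz^2) error: use a
  # finer grid and keep clear of the pole columns
  gf <- build_grid(make_sphere(), 80, 13)
  jm <- which(abs(gf$z) <= 0.8)
  zmatf <- matrix(gf$z, 81, 14)
  v2 <- velocity_from_stream(gf$r^2 * zmatf, gf)
  expect_equal(v2$v_z[jm, 1:13], 2 * zmatf[jm, 1:13], tolerance = 1e-8)
  expect_equal(max(abs(v2$v_r[jm, 2:13] + gf$r[jm, 2:13])), 0,
               tolerance = 2e-3)
  v0 <- velocity_from_stream(g$r * 0, g)
  expect_equal(max(abs(v0$v_z)), 0)
  expect_error(velocity_from_stream(g$r^2 + 1, g), "axis")
})

test_that("benchmark stress drives the analytic cortical slip within 5%", {
  fl <- bench_flow()
  expect_true(fl$converged)
  cv <- cortical_velocity(fl)
  u0 <- u_bench(cv$z)
  int <- 2:25
  expect_lt(max(abs(cv$v_t[int] - u0[int])), 0.05)
  expect_true(all(cv$v_t >= -1e-9)) # slip everywhere source -> drain
  # peak slip at the equator close to 1
  expect_equal(max(cv$v_t), 1, tolerance = 0.05)
})

test_that("Stokes flow is linear in the stress amplitude", {
  g <- sphere_grid()
  fl1 <- bench_flow()
  fl2 <- solve_stokes(g, function(z) 2 * tau_bench(z))
  scale <- max(abs(fl2$v_z))
  expect_lt(max(abs(fl2$v_z - 2 * fl1$v_z)) / scale, 1e-3)
  expect_lt(max(abs(fl2$v_r - 2 * fl1$v_r)) / scale, 1e-3)
  # doubling the viscosity instead halves the velocities
  fl3 <- solve_stokes(g, tau_bench, mu = 2)
  expect_lt(max(abs(fl3$v_z - fl1$v_z / 2)) / max(abs(fl1$v_z)), 1e-3)
})

test_that("interior field matches the closed-form squirmer solution", {
  fl <- bench_flow_fine()
  g <- fl$grid
  jj <- 2:g$Nz
  zmat <- matrix(g$z, g$Nz + 1L, g$Ns + 1L)
  err_z <- abs(fl$v_z[jj, ] - squirmer_vz(zmat[jj, ], g$r[jj, ]))
  err_r <- abs(fl$v_r[jj, ] - squirmer_vr(zmat[jj, ], g$r[jj, ]))
  # velocity scale is 1 (unit slip)
  expect_lt(max(err_z), 0.02)
  expect_lt(max(err_r), 0.02)
})

test_that("mass is conserved through every cross-section", {
  fl <- bench_flow()
  expect_lt(max(abs(section_flux(fl))), 1e-6)
  # the quadrature route carries only discretisation error
  expect_lt(max(abs(section_flux(fl, "quadrature"))), 0.05)
})

test_that("mirroring the stress profile mirrors the flow", {
  g <- build_grid(make_sphere(), 20, 10)
  amps <- c(0.2, 0.5, 1.0, 1.8, 2.6, 2.2, 1.0)
  fa <- solve_stokes(g, stress_spline(amps))
  fb <- solve_stokes(g, stress_spline(rev(amps)))
  flip <- 21:1
  scale <- max(abs(fa$v_z))
  expect_lt(max(abs(fb$v_z - fa$v_z[flip, ])) / scale, 1e-4)
  expect_lt(max(abs(fb$v_r + fa$v_r[flip, ])) / scale, 1e-4)
})

test_that("discretisation error shrinks under grid refinement", {
  err_at <- function(fl) {
    g <- fl$grid
    jj <- 2:g$Nz
    zmat <- matrix(g$z, g$Nz + 1L, g$Ns + 1L)
    max(abs(fl$v_z[jj, ] - squirmer_vz(zmat[jj, ], g$r[jj, ])))
  }
  e_coarse <- err_at(bench_flow())
  e_fine <- err_at(bench_flow_fine())
  expect_lt(e_fine, e_coarse / 1.8) # at least first order in h
})

test_that("bilinear interpolation reproduces nodal values and guards the domain", {
  fl <- bench_flow()
  g <- fl$grid
  j <- c(5L, 13L, 20L); k <- c(3L, 7L, 12L)
  v <- interp_velocity(fl, g$z[j], g$r[cbind(j, k)])
  expect_equal(v$v_z, fl$v_z[cbind(j, k)], tolerance = 1e-12)
  expect_equal(v$v_r, fl$v_r[cbind(j, k)], tolerance = 1e-12)
  expect_error(interp_velocity(fl, 0, 1.2), "boundary")
  expect_error(interp_velocity(fl, 1.5, 0), "axial")
})

test_that("flow fields round-trip through the CSV exchange format", {
  fl <- bench_flow()
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_flow_csv(fl, path)
  fl2 <- read_flow_csv(path)
  expect_equal(fl2$Psi, fl$Psi, tolerance = 1e-12)
  expect_equal(fl2$v_z, fl$v_z, tolerance = 1e-12)
  expect_equal(fl2$mu, fl$mu)
  expect_equal(fl2$grid$Nz, fl$grid$Nz)
  # the solver records the slip of the penultimate iterate, the reader
  # recomputes it from the final stream function: equal to solver tolerance
  expect_equal(cortical_velocity(fl2)$v_t, cortical_velocity(fl)$v_t,
               tolerance = 1e-6)
})

test_that("an exhausted iteration budget is reported, not hidden", {
  g <- build_grid(make_sphere(), 16, 8)
  expect_warning(fl <- solve_stokes(g, tau_bench,
                                    control = list(max_outer = 50L)),
                 "did not reach")
  expect_false(fl$converged)
  expect_error(solve_stokes(g, tau_bench, control = list(bogus = 1)),
               "unknown control")
})
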