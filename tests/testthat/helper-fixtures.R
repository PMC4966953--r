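# Shared fixtures, memoised across test files (test_dir runs one process).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# analytic interior squirmer (unit sphere, unit slip): cylindrical components
squirmer_vz <- function(z, r) 1 - z^2 - 2 * r^2
squirmer_vr <- function(z, r) z * r

tau_bench <- function(z) 3 * sqrt(pmax(1 - z^2, 0))
u_bench <- function(z) sqrt(pmax(1 - z^2, 0))

sphere_grid <- function() memo("sphere_grid", build_grid(make_sphere(), 25, 13))

bench_flow <- function() memo("bench_flow", {
  solve_stokes(sphere_grid(), tau_bench)
})

bench_flow_fine <- function() memo("bench_flow_fine", {
  suppressWarnings(solve_stokes(build_grid(make_sphere(), 50, 26), tau_bench,
                                control = list(dt_safety = 0.8)))
})

# noiseless benchmark observations sampled at every interior grid node
bench_obs <- function() memo("bench_obs", {
  g <- sphere_grid()
  fl <- bench_flow()
  pts <- expand.grid(j = 2:g$Nz, k = 2:g$Ns)
  idx <- cbind(pts$j, pts$k)
  observations(g$z[pts$j], g$r[idx], fl$v_z[idx], fl$v_r[idx])
})

# quick random texture with correlation length of a few pixels
smooth_texture <- function(nx, ny, seed, sigma = 2) {
  set.seed(seed)
  A <- matrix(rnorm(nx * ny), nx, ny)
  k <- dnorm(seq(-3, 3, length.out = 2 * ceiling(2 * sigma) + 1))
  A <- apply(A, 2, function(col) stats::filter(col, k, circular = TRUE))
  A <- t(apply(A, 1, function(row) stats::filter(row, k, circular = TRUE)))
  A <- A - min(A)
  array(A, dim = c(nx, ny, 1L))
}

# integer-translate a (nx, ny, 1) array with circular wrap
shift_xy <- function(A, dx, dy) {
  d <- dim(A)
  ix <- ((seq_len(d[1L]) - 1L - dx) %% d[1L]) + 1L
  iy <- ((seq_len(d[2L]) - 1L - dy) %% d[2L]) + 1L
  A[ix, iy, , drop = FALSE]
}
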