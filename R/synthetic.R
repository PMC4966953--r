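#' Analytic benchmark: stress and slip on the unit sphere
#'
#' In Stokes flow inside a unit sphere with unit viscosity, the cortical
#' stress profile \eqn{\tau_0(z) = 3 (1 - z^2)^{1/2}} drives a cortical
#' slip velocity \eqn{u_0(z) = (1 - z^2)^{1/2}} (the classical interior
#' squirmer solution; the ratio of stress to slip amplitude is exactly 3).
#' This pairing is the reference case for validating both the solver and
#' the inference.
#'
#' @param n_nodes Number of free spline amplitudes for the fitted
#'   representation of \eqn{\tau_0}.
#' @return A list: `shape` (unit sphere), `tau0` / `u0` (functions of z),
#'   `stress` (a [stress_spline()] least-squares fitted to `tau0`), and
#'   `mu = 1`.
#' @export
benchmark_case <- function(n_nodes = 7) {
  tau0 <- function(z) 3 * sqrt(pmax(1 - z^2, 0))
  u0 <- function(z) sqrt(pmax(1 - z^2, 0))
  list(shape = make_sphere(1),
       tau0 = tau0, u0 = u0,
       stress = fit_stress_spline(tau0, R_half = 1, n_nodes = n_nodes),
       mu = 1)
}

#' Synthetic velocity observations from a known stress profile
#'
#' Forward-solves the Stokes problem for a known stress distribution,
#' samples the velocity at stratified-random interior positions (uniform
#' strata over the `(z, s)` rectangle, mapped inside the boundary, with a
#' random image half-plane sign on `r`), and adds i.i.d. Gaussian noise
#' with standard deviation `noise_sd` times the maximum interior speed.
#' The ground truth is returned alongside, so parameter-recovery
#' experiments need no external data.
#'
#' @param shape Boundary shape.
#' @param stress True stress profile (spline, function or nodal vector).
#' @param n_points Number of observation points.
#' @param noise_sd Noise level as a fraction of the maximum speed.
#' @param seed Integer seed (recorded in the output).
#' @param grid_size Intervals `c(Nz, Ns)` of the forward grid.
#' @param mu Viscosity.
#' @param scale Physical scales stored in the observations (see
#'   [observations()]).
#' @param control Solver settings.
#' @return A list: `obs` ([observations()]), `truth` (list with the
#'   stress, the flow field and the noise sd actually applied), and
#'   `seed`.
#' @export
synth_observations <- function(shape, stress, n_points = 100,
                               noise_sd = 0.05, seed = 1,
                               grid_size = c(25, 13), mu = 1,
                               scale = list(), control = list()) {
  if (noise_sd < 0) stopf("`noise_sd` must be non-negative")
  grid <- build_grid(shape, grid_size[1L], grid_size[2L])
  if (n_points > 100L * grid_size[1L] * grid_size[2L]) {
    stopf("`n_points` exceeds what the grid resolution supports")
  }
  flow <- solve_stokes(grid, stress, mu = mu, control = control)
  L <- shape$half_length
  with_seed(seed, {
    # stratified-random placement over the (z, s) rectangle
    n_strat <- max(1L, floor(sqrt(n_points)))
    iz <- (seq_len(n_points) - 1L) %% n_strat
    is <- ((seq_len(n_points) - 1L) %/% n_strat) %% n_strat
    z <- -0.98 * L + (iz + stats::runif(n_points)) / n_strat * 1.96 * L
    s <- (is + stats::runif(n_points)) / n_strat * 0.95
    sgn <- sample(c(-1, 1), n_points, replace = TRUE)
    r <- sgn * s * shape$F(z)
    v <- interp_velocity(flow, z, abs(r))
    vmax <- max(sqrt(flow$v_z^2 + flow$v_r^2))
    noise <- noise_sd * vmax
    v_z <- v$v_z + rnorm(n_points, 0, noise)
    v_r <- sgn * v$v_r + rnorm(n_points, 0, noise)
    # when a velocity scale is recorded, store the table in measured units
    # (um/s), as deposited flow tables are; inference divides it back out
    vs <- scale$velocity_um_s
    if (!is.null(vs) && is.finite(vs)) {
      v_z <- v_z * vs
      v_r <- v_r * vs
    }
    obs <- observations(z, r, v_z, v_r, scale = scale, shape = shape)
    list(obs = obs,
         truth = list(stress = stress, flow = flow, noise_sd_abs = noise,
                      v_max = vmax),
         seed = seed)
  })
}

#' Synthetic particle-image stack pairs advected by a known flow
#'
#' Renders Gaussian-blob particles placed uniformly in a volume, then a
#' second stack in which each particle has moved by its local velocity
#' times `dt`; sampled on the anisotropic voxel grid. This provides a
#' ground-truth test surface for the PIV pipeline.
#'
#' @param velocity The flow: a numeric length-3 vector (uniform, um/s), a
#'   function mapping an `n x 3` matrix of positions (um) to an `n x 3`
#'   matrix of velocities (um/s), or a [solve_stokes()] `flow_field` (its
#'   meridional plane is rendered: image x maps to the axial coordinate,
#'   image y to the signed radius, scaled by `length_um`).
#' @param dim_px Stack size in voxels `c(nx, ny, nz)`.
#' @param n_particles Number of particles.
#' @param dt Frame interval (s).
#' @param voxel_um Voxel size (um).
#' @param psf_sd_um Gaussian point-spread sd (um).
#' @param length_um Physical length of one non-dimensional unit (used only
#'   for `flow_field` velocities).
#' @param shot_noise Add Poisson shot noise (default FALSE).
#' @param seed Integer seed.
#' @return List with `I1`, `I2` ([image_stack()]s), the particle
#'   positions, and `seed`. A warning is raised when the largest
#'   displacement exceeds the default PIV search range.
#' @export
synth_particle_stacks <- function(velocity, dim_px = c(96L, 96L, 1L),
                                  n_particles = 150, dt = 5,
                                  voxel_um = c(0.26, 0.26, 1.0),
                                  psf_sd_um = 0.5, length_um = 15,
                                  shot_noise = FALSE, seed = 1) {
  dim_px <- as.integer(dim_px)
  extent <- dim_px * voxel_um
  vfun <- velocity_function(velocity, extent, length_um)
  with_seed(seed, {
    pos <- cbind(stats::runif(n_particles, 0, extent[1L]),
                 stats::runif(n_particles, 0, extent[2L]),
                 stats::runif(n_particles, 0, extent[3L]))
    vel <- vfun(pos)
    disp <- vel * dt
    max_px <- max(abs(sweep(disp, 2L, voxel_um, "/")))
    if (max_px > 8) {
      warning(sprintf(
        "largest displacement %.1f px exceeds the default PIV search range",
        max_px))
    }
    I1 <- render_particles(pos, dim_px, voxel_um, psf_sd_um)
    I2 <- render_particles(pos + disp, dim_px, voxel_um, psf_sd_um)
    if (shot_noise) {
      I1 <- stats::rpois(length(I1), I1 * 50) / 50
      I2 <- stats::rpois(length(I2), I2 * 50) / 50
      dim(I1) <- dim_px; dim(I2) <- dim_px
    }
    list(I1 = image_stack(I1, voxel_um, time = 0),
         I2 = image_stack(I2, voxel_um, time = dt),
         positions = pos, velocities = vel, seed = seed)
  })
}

velocity_function <- function(velocity, extent, length_um) {
  if (is.numeric(velocity) && length(velocity) == 3L) {
    v <- velocity
    return(function(p) matrix(v, nrow(p), 3L, byrow = TRUE))
  }
  if (is.function(velocity)) return(velocity)
  if (inherits(velocity, "flow_field")) {
    fl <- velocity
    L <- fl$grid$shape$half_length
    return(function(p) {
      # image x spans the axial extent, image y the diameter
      z <- (p[, 1L] / extent[1L] - 0.5) * 2 * L
      r <- (p[, 2L] / extent[2L] - 0.5) * 2 * fl$grid$shape$short_radius
      Fz <- fl$grid$shape$F(pmin(pmax(z, -L), L))
      inside <- abs(r) < Fz & abs(z) < L
      out <- matrix(0, nrow(p), 3L)
      if (any(inside)) {
        v <- interp_velocity(fl, z[inside], abs(r[inside]))
        # um/s = non-dimensional velocity * (length scale / time scale);
        # keep it simple: 1 non-dim velocity unit = 1 um/s at scale length_um
        out[inside, 1L] <- v$v_z
        out[inside, 2L] <- ifelse(r[inside] < 0, -1, 1) * v$v_r
      }
      out
    })
  }
  stopf("`velocity` must be a length-3 vector, a function, or a flow_field")
}

render_particles <- function(pos, dim_px, voxel_um, psf_sd_um) {
  A <- array(0, dim = dim_px)
  # evaluate the Gaussian on a local support of 4 sd
  half <- ceiling(4 * psf_sd_um / voxel_um)
  ax <- lapply(1:3, function(a) (seq_len(dim_px[a]) - 0.5) * voxel_um[a])
  for (i in seq_len(nrow(pos))) {
    ctr <- pos[i, ]
    idx <- lapply(1:3, function(a) {
      c0 <- round(ctr[a] / voxel_um[a])
      lo <- max(1L, c0 - half[a]); hi <- min(dim_px[a], c0 + half[a])
      if (lo > hi) integer(0) else lo:hi
    })
    if (any(!lengths(idx))) next
    gx <- exp(-(ax[[1L]][idx[[1L]]] - ctr[1L])^2 / (2 * psf_sd_um^2))
    gy <- exp(-(ax[[2L]][idx[[2L]]] - ctr[2L])^2 / (2 * psf_sd_um^2))
    gz <- if (dim_px[3L] == 1L) 1 else
      exp(-(ax[[3L]][idx[[3L]]] - ctr[3L])^2 / (2 * psf_sd_um^2))
    blob <- outer(outer(gx, gy), gz)
    patch <- A[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
    A[idx[[1L]], idx[[2L]], idx[[3L]]] <- patch + blob
  }
  A
}

#' Synthetic stand-in observation sets at physical scales
#'
#' Generates a cohort of C. elegans-like (capsule) or mouse-like (sphere)
#' cells: each cell gets a randomly perturbed species-typical stress
#' profile, a forward-solved flow field, and noisy observations expressed
#' through the species' physical scales (so velocities are in um/s and
#' stress estimates convert to pN/um^2). This is a synthetic substitute
#' for deposited experimental flow tables, built to the study conditions
#' reported for each species (C. elegans: viscosity 1 Pa s = 10 Poise,
#' short radius 15 um, peak speed about 0.1 um/s; mouse: 0.1 Pa s,
#' radius 35 um, peak speed about 0.001 um/s).
#'
#' @param species `"celegans"` or `"mouse"`.
#' @param n_cells Number of cells.
#' @param n_points Observation points per cell.
#' @param noise_sd Observation noise (fraction of peak speed).
#' @param seed Integer seed.
#' @param grid_size Forward-solver grid intervals.
#' @param control Solver settings.
#' @return List of per-cell lists (`obs`, `truth`), plus the species
#'   scales.
#' @export
synth_cells <- function(species = c("celegans", "mouse"), n_cells = 3,
                        n_points = 80, noise_sd = 0.05, seed = 1,
                        grid_size = NULL, control = list()) {
  species <- match.arg(species)
  if (species == "celegans") {
    shape <- make_capsule()
    grid_size <- grid_size %||% c(56, 14)
    scale <- list(length_um = 15, velocity_um_s = 0.1, viscosity_pa_s = 1)
    base_amp <- c(0.6, 1.2, 1.8, 2.4, 2.6, 2.2, 1.2) # broad, source-shifted
  } else {
    shape <- make_sphere()
    grid_size <- grid_size %||% c(25, 13)
    scale <- list(length_um = 35, velocity_um_s = 0.001, viscosity_pa_s = 0.1)
    base_amp <- c(0.1, 0.1, 0.2, 0.3, 0.8, 2.4, 2.8) # source-concentrated
  }
  cells <- lapply(seq_len(n_cells), function(i) {
    cell_seed <- seed * 1000L + i
    amps <- with_seed(cell_seed, pmax(base_amp * exp(rnorm(7, 0, 0.15)), 0.01))
    sp <- stress_spline(amps, R_half = shape$half_length)
    syn <- synth_observations(shape, sp, n_points = n_points,
                              noise_sd = noise_sd, seed = cell_seed + 1L,
                              grid_size = grid_size, scale = scale,
                              control = control)
    syn$obs$cell <- sprintf("%s%d", if (species == "celegans") "Ce" else "Mm", i)
    syn$truth$amplitudes <- amps
    syn
  })
  list(cells = cells, species = species, shape = shape, scale = scale,
       seed = seed)
}
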