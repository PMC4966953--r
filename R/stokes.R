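#' Solve steady axisymmetric Stokes flow driven by cortical shear stress
#'
#' Integrates the stream function-vorticity formulation of creeping flow
#' inside an axisymmetric boundary, forced purely through the wall
#' vorticity condition \eqn{\Omega = \tau/\mu + 2 v_t / R} (tangential
#' stress \eqn{\tau} and slip speed \eqn{v_t} both positive from the source
#' pole at `z = +R_half` towards the drain pole; `R` is the meridional
#' curvature radius). On the symmetry axis and at the poles
#' \eqn{\Psi = \Omega = 0}; on the surface \eqn{\Psi = 0}.
#'
#' The vorticity transport equation is marched to steady state with an
#' explicit Euler pseudo-time step (step size `dt_safety` divided by the
#' largest stencil diagonal, a diffusive stability bound), interleaved with
#' successive over-relaxation sweeps of the stream-function Poisson
#' equation (`sor_omega`, default 1.7); the wall vorticity is refreshed
#' from the current stream function every outer iteration with
#' under-relaxation `wall_relax`. Iteration stops when the largest update
#' of both fields drops below `tol` (default 1e-7, non-dimensional).
#'
#' @param grid A [build_grid()] grid.
#' @param stress The cortical stress profile: a [stress_spline()], a
#'   function of `z`, or a numeric vector over the grid's axial nodes.
#' @param mu Viscosity (1 in the non-dimensional system).
#' @param control Named list of solver settings overriding the defaults
#'   `list(sor_omega = 1.7, dt_safety = 0.2, wall_relax = 0.7, tol = 1e-7,
#'   max_outer = 400000, sor_sweeps = 1, euler_steps = 1)`.
#' @return An object of class `flow_field`: matrices `Psi`, `Omega`, `v_z`,
#'   `v_r` over the grid nodes, the wall slip profile, viscosity, and
#'   convergence metadata (`converged`, `iterations`, final update sizes,
#'   residual history).
#' @examples
#' g <- build_grid(make_sphere(), 16, 8)
#' fl <- solve_stokes(g, function(z) 3 * sqrt(pmax(1 - z^2, 0)))
#' fl$converged
#' @export
solve_stokes <- function(grid, stress, mu = 1, control = list()) {
  stopifnot(inherits(grid, "curvi_grid"))
  ctrl <- list(sor_omega = 1.7, dt_safety = 0.2, wall_relax = 0.7,
               tol = 1e-7, max_outer = 400000L, sor_sweeps = 1L,
               euler_steps = 1L)
  unknown <- setdiff(names(control), names(ctrl))
  if (length(unknown)) stopf("unknown control settings: %s",
                             paste(unknown, collapse = ", "))
  ctrl[names(control)] <- control
  if (mu <= 0) stopf("`mu` must be positive")

  nj <- grid$Nz + 1L
  tau_wall <- stress_on_axis(stress, grid)
  Rcurv <- c(NA_real_,
             surface_curvature_radius(grid$shape, grid$z[2:(nj - 1L)]),
             NA_real_)
  # NA metrics at pole columns never enter the interior stencil, but the
  # C++ core expects finite arrays
  Sz <- grid$Sz; Sz[c(1L, nj), ] <- 0
  Szz <- grid$Szz; Szz[c(1L, nj), ] <- 0
  Sr <- grid$Sr; Sr[c(1L, nj)] <- 0
  dF <- grid$dF; dF[c(1L, nj)] <- 0
  Fz <- grid$F; Fz[c(1L, nj)] <- 1
  Rcurv[c(1L, nj)] <- Inf
  tau_wall[c(1L, nj)] <- 0

  res <- .stokes_core(grid$z, grid$s, Fz, dF, Sr, Sz, Szz,
                      tau_wall, Rcurv, mu,
                      ctrl$sor_omega, ctrl$dt_safety, ctrl$wall_relax,
                      ctrl$tol, as.integer(ctrl$max_outer),
                      as.integer(ctrl$sor_sweeps),
                      as.integer(ctrl$euler_steps))
  if (!res$converged) {
    warning(sprintf(
      "stokes solver did not reach tol = %g in %d iterations (last updates: Psi %.3g, Omega %.3g)",
      ctrl$tol, ctrl$max_outer, res$max_dpsi, res$max_domega))
  }
  vel <- velocity_from_stream(res$Psi, grid)
  structure(list(
    grid = grid, Psi = res$Psi, Omega = res$Omega,
    v_z = vel$v_z, v_r = vel$v_r,
    vt_wall = res$vt_wall, tau_wall = tau_wall, mu = mu,
    converged = res$converged, iterations = res$iterations,
    residuals = c(Psi = res$max_dpsi, Omega = res$max_domega),
    residual_history = res$residual_history, control = ctrl
  ), class = "flow_field")
}

# Stress profile evaluated at the grid's axial nodes (0 at the poles).
stress_on_axis <- function(stress, grid) {
  z <- grid$z
  if (inherits(stress, "stress_spline")) {
    tau <- evaluate_stress(stress, pmin(pmax(z, -stress$R_half), stress$R_half))
  } else if (is.function(stress)) {
    tau <- stress(z)
  } else if (is.numeric(stress) && length(stress) == length(z)) {
    tau <- stress
  } else {
    stopf("`stress` must be a stress_spline, a function of z, or a vector over the %d axial nodes",
          length(z))
  }
  if (any(!is.finite(tau[2:(length(z) - 1L)]))) {
    stopf("stress profile evaluates to non-finite values inside the domain")
  }
  tau
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "Axisymmetric Stokes flow on %d x %d grid (%s)\n  converged: %s after %d iterations (updates: Psi %.2g, Omega %.2g)\n  max |v|: %.4g\n",
    x$grid$Nz, x$grid$Ns, x$grid$shape$kind,
    x$converged, x$iterations, x$residuals["Psi"], x$residuals["Omega"],
    max(sqrt(x$v_z^2 + x$v_r^2))))
  invisible(x)
}

#' Velocities from a stream function
#'
#' Reconstructs \eqn{v_z = (1/r) \partial\Psi/\partial r} and
#' \eqn{v_r = -(1/r) \partial\Psi/\partial z} on the boundary-fitted grid
#' with second-order central differences (one-sided at the surface). On the
#' axis the limits are used: \eqn{v_r = 0} and \eqn{v_z = 2a} where `a` is
#' the quadratic coefficient of \eqn{\Psi \approx a r^2}, estimated from the
#' two nearest rows with Richardson extrapolation. Velocities at the pole
#' nodes are 0 (stagnation points of the closed boundary).
#'
#' @param Psi Stream-function matrix over the grid nodes (0 on axis and
#'   surface).
#' @param grid The matching [build_grid()] grid.
#' @return List with matrices `v_z` and `v_r`.
#' @export
velocity_from_stream <- function(Psi, grid) {
  nj <- grid$Nz + 1L
  nk <- grid$Ns + 1L
  if (any(abs(Psi[, 1L]) > 1e-10)) {
    stopf("Psi must vanish on the symmetry axis")
  }
  ds <- grid$ds; dz <- grid$dz
  s <- grid$s; Fz <- grid$F
  Ps <- matrix(0, nj, nk)
  Ps[, 2:(nk - 1L)] <- (Psi[, 3:nk] - Psi[, 1:(nk - 2L)]) / (2 * ds)
  Ps[, nk] <- (3 * Psi[, nk] - 4 * Psi[, nk - 1L] + Psi[, nk - 2L]) / (2 * ds)
  Pz <- matrix(0, nj, nk)
  Pz[2:(nj - 1L), ] <- (Psi[3:nj, ] - Psi[1:(nj - 2L), ]) / (2 * dz)

  v_z <- matrix(0, nj, nk)
  v_r <- matrix(0, nj, nk)
  jj <- 2:(nj - 1L)
  for (k in 2:nk) {
    v_z[jj, k] <- Ps[jj, k] / (Fz[jj]^2 * s[k])
    v_r[jj, k] <- -(Pz[jj, k] + grid$Sz[jj, k] * Ps[jj, k]) / (Fz[jj] * s[k])
  }
  # Near the axis Psi ~ a s^2 + b s^4 (even in r); the centred difference at
  # the first off-axis row is O(1) wrong relative to the small local value,
  # so rows 1-2 use derivatives of the exact two-term even fit instead.
  a_fit <- (16 * Psi[jj, 2L] - Psi[jj, 3L]) / (12 * s[2L]^2)
  b_fit <- (Psi[jj, 3L] - 4 * Psi[jj, 2L]) / (12 * s[2L]^4)
  v_z[jj, 1L] <- 2 * a_fit / Fz[jj]^2
  v_z[jj, 2L] <- (2 * a_fit + 4 * b_fit * s[2L]^2) / Fz[jj]^2
  list(v_z = v_z, v_r = v_r)
}

#' Tangential cortical velocity profile
#'
#' Slip speed along the cell surface, signed positive from the source pole
#' (`z = +R_half`) towards the drain pole, from a second-order one-sided
#' normal derivative of the stream function at the wall.
#'
#' @param flow A [solve_stokes()] result.
#' @return Data frame with columns `z` and `v_t` (0 at the poles).
#' @export
cortical_velocity <- function(flow) {
  stopifnot(inherits(flow, "flow_field"))
  data.frame(z = flow$grid$z, v_t = flow$vt_wall)
}

#' Net volumetric flux through cross-sections
#'
#' For every axial station the flux between axis and boundary is
#' \eqn{2\pi(\Psi_{wall} - \Psi_{axis})}, which must vanish in a closed
#' cell (mass conservation). `method = "quadrature"` instead integrates the
#' reconstructed \eqn{v_z} over the cross-section, which carries the
#' discretisation error of the velocity reconstruction.
#'
#' @param flow A `flow_field`.
#' @param method `"stream"` (exact identity) or `"quadrature"`.
#' @return Numeric vector of fluxes per axial node.
#' @export
section_flux <- function(flow, method = c("stream", "quadrature")) {
  method <- match.arg(method)
  g <- flow$grid
  nk <- g$Ns + 1L
  if (method == "stream") {
    2 * pi * (flow$Psi[, nk] - flow$Psi[, 1L])
  } else {
    vapply(seq_along(g$z), function(j) {
      r <- g$r[j, ]
      2 * pi * trapz(r, flow$v_z[j, ] * r)
    }, 0)
  }
}

#' Bilinear interpolation of a flow field at arbitrary points
#'
#' Maps each `(z, r)` point to boundary-fitted coordinates `(z, s = r/F(z))`
#' and interpolates `v_z` and `v_r` bilinearly between grid nodes.
#'
#' @param flow A `flow_field`.
#' @param z,r Point coordinates (inside the boundary; `s` is clamped to
#'   `[0, 1]` against rounding).
#' @return Data frame with columns `v_z`, `v_r`.
#' @export
interp_velocity <- function(flow, z, r) {
  g <- flow$grid
  L <- g$shape$half_length
  if (any(z < -L - 1e-9 | z > L + 1e-9)) stopf("points outside the axial range")
  Fz <- g$shape$F(z)
  s <- ifelse(Fz > 0, r / Fz, 0)
  if (any(s > 1 + 1e-6)) stopf("points outside the boundary (r > F(z))")
  s <- pmin(pmax(s, 0), 1)
  zc <- pmin(pmax(z, -L), L)
  jf <- (zc - g$z[1L]) / g$dz
  kf <- s / g$ds
  j0 <- pmin(pmax(floor(jf), 0), g$Nz - 1L)
  k0 <- pmin(pmax(floor(kf), 0), g$Ns - 1L)
  tz <- jf - j0
  ts <- kf - k0
  idx <- function(M, j, k) M[cbind(j + 1L, k + 1L)]
  bil <- function(M) {
    (1 - tz) * (1 - ts) * idx(M, j0, k0) +
      tz * (1 - ts) * idx(M, j0 + 1L, k0) +
      (1 - tz) * ts * idx(M, j0, k0 + 1L) +
      tz * ts * idx(M, j0 + 1L, k0 + 1L)
  }
  data.frame(v_z = bil(flow$v_z), v_r = bil(flow$v_r))
}

#' Export a flow field as a tidy table
#'
#' @param flow A `flow_field`.
#' @return Data frame with one row per node: `z`, `r`, `v_z`, `v_r`, `Psi`,
#'   `Omega`.
#' @export
flow_table <- function(flow) {
  g <- flow$grid
  df <- as.data.frame(g)
  df$v_z <- as.vector(flow$v_z)
  df$v_r <- as.vector(flow$v_r)
  df$Psi <- as.vector(flow$Psi)
  df$Omega <- as.vector(flow$Omega)
  df[, c("z", "r", "v_z", "v_r", "Psi", "Omega")]
}

#' Write / read a flow field as CSV
#'
#' The CSV holds the [flow_table()] plus provenance comment lines
#' (`# key: value`) recording the shape, grid, viscosity and convergence,
#' so the field can be reconstructed exactly by [read_flow_csv()].
#'
#' @param flow A `flow_field`.
#' @param path CSV path.
#' @return `write_flow_csv()` returns `path` invisibly; `read_flow_csv()`
#'   a `flow_field`.
#' @export
write_flow_csv <- function(flow, path) {
  g <- flow$grid
  sh <- g$shape
  hdr <- c(
    sprintf("# shape: %s", sh$kind),
    sprintf("# short_radius: %.17g", sh$short_radius),
    sprintf("# long_axis: %.17g", 2 * sh$half_length),
    sprintf("# grid: %d %d", g$Nz, g$Ns),
    sprintf("# mu: %.17g", flow$mu),
    sprintf("# converged: %s", flow$converged),
    sprintf("# iterations: %d", flow$iterations))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(format(flow_table(flow), digits = 17, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_flow_csv
#' @export
read_flow_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE))
  kind <- get("shape")
  shape <- if (kind == "sphere") {
    make_sphere(as.numeric(get("short_radius")))
  } else {
    make_capsule(as.numeric(get("short_radius")),
                 as.numeric(get("long_axis")))
  }
  gg <- as.integer(strsplit(get("grid"), " ")[[1L]])
  grid <- build_grid(shape, gg[1L], gg[2L])
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  nj <- gg[1L] + 1L; nk <- gg[2L] + 1L
  Psi <- matrix(df$Psi, nj, nk)
  Omega <- matrix(df$Omega, nj, nk)
  vt <- numeric(nj)
  jj <- 2:(nj - 1L)
  ps_wall <- (Psi[jj, nk - 2L] - 4 * Psi[jj, nk - 1L]) / (2 * grid$ds)
  vt[jj] <- -sqrt(1 + grid$dF[jj]^2) / grid$F[jj]^2 * ps_wall
  structure(list(
    grid = grid, Psi = Psi, Omega = Omega,
    v_z = matrix(df$v_z, nj, nk), v_r = matrix(df$v_r, nj, nk),
    vt_wall = vt, tau_wall = NULL, mu = as.numeric(get("mu")),
    converged = as.logical(get("converged")),
    iterations = as.integer(get("iterations")),
    residuals = c(Psi = NA_real_, Omega = NA_real_),
    residual_history = NULL, control = list()
  ), class = "flow_field")
}
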