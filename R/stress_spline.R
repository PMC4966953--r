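#' Cortical shear-stress profile as a clamped cubic B-spline
#'
#' The tangential stress exerted by the cortex on the cytoplasm is
#' parametrised as \eqn{\tau(z) = \sum_i \theta_i B_i(z)}, a cubic B-spline
#' over the source-drain axis whose free control points (de Boor points)
#' \eqn{\Theta = (\tau_1, \ldots, \tau_{N})} are the model parameters
#' (default `N = 7`). The end control points are pinned at zero on a knot
#' vector with full multiplicity at the poles — the functional counterpart
#' of placing repeated zero nodes at each pole — so \eqn{\tau(\pm R) = 0}
#' exactly while the slope at the poles stays free (profiles like
#' \eqn{(1 - z^2)^{1/2}}, with vertical tangents at the poles, remain
#' representable). By the convex-hull property \eqn{\tau(z) \ge 0}
#' whenever all \eqn{\theta_i \ge 0} (the assumption that stress always
#' points from the source towards the drain pole). Positive stress drives
#' cortical flow from source to drain.
#'
#' Interior knots are uniform between the poles by default (`spacing =
#' "uniform"`); `spacing = "sine"` clusters them towards the poles, which
#' represents pole-steep profiles slightly better. `node_z` reports the
#' Greville abscissae of the free control points, the natural axial
#' position associated with each amplitude.
#'
#' @param amplitudes Numeric vector of free control-point amplitudes
#'   \eqn{\Theta} (non-dimensional stress); at least 2.
#' @param R_half Half the source-drain distance (source pole at `+R_half`).
#' @param knots Optional interior-knot vector (length `n - 2`) overriding
#'   `spacing`; must be strictly inside `(-R_half, R_half)`.
#' @param spacing `"uniform"` (default) or `"sine"`.
#' @return An object of class `stress_spline` with fields `amplitudes`,
#'   `n_nodes`, `R_half`, `degree`, `knots` (full knot vector) and `node_z`.
#' @examples
#' sp <- stress_spline(rep(1.5, 7), R_half = 1)
#' evaluate_stress(sp, c(-1, 0, 1)) # zero at both poles
#' @export
stress_spline <- function(amplitudes, R_half = 1, knots = NULL,
                          spacing = c("uniform", "sine")) {
  n <- length(amplitudes)
  if (n < 2L) stopf("need at least two amplitudes")
  if (R_half <= 0) stopf("`R_half` must be positive")
  degree <- 3L
  n_cp <- n + 2L # one pinned zero control point at each pole
  n_int <- n_cp - degree - 1L
  if (is.null(knots)) {
    spacing <- match.arg(spacing)
    u <- seq(-1, 1, length.out = n_int + 2L)[-c(1L, n_int + 2L)]
    interior <- if (spacing == "uniform") R_half * u else
      R_half * sin(u * pi / 2)
  } else {
    interior <- knots
    if (length(interior) != n_int) {
      stopf("`knots` must have length %d for %d amplitudes", n_int, n)
    }
    if (any(interior <= -R_half | interior >= R_half)) {
      stopf("interior knots must lie strictly between the poles")
    }
  }
  kv <- c(rep(-R_half, degree + 1L), interior, rep(R_half, degree + 1L))
  # Greville abscissae of the free control points (indices 2..n+1)
  grev <- vapply(seq_len(n_cp), function(i) mean(kv[(i + 1L):(i + degree)]), 0)
  structure(list(
    amplitudes = as.numeric(amplitudes),
    n_nodes = n,
    R_half = R_half,
    degree = degree,
    knots = kv,
    node_z = grev[2:(n + 1L)],
    control = c(0, as.numeric(amplitudes), 0)
  ), class = "stress_spline")
}

#' @export
print.stress_spline <- function(x, digits = 4, ...) {
  cat(sprintf("Cortical stress spline: %d free nodes on [-%g, %g]\n",
              x$n_nodes, x$R_half, x$R_half))
  print(round(rbind(node_z = x$node_z, tau = x$amplitudes), digits))
  invisible(x)
}

#' Evaluate a stress spline
#'
#' @param spline A [stress_spline()].
#' @param z Axial positions in `[-R_half, R_half]`.
#' @return \eqn{\tau(z)}, exactly 0 at the poles.
#' @export
evaluate_stress <- function(spline, z) {
  stopifnot(inherits(spline, "stress_spline"))
  R <- spline$R_half
  if (any(z < -R - 1e-12 | z > R + 1e-12)) {
    stopf("`z` outside [-R_half, R_half]")
  }
  z <- pmin(pmax(z, -R), R)
  B <- splines::splineDesign(spline$knots, z, ord = spline$degree + 1L,
                             outer.ok = FALSE)
  as.vector(B %*% spline$control)
}

#' @export
predict.stress_spline <- function(object, z, ...) evaluate_stress(object, z)

#' Total cortical stress over the cell surface
#'
#' Integrates \eqn{\tau(z)} over the axisymmetric boundary,
#' \eqn{\int \tau \, dA = 2\pi \int \tau(z) F(z) \sqrt{1 + F'(z)^2} \, dz},
#' by adaptive quadrature. (For the sphere and capsule the area element
#' simplifies to \eqn{2\pi\,dz}.) An axial line integral
#' \eqn{\int \tau(z)\,dz} is available via `measure = "line"` since "total
#' stress" admits either reading; the surface integral is the default used
#' by the pressure-gradient comparisons.
#'
#' @inheritParams evaluate_stress
#' @param shape The boundary the stress acts on.
#' @param measure `"surface"` (default) or `"line"`.
#' @return A scalar.
#' @export
total_stress <- function(spline, shape, measure = c("surface", "line")) {
  stopifnot(inherits(spline, "stress_spline"), inherits(shape, "boundary_shape"))
  measure <- match.arg(measure)
  L <- min(spline$R_half, shape$half_length)
  f <- if (measure == "surface") {
    function(z) {
      d1 <- shape$dF(z)
      d1[!is.finite(d1)] <- 0
      2 * pi * evaluate_stress(spline, z) * shape$F(z) * sqrt(1 + d1^2)
    }
  } else {
    function(z) evaluate_stress(spline, z)
  }
  # integrand is bounded (F sqrt(1+F'^2) -> finite at the poles); split at
  # capsule junctions where derivatives jump
  brk <- unique(sort(c(-L, L, if (!is.null(shape$cylinder_half))
    c(-shape$cylinder_half, shape$cylinder_half))))
  tot <- 0
  for (i in seq_len(length(brk) - 1L)) {
    tot <- tot + stats::integrate(f, brk[i], brk[i + 1L],
                                  rel.tol = 1e-9, subdivisions = 400L)$value
  }
  tot
}

#' Rescale a stress spline to a target total
#'
#' Pure scaling of the amplitudes so that [total_stress()] equals `target`
#' (1.5 in the non-dimensional system used for the pressure-gradient
#' comparison); the shape of the profile is preserved.
#'
#' @inheritParams total_stress
#' @param target Desired total stress (default 1.5).
#' @return A new `stress_spline`.
#' @export
normalize_total <- function(spline, shape, target = 1.5,
                            measure = c("surface", "line")) {
  measure <- match.arg(measure)
  tot <- total_stress(spline, shape, measure)
  if (tot <= 0) stopf("total stress must be positive to normalize (got %g)", tot)
  stress_spline(spline$amplitudes * (target / tot), R_half = spline$R_half,
                knots = spline$knots[(spline$degree + 2L):(length(spline$knots) - spline$degree - 1L)])
}

#' Least-squares fit of a stress spline to a target curve
#'
#' Finds the amplitudes minimising the L2 misfit to `tau_fun` on a dense
#' axial grid; used e.g. to express the analytic benchmark profile
#' \eqn{3(1-z^2)^{1/2}} in the 7-node family.
#'
#' @param tau_fun Function of `z` returning the target stress.
#' @param R_half Half source-drain distance.
#' @param n_nodes Number of free control points.
#' @param n_grid Number of fit points.
#' @return A `stress_spline`.
#' @export
fit_stress_spline <- function(tau_fun, R_half = 1, n_nodes = 7, n_grid = 201) {
  z <- seq(-R_half, R_half, length.out = n_grid)
  proto <- stress_spline(rep(0, n_nodes), R_half = R_half)
  B <- splines::splineDesign(proto$knots, z, ord = 4L)
  Bfree <- B[, 2:(n_nodes + 1L), drop = FALSE]
  theta <- qr.solve(crossprod(Bfree), crossprod(Bfree, tau_fun(z)))
  stress_spline(as.vector(theta), R_half = R_half)
}

#' Read / write stress-spline parameters as JSON
#'
#' Round-trips `{node_z, tau, R_half}` through a plain JSON file.
#'
#' @param spline A `stress_spline`.
#' @param path File path.
#' @return `read_stress_json()` returns a `stress_spline`;
#'   `write_stress_json()` returns `path` invisibly.
#' @export
write_stress_json <- function(spline, path) {
  jsonlite::write_json(list(node_z = spline$node_z,
                            tau = spline$amplitudes,
                            R_half = spline$R_half),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_stress_json
#' @export
read_stress_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stress_spline(x$tau, R_half = x$R_half)
}
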