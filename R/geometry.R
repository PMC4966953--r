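#' Axisymmetric cell boundaries
#'
#' Cells are modelled as solids of revolution about the source-drain axis:
#' the boundary is the curve \eqn{r = F(z)} for `z` in `[-half_length,
#' half_length]`, with the source pole at `z = +half_length` and the drain
#' pole at `z = -half_length`. Two idealised outlines are supported: a sphere
#' (mouse oocyte) and a capsule, i.e. a cylinder with hemispherical caps
#' (C. elegans embryo). All lengths are non-dimensional; by convention the
#' short radius of the cell is 1.
#'
#' @param radius Sphere radius (> 0).
#' @return An object of class `boundary_shape`: a list with fields `kind`,
#'   `short_radius`, `half_length` and the functions `F`, `dF`, `d2F`
#'   (radius and its first two axial derivatives). At the capsule
#'   cap-cylinder junction the derivatives carry the cap-side one-sided
#'   values (`dF` is continuous there by tangency; `d2F` jumps from 0 to
#'   the cap value).
#' @seealso [make_capsule()], [build_grid()], [surface_curvature_radius()]
#' @examples
#' sph <- make_sphere(1)
#' sph$F(0.6)   # 0.8 by the 3-4-5 identity
#' @export
make_sphere <- function(radius = 1) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stopf("`radius` must be a single positive number")
  }
  Ffun <- function(z) {
    v <- radius^2 - z^2
    sqrt(pmax(v, 0))
  }
  structure(list(
    kind = "sphere",
    short_radius = radius,
    half_length = radius,
    F = Ffun,
    dF = function(z) ifelse(abs(z) >= radius, NA_real_, -z / Ffun(z)),
    d2F = function(z) ifelse(abs(z) >= radius, NA_real_, -radius^2 / Ffun(z)^3)
  ), class = "boundary_shape")
}

#' @rdname make_sphere
#' @param short_radius Cylinder (and cap) radius.
#' @param long_axis Total axial extent; must be at least `2 * short_radius`.
#'   The C. elegans default aspect gives `long_axis = 55/13` in units of the
#'   short radius.
#' @export
make_capsule <- function(short_radius = 1, long_axis = 55 / 13) {
  if (short_radius <= 0) stopf("`short_radius` must be positive")
  if (long_axis < 2 * short_radius) {
    stopf("`long_axis` (%g) must be >= 2 * short_radius (%g)",
          long_axis, 2 * short_radius)
  }
  a <- short_radius
  L <- long_axis / 2
  zc <- L - a # cap-cylinder junction distance from centre
  Ffun <- function(z) {
    out <- rep(a, length(z))
    cap <- abs(z) > zc
    out[cap] <- sqrt(pmax(a^2 - (abs(z[cap]) - zc)^2, 0))
    out
  }
  dFfun <- function(z) {
    out <- numeric(length(z))
    cap <- abs(z) > zc & abs(z) < L
    zz <- abs(z[cap]) - zc
    out[cap] <- -sign(z[cap]) * zz / sqrt(a^2 - zz^2)
    out[abs(z) >= L] <- NA_real_
    out
  }
  d2Ffun <- function(z) {
    # cap-side one-sided value at the junction node (|z| == zc)
    out <- numeric(length(z))
    cap <- abs(z) >= zc & abs(z) < L
    zz <- abs(z[cap]) - zc
    out[cap] <- -a^2 / (a^2 - zz^2)^1.5
    out[abs(z) >= L] <- NA_real_
    out
  }
  structure(list(
    kind = "capsule",
    short_radius = a,
    half_length = L,
    cylinder_half = zc,
    F = Ffun,
    dF = dFfun,
    d2F = d2Ffun
  ), class = "boundary_shape")
}

#' @export
print.boundary_shape <- function(x, ...) {
  cat(sprintf("Axisymmetric boundary: %s (short radius %g, half length %g)\n",
              x$kind, x$short_radius, x$half_length))
  invisible(x)
}

#' Convert between axial coordinate frames
#'
#' Observation tables record axial position as the distance from the source
#' pole; the solver works in a frame centred on the cell, with the source
#' pole at `z = +half_length` and the drain pole at `z = -half_length`.
#'
#' @param shape A [make_sphere()] / [make_capsule()] boundary.
#' @param d Distance from the source pole (non-negative, at most the full
#'   source-drain distance).
#' @param z Centred axial coordinate.
#' @return The coordinate in the other frame.
#' @export
axial_from_source <- function(shape, d) shape$half_length - d

#' @rdname axial_from_source
#' @export
axial_to_source <- function(shape, z) shape$half_length - z

#' Meridional curvature radius of the boundary
#'
#' Radius of curvature of the boundary curve \eqn{r = F(z)} in the meridional
#' `(z, r)` plane. On straight segments (the capsule cylinder) the radius is
#' infinite, so the wall-vorticity curvature term `2 v_t / R` vanishes there.
#' The azimuthal (hoop) curvature is deliberately not used: for the shapes
#' supported here (sphere and capsule) the meridional radius reproduces the
#' analytic wall vorticity exactly on both the caps and the cylinder.
#'
#' @inheritParams axial_from_source
#' @param z Axial position strictly inside `(-half_length, half_length)`.
#' @return Curvature radius (possibly `Inf`), vectorised over `z`.
#' @export
surface_curvature_radius <- function(shape, z) {
  L <- shape$half_length
  if (any(abs(z) >= L)) stopf("`z` must lie strictly between the poles")
  d1 <- shape$dF(z)
  d2 <- shape$d2F(z)
  out <- ifelse(abs(d2) < 1e-12, Inf, (1 + d1^2)^1.5 / (-d2))
  out
}

#' Boundary-fitted curvilinear grid
#'
#' Maps the cell interior to the rectangle `(z, s)` with `s = r / F(z)`:
#' `s = 0` is the symmetry axis, `s = 1` the cell surface. `Nz` and `Ns`
#' count grid *intervals* along the axis and in `s` (56 x 14 was used for
#' the C. elegans capsule, 25 x 13 for the mouse sphere), so the grid holds
#' `(Nz + 1) x (Ns + 1)` nodes, uniformly spaced in both directions. The
#' metric terms of the coordinate change are stored per node:
#' `S_r = 1/F`, `S_z = -(s/F) F'`, `S_zz = (s/F) (2 F'^2 / F - F'')` and
#' `S_rr = 0`. Pole columns (where `F = 0`) carry `NA` metrics; they enter
#' the solver only as Dirichlet data.
#'
#' @inheritParams axial_from_source
#' @param Nz,Ns Number of intervals along the axis / in `s` (`Nz >= 8`,
#'   `Ns >= 4`).
#' @return An object of class `curvi_grid`.
#' @examples
#' g <- build_grid(make_sphere(), 25, 13)
#' range(g$r[2:25, ] - outer(g$F[2:25], g$s)) # r = s * F(z) exactly
#' @export
build_grid <- function(shape, Nz, Ns) {
  stopifnot(inherits(shape, "boundary_shape"))
  if (Nz < 8L) stopf("`Nz` must be at least 8")
  if (Ns < 4L) stopf("`Ns` must be at least 4")
  L <- shape$half_length
  z <- seq(-L, L, length.out = Nz + 1L)
  s <- seq(0, 1, length.out = Ns + 1L)
  Fz <- shape$F(z)
  Fz[c(1L, Nz + 1L)] <- 0 # exact pole closure
  if (any(Fz[2:Nz] <= 0)) stopf("degenerate shape: F(z) = 0 at an interior node")
  dFz <- shape$dF(z)
  d2Fz <- shape$d2F(z)
  dFz[c(1L, Nz + 1L)] <- NA_real_
  d2Fz[c(1L, Nz + 1L)] <- NA_real_
  Sr <- ifelse(Fz > 0, 1 / Fz, NA_real_)
  Sz <- outer(ifelse(Fz > 0, dFz / Fz, NA_real_), s, function(a, b) -a * b)
  Szz <- outer(ifelse(Fz > 0, (2 * dFz^2 / Fz - d2Fz) / Fz, NA_real_), s)
  r <- outer(Fz, s)
  structure(list(
    shape = shape, Nz = Nz, Ns = Ns,
    z = z, s = s, dz = z[2L] - z[1L], ds = s[2L] - s[1L],
    F = Fz, dF = dFz, d2F = d2Fz,
    Sr = Sr, Sz = Sz, Szz = Szz, Srr = 0,
    r = r
  ), class = "curvi_grid")
}

#' @export
print.curvi_grid <- function(x, ...) {
  cat(sprintf("Boundary-fitted grid: %s, %d x %d intervals (%d x %d nodes)\n",
              x$shape$kind, x$Nz, x$Ns, x$Nz + 1L, x$Ns + 1L))
  invisible(x)
}

#' Node table of a curvilinear grid
#'
#' Serialises the grid as one row per node with its indices, physical
#' coordinates and metric terms, for inspection or export.
#'
#' @param x A `curvi_grid`.
#' @param ... Unused.
#' @return A data frame with columns `j`, `k`, `z`, `s`, `r`, `S_r`, `S_z`,
#'   `S_zz`.
#' @export
as.data.frame.curvi_grid <- function(x, ...) {
  nj <- x$Nz + 1L
  nk <- x$Ns + 1L
  jj <- rep(seq_len(nj), times = nk)
  kk <- rep(seq_len(nk), each = nj)
  data.frame(
    j = jj, k = kk,
    z = x$z[jj], s = x$s[kk], r = as.vector(x$r),
    S_r = x$Sr[jj], S_z = as.vector(x$Sz), S_zz = as.vector(x$Szz)
  )
}
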