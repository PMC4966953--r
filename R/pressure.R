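#' Reconstruct the pressure field from a converged flow
#'
#' Evaluates the pressure gradient of the steady Stokes momentum balance,
#' \deqn{\partial p/\partial z = \mu\,(u_{z,rr} + u_{z,r}/r + u_{z,zz}),
#' \qquad \partial p/\partial r = \mu\,(u_{r,rr} + u_{r,r}/r + u_{r,zz} -
#' u_r/r^2),} and line-integrates it from the drain pole, where the
#' reference `p = 0` is set: first along the symmetry axis, then radially
#' outwards at each axial station. (The \eqn{-u_r/r^2} term belongs to the
#' axisymmetric vector Laplacian; without it the gradient field is not
#' curl-free and path closure fails.)
#'
#' Two discretisations of the same right-hand side are available. The
#' default, `method = "vorticity"`, uses the divergence-free identity
#' \eqn{\mu \nabla^2 u = -\mu \nabla\times\Omega}, i.e.
#' \eqn{\partial p/\partial z = -\mu (\partial\Omega/\partial r + \Omega/r)}
#' and \eqn{\partial p/\partial r = \mu\,\partial\Omega/\partial z}: it
#' differentiates the solver's vorticity once instead of the reconstructed
#' velocities twice and is markedly more accurate on coarse grids.
#' `method = "velocity"` evaluates the velocity form directly with
#' first-order one-sided differences (`order = 1`) or centred differences
#' (`order = 2`) for the first derivatives; it evaluates the momentum
#' balance exactly as written but triple-differentiates the stream function, and on the
#' grid sizes used here its loop-closure error does not vanish under
#' refinement. All derivatives are taken in boundary-fitted `(z, s)`
#' coordinates via the chain rule.
#'
#' Pressure is defined only up to the additive reference. As a quality
#' metric the gradient field is integrated a second way (radially at the
#' mid column, then axially along constant-`s` rows); `path_residual` is
#' the largest disagreement between the two routes over interior nodes
#' with `|z| <= 0.8 half_length`, relative to the pressure range. The
#' pole-adjacent columns are excluded because the boundary-fitted map is
#' singular there (`F' -> Inf` on curved caps); inside the retained region
#' the residual shrinks as O(h^2).
#'
#' @param flow A converged [solve_stokes()] result.
#' @param method `"vorticity"` (default) or `"velocity"`; see Details.
#' @param order First-derivative differencing for `method = "velocity"`:
#'   1 (one-sided) or 2 (centred).
#' @return An object of class `pressure_field`: matrix `p` over the grid
#'   (`NA` on the degenerate pole columns is replaced by the adjacent
#'   axial value), `gradient_profile` (\eqn{\partial p/\partial z} along
#'   the axis), `path_residual`, and the grid.
#' @export
compute_pressure <- function(flow, method = c("vorticity", "velocity"),
                             order = 1) {
  stopifnot(inherits(flow, "flow_field"))
  method <- match.arg(method)
  if (!flow$converged) stopf("pressure requires a converged flow field")
  if (!order %in% c(1, 2)) stopf("`order` must be 1 or 2")
  g <- flow$grid
  nj <- g$Nz + 1L; nk <- g$Ns + 1L
  jj <- 2:(nj - 1L)

  G <- if (method == "vorticity") {
    pressure_rhs_vorticity(flow)
  } else {
    pressure_rhs_velocity(flow, order)
  }

  ct <- function(x, y) c(0, cumsum((x[-1L] - x[-length(x)]) *
                                     (y[-1L] + y[-length(y)]) / 2))
  # drain pole -> source pole along the axis, then radially outwards
  p <- matrix(NA_real_, nj, nk)
  ax <- ct(g$z[jj], G$Gz[jj, 1L])
  for (i in seq_along(jj)) {
    j <- jj[i]
    p[j, ] <- ax[i] + ct(g$s, g$F[j] * G$Gr[j, ])
  }
  p[1L, ] <- p[2L, 1L] # pole columns collapse to single physical points
  p[nj, ] <- p[nj - 1L, 1L] + g$dz * G$Gz[nj - 1L, 1L]
  p <- p - p[1L, 1L]   # reference: p = 0 at the drain pole

  # radial-first route anchored at the mid column, for the closure metric
  jmid <- jj[which.min(abs(g$z[jj]))]
  radm <- p[jmid, 1L] + ct(g$s, g$F[jmid] * G$Gr[jmid, ])
  Gz_s <- G$Gz + outer(rep(1, nj), g$s) * outer(g$dF, rep(1, nk)) * G$Gr
  p_alt <- matrix(NA_real_, nj, nk)
  for (k in seq_len(nk)) {
    pa <- numeric(nj)
    pa[jj] <- ct(g$z[jj], Gz_s[jj, k])
    p_alt[jj, k] <- radm[k] + pa[jj] - pa[jmid]
  }
  sel_j <- jj[abs(g$z[jj]) <= 0.8 * g$shape$half_length]
  rng <- diff(range(p[jj, ]))
  path_residual <- if (rng > 0) {
    max(abs(p[sel_j, 2:(nk - 1L)] - p_alt[sel_j, 2:(nk - 1L)])) / rng
  } else 0

  structure(list(
    grid = g, p = p, mu = flow$mu,
    gradient_profile = G$Gz[, 1L],
    path_residual = path_residual,
    method = method, order = order
  ), class = "pressure_field")
}

# dp gradient via -mu curl(Omega): first derivatives of the vorticity field
pressure_rhs_vorticity <- function(flow) {
  g <- flow$grid
  nj <- g$Nz + 1L; nk <- g$Ns + 1L
  ds <- g$ds; dz <- g$dz
  W <- flow$Omega
  mu <- flow$mu
  Ws <- matrix(0, nj, nk)
  Ws[, 2:(nk - 1L)] <- (W[, 3:nk] - W[, 1:(nk - 2L)]) / (2 * ds)
  Ws[, nk] <- (3 * W[, nk] - 4 * W[, nk - 1L] + W[, nk - 2L]) / (2 * ds)
  Ws[, 1L] <- (-3 * W[, 1L] + 4 * W[, 2L] - W[, 3L]) / (2 * ds)
  Wz <- matrix(0, nj, nk)
  Wz[2:(nj - 1L), ] <- (W[3:nj, ] - W[1:(nj - 2L), ]) / (2 * dz)
  Gz <- matrix(NA_real_, nj, nk)
  Gr <- matrix(NA_real_, nj, nk)
  for (j in 2:(nj - 1L)) {
    r <- g$F[j] * g$s
    Wr <- g$Sr[j] * Ws[j, ]
    # Omega is odd in r, so Omega/r -> dOmega/dr on the axis
    Gz[j, ] <- -mu * (Wr + c(Wr[1L], W[j, -1L] / r[-1L]))
    Gr[j, ] <- mu * (Wz[j, ] + g$Sz[j, ] * Ws[j, ])
  }
  list(Gz = Gz, Gr = Gr)
}

# dp gradient via the velocity Laplacian (direct discretisation)
pressure_rhs_velocity <- function(flow, order) {
  g <- flow$grid
  nj <- g$Nz + 1L; nk <- g$Ns + 1L
  ds <- g$ds; dz <- g$dz
  mu <- flow$mu
  s <- g$s; Fz <- g$F
  jj <- 2:(nj - 1L)
  d1 <- function(M, along) {
    D <- matrix(NA_real_, nj, nk)
    if (along == "s") {
      if (order == 1) {
        D[, 1:(nk - 1L)] <- (M[, 2:nk] - M[, 1:(nk - 1L)]) / ds
        D[, nk] <- (M[, nk] - M[, nk - 1L]) / ds
      } else {
        D[, 2:(nk - 1L)] <- (M[, 3:nk] - M[, 1:(nk - 2L)]) / (2 * ds)
        D[, 1L] <- (M[, 2L] - M[, 1L]) / ds
        D[, nk] <- (M[, nk] - M[, nk - 1L]) / ds
      }
    } else {
      if (order == 1) {
        D[1:(nj - 1L), ] <- (M[2:nj, ] - M[1:(nj - 1L), ]) / dz
        D[nj, ] <- (M[nj, ] - M[nj - 1L, ]) / dz
      } else {
        D[2:(nj - 1L), ] <- (M[3:nj, ] - M[1:(nj - 2L), ]) / (2 * dz)
        D[1L, ] <- (M[2L, ] - M[1L, ]) / dz
        D[nj, ] <- (M[nj, ] - M[nj - 1L, ]) / dz
      }
    }
    D
  }
  d1c <- function(M, along) { # centred (used where 1/r weighting demands it)
    D <- matrix(NA_real_, nj, nk)
    if (along == "s") {
      D[, 2:(nk - 1L)] <- (M[, 3:nk] - M[, 1:(nk - 2L)]) / (2 * ds)
      D[, 1L] <- (M[, 2L] - M[, 1L]) / ds
      D[, nk] <- (M[, nk] - M[, nk - 1L]) / ds
    } else {
      D[2:(nj - 1L), ] <- (M[3:nj, ] - M[1:(nj - 2L), ]) / (2 * dz)
      D[1L, ] <- (M[2L, ] - M[1L, ]) / dz
      D[nj, ] <- (M[nj, ] - M[nj - 1L, ]) / dz
    }
    D
  }
  d2 <- function(M, along) {
    D <- matrix(NA_real_, nj, nk)
    if (along == "s") {
      D[, 2:(nk - 1L)] <- (M[, 3:nk] - 2 * M[, 2:(nk - 1L)] + M[, 1:(nk - 2L)]) / ds^2
      D[, 1L] <- (M[, 3L] - 2 * M[, 2L] + M[, 1L]) / ds^2
      D[, nk] <- (M[, nk] - 2 * M[, nk - 1L] + M[, nk - 2L]) / ds^2
    } else {
      D[2:(nj - 1L), ] <- (M[3:nj, ] - 2 * M[2:(nj - 1L), ] + M[1:(nj - 2L), ]) / dz^2
      D[1L, ] <- (M[3L, ] - 2 * M[2L, ] + M[1L, ]) / dz^2
      D[nj, ] <- (M[nj, ] - 2 * M[nj - 1L, ] + M[nj - 2L, ]) / dz^2
    }
    D
  }
  lap <- function(U, swirl_term) {
    Us <- d1(U, "s")
    # the 1/r-weighted derivative must be centred: a one-sided difference
    # divided by r has an O(ds/s) error that does not vanish near the axis
    Usc <- d1c(U, "s")
    Uss <- d2(U, "s"); Uzz <- d2(U, "z")
    Usz <- d1(d1(U, "s"), "z")
    G <- matrix(NA_real_, nj, nk)
    for (j in jj) {
      Sr <- g$Sr[j]
      Urr <- Sr^2 * Uss[j, ]
      Uzz_r <- Uzz[j, ] + 2 * g$Sz[j, ] * Usz[j, ] +
        g$Sz[j, ]^2 * Uss[j, ] + g$Szz[j, ] * Us[j, ]
      r <- Fz[j] * s
      over_r <- c(NA_real_, Sr * Usc[j, -1L] / r[-1L])
      G[j, ] <- Urr + over_r + Uzz_r
      if (swirl_term) {
        G[j, -1L] <- G[j, -1L] - U[j, -1L] / r[-1L]^2
      } else {
        # axis limit: u_z even in r, so u_z,r/r -> u_z,rr
        G[j, 1L] <- 2 * Sr^2 * 2 * (U[j, 2L] - U[j, 1L]) / ds^2 + Uzz_r[1L]
      }
    }
    G
  }
  Gz <- mu * lap(flow$v_z, swirl_term = FALSE)
  Gr <- mu * lap(flow$v_r, swirl_term = TRUE)
  Gr[, 1L] <- 0 # u_r odd in r: dp/dr vanishes on the axis
  list(Gz = Gz, Gr = Gr)
}

#' @export
print.pressure_field <- function(x, ...) {
  jj <- 2:(x$grid$Nz)
  cat(sprintf(
    "Pressure field on %d x %d grid (%s form): range [%.4g, %.4g] (p = 0 at drain pole)\n  path-closure residual: %.3g\n",
    x$grid$Nz, x$grid$Ns, x$method, min(x$p[jj, ]), max(x$p[jj, ]),
    x$path_residual))
  invisible(x)
}

#' Pressure gradient at the source pole
#'
#' Least-squares slope of the axial pressure profile over the window of the
#' axis nearest the source pole (`z = +R_half`).
#'
#' @param pf A [compute_pressure()] field.
#' @param window Fraction of the axial extent to fit over (default 0.1, the
#'   last 10 percent before the source pole).
#' @return The fitted slope \eqn{\partial p/\partial z} (a scalar).
#' @export
source_gradient <- function(pf, window = 0.1) {
  stopifnot(inherits(pf, "pressure_field"))
  g <- pf$grid
  z <- g$z
  keep <- z >= max(z) - window * diff(range(z))
  if (sum(keep) < 3L) {
    stopf("window covers %d grid points; at least 3 are required", sum(keep))
  }
  unname(coef(lm(pf$p[keep, 1L] ~ z[keep]))[2L])
}

#' Welch comparison of source-pole pressure gradients
#'
#' Two-sample t test with unequal variances between two groups of pressure
#' gradients (e.g. one value per cell for two species).
#'
#' @param gradients_a,gradients_b Numeric vectors (length >= 2 each).
#' @return A list with `t`, `df`, `p_value`, group `means` and `sds`, and a
#'   `degenerate` flag set when both groups have zero variance (the t
#'   statistic is undefined there).
#' @export
compare_gradients <- function(gradients_a, gradients_b) {
  if (length(gradients_a) < 2L || length(gradients_b) < 2L) {
    stopf("need at least 2 values per group")
  }
  m <- c(mean(gradients_a), mean(gradients_b))
  s <- c(sd(gradients_a), sd(gradients_b))
  if (all(s == 0)) {
    return(list(t = if (m[1L] == m[2L]) 0 else sign(m[1L] - m[2L]) * Inf,
                df = NA_real_,
                p_value = if (m[1L] == m[2L]) 1 else 0,
                means = m, sds = s, degenerate = TRUE))
  }
  tt <- stats::t.test(gradients_a, gradients_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, means = m, sds = s, degenerate = FALSE)
}
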