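#' Fit a cortical stress distribution to an observed flow field
#'
#' The package's central fitting function: given velocity observations
#' inside an axisymmetric cell, estimates the cortical shear-stress
#' profile \eqn{\tau(z)} (a clamped cubic B-spline, [stress_spline()])
#' whose simulated Stokes flow best explains the data, by two-round
#' sampling-based Bayesian data assimilation ([run_inference()]).
#'
#' The prior defaults to the mouse-style construction for spheres
#' ([prior_mouse()]) and to profile-matching of the cortical points for
#' capsules ([prior_from_cortical()] on [project_cortical()] of the
#' outermost observations); pass `prior` to override.
#'
#' @param obs An [observations()] object (or path to an observation CSV,
#'   forwarded to [read_observations()]).
#' @param shape `"sphere"`, `"capsule"`, or a [make_sphere()] /
#'   [make_capsule()] object.
#' @param grid_size Intervals `c(Nz, Ns)`; defaults to 25 x 13 for the
#'   sphere and 56 x 14 for the capsule.
#' @param prior Optional [prior_spec()].
#' @param n_sample,M,rounds,seed,n_nodes,forward,control Passed to
#'   [run_inference()].
#' @param mu Viscosity (non-dimensional default 1).
#' @return An object of class `stressfit` with methods `print`, `summary`,
#'   `coef` (the amplitude vector), `predict` (velocities at new points),
#'   `fitted`, `residuals`, `logLik`, `plot` and `simulate`.
#' @examples
#' \donttest{
#' bench <- benchmark_case()
#' syn <- synth_observations(shape = bench$shape, stress = bench$stress,
#'                           n_points = 60, noise_sd = 0, seed = 1,
#'                           grid_size = c(16, 8))
#' fit <- fit_stress(syn$obs, shape = bench$shape, grid_size = c(16, 8),
#'                   n_sample = 500, M = 20, seed = 1)
#' coef(fit)
#' }
#' @export
fit_stress <- function(obs, shape = c("sphere", "capsule"),
                       grid_size = NULL, prior = NULL,
                       n_sample = 5000, M = 100, rounds = 2, seed = 1,
                       n_nodes = 7, forward = c("superposition", "direct"),
                       mu = 1, control = list()) {
  cl <- match.call()
  if (is.character(obs)) obs <- read_observations(obs)
  stopifnot(inherits(obs, "observations"))
  if (is.character(shape)) {
    shape <- switch(match.arg(shape),
                    sphere = make_sphere(),
                    capsule = make_capsule())
  }
  stopifnot(inherits(shape, "boundary_shape"))
  if (is.null(grid_size)) {
    grid_size <- if (shape$kind == "capsule") c(56L, 14L) else c(25L, 13L)
  }
  grid <- build_grid(shape, grid_size[1L], grid_size[2L])
  if (is.null(prior)) {
    prior <- default_prior(obs, shape, n_nodes)
  }
  da <- run_inference(obs, prior, grid, n_sample = n_sample, M = M,
                      rounds = rounds, seed = seed, n_nodes = n_nodes,
                      forward = match.arg(forward), mu = mu,
                      control = control)
  structure(list(
    call = cl, obs = obs, shape = shape, grid = grid, prior = prior,
    da = da, spline = da$spline, sigma_hat = da$sigma_hat,
    mu = mu, seed = seed
  ), class = "stressfit")
}

# sphere: actin-cap style prior; capsule: profile-matched prior from the
# outermost (cortical) observation points
default_prior <- function(obs, shape, n_nodes) {
  R <- shape$half_length
  if (shape$kind == "sphere") return(prior_mouse(n_nodes, R_half = R))
  pts <- obs$points
  sfrac <- abs(pts$r) / pmax(shape$F(pts$z), 1e-9)
  cort <- pts[sfrac >= stats::quantile(sfrac, 0.8), , drop = FALSE]
  vt <- project_cortical(cort$z, cort$r, cort$v_z, cort$v_r, shape)
  prior_from_cortical(vt, R_half = R, n_nodes = n_nodes)
}

#' @export
print.stressfit <- function(x, digits = 4, ...) {
  cat("Cortical shear-stress fit (two-round Bayesian data assimilation)\n")
  cat(sprintf("  %s cell, %d x %d grid, %d observation points\n",
              x$shape$kind, x$grid$Nz, x$grid$Ns, x$obs$n))
  cat(sprintf("  n_sample = %d per round, top M = %d, seed = %d\n",
              x$da$n_sample, x$da$M, x$seed))
  cat("  amplitudes (non-dimensional stress at spline nodes):\n")
  print(round(rbind(node_z = x$spline$node_z, tau = coef(x)), digits))
  cat(sprintf("  log-likelihood at estimate: %.4g\n", x$da$loglik_at_estimate))
  invisible(x)
}

#' @export
summary.stressfit <- function(object, ...) {
  res <- residuals(object)
  out <- list(
    coefficients = cbind(node_z = object$spline$node_z,
                         tau = coef(object)),
    sigma_hat = object$sigma_hat,
    loglik = object$da$loglik_at_estimate,
    loglik_per_round = vapply(object$da$per_round,
                              function(r) r$loglik_at_estimate, 0),
    rmse = c(v_z = sqrt(mean(res$v_z^2)), v_r = sqrt(mean(res$v_r^2))),
    max_stress = max(evaluate_stress(object$spline,
                                     seq(-object$spline$R_half,
                                         object$spline$R_half,
                                         length.out = 201))),
    n = object$obs$n,
    physical = stress_physical(object, quiet = TRUE)
  )
  class(out) <- "summary.stressfit"
  out
}

#' @export
print.summary.stressfit <- function(x, digits = 4, ...) {
  cat("Stress-fit summary\n\ncoefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nplug-in residual covariance: sigma_z2 = %.3g, sigma_r2 = %.3g, sigma_zr = %.3g\n",
              x$sigma_hat[1L], x$sigma_hat[2L], x$sigma_hat[3L]))
  cat(sprintf("log-likelihood per round: %s\n",
              paste(signif(x$loglik_per_round, 6), collapse = " -> ")))
  cat(sprintf("velocity RMSE: v_z %.3g, v_r %.3g (n = %d)\n",
              x$rmse[1L], x$rmse[2L], x$n))
  cat(sprintf("peak stress: %.4g (non-dimensional)", x$max_stress))
  if (!is.na(x$physical)) {
    cat(sprintf(" = %.3g pN/um^2", x$physical))
  }
  cat("\n")
  invisible(x)
}

#' @export
coef.stressfit <- function(object, ...) {
  stats::setNames(object$spline$amplitudes,
                  paste0("tau", seq_along(object$spline$amplitudes)))
}

#' @export
logLik.stressfit <- function(object, ...) {
  structure(object$da$loglik_at_estimate,
            df = object$da$n_nodes, nobs = 2L * object$obs$n,
            class = "logLik")
}

#' Predicted velocities from a fitted stress distribution
#'
#' Solves (via the cached basis flows) for the velocities generated by the
#' fitted stress at the observation points, or at new `(z, r)` points.
#'
#' @param object A [fit_stress()] result.
#' @param newdata Optional data frame with columns `z` and `r`.
#' @param ... Unused.
#' @return Data frame with `v_z`, `v_r`.
#' @export
predict.stressfit <- function(object, newdata = NULL, ...) {
  pts <- if (is.null(newdata)) object$obs$points else newdata
  op <- forward_operator(object$grid, pts, object$da$n_nodes, object$mu)
  pr <- op$predict(coef(object))
  vs <- object$da$velocity_scale # back to the observations' measured units
  data.frame(v_z = vs * pr$v_z[, 1L], v_r = vs * pr$v_r[, 1L])
}

#' @export
fitted.stressfit <- function(object, ...) predict(object)

#' @export
residuals.stressfit <- function(object, ...) {
  f <- fitted(object)
  data.frame(v_z = object$obs$points$v_z - f$v_z,
             v_r = object$obs$points$v_r - f$v_r)
}

#' Simulate observation sets from a fitted model
#'
#' Draws `nsim` replicate observation tables at the fitted points: the
#' fitted velocities plus bivariate Gaussian noise with the plug-in
#' residual covariance.
#'
#' @param object A `stressfit`.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of [observations()] objects.
#' @export
simulate.stressfit <- function(object, nsim = 1, seed = NULL, ...) {
  f <- fitted(object)
  vs <- object$da$velocity_scale
  S <- object$sigma_hat * vs^2 # plug-in covariance back in measured units
  cov <- matrix(c(S[1L], S[3L], S[3L], S[2L]), 2L)
  ch <- chol(cov + diag(1e-30, 2L))
  n <- object$obs$n
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      eps <- matrix(rnorm(2L * n), n, 2L) %*% ch
      observations(object$obs$points$z, object$obs$points$r,
                   f$v_z + eps[, 1L], f$v_r + eps[, 2L],
                   scale = object$obs$scale, cell = object$obs$cell)
    })
  })
}

#' Plot a fitted stress distribution
#'
#' Draws the estimated stress profile \eqn{\hat\tau(z)} with its node
#' amplitudes, and (optionally) the prior-mean profile for comparison.
#'
#' @param x A `stressfit`.
#' @param show_prior Overlay the prior-mean spline (default TRUE).
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.stressfit <- function(x, show_prior = TRUE, ...) {
  R <- x$spline$R_half
  z <- seq(-R, R, length.out = 201)
  tau <- evaluate_stress(x$spline, z)
  prior_sp <- stress_spline(x$prior$means, R_half = R)
  tau_pr <- evaluate_stress(prior_sp, z)
  ylim <- range(0, tau, if (show_prior) tau_pr)
  plot(z, tau, type = "l", lwd = 2, ylim = ylim,
       xlab = "position along source-drain axis (drain < 0 < source)",
       ylab = "cortical shear stress (non-dimensional)", ...)
  points(x$spline$node_z, x$spline$amplitudes, pch = 19)
  if (show_prior) {
    lines(z, tau_pr, lty = 2, col = "grey40")
    legend("topleft", bty = "n", lty = c(1, 2), lwd = c(2, 1),
           col = c("black", "grey40"), legend = c("estimate", "prior mean"))
  }
  invisible(x)
}

#' Convert fitted stress to physical units
#'
#' The non-dimensional system sets viscosity and the cell short radius
#' to 1; a non-dimensional stress \eqn{\tau^*} corresponds to
#' \eqn{\tau^* \mu V / L} in physical units, where \eqn{\mu} is the
#' cytoplasmic viscosity (Pa s), \eqn{V} the velocity scale (um/s of one
#' non-dimensional velocity unit) and \eqn{L} the short radius (um). With
#' these units the result is in Pa = pN/um^2.
#'
#' @param fit A `stressfit`.
#' @param what `"max"` (peak of the fitted profile, default) or `"nodes"`
#'   (each amplitude).
#' @param quiet Return `NA` instead of erroring when scales are missing.
#' @return Stress in pN/um^2.
#' @export
stress_physical <- function(fit, what = c("max", "nodes"), quiet = FALSE) {
  what <- match.arg(what)
  sc <- fit$obs$scale
  if (anyNA(c(sc$length_um, sc$velocity_um_s, sc$viscosity_pa_s))) {
    if (quiet) return(NA_real_)
    stopf("observation scales (length_um, velocity_um_s, viscosity_pa_s) are required")
  }
  factor <- sc$viscosity_pa_s * sc$velocity_um_s / sc$length_um
  if (what == "max") {
    R <- fit$spline$R_half
    z <- seq(-R, R, length.out = 401)
    max(evaluate_stress(fit$spline, z)) * factor
  } else {
    coef(fit) * factor
  }
}
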