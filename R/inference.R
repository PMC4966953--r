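#' Prior for the stress amplitudes
#'
#' Independent Gaussian priors, one per spline amplitude, truncated to
#' positive values: the stress is assumed to act from the source towards
#' the drain pole everywhere. The common standard deviation defaults to
#' 0.75 (non-dimensional stress).
#'
#' @param means Numeric vector of prior means, one per amplitude.
#' @param sd Common standard deviation (> 0).
#' @param positivity Truncate every component to `(0, Inf)` (default TRUE).
#' @return An object of class `prior_spec`.
#' @seealso [prior_mouse()] and [prior_from_cortical()] for the two default
#'   constructions.
#' @export
prior_spec <- function(means, sd = 0.75, positivity = TRUE) {
  if (sd <= 0) stopf("`sd` must be positive")
  structure(list(means = as.numeric(means), sd = sd, positivity = positivity),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Stress prior: %d truncated-Gaussian nodes, sd = %g\n  means: %s\n",
              length(x$means), x$sd,
              paste(signif(x$means, 3), collapse = ", ")))
  invisible(x)
}

#' Default mouse-oocyte prior
#'
#' Mean 2.5 for amplitudes whose node position lies in the source-proximal
#' fraction of the axis (default: the third of the source-drain distance
#' adjacent to the source pole, where the actin cap sits), 0.5 elsewhere;
#' common sd 0.75.
#'
#' @param n_nodes Number of free amplitudes.
#' @param R_half Half source-drain distance.
#' @param source_frac Fraction of the axis counted as source-proximal.
#' @param high,low Prior means inside/outside the source-proximal region.
#' @inheritParams prior_spec
#' @return A `prior_spec`.
#' @export
prior_mouse <- function(n_nodes = 7, R_half = 1, source_frac = 1 / 3,
                        high = 2.5, low = 0.5, sd = 0.75) {
  nz <- stress_spline(rep(0, n_nodes), R_half = R_half)$node_z
  means <- ifelse(nz >= R_half - source_frac * 2 * R_half, high, low)
  prior_spec(means, sd = sd)
}

#' Prior means from a cortical velocity profile
#'
#' Sets the prior means by least-squares fitting the stress spline to a
#' scaled cortical velocity profile (for a unit sphere, a stress amplitude
#' of about 3 produces unit slip, hence the default scaling). This
#' automates the manual profile-matching construction used for the
#' C. elegans cells; means are floored at a small positive value so the
#' truncated prior stays proper.
#'
#' @param vt Data frame with columns `z` and `v_t` (tangential cortical
#'   velocity, positive source to drain).
#' @param R_half Half source-drain distance.
#' @param n_nodes Number of free amplitudes.
#' @param stress_per_speed Scaling from slip speed to stress (default 3).
#' @param floor Minimum prior mean.
#' @inheritParams prior_spec
#' @return A `prior_spec`.
#' @export
prior_from_cortical <- function(vt, R_half = 1, n_nodes = 7,
                                stress_per_speed = 3, floor = 0.1,
                                sd = 0.75) {
  keep <- is.finite(vt$v_t)
  f <- stats::approxfun(vt$z[keep], stress_per_speed * vt$v_t[keep],
                        rule = 2)
  sp <- fit_stress_spline(f, R_half = R_half, n_nodes = n_nodes)
  prior_spec(pmax(sp$amplitudes, floor), sd = sd)
}

#' Sample stress amplitudes from the prior
#'
#' Component-wise truncated-Gaussian sampling by rejection, with an
#' inverse-CDF fallback for components whose acceptance probability is
#' below 10 percent; reproducible for a given seed.
#'
#' @param prior A [prior_spec()].
#' @param n Number of samples.
#' @param seed Integer seed (optional; caller's RNG state is restored).
#' @return An `n x length(means)` matrix of positive amplitudes.
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "prior_spec"), n >= 1)
  k <- length(prior$means)
  with_seed(seed, {
    out <- matrix(NA_real_, n, k)
    for (i in seq_len(k)) {
      m <- prior$means[i]
      if (!prior$positivity) {
        out[, i] <- rnorm(n, m, prior$sd)
        next
      }
      acc <- pnorm(0, m, prior$sd, lower.tail = FALSE)
      if (acc < 1e-6) {
        stopf("prior mean %g with sd %g leaves truncation acceptance %.2g < 1e-6",
              m, prior$sd, acc)
      }
      if (acc >= 0.1) {
        draws <- rnorm(ceiling(n / acc * 1.2) + 50L, m, prior$sd)
        draws <- draws[draws > 0]
        while (length(draws) < n) {
          extra <- rnorm(ceiling(n / acc) + 50L, m, prior$sd)
          draws <- c(draws, extra[extra > 0])
        }
        out[, i] <- draws[seq_len(n)]
      } else {
        u <- stats::runif(n)
        p0 <- pnorm(0, m, prior$sd)
        out[, i] <- qnorm(p0 + u * (1 - p0), m, prior$sd)
      }
    }
    out
  })
}

#' Gaussian log-likelihood of observed velocities
#'
#' The likelihood compares simulated and observed velocities at the
#' observation points under an i.i.d. bivariate Gaussian error model whose
#' covariance (\eqn{\sigma_z^2, \sigma_r^2, \sigma_{zr}}) is replaced by
#' its maximum-likelihood plug-in: the empirical second moments of the
#' residuals. At that optimum the quadratic form collapses and
#' \deqn{\log p(Y|\Theta) = -N(1 + \log 2\pi) - (N/2) \log\det\hat\Sigma.}
#' A perfect or rank-deficient fit makes \eqn{\det\hat\Sigma} vanish and
#' the density improper; the determinant is floored at `det_floor` and the
#' result flagged via the `"degenerate"` attribute instead of returning
#' non-finite values.
#'
#' @param obs An [observations()] object (or a data frame with `v_z`,
#'   `v_r`).
#' @param sim Data frame or list with simulated `v_z`, `v_r` at exactly
#'   the observation points.
#' @param det_floor Lower bound for \eqn{\det\hat\Sigma} (default 1e-24).
#' @return The scalar log-likelihood, with attributes `sigma`
#'   (`sigma_z2`, `sigma_r2`, `sigma_zr`) and `degenerate`.
#' @export
log_likelihood <- function(obs, sim, det_floor = 1e-24) {
  pts <- if (inherits(obs, "observations")) obs$points else obs
  rz <- sim$v_z - pts$v_z
  rr <- sim$v_r - pts$v_r
  n <- length(rz)
  if (n != length(pts$v_z)) stopf("sim and obs lengths differ")
  sz <- mean(rz^2)
  sr <- mean(rr^2)
  szr <- mean(rz * rr)
  det <- sz * sr - szr^2
  degenerate <- det <= det_floor
  ll <- -n * (1 + log(2 * pi)) - (n / 2) * log(max(det, det_floor))
  structure(ll, sigma = c(sigma_z2 = sz, sigma_r2 = sr, sigma_zr = szr),
            degenerate = degenerate)
}

# vectorised plug-in log-likelihood over residual matrices (N x m)
loglik_columns <- function(Rz, Rr, det_floor = 1e-24) {
  n <- nrow(Rz)
  sz <- colMeans(Rz^2)
  sr <- colMeans(Rr^2)
  szr <- colMeans(Rz * Rr)
  det <- sz * sr - szr^2
  list(ll = -n * (1 + log(2 * pi)) - (n / 2) * log(pmax(det, det_floor)),
       degenerate = det <= det_floor)
}

#' Posterior estimate from weighted top samples
#'
#' Ranks prior samples by log-likelihood (equal, up to a constant, to the
#' unnormalised log-posterior because the samples are drawn from the
#' prior), keeps the `M` best (ties broken by sample index), and returns
#' their posterior-weighted mean
#' \eqn{\hat\Theta = \sum_{i=1}^{M} \Theta_i w_i} with
#' \eqn{w_i \propto \exp(\ell_i - \max \ell)}.
#'
#' @param samples Matrix of sampled amplitude vectors (one row per sample).
#' @param logliks Numeric vector of log-likelihoods, one per row.
#' @param M Number of top samples to average (default 100).
#' @return An object of class `posterior_estimate`: `theta_hat`, `top`
#'   (indices), `weights` (summing to 1), `loglik` (of the top samples).
#' @export
estimate_posterior <- function(samples, logliks, M = 100) {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(logliks)) stopf("length mismatch")
  if (nrow(samples) < M) {
    stopf("need at least M = %d samples, got %d", M, nrow(samples))
  }
  ord <- order(logliks, decreasing = TRUE) # stable: ties keep sample order
  top <- ord[seq_len(M)]
  ll <- logliks[top]
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  theta_hat <- as.vector(crossprod(samples[top, , drop = FALSE], w))
  structure(list(theta_hat = theta_hat, top = top, weights = w, loglik = ll,
                 M = M), class = "posterior_estimate")
}

#' @export
print.posterior_estimate <- function(x, ...) {
  cat(sprintf("Posterior estimate from top %d samples\n  theta_hat: %s\n  best log-likelihood: %.4g\n",
              x$M, paste(signif(x$theta_hat, 4), collapse = ", "),
              max(x$loglik)))
  invisible(x)
}

# --- forward model -----------------------------------------------------

.fwd_cache <- new.env(parent = emptyenv())

fwd_signature <- function(grid, n_nodes, control) {
  sh <- grid$shape
  paste(sh$kind, signif(sh$short_radius, 12), signif(sh$half_length, 12),
        grid$Nz, grid$Ns, n_nodes,
        signif(control$tol %||% 1e-7, 6), sep = "|")
}

#' Basis flow solutions for the spline amplitudes
#'
#' Stokes flow is linear in the boundary stress, so the flow for any
#' amplitude vector is the linear combination of the flows driven by the
#' individual basis splines. These `n_nodes` solutions are computed once
#' per grid (and memoised within the session); the forward model then
#' reduces to a matrix product, which is what makes scoring 1e4-1e5 prior
#' samples tractable.
#'
#' @param grid A [build_grid()] grid.
#' @param n_nodes Number of free amplitudes.
#' @param mu Viscosity.
#' @param control Solver settings (see [solve_stokes()]).
#' @param cache Reuse memoised solutions (default TRUE).
#' @return List of `n_nodes` `flow_field` objects.
#' @export
basis_flows <- function(grid, n_nodes = 7, mu = 1, control = list(),
                        cache = TRUE) {
  key <- fwd_signature(grid, n_nodes, control)
  if (cache && !is.null(.fwd_cache[[key]])) return(.fwd_cache[[key]])
  R <- grid$shape$half_length
  flows <- lapply(seq_len(n_nodes), function(i) {
    amps <- rep(0, n_nodes)
    amps[i] <- 1
    solve_stokes(grid, stress_spline(amps, R_half = R), mu = mu,
                 control = control)
  })
  if (cache) .fwd_cache[[key]] <- flows
  flows
}

# Linear operator (z, r) points x amplitudes -> velocities; handles the
# signed radial coordinate by mirroring v_r.
forward_operator <- function(grid, points, n_nodes = 7, mu = 1,
                             control = list()) {
  flows <- basis_flows(grid, n_nodes, mu, control)
  sgn <- ifelse(points$r < 0, -1, 1)
  Bz <- matrix(0, nrow(points), n_nodes)
  Br <- matrix(0, nrow(points), n_nodes)
  for (i in seq_len(n_nodes)) {
    v <- interp_velocity(flows[[i]], points$z, abs(points$r))
    Bz[, i] <- v$v_z
    Br[, i] <- sgn * v$v_r
  }
  list(Bz = Bz, Br = Br,
       predict = function(theta) {
         theta <- as.matrix(theta)
         list(v_z = Bz %*% theta, v_r = Br %*% theta)
       })
}

#' Estimate the stress distribution by sampling-based data assimilation
#'
#' Draws `n_sample` amplitude vectors from the prior, scores each against
#' the observations with the plug-in Gaussian likelihood
#' ([log_likelihood()]), and estimates the amplitudes as the
#' posterior-weighted mean of the `M` best samples
#' ([estimate_posterior()]). Two rounds are performed: the second round
#' re-centres the prior means on the first-round estimate. Because the
#' plug-in likelihood is extremely peaked (its log scales with
#' \eqn{-2N\log} of the residual norm), the top-`M` weights concentrate
#' on very few samples and each round's precision is set by the
#' nearest-draw distance, which scales with the proposal sd; refinement
#' rounds therefore shrink the sd by `round_sd_factor` (default 0.5) so
#' round 2 exploits the neighbourhood located by round 1 instead of
#' re-exploring the full prior width. `round_sd_factor = 1` reproduces
#' the flat-reuse variant.
#'
#' The forward model is evaluated either by exact linear superposition of
#' the basis-spline flow solutions (`forward = "superposition"`, default;
#' algebraically identical to solving per sample, since Stokes flow is
#' linear in the stress) or by one full solve per sample
#' (`forward = "direct"`, memoised per amplitude vector). In direct mode a
#' non-converged solve discards the sample; more than 10 percent discards
#' is an error.
#'
#' @param obs [observations()] to fit.
#' @param prior A [prior_spec()]; round 1 prior.
#' @param grid The simulation grid (its shape fixes `R_half`).
#' @param n_sample Prior samples per round. A budget of about 120,000 is
#'   cheap with the superposition forward model and gives benchmark-quality
#'   recovery; a few thousand are often enough for exploratory fits.
#' @param M Top samples averaged (default 100).
#' @param rounds Number of estimation rounds (default 2).
#' @param round_sd_factor Multiplier applied to the proposal sd at each
#'   refinement round (see Details).
#' @param seed Integer seed; every random draw derives from it.
#' @param n_nodes Number of free spline amplitudes (default 7).
#' @param forward `"superposition"` or `"direct"`.
#' @param mu Viscosity.
#' @param control Solver settings.
#' @param chunk Samples per scoring block (memory control).
#' @return A `da_fit` list: `estimate` (final round
#'   [estimate_posterior()]), `spline` (the fitted [stress_spline()]),
#'   `per_round` (estimates and log-likelihood of the estimate per round),
#'   `sigma_hat`, `n_degenerate`, `n_discarded`, and the configuration
#'   echo (`n_sample`, `M`, `rounds`, `seed`, `n_nodes`).
#' @export
run_inference <- function(obs, prior, grid, n_sample = 120000, M = 100,
                          rounds = 2, seed = 1, n_nodes = 7,
                          round_sd_factor = 0.5,
                          forward = c("superposition", "direct"),
                          mu = 1, control = list(), chunk = 5000L) {
  stopifnot(inherits(obs, "observations"), inherits(prior, "prior_spec"),
            inherits(grid, "curvi_grid"))
  forward <- match.arg(forward)
  if (n_sample < M) stopf("`n_sample` (%d) must be at least M (%d)",
                          n_sample, M)
  if (obs$n < n_nodes) {
    stopf("need at least as many observation points (%d) as amplitudes (%d)",
          obs$n, n_nodes)
  }
  R <- grid$shape$half_length
  op <- forward_operator(grid, obs$points, n_nodes, mu, control)
  # observed velocities stay in their measured units on disk and in the
  # object; the recorded velocity scale non-dimensionalises them here
  vs <- obs$scale$velocity_um_s
  if (is.null(vs) || !is.finite(vs)) vs <- 1
  vz_obs <- obs$points$v_z / vs
  vr_obs <- obs$points$v_r / vs

  per_round <- vector("list", rounds)
  pr <- prior
  n_degenerate <- 0L
  n_discarded <- 0L
  est <- NULL
  for (rd in seq_len(rounds)) {
    thetas <- sample_prior(pr, n_sample, seed = seed * 13L + rd)
    ll <- numeric(n_sample)
    keep <- rep(TRUE, n_sample)
    for (start in seq(1L, n_sample, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n_sample)
      th <- thetas[idx, , drop = FALSE]
      if (forward == "superposition") {
        pred <- op$predict(t(th))
      } else {
        pred <- direct_predict(grid, th, obs$points, n_nodes, mu, control)
        keep[idx[pred$failed]] <- FALSE
      }
      sc <- loglik_columns(pred$v_z - vz_obs, pred$v_r - vr_obs)
      ll[idx] <- sc$ll
      n_degenerate <- n_degenerate + sum(sc$degenerate)
    }
    if (!all(keep)) {
      n_discarded <- n_discarded + sum(!keep)
      if (mean(!keep) > 0.1) {
        stopf("more than 10%% of forward solves failed to converge (%d of %d)",
              sum(!keep), n_sample)
      }
      thetas <- thetas[keep, , drop = FALSE]
      ll <- ll[keep]
    }
    est <- estimate_posterior(thetas, ll, M = M)
    pred_hat <- op$predict(est$theta_hat)
    ll_hat <- log_likelihood(data.frame(v_z = vz_obs, v_r = vr_obs),
                             list(v_z = pred_hat$v_z[, 1L],
                                  v_r = pred_hat$v_r[, 1L]))
    per_round[[rd]] <- list(estimate = est, loglik_at_estimate = as.numeric(ll_hat),
                            sigma_hat = attr(ll_hat, "sigma"),
                            prior_means = pr$means)
    pr <- prior_spec(est$theta_hat, sd = prior$sd * round_sd_factor^rd,
                     positivity = prior$positivity)
  }
  final <- per_round[[rounds]]
  list(
    estimate = final$estimate,
    spline = stress_spline(final$estimate$theta_hat, R_half = R),
    per_round = per_round,
    sigma_hat = final$sigma_hat,
    loglik_at_estimate = final$loglik_at_estimate,
    n_degenerate = n_degenerate,
    n_discarded = n_discarded,
    n_sample = n_sample, M = M, rounds = rounds, seed = seed,
    n_nodes = n_nodes, forward = forward, mu = mu, velocity_scale = vs
  )
}

# one full solve per amplitude vector, memoised; returns predicted
# velocities and a failure flag per sample
direct_predict <- function(grid, thetas, points, n_nodes, mu, control) {
  m <- nrow(thetas)
  Vz <- matrix(NA_real_, nrow(points), m)
  Vr <- matrix(NA_real_, nrow(points), m)
  failed <- logical(m)
  R <- grid$shape$half_length
  key0 <- fwd_signature(grid, n_nodes, control)
  sgn <- ifelse(points$r < 0, -1, 1)
  for (i in seq_len(m)) {
    key <- paste(key0, paste(signif(thetas[i, ], 12), collapse = ","))
    fl <- .fwd_cache[[key]]
    if (is.null(fl)) {
      fl <- tryCatch(
        suppressWarnings(solve_stokes(grid,
                                      stress_spline(thetas[i, ], R_half = R),
                                      mu = mu, control = control)),
        error = function(e) NULL)
      if (!is.null(fl)) .fwd_cache[[key]] <- fl
    }
    if (is.null(fl) || !fl$converged) {
      failed[i] <- TRUE
      Vz[, i] <- 0
      Vr[, i] <- 0
    } else {
      v <- interp_velocity(fl, points$z, abs(points$r))
      Vz[, i] <- v$v_z
      Vr[, i] <- sgn * v$v_r
    }
  }
  list(v_z = Vz, v_r = Vr, failed = failed)
}
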