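test_that("truncated-Gaussian sampling matches the closed-form moment", {
  pr <- prior_spec(rep(2.5, 2), sd = 0.75)
  th <- sample_prior(pr, 1e5, seed = 1)
  expect_true(all(th > 0))
  # truncated-normal mean: m + sd * phi(a) / (1 - Phi(a)), a = -m/sd
  a <- -2.5 / 0.75
  mu_trunc <- 2.5 + 0.75 * dnorm(a) / (1 - pnorm(a))
  sd_trunc <- sqrt(0.75^2 * (1 + a * dnorm(a) / (1 - pnorm(a)) -
                               (dnorm(a) / (1 - pnorm(a)))^2))
  se <- sd_trunc / sqrt(1e5)
  expect_lt(abs(mean(th[, 1L]) - mu_trunc), 3 * se)
  expect_lt(abs(mean(th[, 2L]) - mu_trunc), 3 * se)
})

test_that("sampling edge cases behave", {
  # near-degenerate sd pins samples at the mean
  th <- sample_prior(prior_spec(1.5, sd = 1e-9), 100, seed = 2)
  expect_equal(as.vector(th), rep(1.5, 100), tolerance = 1e-6)
  # identical seeds give identical draws; the caller's RNG is untouched
  set.seed(99); before <- runif(1)
  a <- sample_prior(prior_spec(c(2.5, 0.5)), 50, seed = 7)
  set.seed(99); expect_identical(runif(1), before)
  b <- sample_prior(prior_spec(c(2.5, 0.5)), 50, seed = 7)
  expect_identical(a, b)
  # low-acceptance component uses the inverse-CDF branch, still positive
  th2 <- sample_prior(prior_spec(-2, sd = 0.75), 1000, seed = 3)
  expect_true(all(th2 > 0))
  # hopeless truncation is an explicit error
  expect_error(sample_prior(prior_spec(-4, sd = 0.75), 10, seed = 1),
               "acceptance")
})

test_that("plug-in log-likelihood equals the log-determinant identity", {
  set.seed(5)
  n <- 17
  obs <- data.frame(v_z = rnorm(n), v_r = rnorm(n))
  sim <- list(v_z = obs$v_z + rnorm(n, 0, 0.3),
              v_r = obs$v_r + rnorm(n, 0, 0.2))
  ll <- log_likelihood(obs, sim)
  # independent oracle: product of bivariate normal densities at the MLE
  rz <- sim$v_z - obs$v_z; rr <- sim$v_r - obs$v_r
  S <- matrix(c(mean(rz^2), mean(rz * rr), mean(rz * rr), mean(rr^2)), 2L)
  Sinv <- solve(S)
  dens <- vapply(seq_len(n), function(i) {
    x <- c(rz[i], rr[i])
    -log(2 * pi) - 0.5 * log(det(S)) - 0.5 * drop(t(x) %*% Sinv %*% x)
  }, 0)
  expect_equal(as.numeric(ll), sum(dens), tolerance = 1e-9)
  expect_false(attr(ll, "degenerate"))
  expect_equal(unname(attr(ll, "sigma")),
               c(mean(rz^2), mean(rr^2), mean(rz * rr)))
})

test_that("degenerate residual covariances are floored and flagged", {
  obs <- data.frame(v_z = c(0, 0), v_r = c(0, 0))
  # residuals (+1, 0) and (-1, 0): sigma_r2 = 0, rank-deficient
  ll <- log_likelihood(obs, list(v_z = c(1, -1), v_r = c(0, 0)))
  expect_true(attr(ll, "degenerate"))
  expect_true(is.finite(as.numeric(ll)))
  expect_equal(unname(attr(ll, "sigma")), c(1, 0, 0))
  # identical residuals (c, c): all moments c^2, singular covariance
  ll2 <- log_likelihood(obs, list(v_z = c(0.4, 0.4), v_r = c(0.4, 0.4)))
  expect_true(attr(ll2, "degenerate"))
  expect_equal(unname(attr(ll2, "sigma")), rep(0.16, 3), tolerance = 1e-12)
  # a perfect fit is capped, never NaN
  ll3 <- log_likelihood(obs, list(v_z = c(0, 0), v_r = c(0, 0)))
  expect_true(is.finite(as.numeric(ll3)))
})

test_that("posterior estimate is the weighted mean of the top samples", {
  set.seed(6)
  th <- matrix(runif(200 * 3), 200, 3)
  # equal log-likelihoods: uniform weights over the first M by index ties
  est <- estimate_posterior(th, rep(1.25, 200), M = 50)
  expect_equal(est$top, 1:50)
  expect_equal(est$theta_hat, colMeans(th[1:50, ]), tolerance = 1e-12)
  expect_equal(sum(est$weights), 1)
  # one dominating sample takes all the weight
  ll <- rep(0, 200); ll[137] <- 60
  est2 <- estimate_posterior(th, ll, M = 50)
  expect_equal(est2$theta_hat, th[137, ], tolerance = 1e-12)
  # M = 1 is the argmax
  est3 <- estimate_posterior(th, seq_len(200) / 10, M = 1)
  expect_equal(est3$theta_hat, th[200, ])
  # the estimate lies in the componentwise hull of the top samples
  ll4 <- rnorm(200)
  est4 <- estimate_posterior(th, ll4, M = 100)
  top <- th[est4$top, ]
  expect_true(all(est4$theta_hat >= apply(top, 2, min) - 1e-12))
  expect_true(all(est4$theta_hat <= apply(top, 2, max) + 1e-12))
  expect_error(estimate_posterior(th[1:10, ], rnorm(10), M = 50), "at least")
})

test_that("superposition forward model equals a direct solve", {
  g <- sphere_grid()
  set.seed(8)
  theta <- runif(7, 0.5, 3)
  pts <- data.frame(z = runif(20, -0.9, 0.9))
  pts$r <- runif(20, -0.9, 0.9) * g$shape$F(pts$z)
  op <- streamstress:::forward_operator(g, pts, 7, 1)
  pred <- op$predict(theta)
  fl <- solve_stokes(g, stress_spline(theta))
  v <- interp_velocity(fl, pts$z, abs(pts$r))
  scale <- max(abs(v$v_z))
  expect_lt(max(abs(pred$v_z[, 1L] - v$v_z)) / scale, 5e-3)
  expect_lt(max(abs(pred$v_r[, 1L] - ifelse(pts$r < 0, -1, 1) * v$v_r)) /
              scale, 5e-3)
})

test_that("inference is deterministic and its weights are proper", {
  obs <- bench_obs()
  g <- sphere_grid()
  prior <- prior_spec(rep(1.5, 7))
  da1 <- run_inference(obs, prior, g, n_sample = 800, M = 50, seed = 4)
  da2 <- run_inference(obs, prior, g, n_sample = 800, M = 50, seed = 4)
  expect_identical(da1$estimate$theta_hat, da2$estimate$theta_hat)
  expect_equal(sum(da1$estimate$weights), 1)
  expect_true(all(da1$estimate$theta_hat > 0))
  da3 <- run_inference(obs, prior, g, n_sample = 800, M = 50, seed = 5)
  expect_false(identical(da1$estimate$theta_hat, da3$estimate$theta_hat))
  expect_error(run_inference(obs, prior, g, n_sample = 10, M = 50),
               "at least")
})

test_that("the refinement round improves the likelihood on the benchmark", {
  obs <- bench_obs()
  da <- run_inference(obs, prior_spec(rep(1.5, 7)), sphere_grid(),
                      n_sample = 3000, M = 100, rounds = 2, seed = 2)
  lls <- vapply(da$per_round, function(r) r$loglik_at_estimate, 0)
  expect_gte(lls[2L], lls[1L])
})

test_that("noisy synthetic amplitudes are recovered within tolerance", {
  set.seed(31)
  theta_star <- c(0.8, 1.4, 2.2, 2.9, 2.4, 1.6, 0.9)
  syn <- synth_observations(make_sphere(), stress_spline(theta_star),
                            n_points = 150, noise_sd = 0.05, seed = 12)
  da <- run_inference(syn$obs, prior_spec(rep(1.5, 7)), sphere_grid(),
                      n_sample = 10000, M = 100, rounds = 2, seed = 3)
  nz <- da$spline$node_z
  tau_hat <- evaluate_stress(da$spline, nz)
  tau_star <- evaluate_stress(stress_spline(theta_star), nz)
  rmse <- sqrt(mean((tau_hat - tau_star)^2))
  expect_lt(rmse, 0.15 * max(theta_star))
})

test_that("more prior samples do not hurt noiseless recovery", {
  obs <- bench_obs()
  g <- sphere_grid()
  prior <- prior_spec(rep(1.5, 7))
  nz <- benchmark_case()$stress$node_z
  rmse_at <- function(n_sample, seed) {
    da <- run_inference(obs, prior, g, n_sample = n_sample, M = 100,
                        rounds = 2, seed = seed)
    sqrt(mean((evaluate_stress(da$spline, nz) - tau_bench(nz))^2))
  }
  seeds <- 1:5
  r5k <- vapply(seeds, function(s) rmse_at(5000, s), 0)
  r20k <- vapply(seeds, function(s) rmse_at(20000, s), 0)
  # Monte-Carlo tolerance: allow a small margin on the mean over seeds
  expect_lte(mean(r20k), mean(r5k) + 0.05)
})
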