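test_that("one-class GBTM fit equals the closed-form polynomial regression", {
  spec <- lgm_spec("GBTM", 1, 2, character(), "FIXED", sched9)
  params <- growth_parameters(spec, 1, list(c(10, -0.5, 0.01)), NULL, 4)
  sim <- generate_from_model(spec, params, 150, seed = 3)
  fit <- fit_lgm(sim$data, spec, fast_protocol(polish = TRUE,
                                               polish_maxit = 10), seed = 1)
  df <- tibble::as_tibble(sim$data)
  ols <- lm(value ~ time + I(time^2), data = df)
  expect_equal(unname(fit$params$beta[[1]]), unname(coef(ols)),
               tolerance = 1e-6)
  expect_equal(fit$params$theta, mean(residuals(ols)^2), tolerance = 1e-6)
})

test_that("EM log-likelihood trace is monotone and the fit is seed-reproducible", {
  m <- gbtm2_model()
  sim <- generate_from_model(m$spec, m$params, 200, seed = 5)
  f1 <- fit_lgm(sim$data, m$spec, fast_protocol(), seed = 42)
  f2 <- fit_lgm(sim$data, m$spec, fast_protocol(), seed = 42)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$posteriors, f2$posteriors)
  expect_identical(unname(f1$params$pi), unname(f2$params$pi))
  # monotonicity of the underlying ECM on one long run
  wide <- trajmix:::as_lgm_wide(sim$data, times = m$spec$times)
  spec_s <- trajmix:::scale_spec(m$spec)
  wide$times <- wide$times / trajmix:::TIME_SCALE
  st0 <- trajmix:::params_to_state(m$spec, m$params)
  run <- trajmix:::em_fit(spec_s, wide, st0, 200, 1e-12,
                          1e-6 * var(wide$Y[wide$obs]))
  expect_true(all(diff(run$trace) > -1e-8 * (abs(run$trace[-1]) + 1)))
})

test_that("well-separated 2-class GBTM parameters are recovered", {
  m <- gbtm2_model(sigma = 1.5)  # classes ~4.7 residual SDs apart at baseline
  reps <- lapply(1:5, function(s) {
    sim <- generate_from_model(m$spec, m$params, 600, seed = 100 + s)
    fit <- fit_lgm(sim$data, m$spec, fast_protocol(), seed = s)
    # align labels to truth via baseline intercept
    ord <- order(-sapply(fit$params$beta, `[`, 1))
    list(pi = fit$params$pi[ord],
         b1 = fit$params$beta[[ord[1]]], b2 = fit$params$beta[[ord[2]]])
  })
  pis <- sapply(reps, function(r) r$pi[1])
  expect_true(all(abs(pis - 0.6) <= 0.05))
  b1 <- sapply(reps, function(r) r$b1[1])
  expect_lt(abs(mean(b1) - 10), 3 * sd(b1) / sqrt(length(b1)) + 0.05)
})

test_that("fits are invariant to class-label permutation of the initialization", {
  m <- gbtm2_model()
  sim <- generate_from_model(m$spec, m$params, 150, seed = 8)
  st <- trajmix:::params_to_state(m$spec, m$params)
  st_perm <- st
  st_perm$pi <- st$pi[2:1]
  st_perm$beta <- st$beta[2:1]
  st_perm$theta <- st$theta[2:1, , drop = FALSE]
  f1 <- fit_lgm(sim$data, m$spec, fast_protocol(n_starts = 1L), seed = 1,
                init = list(st))
  f2 <- fit_lgm(sim$data, m$spec, fast_protocol(n_starts = 1L), seed = 1,
                init = list(st_perm))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("GCM fit matches a generic-optimizer mixed-model oracle on complete data", {
  spec <- lgm_spec("GCM", 1, 1, c("intercept", "linear_slope"), "FIXED",
                   c(0, 6, 12, 18, 24))
  params <- growth_parameters(spec, 1, list(c(8, -0.2)),
                              matrix(c(2, 0.02, 0.02, 0.01), 2), 1.2)
  sim <- generate_from_model(spec, params, 150, seed = 21)
  fit <- fit_lgm(sim$data, spec, fast_protocol(polish = TRUE,
                                               polish_maxit = 40), seed = 2)
  # oracle: maximize the same marginal likelihood with nlminb over a naive
  # parameterization, independent of the EM path
  wide <- trajmix:::as_lgm_wide(sim$data, times = spec$times)
  X <- trajmix:::design_matrix(spec$times / 12, 1)
  Z <- X
  nll <- function(p) {
    L <- matrix(c(exp(p[3]), p[4], 0, exp(p[5])), 2, byrow = TRUE)
    S <- Z %*% (t(L) %*% L) %*% t(Z) + diag(exp(p[6]), 5)
    mu <- drop(X %*% p[1:2])
    -sum(mvtnorm::dmvnorm(wide$Y, mean = mu, sigma = S, log = TRUE))
  }
  skip_if_not_installed("mvtnorm")
  opt <- nlminb(c(8, -2, 0, 0, -2, 0), nll)
  expect_equal(fit$loglik, -opt$objective, tolerance = 1e-4)
})

test_that("replication protocol reports agreement for a deterministic one-class model", {
  spec <- lgm_spec("GBTM", 1, 1, character(), "FIXED", c(0, 12, 24))
  params <- growth_parameters(spec, 1, list(c(5, -0.1)), NULL, 1)
  sim <- generate_from_model(spec, params, 80, seed = 2)
  fit <- fit_lgm_replicated(sim$data, spec, fast_protocol(n_starts = 2L),
                            seed = 3)
  expect_true(fit$convergence$replicated_between_runs)
  expect_identical(fit$convergence$n_doublings_used, 0L)
})

test_that("degenerate tiny classes are flagged rather than silently dropped", {
  m <- gbtm2_model()
  sim <- generate_from_model(m$spec, m$params, 60, seed = 9)
  spec4 <- lgm_spec("GBTM", 4, 2, character(), "FIXED", sched9)
  fit <- suppressWarnings(
    fit_lgm(sim$data, spec4, fast_protocol(n_starts = 2L), seed = 1))
  expect_s3_class(fit, "lgm_fit")
  deg <- fit$convergence$degenerate_classes
  expect_true(all(fit$params$pi[deg] < 1 / fit$n_subjects))
  expect_true(all(fit$params$pi[setdiff(1:4, deg)] >= 1 / fit$n_subjects))
  # every class is still present in the returned parameter set
  expect_length(fit$params$pi, 4L)
})
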