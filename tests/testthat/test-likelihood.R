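test_that("single-visit normal density and mixture collapse are exact", {
  times <- c(0, 6)
  spec <- lgm_spec("GBTM", 1, 1, character(), "FIXED", times)
  sigma2 <- 2.3
  params <- growth_parameters(spec, 1, list(c(4, 0)), NULL, sigma2)
  dat <- lgm_data(tibble::tibble(subject_id = "a", time = 0, value = 4),
                  times = times)
  expect_equal(marginal_loglik(spec, params, dat),
               -0.5 * log(2 * pi * sigma2))
  # two identical components collapse to the one-class value for any pi
  spec2 <- lgm_spec("GBTM", 2, 1, character(), "FIXED", times)
  for (p1 in c(0.2, 0.5, 0.9)) {
    params2 <- growth_parameters(spec2, c(p1, 1 - p1),
                                 list(c(4, 0), c(4, 0)), NULL, sigma2)
    expect_equal(marginal_loglik(spec2, params2, dat),
                 -0.5 * log(2 * pi * sigma2))
  }
})

test_that("FIML marginal loglik matches a dense MVN mixture oracle on random instances", {
  skip_if_not_installed("mvtnorm")
  for (seed in 1:40) {
    inst <- random_small_instance(seed)
    expect_equal(
      marginal_loglik(inst$spec, inst$params, inst$data),
      oracle_mixture_loglik(inst$spec, inst$params, inst$data),
      tolerance = 1e-8, info = paste("seed", seed))
  }
})

test_that("posteriors follow Bayes rule, rows sum to one, and respect degenerate priors", {
  skip_if_not_installed("mvtnorm")
  for (seed in 41:55) {
    inst <- random_small_instance(seed)
    if (inst$spec$n_classes < 2) next
    po <- class_posteriors(inst$spec, inst$params, inst$data)
    expect_equal(unname(po), unname(oracle_posteriors(inst$spec, inst$params,
                                                      inst$data)),
                 tolerance = 1e-10)
    expect_equal(rowSums(po), rep(1, nrow(po)), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # degenerate prior forces the posterior
  m <- gbtm2_model()
  sim <- generate_from_model(m$spec, m$params, 6, seed = 2)
  pdeg <- growth_parameters(m$spec, c(1, 0), m$params$beta, NULL,
                            m$params$theta)
  po <- class_posteriors(m$spec, pdeg, sim$data)
  expect_equal(unname(po[, 1]), rep(1, 6))
  # symmetric subject equidistant between symmetric classes
  spec <- lgm_spec("GBTM", 2, 1, character(), "FIXED", c(0, 6))
  params <- growth_parameters(spec, c(0.5, 0.5), list(c(1, 0), c(3, 0)),
                              NULL, 1)
  dat <- lgm_data(tibble::tibble(subject_id = "a", time = c(0, 6),
                                 value = c(2, 2)), times = c(0, 6))
  expect_equal(unname(class_posteriors(spec, params, dat)[1, ]), c(0.5, 0.5))
})

test_that("marking visits missing reduces FIML to the complete-data likelihood", {
  m <- small_gmm_model()
  sim <- generate_from_model(m$spec, m$params, 10, seed = 9)
  ll_complete <- marginal_loglik(m$spec, m$params, sim$data)
  # dropping zero visits is a no-op
  expect_equal(marginal_loglik(m$spec, m$params,
                               lgm_data(tibble::as_tibble(sim$data),
                                        times = m$spec$times)),
               ll_complete)
  # dropping one subject's visit changes only that subject's contribution,
  # computed independently by the oracle
  skip_if_not_installed("mvtnorm")
  dat2 <- tibble::as_tibble(sim$data)[-2, ]
  dat2 <- lgm_data(dat2, times = m$spec$times)
  expect_equal(marginal_loglik(m$spec, m$params, dat2),
               oracle_mixture_loglik(m$spec, m$params, dat2),
               tolerance = 1e-8)
})

test_that("month-unit and internally rescaled parameterizations give identical likelihoods", {
  m <- small_gmm_model()
  sim <- generate_from_model(m$spec, m$params, 6, seed = 5)
  spec_s <- trajmix:::scale_spec(m$spec)
  params_s_state <- trajmix:::params_to_state(m$spec, m$params)
  params_s <- trajmix:::em_state_to_params(spec_s, params_s_state)
  dat_s <- tibble::as_tibble(sim$data)
  dat_s$time <- dat_s$time / trajmix:::TIME_SCALE
  ll_s <- marginal_loglik(spec_s, params_s, lgm_data(dat_s, times = spec_s$times))
  expect_equal(ll_s, marginal_loglik(m$spec, m$params, sim$data),
               tolerance = 1e-10)
})
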