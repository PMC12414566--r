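test_that("parameter counting matches direct enumeration across structures", {
  # class-variant cubic GMM, free residuals over time and classes:
  # 2*4 fixed + 2*3 covariance + 2*9 residual + 1 proportion
  expect_identical(count_parameters(spec_saps_t2()), 33L)
  # class-invariant mixed-order GMM, residuals free over classes:
  # (4+4+2) + 3 + 3 + 2
  expect_identical(count_parameters(spec_sans_t2()), 18L)
  # 2-class quadratic GBTM: 2*3 + 0 + 1 + 1
  expect_identical(count_parameters(spec_sofas_t2()), 8L)
  # 1-class quadratic GCM with random intercept+slope: 3 + 3 + 1 + 0
  gcm <- lgm_spec("GCM", 1, 2, c("intercept", "linear_slope"), "FIXED", sched3)
  expect_identical(count_parameters(gcm), 7L)
})

test_that("specs violating identifiability or family rules are rejected", {
  expect_error(lgm_spec("GCM", 2, 2, "intercept", "FIXED", sched9),
               "single-class")
  expect_error(lgm_spec("GBTM", 2, 2, "intercept", "FIXED", sched9),
               "no random effects")
  expect_error(lgm_spec("GMM_CLASS_VARIANT", 2, 2, character(), "FIXED",
                        sched9), "random-effect")
  expect_error(lgm_spec("GBTM", 2, 2, character(), "FREE_BOTH", sched9),
               "LCGA")
  # cubic needs 4 visits, quadratic 3
  expect_error(lgm_spec("GBTM", 1, 3, character(), "FIXED", sched3),
               "at least 4")
  expect_silent(lgm_spec("GBTM", 1, 2, character(), "FIXED", sched3))
})

test_that("class mean trajectories evaluate polynomials in month units", {
  expect_equal(class_mean_trajectory(c(5, 0, 0, 0), times = c(0, 7, 24)),
               rep(5, 3))
  expect_equal(class_mean_trajectory(c(0, 1), times = c(0, 12, 24)),
               c(0, 12, 24))
  expect_equal(class_mean_trajectory(c(1, 2, 3), times = 2), 17)
  m <- gbtm2_model()
  expect_equal(class_mean_trajectory(m$params, 2, 0), 3)
  expect_error(class_mean_trajectory(m$params, 5, 0), "class_index")
})

test_that("growth parameter validation enforces simplex and PSD rules", {
  spec <- spec_sofas_t2()
  expect_error(growth_parameters(spec, c(0.6, 0.5), list(1:3, 1:3), NULL, 1),
               "sum to 1")
  expect_error(growth_parameters(spec, c(0.5, 0.5), list(1:3, 1:3), NULL, -1),
               "positive")
  expect_error(growth_parameters(spec, c(0.5, 0.5), list(1:2, 1:3), NULL, 1),
               "length")
  spec_re <- lgm_spec("GMM_CLASS_INVARIANT", 2, 2, c("intercept",
                                                     "linear_slope"),
                      "FIXED", sched9)
  bad_psi <- matrix(c(1, 2, 2, 1), 2)  # negative eigenvalue
  expect_error(growth_parameters(spec_re, c(0.5, 0.5), list(1:3, 1:3),
                                 bad_psi, 1), "PSD")
})

test_that("likelihood and posteriors are invariant to joint class relabeling", {
  m <- small_gmm_model()
  sim <- generate_from_model(m$spec, m$params, 8, seed = 3)
  perm <- c(2L, 1L)
  p2 <- trajmix:::permute_classes(m$params, perm)
  expect_equal(marginal_loglik(m$spec, m$params, sim$data),
               marginal_loglik(p2$spec, p2, sim$data))
  po1 <- class_posteriors(m$spec, m$params, sim$data)
  po2 <- class_posteriors(p2$spec, p2, sim$data)
  expect_equal(unname(po1), unname(po2[, perm]), tolerance = 1e-12)
})
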