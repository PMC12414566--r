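test_that("noiseless simulation puts every subject on its class mean curve", {
  spec <- lgm_spec("GBTM", 2, 2, character(), "FIXED", sched3)
  params <- growth_parameters(spec, c(0.5, 0.5),
                              list(c(10, -0.5, 0.01), c(3, 0, 0)), NULL, 1e-9)
  sim <- generate_from_model(spec, params, 30, seed = 1)
  wide <- trajmix:::as_lgm_wide(sim$data, times = sched3)
  for (k in 1:2) {
    rows <- which(sim$truth$class == k)
    mu <- class_mean_trajectory(params, k, sched3)
    expect_equal(max(abs(sweep(wide$Y[rows, , drop = FALSE], 2, mu))), 0,
                 tolerance = 1e-3)
  }
})

test_that("empirical class frequencies and covariances match the generating model", {
  m <- small_gmm_model()
  sim <- generate_from_model(m$spec, m$params, 10000, seed = 6)
  freq <- table(sim$truth$class) / 10000
  expect_equal(as.numeric(freq), m$params$pi, tolerance = 3 * sqrt(0.25 / 10000) / 0.4)
  # moment check on a 1-class model: per-visit covariance = Z Psi Z' + Theta
  spec1 <- lgm_spec("GCM", 1, 1, c("intercept", "linear_slope"), "FIXED",
                    c(0, 12, 24))
  psi <- matrix(c(3, 0.05, 0.05, 0.01), 2)
  params1 <- growth_parameters(spec1, 1, list(c(5, 0.3)), psi, 2)
  sim1 <- generate_from_model(spec1, params1, 8000, seed = 7)
  wide <- trajmix:::as_lgm_wide(sim1$data, times = spec1$times)
  Z <- trajmix:::re_design(spec1$times, spec1$random_effects)
  target <- Z %*% psi %*% t(Z) + diag(2, 3)
  emp <- cov(wide$Y)
  expect_lt(max(abs(emp - target) / (abs(target) + 1)), 0.1)
})

test_that("simulation is seed-deterministic and obs masks are honored", {
  m <- gbtm2_model()
  s1 <- generate_from_model(m$spec, m$params, 25, seed = 9)
  s2 <- generate_from_model(m$spec, m$params, 25, seed = 9)
  s3 <- generate_from_model(m$spec, m$params, 25, seed = 10)
  expect_identical(s1$data$value, s2$data$value)
  expect_false(identical(s1$data$value, s3$data$value))
  mask <- matrix(TRUE, 25, length(sched9)); mask[, 2] <- FALSE
  s4 <- generate_from_model(m$spec, m$params, 25, seed = 9, obs_mask = mask)
  expect_false(any(s4$data$time == sched9[2]))
})

test_that("anchor curves interpolate exactly at order+1 points and solve LS otherwise", {
  cf <- curve_from_anchors(rbind(c(0, 40), c(12, 70), c(24, 76.4)), 2)
  expect_equal(class_mean_trajectory(cf, times = c(0, 12, 24)),
               c(40, 70, 76.4), tolerance = 1e-10)
  expect_equal(curve_from_anchors(cbind(c(0, 6, 24), 7), 2), c(7, 0, 0),
               tolerance = 1e-10)
  # 4 noisy anchors, order 1: normal-equation oracle
  set.seed(2)
  a <- cbind(c(0, 6, 12, 24), c(10, 8, 7, 3) + rnorm(4, 0, 0.1))
  cf1 <- curve_from_anchors(a, 1)
  X <- cbind(1, a[, 1])
  expect_equal(unname(cf1), unname(drop(solve(crossprod(X), crossprod(X, a[, 2])))),
               tolerance = 1e-10)
  expect_error(curve_from_anchors(rbind(c(0, 1), c(6, 2)), 2), "anchors")
})

test_that("default cohort hits the study missingness targets and is seed-stable", {
  coh <- generate_cohort(cohort_config(n_subjects = 689, seed = 3))
  miss_rate <- function(o) {
    1 - nrow(o$data) / (689 * length(trajmix:::schedule_times(o$data)))
  }
  expect_lt(abs(miss_rate(coh$outcomes$saps) - 0.30), 0.03)
  expect_lt(abs(miss_rate(coh$outcomes$sans) - 0.30), 0.03)
  expect_lt(abs(miss_rate(coh$outcomes$sofas) - 0.34), 0.04)
  # zero-rate config is complete
  coh0 <- generate_cohort(cohort_config(n_subjects = 40, seed = 3,
                                        missing_targets = c(symptoms = 0,
                                                            sofas = 0)))
  expect_equal(miss_rate_40 <- 1 - nrow(coh0$outcomes$saps$data) / (40 * 9), 0)
  # determinism
  c1 <- generate_cohort(cohort_config(n_subjects = 50, seed = 8))
  c2 <- generate_cohort(cohort_config(n_subjects = 50, seed = 8))
  c3 <- generate_cohort(cohort_config(n_subjects = 50, seed = 9))
  expect_identical(c1$outcomes$saps$data$value, c2$outcomes$saps$data$value)
  expect_false(identical(c1$outcomes$saps$data$value,
                         c3$outcomes$saps$data$value))
})

test_that("cohort values respect score ranges and item sums track the rounded totals", {
  coh <- generate_cohort(cohort_config(n_subjects = 100, seed = 5))
  expect_true(all(coh$outcomes$saps$complete$value >= 0 &
                    coh$outcomes$saps$complete$value <= 20))
  expect_true(all(coh$outcomes$sofas$complete$value >= 0 &
                    coh$outcomes$sofas$complete$value <= 100))
  expect_true(all(coh$items$sans$value %in% 0:5))
  sums <- coh$items$saps |>
    dplyr::group_by(subject_id, time) |>
    dplyr::summarise(s = sum(value), .groups = "drop")
  truth <- tibble::as_tibble(coh$outcomes$saps$complete) |>
    dplyr::semi_join(sums, by = c("subject_id", "time"))
  merged <- dplyr::inner_join(sums, truth, by = c("subject_id", "time"))
  expect_true(all(abs(merged$s - pmin(round(merged$value), 20)) <= 0.5 + 1e-9))
})

test_that("shared-propensity linkage calibration reproduces target risk ratios", {
  lam <- calibrate_linkage(c(0.68, 0.32), c(0.57, 0.43), 2.23)
  expect_equal(trajmix:::linked_rr(c(0.68, 0.32), c(0.57, 0.43), lam, lam),
               2.23, tolerance = 1e-3)
  expect_error(calibrate_linkage(c(0.5, 0.5), c(0.5, 0.5), 50),
               "unreachable")
  # empirical RR of a large default cohort lands near the calibrated targets
  coh <- generate_cohort(cohort_config(n_subjects = 6000, seed = 12))
  cls <- function(nm) coh$outcomes[[nm]]$classes |>
    dplyr::select(subject_id, class)
  rr <- cross_trajectory_rr(cls("saps"), cls("sofas"), 1, c(1, 2))
  expect_lt(abs(rr$rr - 2.23), 0.25)
  rr2 <- cross_trajectory_rr(cls("sans"), cls("sofas"), 1, c(1, 3))
  expect_lt(abs(rr2$rr - 1.53), 0.20)
})
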