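# a small fitted-model stand-in with controllable posteriors
fake_fit <- function(posteriors, ids = sprintf("s%03d", seq_len(nrow(posteriors)))) {
  modal <- apply(posteriors, 1, which.max)
  rownames(posteriors) <- ids
  structure(list(posteriors = posteriors, modal = setNames(modal, ids),
                 subject_ids = ids, n_subjects = length(ids)),
            class = "lgm_fit")
}

test_that("misclassification logits reproduce the Vermunt construction", {
  # one-hot posteriors -> identity classification matrix, capped logits
  p <- diag(2)[c(1, 1, 2, 2), ]
  ml <- misclassification_logits(p)
  expect_equal(ml$D, diag(2), tolerance = 1e-12)
  # off-diagonal zero probabilities map to capped logits (reference row
  # is identically zero by construction)
  expect_equal(ml$logits[1, ], c(ml$cap, -ml$cap))
  expect_equal(ml$logits[2, ], c(0, 0))
  # uninformative posteriors -> uniform matrix, zero logits
  p2 <- matrix(0.5, 4, 2)
  ml2 <- misclassification_logits(p2, modal = c(1, 1, 2, 2))
  expect_equal(ml2$D, matrix(0.5, 2, 2), tolerance = 1e-12)
  expect_equal(ml2$logits, matrix(0, 2, 2), tolerance = 1e-12)
  # random instance vs direct counting oracle
  set.seed(3)
  p3 <- matrix(rexp(30), 10); p3 <- p3 / rowSums(p3)
  modal <- apply(p3, 1, which.max)
  if (length(unique(modal)) == 3) {
    ml3 <- misclassification_logits(p3)
    D_oracle <- sapply(1:3, function(k)
      sapply(1:3, function(s) sum(p3[modal == s, k]) / sum(p3[, k])))
    expect_equal(ml3$D, D_oracle, tolerance = 1e-12)
    expect_equal(colSums(ml3$D), rep(1, 3), tolerance = 1e-10)
  }
  expect_error(misclassification_logits(diag(2)[c(1, 1), , drop = FALSE],
                                        modal = c(1, 1)), "empty")
})

sim_threestep <- function(n = 700, b = 1.2, entropy_noise = 0.25, seed = 1) {
  # true class from a logistic model on x, modal class with known error
  set.seed(seed)
  x <- rnorm(n)
  p2 <- plogis(-0.3 + b * x)
  true <- 1L + rbinom(n, 1, p2)
  post <- matrix(0, n, 2)
  acc <- 1 - entropy_noise
  flip <- runif(n) > acc
  modal <- ifelse(flip, 3L - true, true)
  post[cbind(seq_len(n), modal)] <- acc
  post[cbind(seq_len(n), 3L - modal)] <- 1 - acc
  list(x = x, true = true, fit = fake_fit(post))
}

test_that("membership prediction recovers a known logistic effect and keeps proportions fixed", {
  b <- 1.0
  sims <- lapply(1:3, function(s) sim_threestep(700, b = b, seed = s))
  ests <- sapply(sims, function(sm) {
    cov <- tibble::tibble(subject_id = sm$fit$subject_ids, x = sm$x)
    eff <- predict_membership(sm$fit, cov, "x", reference_class = 1)
    eff$log_or
  })
  # within Monte-Carlo error of the generating coefficient
  expect_lt(abs(mean(ests) - b), 3 * sd(ests) / sqrt(length(ests)) + 0.15)
  # class distribution reported by the 3-step is the fixed step-1 one
  sm <- sims[[1]]
  cov <- tibble::tibble(subject_id = sm$fit$subject_ids, x = sm$x)
  lg <- misclassification_logits(sm$fit)
  eff <- predict_membership(sm$fit, cov, "x", reference_class = 1, logits = lg)
  expect_equal(attr(eff, "class_proportions"), lg$pi, tolerance = 1e-12)
})

test_that("null covariates give OR near 1 with nominal CI coverage", {
  set.seed(42)
  cover <- replicate(40, {
    sm <- sim_threestep(250, b = 0.8, seed = sample.int(1e6, 1))
    z <- rnorm(250)  # independent of class
    cov <- tibble::tibble(subject_id = sm$fit$subject_ids, z = z)
    eff <- predict_membership(sm$fit, cov, "z", reference_class = 1)
    eff$conf_low <= 1 && eff$conf_high >= 1
  })
  expect_gte(mean(cover), 0.85)  # ~95% nominal, binomial slack at 40 reps
})

test_that("distal outcome tests recover class means, SMD formula, and flag unbounded ORs", {
  # SMD formula: means 1 and 0, sample SD forced
  sm <- sim_threestep(600, b = 1.5, entropy_noise = 0.1, seed = 7)
  y <- ifelse(sm$true == 2, 1, 0) + rnorm(600, sd = 0.4)
  out <- distal_outcome_test(sm$fit, tibble::tibble(
    subject_id = sm$fit$subject_ids, y = y), "y", "continuous")
  est <- attr(out, "class_estimates")
  expect_equal(out$smd, out$estimate / sd(y))
  expect_lt(abs(abs(out$estimate) - 1), 0.2)
  expect_lt(out$p_value, 1e-6)
  # binary with a structural zero in one class -> unbounded OR flagged
  yb <- as.integer(sm$true == 2 & runif(600) < 0.5)
  outb <- distal_outcome_test(sm$fit, tibble::tibble(
    subject_id = sm$fit$subject_ids, yb = yb), "yb", "binary")
  expect_true(any(outb$unbounded))
  expect_true(any(!is.finite(outb$or) | outb$or == 0))
})

test_that("distal Wald p values are roughly uniform under the null", {
  set.seed(9)
  ps <- replicate(120, {
    sm <- sim_threestep(150, b = 1.0, entropy_noise = 0.15,
                        seed = sample.int(1e6, 1))
    y <- rnorm(150)
    distal_outcome_test(sm$fit, tibble::tibble(
      subject_id = sm$fit$subject_ids, y = y), "y", "continuous")$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(ps < 0.5), 0.35)
})

test_that("cross-trajectory risk ratios match hand computation with Katz CI", {
  aa <- tibble::tibble(subject_id = as.character(1:80),
                       class = rep(c(1, 2), each = 40))
  bb <- tibble::tibble(subject_id = as.character(1:80),
                       class = rep(c(1, 2, 1, 2), times = c(30, 10, 10, 30)))
  rr <- cross_trajectory_rr(aa, bb, target_class_b = 1, classes_a = c(1, 2))
  expect_equal(rr$rr, 3.0)
  se <- sqrt(1 / 30 - 1 / 40 + 1 / 10 - 1 / 40)
  expect_equal(rr$conf_low, exp(log(3) - qnorm(0.975) * se))
  expect_equal(rr$conf_high, exp(log(3) + qnorm(0.975) * se))
  # brute-force equality on random instances; independence -> RR near 1
  set.seed(5)
  rrs <- replicate(30, {
    a <- tibble::tibble(subject_id = as.character(1:500),
                        class = sample(1:2, 500, TRUE))
    b <- tibble::tibble(subject_id = as.character(1:500),
                        class = sample(1:2, 500, TRUE))
    out <- cross_trajectory_rr(a, b, 1)
    tab <- table(a$class, b$class)
    expect_equal(out$rr, (tab[1, 1] / sum(tab[1, ])) /
                   (tab[2, 1] / sum(tab[2, ])))
    out$rr
  })
  expect_lt(abs(mean(log(rrs))), 0.1)
  # subjects missing from one side are excluded and counted
  rr2 <- cross_trajectory_rr(aa[1:60, ], bb, 1)
  expect_equal(rr2$n_excluded, 20L)
})

test_that("Bonferroni thresholds reproduce the published family corrections", {
  expect_equal(unique(bonferroni_adjust(runif(3), n_tests = 50)$threshold),
               0.001)
  expect_equal(unique(bonferroni_adjust(runif(3), n_tests = 10)$threshold),
               0.005)
  one <- bonferroni_adjust(0.04, n_tests = 1)
  expect_equal(one$threshold, 0.05)
  expect_true(one$significant)
})
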