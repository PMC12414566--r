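# selection-pipeline behavior on small simulated cohorts (fast settings;
# full-scale structure recovery lives in the acceptance suite)

small_two_class <- function(n = 250, seed = 1) {
  m <- gbtm2_model(sigma = 1.5)
  generate_from_model(m$spec, m$params, n, seed = seed)
}

test_that("bootstrap LRT p values live on the attainable grid and detect real structure", {
  sim <- small_two_class(200, seed = 3)
  spec1 <- lgm_spec("GBTM", 1, 2, character(), "FIXED", sched9)
  spec2 <- lgm_spec("GBTM", 2, 2, character(), "FIXED", sched9)
  lrt <- bootstrap_lrt(sim$data, spec2, spec1, replicates = 19, seed = 5,
                       protocol = fast_protocol())
  expect_gte(lrt$p_value, 1 / 20)
  expect_lte(lrt$p_value, 1)
  expect_equal(lrt$p_value, 1 / 20)   # two well-separated classes: minimum p
  expect_gt(lrt$statistic, 0)
  # seed reproducibility
  lrt2 <- bootstrap_lrt(sim$data, spec2, spec1, replicates = 19, seed = 5,
                        protocol = fast_protocol())
  expect_identical(lrt$p_value, lrt2$p_value)
  expect_identical(lrt$boot_stats, lrt2$boot_stats)
})

test_that("LRT of an extra spurious class is conservative on one-class data", {
  spec1 <- lgm_spec("GBTM", 1, 2, character(), "FIXED", c(0, 6, 12, 24))
  params <- growth_parameters(spec1, 1, list(c(8, -0.4, 0.01)), NULL, 2)
  sim <- generate_from_model(spec1, params, 120, seed = 17)
  spec2 <- lgm_spec("GBTM", 2, 2, character(), "FIXED", c(0, 6, 12, 24))
  lrt <- bootstrap_lrt(sim$data, spec2, spec1, replicates = 19, seed = 2,
                       protocol = fast_protocol())
  expect_gte(lrt$p_value, 0.05)
})

test_that("stepwise selection recovers a 2-class structure and degenerates gracefully", {
  sim <- small_two_class(300, seed = 7)
  sel <- select_trajectory_model(
    sim$data, preset_poly_order = 2,
    config = selection_config(max_classes = 3, lrt_replicates = 19),
    protocol = fast_protocol(), seed = 4)
  expect_equal(sel$fit$spec$n_classes, 2L)
  # audit integrity: every fitted candidate once, selected model marked
  expect_equal(sum(sel$audit$selected), 1L)
  expect_true(all(c("1_baseline", "2_enumeration", "3_residuals",
                    "4_random_effects", "5_pruning") %in% sel$audit$stage))
  fitted_rows <- sel$audit[!is.na(sel$audit$bic) &
                             !grepl("winner|selected|LRT|final",
                                    sel$audit$label), ]
  expect_false(any(duplicated(fitted_rows$label)))
  # max_classes = 1 collapses to the baseline
  sel1 <- select_trajectory_model(
    sim$data, preset_poly_order = 2,
    config = selection_config(max_classes = 1, lrt_replicates = 0),
    protocol = fast_protocol(), seed = 4)
  expect_equal(sel1$fit$spec$n_classes, 1L)
})

test_that("one-class truth retains the single-class baseline", {
  spec1 <- lgm_spec("GBTM", 1, 2, character(), "FIXED", c(0, 6, 12, 24))
  params <- growth_parameters(spec1, 1, list(c(8, -0.4, 0.01)), NULL, 2)
  sim <- generate_from_model(spec1, params, 150, seed = 23)
  sel <- select_trajectory_model(
    sim$data, preset_poly_order = 2,
    config = selection_config(max_classes = 3, lrt_replicates = 19),
    protocol = fast_protocol(), seed = 6)
  expect_equal(sel$fit$spec$n_classes, 1L)
})

test_that("Wald pruning drops spurious high-order terms and keeps real ones", {
  # pure linear truth fitted as cubic: cubic then quadratic pruned
  spec_lin <- lgm_spec("GBTM", 1, 1, character(), "FIXED", sched9)
  params <- growth_parameters(spec_lin, 1, list(c(10, -0.3)), NULL, 1.5)
  sim <- generate_from_model(spec_lin, params, 300, seed = 31)
  spec_cub <- lgm_spec("GBTM", 1, 3, character(), "FIXED", sched9)
  fit <- fit_lgm(sim$data, spec_cub, fast_protocol(), seed = 1)
  ref <- refine_polynomial(fit, sim$data, alpha_wald = 0.05,
                           protocol = fast_protocol(), seed = 2)
  expect_equal(ref$fit$spec$poly_order, 1L)
  expect_gte(nrow(ref$audit), 2L)
  # strong quadratic truth: top term significant, model unchanged
  m <- gbtm2_model(sigma = 1)
  sim2 <- generate_from_model(m$spec, m$params, 400, seed = 32)
  fit2 <- fit_lgm(sim2$data, m$spec, fast_protocol(), seed = 1)
  ref2 <- refine_polynomial(fit2, sim2$data, alpha_wald = 0.05,
                            protocol = fast_protocol(), seed = 3)
  expect_equal(ref2$fit$spec$poly_order, c(2L, 2L))
  expect_equal(ref2$fit$loglik, fit2$loglik)
})

test_that("selection prefers parsimony within the BIC tie band", {
  fits <- list(
    structure(list(spec = lgm_spec("GBTM", 2, 2, character(), "FIXED",
                                   sched9),
                   fit_indices = list(bic = 1000.5)), class = "lgm_fit"),
    structure(list(spec = lgm_spec("LCGA", 2, 2, character(),
                                   "FREE_OVER_TIME", sched9),
                   fit_indices = list(bic = 1000.0)), class = "lgm_fit"))
  # BIC difference 0.5 < 2: fewer-parameter GBTM wins despite higher BIC
  expect_equal(trajmix:::pick_best(fits, selection_config()), 1L)
  fits[[2]]$fit_indices$bic <- 990
  expect_equal(trajmix:::pick_best(fits, selection_config()), 2L)
})
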