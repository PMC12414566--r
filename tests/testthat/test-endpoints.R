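long1 <- function(...) {
  v <- c(...)
  tibble::tibble(subject_id = "s1", time = as.numeric(names(v)), value = v)
}

test_that("early response is a strict 50% reduction with degenerate-zero handling", {
  er <- early_response(long1(`0` = 10, `3` = 5))
  expect_true(er$early_response)
  expect_false(early_response(long1(`0` = 10, `3` = 6))$early_response)
  er0 <- early_response(long1(`0` = 0, `3` = 0))
  expect_true(er0$early_response)
  expect_true(er0$degenerate_baseline)
  expect_false(early_response(long1(`0` = 0, `3` = 1))$early_response)
  # missing month 3 -> not evaluable, never FALSE
  miss <- early_response(long1(`0` = 10, `6` = 1))
  expect_true(is.na(miss$early_response))
  expect_false(miss$evaluable)
})

items_tbl <- function(values18, values24, items = paste0("i", 1:4)) {
  tibble::tibble(
    subject_id = "s1",
    time = rep(c(18, 24), each = length(items)),
    item = rep(items, 2),
    value = c(values18, values24))
}

test_that("symptom remission needs all global items at/below threshold at both window visits", {
  expect_true(symptom_remission(items_tbl(rep(2, 4), rep(2, 4)))$remission)
  expect_false(symptom_remission(items_tbl(c(3, 2, 2, 2), rep(2, 4)))$remission)
  # attention excluded: a high attention item cannot block remission
  it <- items_tbl(c(rep(2, 4), 4), c(rep(1, 4), 4),
                  items = c(paste0("i", 1:4), "attention"))
  expect_true(symptom_remission(it, exclude_items = "attention")$remission)
  expect_false(symptom_remission(it)$remission)
  # a missing item at one visit -> not evaluable
  it2 <- items_tbl(rep(2, 4), c(2, 2, 2, NA))
  out <- symptom_remission(it2)
  expect_true(is.na(out$remission))
})

test_that("functional remission uses a strict cut-off at both visits", {
  expect_true(functional_remission(long1(`12` = 61, `24` = 61))$functional_remission)
  expect_false(functional_remission(long1(`12` = 60, `24` = 80))$functional_remission)
  out <- functional_remission(long1(`12` = 80))
  expect_true(is.na(out$functional_remission))
  expect_false(out$evaluable)
})

test_that("recovery composes clinical and functional remission with three-valued logic", {
  coh <- generate_cohort(cohort_config(n_subjects = 60, seed = 4,
                                       missing_targets = c(symptoms = 0,
                                                           sofas = 0)))
  ep <- derive_endpoints(
    saps = coh$outcomes$saps$complete, sans = coh$outcomes$sans$complete,
    saps_items = coh$items$saps, sans_items = coh$items$sans,
    sofas = coh$outcomes$sofas$complete)
  expect_equal(ep$recovery, ep$clinical_remission & ep$functional_remission)
  expect_equal(ep$clinical_remission, ep$remission_pos & ep$remission_neg)
  # definite FALSE dominates an NA partner
  expect_false(isTRUE(NA & FALSE))
})

test_that("attrition filter excludes strictly above the 30% missing threshold", {
  times <- sched9
  base <- tidyr::expand_grid(subject_id = c("a", "b", "c"), time = times)
  base$value <- 5
  # a: complete; b: missing 2/9 (22%); c: missing 3/9 (33%)
  drop <- !(base$subject_id == "b" & base$time %in% c(18, 24)) &
    !(base$subject_id == "c" & base$time %in% c(12, 18, 24))
  dat <- lgm_data(base[drop, ], times = times)
  out <- attrition_filter(dat, 0.30)
  expect_setequal(unique(out$data$subject_id), c("a", "b"))
  expect_equal(out$excluded$subject_id, "c")
  # complete data: identity
  full <- lgm_data(base, times = times)
  expect_equal(nrow(attrition_filter(full, 0.30)$excluded), 0L)
  expect_equal(nrow(attrition_filter(full, 0.30)$data), nrow(full))
})

test_that("rederived endpoint flags equal generator ground truth on complete data", {
  coh <- generate_cohort(cohort_config(n_subjects = 80, seed = 11,
                                       missing_targets = c(symptoms = 0,
                                                           sofas = 0)))
  ep <- derive_endpoints(
    saps = coh$outcomes$saps$data, sans = coh$outcomes$sans$data,
    saps_items = coh$items$saps, sans_items = coh$items$sans,
    sofas = coh$outcomes$sofas$data)
  truth <- coh$endpoints_truth
  expect_identical(ep, truth)
})
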