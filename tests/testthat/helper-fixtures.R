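# shared fixtures: small specs, parameter sets and simulated datasets

sched9 <- c(0, 1, 2, 3, 6, 9, 12, 18, 24)
sched3 <- c(0, 12, 24)

spec_saps_t2 <- function() {
  lgm_spec("GMM_CLASS_VARIANT", 2, 3, c("intercept", "linear_slope"),
           "FREE_BOTH", sched9)
}
spec_sans_t2 <- function() {
  lgm_spec("GMM_CLASS_INVARIANT", 3, c(3, 3, 1),
           c("intercept", "linear_slope"), "FREE_OVER_CLASSES", sched9)
}
spec_sofas_t2 <- function() {
  lgm_spec("GBTM", 2, 2, character(), "FIXED", sched9)
}

# well-separated 2-class quadratic GBTM used in several recovery tests
gbtm2_model <- function(sigma = 1.5) {
  spec <- lgm_spec("GBTM", 2, 2, character(), "FIXED", sched9)
  beta <- list(curve_from_anchors(rbind(c(0, 10), c(12, 6), c(24, 4)), 2),
               curve_from_anchors(rbind(c(0, 3), c(12, 1.5), c(24, 1)), 2))
  params <- growth_parameters(spec, c(0.6, 0.4), beta, NULL, sigma^2)
  list(spec = spec, params = params)
}

# tiny mixed-effect model for likelihood oracle checks
small_gmm_model <- function() {
  spec <- lgm_spec("GMM_CLASS_INVARIANT", 2, 2, c("intercept", "linear_slope"),
                   "FREE_OVER_TIME", c(0, 6, 12))
  params <- growth_parameters(
    spec, c(0.4, 0.6),
    list(c(1, 0.5, 0.01), c(5, -0.2, 0.02)),
    matrix(c(1.5, 0.02, 0.02, 0.05), 2), c(1, 1.5, 2))
  list(spec = spec, params = params)
}

fast_protocol <- function(n_starts = 4L, ...) {
  trajmix:::default_protocol(n_starts = n_starts, ...)
}

long_from_matrix <- function(Y, times) {
  ids <- sprintf("s%03d", seq_len(nrow(Y)))
  df <- tibble::tibble(
    subject_id = rep(ids, each = length(times)),
    time = rep(times, nrow(Y)),
    value = as.vector(t(Y)))
  df[!is.na(df$value), ]
}
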