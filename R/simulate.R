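#' Simulate a cohort exactly from a latent growth model
#'
#' Draws each subject's class from the class proportions, random effects
#' from the class covariance, and residuals from the residual variances,
#' producing complete data (no missingness) on the spec's visit schedule.
#' This is the exact model-based simulator used for parameter-recovery
#' checks and the parametric bootstrap likelihood ratio test.
#'
#' @param spec An [lgm_spec()].
#' @param params [growth_parameters()] to simulate from (month units).
#' @param n Number of subjects.
#' @param seed Integer seed; the draw is fully determined by it.
#' @param obs_mask Optional N x T logical matrix marking which scheduled
#'   visits are observed (used by the bootstrap to preserve the observed
#'   missingness patterns). Default: all observed.
#' @return A list of class `lgm_sim` with elements `data` (an [lgm_data()]
#'   long tibble) and `truth` (tibble of `subject_id`, `class`).
#' @export
generate_from_model <- function(spec, params, n, seed = 1L, obs_mask = NULL) {
  stopifnot(inherits(spec, "lgm_spec"), inherits(params, "growth_parameters"))
  sim <- simulate_wide(spec, params, n, seed, obs_mask)
  Y <- sim$Y
  cls <- sim$classes
  T_ <- length(spec$times)
  ids <- sprintf("s%04d", seq_len(n))
  long <- tibble(
    subject_id = rep(ids, each = T_),
    time = rep(spec$times, n),
    value = as.vector(t(Y))) |>
    dplyr::filter(!is.na(.data$value))
  structure(
    list(data = lgm_data(long, times = spec$times),
         truth = tibble(subject_id = ids, class = cls)),
    class = "lgm_sim")
}

# matrix-level simulator shared by generate_from_model and the bootstrap
simulate_wide <- function(spec, params, n, seed = 1L, obs_mask = NULL) {
  T_ <- length(spec$times)
  r <- n_random_effects(spec)
  theta <- expand_theta(spec, params$theta)
  Z <- if (r > 0L) re_design(spec$times, spec$random_effects) else NULL
  withr::with_seed(as.integer(seed), {
    cls <- sample.int(spec$n_classes, n, replace = TRUE, prob = params$pi)
    Y <- matrix(NA_real_, n, T_)
    for (k in seq_len(spec$n_classes)) {
      rows <- which(cls == k)
      if (!length(rows)) next
      mu <- class_mean_trajectory(params, k, spec$times)
      E <- matrix(rnorm(length(rows) * T_), length(rows), T_) *
        matrix(sqrt(theta[k, ]), length(rows), T_, byrow = TRUE)
      Yk <- matrix(mu, length(rows), T_, byrow = TRUE) + E
      if (r > 0L) {
        psi_k <- psi_for_class(params, k)
        b <- MASS::mvrnorm(length(rows), mu = rep(0, r), Sigma = psi_k)
        if (length(rows) == 1L) b <- matrix(b, 1L)
        Yk <- Yk + b %*% t(Z)
      }
      Y[rows, ] <- Yk
    }
  })
  if (!is.null(obs_mask)) {
    stopifnot(nrow(obs_mask) == n, ncol(obs_mask) == T_)
    Y[!obs_mask] <- NA_real_
  }
  list(Y = Y, classes = cls)
}

#' Polynomial coefficients through printed anchor values
#'
#' Fits a polynomial of the requested order through (time, value) anchor
#' points by least squares; when the number of anchors equals `order + 1`
#' the curve interpolates them exactly. Used to turn the trajectory values
#' printed for each latent class into generating mean curves.
#'
#' @param anchors A two-column matrix or data frame of (time, value) pairs,
#'   times in months.
#' @param order Polynomial order (1-3).
#' @return Numeric coefficient vector `(beta_0, ..., beta_order)` in
#'   outcome units per month^j.
#' @examples
#' curve_from_anchors(cbind(c(0, 12, 24), c(40, 70, 76.4)), order = 2)
#' @export
curve_from_anchors <- function(anchors, order) {
  anchors <- as.matrix(anchors)
  stopifnot(ncol(anchors) == 2L)
  if (nrow(anchors) < order + 1L) {
    abort(sprintf("Need at least %d anchors for order %d.", order + 1L, order))
  }
  X <- design_matrix(anchors[, 1L], order)
  drop(qr.solve(X, anchors[, 2L]))
}
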