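# Marginal Gaussian mixture likelihood under missing-at-random visits.
#
# Under a linear-Gaussian growth structure the random effects integrate out
# in closed form: restricted to a subject's observed visits,
#   y_i | class k  ~  N(X_i beta_k,  Z_i Psi_k Z_i' + Theta_k),
# so the observed-data (FIML) log likelihood is
#   sum_i log sum_k pi_k phi(y_i^obs; mu_ik^obs, Sigma_ik^obs).

# N x K matrix of per-class log densities log f_k(y_i^obs)
class_logdensities <- function(spec, params, wide) {
  K <- spec$n_classes
  T_ <- length(wide$times)
  N <- nrow(wide$Y)
  stopifnot(identical(as.numeric(wide$times), as.numeric(spec$times)))
  theta <- expand_theta(spec, params$theta)
  r <- n_random_effects(spec)
  logf <- matrix(NA_real_, N, K)
  mu <- vapply(seq_len(K),
               function(k) class_mean_trajectory(params, k, wide$times),
               numeric(T_))               # T x K
  if (r == 0L) {
    # diagonal covariance: fully vectorized over subjects
    for (k in seq_len(K)) {
      ll <- dnorm(wide$Y, mean = matrix(mu[, k], N, T_, byrow = TRUE),
                  sd = matrix(sqrt(theta[k, ]), N, T_, byrow = TRUE),
                  log = TRUE)
      ll[!wide$obs] <- 0
      logf[, k] <- rowSums(ll)
    }
    return(logf)
  }
  Z <- re_design(wide$times, spec$random_effects)
  for (k in seq_len(K)) {
    psi_k <- psi_for_class(params, k)
    sigma_full <- Z %*% psi_k %*% t(Z) + diag(theta[k, ], T_)
    for (p in wide$patterns) {
      idx <- p$idx
      S <- sigma_full[idx, idx, drop = FALSE]
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(ch)) {
        abort(sprintf(
          "Singular within-class covariance for class %d (subject %s).",
          k, as.character(wide$subject_ids[p$rows[1L]])))
      }
      R <- wide$Y[p$rows, idx, drop = FALSE] -
        matrix(mu[idx, k], length(p$rows), length(idx), byrow = TRUE)
      U <- backsolve(ch, t(R), transpose = TRUE)   # solves t(ch) %*% U = t(R)
      q <- colSums(U^2)
      logf[p$rows, k] <- -0.5 * (length(idx) * log(2 * pi) +
                                   2 * sum(log(diag(ch))) + q)
    }
  }
  logf
}

logsumexp_rows <- function(m) {
  K <- ncol(m)
  mx <- m[, 1L]
  if (K > 1L) for (k in 2:K) mx <- pmax(mx, m[, k])
  mx + log(rowSums(exp(m - mx)))
}

#' Marginal (FIML) log likelihood of a latent growth model
#'
#' Each subject contributes the log of a mixture of multivariate normal
#' densities restricted to that subject's observed visits, which is the
#' full-information maximum likelihood treatment of assessments missing at
#' random.
#'
#' @param spec An [lgm_spec()].
#' @param params A [growth_parameters()] consistent with `spec`.
#' @param data An [lgm_data()] table (or a data frame coercible to one)
#'   whose schedule matches `spec$times`.
#' @return The scalar log likelihood.
#' @export
marginal_loglik <- function(spec, params, data) {
  wide <- as_lgm_wide(data, times = spec$times)
  logf <- class_logdensities(spec, params, wide)
  sum(logsumexp_rows(sweep(logf, 2L, log(params$pi), `+`)))
}

#' Posterior class membership probabilities
#'
#' Bayes-rule posteriors `p_ik = pi_k f_k(y_i) / sum_m pi_m f_m(y_i)`,
#' computed in log space so that no row underflows to zero.
#'
#' @inheritParams marginal_loglik
#' @return An N x K matrix with rows summing to 1, with subject ids as row
#'   names.
#' @export
class_posteriors <- function(spec, params, data) {
  wide <- as_lgm_wide(data, times = spec$times)
  post <- posterior_from_logf(
    class_logdensities(spec, params, wide), params$pi)
  rownames(post) <- as.character(wide$subject_ids)
  post
}

posterior_from_logf <- function(logf, pi) {
  lp <- sweep(logf, 2L, log(pmax(pi, 1e-300)), `+`)
  lse <- logsumexp_rows(lp)
  exp(lp - lse)
}

# modal assignment with ties broken to the lowest class index
modal_assignment <- function(posteriors) {
  apply(posteriors, 1L, which.max)
}
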