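# independent oracles used to validate the package's own implementations

# dense multivariate-normal mixture log likelihood, built directly from
# the marginal covariance per subject (mvtnorm::dmvnorm as the density)
oracle_mixture_loglik <- function(spec, params, data) {
  wide <- trajmix:::as_lgm_wide(data, times = spec$times)
  theta <- trajmix:::expand_theta(spec, params$theta)
  r <- length(spec$random_effects)
  Z <- if (r > 0) trajmix:::re_design(spec$times, spec$random_effects) else NULL
  total <- 0
  for (i in seq_len(nrow(wide$Y))) {
    idx <- which(wide$obs[i, ])
    y <- wide$Y[i, idx]
    comp <- vapply(seq_len(spec$n_classes), function(k) {
      mu <- class_mean_trajectory(params, k, spec$times)[idx]
      S <- diag(theta[k, idx], length(idx))
      if (r > 0) {
        psi_k <- trajmix:::psi_for_class(params, k)
        Zi <- Z[idx, , drop = FALSE]
        S <- S + Zi %*% psi_k %*% t(Zi)
      }
      mvtnorm::dmvnorm(y, mean = mu, sigma = S)
    }, numeric(1))
    total <- total + log(sum(params$pi * comp))
  }
  total
}

# Bayes-rule posteriors from the oracle densities
oracle_posteriors <- function(spec, params, data) {
  wide <- trajmix:::as_lgm_wide(data, times = spec$times)
  theta <- trajmix:::expand_theta(spec, params$theta)
  r <- length(spec$random_effects)
  Z <- if (r > 0) trajmix:::re_design(spec$times, spec$random_effects) else NULL
  t(vapply(seq_len(nrow(wide$Y)), function(i) {
    idx <- which(wide$obs[i, ])
    y <- wide$Y[i, idx]
    comp <- vapply(seq_len(spec$n_classes), function(k) {
      mu <- class_mean_trajectory(params, k, spec$times)[idx]
      S <- diag(theta[k, idx], length(idx))
      if (r > 0) {
        psi_k <- trajmix:::psi_for_class(params, k)
        Zi <- Z[idx, , drop = FALSE]
        S <- S + Zi %*% psi_k %*% t(Zi)
      }
      mvtnorm::dmvnorm(y, mean = mu, sigma = S)
    }, numeric(1))
    params$pi * comp / sum(params$pi * comp)
  }, numeric(spec$n_classes)))
}

# random small model + dataset for property-style likelihood checks
random_small_instance <- function(seed) {
  set.seed(seed)
  T_ <- sample(2:3, 1)
  K <- sample(1:2, 1)
  times <- sort(sample(c(0, 3, 6, 12, 24), T_))
  r <- sample(0:min(2, T_ - 1), 1)
  re <- c("intercept", "linear_slope")[seq_len(r)]
  fam <- if (K == 1 && r > 0) "GCM" else if (r == 0) "GBTM"
  else sample(c("GMM_CLASS_INVARIANT", "GMM_CLASS_VARIANT"), 1)
  if (fam == "GBTM") resid <- "FIXED" else
    resid <- sample(c("FIXED", "FREE_OVER_TIME", "FREE_OVER_CLASSES",
                      "FREE_BOTH"), 1)
  ord <- sample(seq_len(min(3, T_ - 1)), 1)
  spec <- lgm_spec(fam, K, ord, re, resid, times)
  beta <- lapply(seq_len(K), function(k) round(rnorm(ord + 1), 2))
  psi <- NULL
  if (r > 0) {
    mk <- function() {
      A <- matrix(rnorm(r * r), r)
      crossprod(A) / 2 + diag(0.3, r)
    }
    psi <- if (fam == "GMM_CLASS_VARIANT") replicate(K, mk(), simplify = FALSE)
    else mk()
  }
  theta <- switch(resid,
    FIXED = runif(1, 0.5, 2),
    FREE_OVER_TIME = runif(T_, 0.5, 2),
    FREE_OVER_CLASSES = runif(K, 0.5, 2),
    FREE_BOTH = matrix(runif(K * T_, 0.5, 2), K))
  pi <- if (K == 1) 1 else {
    p <- runif(K, 0.2, 1); p / sum(p)
  }
  params <- growth_parameters(spec, pi, beta, psi, theta)
  n <- sample(2:5, 1)
  sim <- generate_from_model(spec, params, n, seed = seed + 1)
  # knock out some visits (keep >= 1 per subject) to exercise FIML
  dat <- sim$data
  if (T_ > 1 && n > 2) {
    drop_rows <- sample(nrow(dat), floor(nrow(dat) * 0.2))
    keep <- setdiff(seq_len(nrow(dat)), drop_rows)
    kept <- dat[keep, ]
    have <- unique(kept$subject_id)
    kept <- rbind(kept, dat[!dat$subject_id %in% have, ])
    dat <- lgm_data(kept, times = times)
  }
  list(spec = spec, params = params, data = dat)
}
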