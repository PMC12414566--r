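#' Parametric bootstrap likelihood ratio test of K vs K-1 classes
#'
#' Fits both models to the data, then simulates `replicates` datasets from
#' the fitted (K-1)-class model — preserving each subject's observed-visit
#' pattern — and refits both models on each replicate. The p value is the
#' proportion of bootstrap `-2 * (ll_{K-1} - ll_K)` statistics at least as
#' large as the observed one, computed as `(1 + #exceed) / (R + 1)` so that
#' attainable p values are `1/(R+1), ..., 1`. A small p indicates the
#' K-class model fits significantly better than the (K-1)-class model.
#'
#' Bootstrap refits are warm-started at the generating and observed-data
#' solutions in addition to a couple of random starts, the standard
#' cost-saving device for bootstrap LRTs in mixture software.
#'
#' @param data An [lgm_data()] table.
#' @param spec_k Spec with K classes.
#' @param spec_km1 The same spec with one fewer class.
#' @param replicates Number of bootstrap replicates R.
#' @param seed Integer seed (the test is seed-reproducible).
#' @param protocol [start_protocol()] for the two observed-data fits.
#' @param fit_k,fit_km1 Optional pre-computed observed-data fits (skips
#'   refitting).
#' @param max_failures Maximum tolerated fraction of failed bootstrap
#'   refits before the test errors out.
#' @return A list of class `lgm_lrt`: `p_value`, `statistic` (the observed
#'   `-2` delta log likelihood), `boot_stats`, `replicates`, and the two
#'   observed-data fits.
#' @export
bootstrap_lrt <- function(data, spec_k, spec_km1, replicates = 99L, seed = 1L,
                          protocol = default_protocol(),
                          fit_k = NULL, fit_km1 = NULL,
                          max_failures = 0.10) {
  stopifnot(spec_km1$n_classes == spec_k$n_classes - 1L)
  data <- if (inherits(data, "lgm_data")) data else lgm_data(data, times = spec_k$times)
  if (is.null(fit_km1)) fit_km1 <- fit_lgm(data, spec_km1, protocol, seed = seed)
  if (is.null(fit_k)) fit_k <- fit_lgm(data, spec_k, protocol, seed = seed + 1L)
  obs_stat <- 2 * (fit_k$loglik - fit_km1$loglik)
  wide <- as_lgm_wide(data, times = spec_k$times)
  n <- nrow(wide$Y)
  # replicate refits are warm-started at the generating and observed-data
  # solutions, so one random start and looser convergence suffice (the
  # usual cost-saving device in bootstrap LRTs for mixtures)
  boot_proto <- protocol
  boot_proto$n_starts <- 1L
  boot_proto$n_final_stage <- 1L
  boot_proto$polish <- FALSE
  boot_proto$tol <- max(protocol$tol, 1e-6)
  boot_proto$stage1_iters <- min(protocol$stage1_iters, 10L)
  boot_proto$max_iter <- min(protocol$max_iter, 300L)
  init_km1 <- list(params_to_state(spec_km1, fit_km1$params))
  init_k <- list(params_to_state(spec_k, fit_k$params))
  boot_stats <- rep(NA_real_, replicates)
  # the observed-visit patterns are reused by every replicate
  wide_tpl <- wide
  for (b in seq_len(replicates)) {
    sim <- simulate_wide(spec_km1, fit_km1$params, n,
                         seed = seed + 7000L + b)
    Yb <- sim$Y
    Yb[!wide$obs] <- NA_real_
    wide_tpl$Y <- Yb
    # degenerate-class warnings are routine for K-class fits on (K-1)-class
    # null draws; they carry no information inside the bootstrap
    res <- tryCatch(suppressWarnings({
      f0 <- fit_lgm_wide(wide_tpl, spec_km1, boot_proto,
                         seed = seed + 100L + b, init = init_km1)
      f1 <- fit_lgm_wide(wide_tpl, spec_k, boot_proto,
                         seed = seed + 200L + b, init = init_k)
      2 * (f1$loglik - f0$loglik)
    }), error = function(e) NA_real_)
    boot_stats[b] <- res
  }
  failed <- sum(is.na(boot_stats))
  if (failed > max_failures * replicates) {
    abort(sprintf("Bootstrap LRT: %d of %d replicate refits failed.",
                  failed, replicates))
  }
  ok <- boot_stats[!is.na(boot_stats)]
  p <- (1 + sum(ok >= obs_stat)) / (length(ok) + 1)
  structure(
    list(p_value = p, statistic = obs_stat, boot_stats = boot_stats,
         replicates = replicates, n_failed = failed,
         fit_k = fit_k, fit_km1 = fit_km1),
    class = "lgm_lrt")
}

#' @export
print.lgm_lrt <- function(x, ...) {
  cat(sprintf(
    "<bootstrap LRT> %d vs %d classes: -2dLL = %.3f, p = %.4f (%d replicates%s)\n",
    x$fit_k$spec$n_classes, x$fit_km1$spec$n_classes,
    x$statistic, x$p_value, x$replicates,
    if (x$n_failed > 0) sprintf(", %d failed", x$n_failed) else ""))
  invisible(x)
}
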