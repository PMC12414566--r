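#' Bundle the free parameters of a latent growth model
#'
#' @param spec The [lgm_spec()] the parameters belong to.
#' @param pi Numeric vector of class proportions on the K-simplex.
#' @param beta List of per-class growth coefficient vectors; class `k` has
#'   length `poly_order[k] + 1`, in outcome units per month^j.
#' @param psi Random-effect covariance: a single symmetric positive
#'   semi-definite matrix (class-invariant families, GCM) or a list of one
#'   matrix per class (class-variant GMM). `NULL` for GBTM/LCGA.
#' @param theta Residual variances, matching `spec$residuals`: a scalar
#'   (`FIXED`), a vector over visits (`FREE_OVER_TIME`), a vector over
#'   classes (`FREE_OVER_CLASSES`) or a K x T matrix (`FREE_BOTH`).
#'   Outcome-units squared.
#'
#' @return An object of class `growth_parameters`.
#' @export
growth_parameters <- function(spec, pi, beta, psi = NULL, theta) {
  stopifnot(inherits(spec, "lgm_spec"))
  K <- spec$n_classes
  pi <- as.numeric(pi)
  if (length(pi) != K || any(pi < -1e-12)) {
    abort("`pi` must be a non-negative vector of length K.")
  }
  if (abs(sum(pi) - 1) > 1e-10) {
    abort("Class proportions must sum to 1 (tolerance 1e-10).")
  }
  pi <- pmax(pi, 0); pi <- pi / sum(pi)
  if (!is.list(beta)) beta <- list(as.numeric(beta))
  if (length(beta) != K) abort("`beta` must be a list with one vector per class.")
  for (k in seq_len(K)) {
    if (length(beta[[k]]) != spec$poly_order[k] + 1L) {
      abort(sprintf("beta[[%d]] must have length poly_order + 1 = %d.",
                    k, spec$poly_order[k] + 1L))
    }
  }
  r <- n_random_effects(spec)
  if (r == 0L) {
    if (!is.null(psi)) abort("`psi` must be NULL for models without random effects.")
  } else {
    if (spec$family == "GMM_CLASS_VARIANT") {
      if (!is.list(psi) || length(psi) != K) {
        abort("Class-variant GMM needs a list of K covariance matrices.")
      }
    } else {
      if (is.list(psi)) abort("Class-invariant families take a single `psi` matrix.")
      psi <- list(psi)
    }
    for (m in psi) {
      m <- as.matrix(m)
      if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)) ||
          any(eigen(m, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
        abort("Every random-effect covariance must be symmetric PSD.")
      }
      if (nrow(m) != r) abort("`psi` dimension must equal the number of random effects.")
    }
    if (spec$family != "GMM_CLASS_VARIANT") psi <- psi[[1]]
  }
  theta_m <- expand_theta(spec, theta)
  if (any(theta_m <= 0)) abort("Residual variances must be strictly positive.")
  structure(
    list(spec = spec, pi = pi, beta = beta, psi = psi, theta = theta),
    class = "growth_parameters")
}

# expand residual parameters to a K x T matrix whatever the structure
expand_theta <- function(spec, theta) {
  K <- spec$n_classes; T_ <- length(spec$times)
  out <- switch(spec$residuals,
    FIXED = {
      stopifnot(length(theta) == 1L)
      matrix(theta, K, T_)
    },
    FREE_OVER_TIME = {
      stopifnot(length(theta) == T_)
      matrix(theta, K, T_, byrow = TRUE)
    },
    FREE_OVER_CLASSES = {
      stopifnot(length(theta) == K)
      matrix(theta, K, T_)
    },
    FREE_BOTH = {
      theta <- as.matrix(theta)
      stopifnot(nrow(theta) == K, ncol(theta) == T_)
      theta
    })
  out
}

# psi for class k as an r x r matrix (0 x 0 when no random effects)
psi_for_class <- function(params, k) {
  spec <- params$spec
  if (n_random_effects(spec) == 0L) return(matrix(0, 0, 0))
  if (spec$family == "GMM_CLASS_VARIANT") as.matrix(params$psi[[k]])
  else as.matrix(params$psi)
}

#' Evaluate a class mean trajectory
#'
#' Computes the polynomial mean curve `sum_j beta[j+1] * t^j` of one latent
#' class at the requested times, in outcome units.
#'
#' @param params A [growth_parameters()] object, or a bare numeric
#'   coefficient vector `(beta_0, beta_1, ...)`.
#' @param class_index Class whose curve to evaluate (ignored for bare
#'   coefficient vectors).
#' @param times Numeric vector of times (months).
#' @return Numeric vector of outcome values, one per time.
#' @examples
#' class_mean_trajectory(c(1, 2, 3), times = 2)  # 1 + 2*2 + 3*4 = 17
#' @export
class_mean_trajectory <- function(params, class_index = 1L, times) {
  beta <- if (inherits(params, "growth_parameters")) {
    K <- params$spec$n_classes
    if (class_index < 1L || class_index > K) {
      abort(sprintf("`class_index` must be in 1..%d.", K))
    }
    params$beta[[class_index]]
  } else {
    as.numeric(params)
  }
  drop(design_matrix(times, length(beta) - 1L) %*% beta)
}

#' @export
print.growth_parameters <- function(x, ...) {
  cat("<growth_parameters> K =", x$spec$n_classes, "\n")
  cat("  pi:", paste(sprintf("%.3f", x$pi), collapse = ", "), "\n")
  for (k in seq_along(x$beta)) {
    cat(sprintf("  beta[%d]: %s\n", k,
                paste(signif(x$beta[[k]], 4), collapse = ", ")))
  }
  invisible(x)
}

# jointly permute class labels of a parameter set
permute_classes <- function(params, perm) {
  spec <- params$spec
  K <- spec$n_classes
  stopifnot(sort(perm) == seq_len(K))
  spec2 <- spec
  spec2$poly_order <- spec$poly_order[perm]
  theta_m <- expand_theta(spec, params$theta)[perm, , drop = FALSE]
  theta2 <- switch(spec$residuals,
    FIXED = theta_m[1, 1],
    FREE_OVER_TIME = theta_m[1, ],
    FREE_OVER_CLASSES = theta_m[, 1],
    FREE_BOTH = theta_m)
  psi2 <- if (spec$family == "GMM_CLASS_VARIANT") params$psi[perm] else params$psi
  growth_parameters(spec2, params$pi[perm], params$beta[perm], psi2, theta2)
}
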