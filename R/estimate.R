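# Maximum-likelihood estimation of latent growth mixtures.
#
# The workhorse is an ECM algorithm on the marginal (random effects
# integrated out) likelihood: the E step computes posterior class
# probabilities and the conditional moments of the random effects, the CM
# steps update growth coefficients by weighted generalized least squares
# and the covariance/residual parameters in closed form.  Subjects sharing
# an observation pattern share design and covariance matrices, so all
# per-pattern work is done once per class and iteration.  Time is rescaled
# internally (months / 12) for numerical conditioning of cubic designs;
# reported coefficients are always back-transformed to month units.

TIME_SCALE <- 12

#' Random multi-start protocol for mixture estimation
#'
#' Mirrors the two-stage random-start strategy used by mainstream mixture
#' software: `n_starts` short exploratory EM runs, of which the best
#' `n_final_stage` are run to convergence. [fit_lgm_replicated()] doubles
#' `n_starts` until the best log likelihood replicates within and between
#' two independent runs.
#'
#' @param n_starts Number of random starts (the reference protocol uses
#'   500; smaller values are adequate for well-separated desk-scale
#'   problems).
#' @param n_final_stage Starts carried to full convergence (default
#'   `n_starts / 4`).
#' @param max_doublings Maximum number of times [fit_lgm_replicated()] may
#'   double `n_starts` while seeking replication.
#' @param replication_tolerance Log-likelihood agreement required to call
#'   the maximum replicated.
#' @param stage1_iters EM iterations in the exploratory stage.
#' @param max_iter,tol Full-convergence EM iteration cap and relative
#'   log-likelihood tolerance.
#' @param polish Run a quasi-Newton polish of the full likelihood after EM.
#' @param polish_maxit Iteration cap for the polish.
#' @return A `start_protocol` list.
#' @export
start_protocol <- function(n_starts = 500L,
                           n_final_stage = max(1L, n_starts %/% 4L),
                           max_doublings = 3L,
                           replication_tolerance = 1e-4,
                           stage1_iters = 30L,
                           max_iter = 2000L,
                           tol = 1e-8,
                           polish = TRUE,
                           polish_maxit = 25L) {
  stopifnot(n_starts >= 1L, n_final_stage >= 1L, n_final_stage <= n_starts,
            replication_tolerance > 0)
  structure(list(n_starts = as.integer(n_starts),
                 n_final_stage = as.integer(n_final_stage),
                 max_doublings = as.integer(max_doublings),
                 replication_tolerance = replication_tolerance,
                 stage1_iters = as.integer(stage1_iters),
                 max_iter = as.integer(max_iter),
                 tol = tol,
                 polish = polish,
                 polish_maxit = as.integer(polish_maxit)),
            class = "start_protocol")
}

# compact protocol for desk-scale fits (used throughout the pipeline):
# fewer random starts and slightly looser EM convergence than the full
# reference protocol; the final selected model can always be refit with
# start_protocol() defaults
default_protocol <- function(n_starts = 8L, ...) {
  args <- list(...)
  defaults <- list(n_final_stage = max(1L, n_starts %/% 4L),
                   stage1_iters = 25L, max_iter = 600L, tol = 1e-7,
                   polish = FALSE)
  do.call(start_protocol,
          c(list(n_starts = n_starts), modifyList(defaults, args)))
}

scale_spec <- function(spec) {
  spec$times <- spec$times / TIME_SCALE
  spec
}

# month-unit -> scaled-unit parameters (and inverse)
rescale_params <- function(params, spec_target, to_scaled = TRUE) {
  f <- if (to_scaled) TIME_SCALE else 1 / TIME_SCALE
  K <- spec_target$n_classes
  beta <- lapply(seq_len(K), function(k) {
    b <- params$beta[[k]]
    b * f^(seq_along(b) - 1L)
  })
  r <- n_random_effects(spec_target)
  psi <- params$psi
  if (r > 0L) {
    d <- c(intercept = 1, linear_slope = f)[spec_target$random_effects]
    D <- diag(d, r)
    if (spec_target$family == "GMM_CLASS_VARIANT") {
      psi <- lapply(psi, function(m) D %*% as.matrix(m) %*% D)
    } else {
      psi <- D %*% as.matrix(psi) %*% D
    }
  }
  growth_parameters(spec_target, params$pi, beta, psi, params$theta)
}

# ---- internal EM ----------------------------------------------------------

# internal parameter state: pi (K), beta (list), psi (list of K r x r),
# theta (K x T matrix); all in scaled time units.
em_state_to_params <- function(spec, st) {
  psi <- NULL
  if (n_random_effects(spec) > 0L) {
    psi <- if (spec$family == "GMM_CLASS_VARIANT") st$psi else st$psi[[1L]]
  }
  theta <- switch(spec$residuals,
    FIXED = st$theta[1L, 1L],
    FREE_OVER_TIME = st$theta[1L, ],
    FREE_OVER_CLASSES = st$theta[, 1L],
    FREE_BOTH = st$theta)
  growth_parameters(spec, st$pi, st$beta, psi, theta)
}

# one full log-density + sufficient-stat precompute for the current state
em_logf <- function(spec, wide, st) {
  params <- em_state_to_params(spec, st)
  class_logdensities(spec, params, wide)
}

em_fit <- function(spec, wide, st, max_iter, tol, var_floor) {
  K <- spec$n_classes
  T_ <- length(wide$times)
  N <- nrow(wide$Y)
  r <- n_random_effects(spec)
  times <- wide$times
  X_by_class <- lapply(seq_len(K), function(k) design_matrix(times, spec$poly_order[k]))
  Z <- if (r > 0L) re_design(times, spec$random_effects) else NULL
  obs <- wide$obs * 1
  Y0 <- wide$Y; Y0[!wide$obs] <- 0
  if (r == 0L) {
    # diagonal-covariance families run in the compiled kernel
    res_code <- match(spec$residuals,
                      c("FIXED", "FREE_OVER_TIME", "FREE_OVER_CLASSES",
                        "FREE_BOTH")) - 1L
    out <- em_gbtm_cpp(Y0, obs, X_by_class, st$pi, st$beta, st$theta,
                       res_code, max_iter, tol, var_floor)
    st$pi <- drop(out$pi)
    st$beta <- lapply(out$beta, drop)
    st$theta <- out$theta
    return(list(state = st, loglik = out$loglik, trace = drop(out$trace),
                n_iter = out$n_iter, converged = out$converged,
                posteriors = out$posteriors,
                floor_active = out$floor_active))
  }
  n_obs_i <- rowSums(obs)
  psi_floor <- 1e-8 * var(wide$Y[wide$obs])
  ll_old <- -Inf
  trace <- numeric(0)
  floor_active <- FALSE
  converged <- FALSE
  P <- NULL
  for (iter in seq_len(max_iter)) {
    # ---- E step: per-class log densities via the Woodbury identity,
    # vectorized over subjects (random-effect dimension is at most 2) ----
    logf <- matrix(NA_real_, N, K)
    estash <- vector("list", K)
    for (k in seq_len(K)) {
      thk <- st$theta[k, ]
      mu <- drop(X_by_class[[k]] %*% st$beta[[k]])
      Rk <- (Y0 - rep(mu, each = N)) * obs
      Rw <- Rk * rep(1 / thk, each = N)
      q1 <- rowSums(Rk * Rw)
      logdetD <- drop(obs %*% log(thk))
      if (r == 0L) {
        logf[, k] <- -0.5 * (n_obs_i * log(2 * pi) + logdetD + q1)
        estash[[k]] <- list(Rk = Rk)
        next
      }
      psi_k <- st$psi[[k]]
      # guard against a collapsing random-effect covariance
      if (min(eigen(psi_k, symmetric = TRUE, only.values = TRUE)$values) <
          psi_floor) {
        psi_k <- make_psd(psi_k, psi_floor)
        st$psi[[k]] <- psi_k
        floor_active <- TRUE
      }
      psi_inv <- solve(psi_k)
      logdet_psi <- determinant(psi_k, logarithm = TRUE)$modulus
      G <- Rw %*% Z                                   # N x r
      # C_i = psi^-1 + Z_i' D_i^-1 Z_i, entries vectorized per subject
      ZtDZ <- lapply(seq_len(r), function(a) lapply(seq_len(r), function(b) {
        drop(obs %*% (Z[, a] * Z[, b] / thk))
      }))
      if (r == 1L) {
        C11 <- psi_inv[1, 1] + ZtDZ[[1]][[1]]
        if (any(C11 <= 0)) {
          bad <- which(C11 <= 0)[1L]
          abort(sprintf(
            "Singular within-class covariance for class %d (subject %s).",
            k, as.character(wide$subject_ids[bad])))
        }
        a_i <- 1 / C11
        logdetC <- log(C11)
        M <- matrix(G[, 1] * a_i, N, 1L)
        q2 <- G[, 1]^2 * a_i
        Vt <- list(a = a_i)
      } else {
        C11 <- psi_inv[1, 1] + ZtDZ[[1]][[1]]
        C12 <- psi_inv[1, 2] + ZtDZ[[1]][[2]]
        C22 <- psi_inv[2, 2] + ZtDZ[[2]][[2]]
        detC <- C11 * C22 - C12^2
        if (any(detC <= 0 | C11 <= 0)) {
          bad <- which(detC <= 0 | C11 <= 0)[1L]
          abort(sprintf(
            "Singular within-class covariance for class %d (subject %s).",
            k, as.character(wide$subject_ids[bad])))
        }
        a_i <- C22 / detC; b_i <- -C12 / detC; c_i <- C11 / detC
        logdetC <- log(detC)
        M <- cbind(G[, 1] * a_i + G[, 2] * b_i,
                   G[, 1] * b_i + G[, 2] * c_i)
        q2 <- G[, 1] * M[, 1] + G[, 2] * M[, 2]
        Vt <- list(a = a_i, b = b_i, c = c_i)
      }
      logf[, k] <- -0.5 * (n_obs_i * log(2 * pi) + logdetD +
                             logdet_psi + logdetC + q1 - q2)
      estash[[k]] <- list(Rk = Rk, M = M, Vt = Vt)
    }
    lp <- logf + rep(log(pmax(st$pi, 1e-300)), each = N)
    lse <- logsumexp_rows(lp)
    ll <- sum(lse)
    trace <- c(trace, ll)
    P <- exp(lp - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # ---- CM steps ---------------------------------------------------------
    st$pi <- pmax(colMeans(P), 1e-12)
    st$pi <- st$pi / sum(st$pi)
    num <- matrix(0, K, T_)
    den <- matrix(0, K, T_)
    psi_acc <- vector("list", K)
    psi_w <- numeric(K)
    for (k in seq_len(K)) {
      Xk <- X_by_class[[k]]
      thk <- st$theta[k, ]
      w <- P[, k]
      es <- estash[[k]]
      if (r == 0L) {
        a_t <- colSums(w * obs) / thk
        XtWX <- crossprod(Xk, Xk * a_t)
        XtWy <- crossprod(Xk, colSums(w * Y0) / thk)
        beta_new <- tryCatch(drop(solve(XtWX, XtWy)),
                             error = function(e) st$beta[[k]])
        st$beta[[k]] <- beta_new
        mu <- drop(Xk %*% beta_new)
        E2 <- (Y0 - rep(mu, each = N))^2 * obs
        num[k, ] <- colSums(w * E2)
        den[k, ] <- colSums(w * obs)
        next
      }
      ZM <- es$M %*% t(Z)                             # N x T, E[Zb | y]
      Yadj <- (Y0 - ZM * obs)
      a_t <- colSums(w * obs) / thk
      XtWX <- crossprod(Xk, Xk * a_t)
      XtWy <- crossprod(Xk, colSums(w * Yadj) / thk)
      beta_new <- tryCatch(drop(solve(XtWX, XtWy)),
                           error = function(e) st$beta[[k]])
      st$beta[[k]] <- beta_new
      # psi sufficient statistics: sum_i w_i (m_i m_i' + V_i)
      Vt <- es$Vt
      if (r == 1L) {
        S_psi <- matrix(sum(w * (es$M[, 1]^2 + Vt$a)), 1L, 1L)
      } else {
        s11 <- sum(w * (es$M[, 1]^2 + Vt$a))
        s12 <- sum(w * (es$M[, 1] * es$M[, 2] + Vt$b))
        s22 <- sum(w * (es$M[, 2]^2 + Vt$c))
        S_psi <- matrix(c(s11, s12, s12, s22), 2L)
      }
      psi_acc[[k]] <- S_psi
      psi_w[k] <- sum(w)
      mu_new <- drop(Xk %*% beta_new)
      Ehat <- (Y0 - rep(mu_new, each = N) - ZM) * obs
      # diag(Z V Z') per subject and visit
      if (r == 1L) {
        zvz <- outer(Vt$a, Z[, 1]^2)
      } else {
        zvz <- outer(Vt$a, Z[, 1]^2) + 2 * outer(Vt$b, Z[, 1] * Z[, 2]) +
          outer(Vt$c, Z[, 2]^2)
      }
      num[k, ] <- colSums(w * (Ehat^2 + zvz * obs))
      den[k, ] <- colSums(w * obs)
    }
    if (r > 0L) {
      if (spec$family == "GMM_CLASS_VARIANT") {
        for (k in seq_len(K)) {
          m <- psi_acc[[k]] / max(psi_w[k], 1e-12)
          st$psi[[k]] <- make_psd(0.5 * (m + t(m)), psi_floor)
        }
      } else {
        m <- Reduce(`+`, psi_acc) / max(sum(psi_w), 1e-12)
        m <- make_psd(0.5 * (m + t(m)), psi_floor)
        st$psi <- rep(list(m), K)
      }
    }
    theta_new <- switch(spec$residuals,
      FIXED = matrix(sum(num) / max(sum(den), 1e-12), K, T_),
      FREE_OVER_TIME = matrix(colSums(num) / pmax(colSums(den), 1e-12),
                              K, T_, byrow = TRUE),
      FREE_OVER_CLASSES = matrix(rowSums(num) / pmax(rowSums(den), 1e-12), K, T_),
      FREE_BOTH = num / pmax(den, 1e-12))
    bad <- !is.finite(theta_new) | theta_new < var_floor
    if (any(bad)) floor_active <- TRUE
    theta_new[bad] <- pmax(st$theta[bad], var_floor)
    st$theta <- theta_new
  }
  list(state = st, loglik = trace[length(trace)], trace = trace,
       n_iter = length(trace), converged = converged,
       posteriors = P, floor_active = floor_active)
}

make_psd <- function(m, floor = 0) {
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, floor)
  e$vectors %*% (v * t(e$vectors))
}

# month-unit growth_parameters -> scaled internal EM state
params_to_state <- function(spec, params) {
  K <- spec$n_classes
  r <- n_random_effects(spec)
  beta <- lapply(params$beta, function(b) b * TIME_SCALE^(seq_along(b) - 1L))
  psi <- NULL
  if (r > 0L) {
    d <- c(intercept = 1, linear_slope = TIME_SCALE)[spec$random_effects]
    D <- diag(d, r)
    lst <- if (spec$family == "GMM_CLASS_VARIANT") params$psi else
      rep(list(params$psi), K)
    psi <- lapply(lst, function(m) D %*% as.matrix(m) %*% D)
  }
  list(pi = params$pi, beta = beta, psi = psi,
       theta = expand_theta(spec, params$theta))
}

# ---- initialization -------------------------------------------------------

# per-subject OLS growth coefficients on scaled time, padded to max order
subject_ols_coefs <- function(wide, max_order) {
  cache <- attr(wide, "ols_cache")
  if (!is.null(cache) && ncol(cache) >= max_order + 1L) {
    return(cache[, seq_len(max_order + 1L), drop = FALSE])
  }
  N <- nrow(wide$Y)
  B <- matrix(0, N, max_order + 1L)
  for (i in seq_len(N)) {
    idx <- which(wide$obs[i, ])
    y <- wide$Y[i, idx]
    q <- min(max_order, length(idx) - 1L)
    if (q < 1L) {
      B[i, 1L] <- mean(y)
    } else {
      X <- design_matrix(wide$times[idx], q)
      cf <- tryCatch(qr.solve(X, y), error = function(e) c(mean(y), rep(0, q)))
      B[i, seq_len(q + 1L)] <- cf
    }
  }
  B
}

# initial EM state from soft responsibilities
state_from_resp <- function(spec, wide, resp, var_floor) {
  K <- spec$n_classes
  T_ <- length(wide$times)
  r <- n_random_effects(spec)
  N <- nrow(wide$Y)
  Y0 <- wide$Y; Y0[!wide$obs] <- 0
  obs_num <- wide$obs * 1
  beta <- vector("list", K)
  vy <- var(wide$Y[wide$obs])
  for (k in seq_len(K)) {
    Xk <- design_matrix(wide$times, spec$poly_order[k])
    w <- resp[, k]
    a_t <- colSums(w * obs_num)
    XtWX <- crossprod(Xk, Xk * a_t) + diag(1e-8, ncol(Xk))
    XtWy <- crossprod(Xk, colSums(w * Y0))
    beta[[k]] <- drop(solve(XtWX, XtWy))
  }
  theta0 <- max(vy * 0.5, var_floor * 2)
  psi <- NULL
  if (r > 0L) {
    B <- subject_ols_coefs(wide, 1L)
    cols <- c(intercept = 1L, linear_slope = 2L)[spec$random_effects]
    cv <- cov(B[, cols, drop = FALSE]) * 0.3
    cv <- make_psd(cv, floor = 1e-4 * vy) + diag(1e-4 * vy, r)
    psi <- rep(list(cv), K)
  }
  list(pi = pmax(colMeans(resp), 1e-6) / sum(pmax(colMeans(resp), 1e-6)),
       beta = beta,
       psi = psi,
       theta = matrix(theta0, K, T_))
}

# responsibilities for one random start: perturbed k-means partition of
# subject-level OLS growth coefficients
start_responsibilities <- function(wide, K, base_labels, perturb) {
  N <- nrow(wide$Y)
  labels <- base_labels
  if (perturb > 0) {
    flip <- runif(N) < perturb
    labels[flip] <- sample.int(K, sum(flip), replace = TRUE)
  }
  resp <- matrix(0.1 / max(K - 1, 1), N, K)
  resp[cbind(seq_len(N), labels)] <- 0.9
  if (K == 1L) resp[] <- 1
  resp
}

kmeans_labels <- function(wide, K, max_order, cheap = FALSE) {
  if (K == 1L) return(rep(1L, nrow(wide$Y)))
  B <- subject_ols_coefs(wide, max_order)
  if (cheap) {
    # quantile split on the OLS intercept: adequate seed partition for
    # warm-started refits
    br <- quantile(B[, 1L], probs = seq(0, 1, length.out = K + 1L))
    br[1L] <- -Inf; br[K + 1L] <- Inf
    lab <- cut(B[, 1L], unique(br), labels = FALSE, include.lowest = TRUE)
    lab[is.na(lab)] <- 1L
    return(as.integer(lab))
  }
  B <- scale(B)
  B[!is.finite(B)] <- 0
  km <- tryCatch(kmeans(B, centers = K, nstart = 3L, iter.max = 30L),
                 error = function(e) NULL)
  if (is.null(km)) sample.int(K, nrow(wide$Y), replace = TRUE) else km$cluster
}

# ---- parameter packing (scaled units) ------------------------------------

pack_params <- function(spec, st) {
  K <- spec$n_classes
  r <- n_random_effects(spec)
  par <- log(st$pi[-K] / st$pi[K])
  nm <- if (K > 1L) paste0("alpha", seq_len(K - 1L)) else character()
  for (k in seq_len(K)) {
    par <- c(par, st$beta[[k]])
    nm <- c(nm, paste0("beta", k, ".", seq_along(st$beta[[k]]) - 1L))
  }
  if (r > 0L) {
    n_psi <- if (spec$family == "GMM_CLASS_VARIANT") K else 1L
    for (j in seq_len(n_psi)) {
      m <- st$psi[[j]] + diag(1e-10, r)
      L <- t(chol(make_psd(m, 1e-12) + diag(1e-12, r)))
      v <- c()
      for (a in seq_len(r)) for (b in seq_len(a)) {
        v <- c(v, if (a == b) log(L[a, a]) else L[a, b])
      }
      par <- c(par, v)
      nm <- c(nm, paste0("psi", j, ".", seq_along(v)))
    }
  }
  th <- switch(spec$residuals,
    FIXED = st$theta[1L, 1L],
    FREE_OVER_TIME = st$theta[1L, ],
    FREE_OVER_CLASSES = st$theta[, 1L],
    FREE_BOTH = as.vector(t(st$theta)))
  par <- c(par, log(th))
  nm <- c(nm, paste0("log_theta", seq_along(th)))
  names(par) <- nm
  par
}

unpack_params <- function(spec, par) {
  K <- spec$n_classes
  T_ <- length(spec$times)
  r <- n_random_effects(spec)
  pos <- 0L
  take <- function(n) {
    out <- par[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  if (K > 1L) {
    a <- take(K - 1L)
    ex <- exp(c(a, 0))
    pi <- ex / sum(ex)
  } else pi <- 1
  beta <- vector("list", K)
  for (k in seq_len(K)) beta[[k]] <- unname(take(spec$poly_order[k] + 1L))
  psi <- NULL
  if (r > 0L) {
    n_psi <- if (spec$family == "GMM_CLASS_VARIANT") K else 1L
    psi_list <- vector("list", n_psi)
    for (j in seq_len(n_psi)) {
      v <- take(r * (r + 1L) / 2L)
      L <- matrix(0, r, r)
      ix <- 1L
      for (a in seq_len(r)) for (b in seq_len(a)) {
        L[a, b] <- if (a == b) exp(v[ix]) else v[ix]
        ix <- ix + 1L
      }
      psi_list[[j]] <- L %*% t(L)
    }
    psi <- if (spec$family == "GMM_CLASS_VARIANT") {
      rep(psi_list, length.out = K)
    } else rep(psi_list[1L], K)
  }
  n_th <- switch(spec$residuals, FIXED = 1L, FREE_OVER_TIME = T_,
                 FREE_OVER_CLASSES = K, FREE_BOTH = K * T_)
  th <- exp(take(n_th))
  theta <- switch(spec$residuals,
    FIXED = matrix(th, K, T_),
    FREE_OVER_TIME = matrix(th, K, T_, byrow = TRUE),
    FREE_OVER_CLASSES = matrix(th, K, T_),
    FREE_BOTH = matrix(th, K, T_, byrow = TRUE))
  list(pi = unname(pi), beta = beta, psi = psi, theta = theta)
}

# fast marginal log likelihood for an internal state: same Woodbury
# algebra as the EM E step (random-effect dimension at most 2), with no
# data-frame or validation layers — used by the quasi-Newton polish and
# the observed-information Hessian, which evaluate it thousands of times
fast_state_loglik <- function(spec, wide, st) {
  K <- spec$n_classes
  T_ <- length(wide$times)
  N <- nrow(wide$Y)
  r <- n_random_effects(spec)
  X_by_class <- lapply(seq_len(K), function(k)
    design_matrix(wide$times, spec$poly_order[k]))
  Z <- if (r > 0L) re_design(wide$times, spec$random_effects) else NULL
  obs <- wide$obs * 1
  Y0 <- wide$Y; Y0[!wide$obs] <- 0
  n_obs_i <- rowSums(obs)
  logf <- matrix(NA_real_, N, K)
  for (k in seq_len(K)) {
    thk <- st$theta[k, ]
    if (any(thk <= 0)) return(-Inf)
    mu <- drop(X_by_class[[k]] %*% st$beta[[k]])
    Rk <- (Y0 - rep(mu, each = N)) * obs
    Rw <- Rk * rep(1 / thk, each = N)
    q1 <- rowSums(Rk * Rw)
    logdetD <- drop(obs %*% log(thk))
    if (r == 0L) {
      logf[, k] <- -0.5 * (n_obs_i * log(2 * pi) + logdetD + q1)
      next
    }
    psi_k <- st$psi[[k]]
    psi_inv <- tryCatch(solve(psi_k), error = function(e) NULL)
    if (is.null(psi_inv)) return(-Inf)
    logdet_psi <- determinant(psi_k, logarithm = TRUE)$modulus
    G <- Rw %*% Z
    if (r == 1L) {
      C11 <- psi_inv[1, 1] + drop(obs %*% (Z[, 1]^2 / thk))
      if (any(C11 <= 0)) return(-Inf)
      q2 <- G[, 1]^2 / C11
      logdetC <- log(C11)
    } else {
      C11 <- psi_inv[1, 1] + drop(obs %*% (Z[, 1]^2 / thk))
      C12 <- psi_inv[1, 2] + drop(obs %*% (Z[, 1] * Z[, 2] / thk))
      C22 <- psi_inv[2, 2] + drop(obs %*% (Z[, 2]^2 / thk))
      detC <- C11 * C22 - C12^2
      if (any(detC <= 0 | C11 <= 0)) return(-Inf)
      q2 <- (C22 * G[, 1]^2 - 2 * C12 * G[, 1] * G[, 2] +
               C11 * G[, 2]^2) / detC
      logdetC <- log(detC)
    }
    logf[, k] <- -0.5 * (n_obs_i * log(2 * pi) + logdetD + logdet_psi +
                           logdetC + q1 - q2)
  }
  sum(logsumexp_rows(logf + rep(log(pmax(st$pi, 1e-300)), each = N)))
}

negloglik_packed <- function(par, spec, wide) {
  st <- tryCatch(unpack_params(spec, par), error = function(e) NULL)
  if (is.null(st)) return(1e10)
  ll <- tryCatch(fast_state_loglik(spec, wide, st), error = function(e) -Inf)
  if (!is.finite(ll)) return(1e10)
  -ll
}

# ---- user-facing fitting --------------------------------------------------

#' Fit a latent growth mixture model by replicated multistart EM
#'
#' Maximizes the FIML mixture likelihood with the two-stage random
#' multistart protocol of [start_protocol()]: initial responsibilities come
#' from per-start random perturbations of a k-means partition of
#' subject-level OLS growth coefficients; each start is advanced by a
#' monotone ECM algorithm and the survivors are run to convergence, with an
#' optional quasi-Newton polish of the best solution. All randomness flows
#' from `seed`, so the fit is exactly reproducible.
#'
#' @param data An [lgm_data()] table (or coercible data frame).
#' @param spec The [lgm_spec()] to fit.
#' @param protocol A [start_protocol()].
#' @param seed Integer seed controlling starts.
#' @param init Optional list of extra initial states (internal use, e.g.
#'   bootstrap refits warm-started at generating values).
#' @return An object of class `lgm_fit`: the spec, estimated
#'   [growth_parameters()] in month units, log likelihood, posterior
#'   classification matrix, modal assignment, fit indices (BIC, scaled
#'   entropy, per-class APPA, class counts) and a convergence report.
#' @seealso [fit_lgm_replicated()], [select_trajectory_model()]
#' @export
fit_lgm <- function(data, spec, protocol = default_protocol(), seed = 1L,
                    init = NULL) {
  data <- if (inherits(data, "lgm_data")) data else lgm_data(data, times = spec$times)
  wide <- as_lgm_wide(data, times = spec$times)
  fit_lgm_wide(wide, spec, protocol, seed, init)
}

# matrix-level fitting path (no data-frame layers); used directly by the
# bootstrap LRT where thousands of small refits are made
fit_lgm_wide <- function(wide, spec, protocol = default_protocol(), seed = 1L,
                         init = NULL) {
  spec_s <- scale_spec(spec)
  wide_s <- wide
  wide_s$times <- wide$times / TIME_SCALE
  K <- spec$n_classes
  var_floor <- 1e-6 * var(wide$Y[wide$obs])
  attr(wide_s, "ols_cache") <-
    subject_ols_coefs(wide_s, max(2L, max(spec$poly_order)))
  withr::with_seed(as.integer(seed), {
    base_labels <- kmeans_labels(wide_s, K, max(spec$poly_order),
                                 cheap = protocol$n_starts <= 1L)
    n_starts <- if (K == 1L) min(protocol$n_starts, 2L) else protocol$n_starts
    stage1 <- vector("list", n_starts + length(init %||% list()))
    for (s in seq_len(n_starts)) {
      perturb <- if (s == 1L) 0 else min(0.5, 0.1 + 0.4 * (s - 1) / n_starts)
      resp <- start_responsibilities(wide_s, K, base_labels, perturb)
      st0 <- state_from_resp(spec_s, wide_s, resp, var_floor)
      stage1[[s]] <- tryCatch(
        em_fit(spec_s, wide_s, st0, protocol$stage1_iters, protocol$tol, var_floor),
        error = function(e) NULL)
    }
    if (length(init)) {
      for (j in seq_along(init)) {
        stage1[[n_starts + j]] <- tryCatch(
          em_fit(spec_s, wide_s, init[[j]], protocol$stage1_iters,
                 protocol$tol, var_floor),
          error = function(e) NULL)
      }
    }
    ok <- !vapply(stage1, is.null, logical(1))
    if (!any(ok)) abort("No start converged; all EM runs failed.")
    stage1 <- stage1[ok]
    lls <- vapply(stage1, `[[`, numeric(1), "loglik")
    keep <- order(lls, decreasing = TRUE)[seq_len(min(protocol$n_final_stage,
                                                      length(stage1)))]
    finals <- lapply(stage1[keep], function(run) {
      tryCatch(
        em_fit(spec_s, wide_s, run$state, protocol$max_iter, protocol$tol,
               var_floor),
        error = function(e) NULL)
    })
    finals <- finals[!vapply(finals, is.null, logical(1))]
    if (!length(finals)) abort("No start converged in the final stage.")
    lls_f <- vapply(finals, `[[`, numeric(1), "loglik")
    best <- finals[[which.max(lls_f)]]
    n_repl <- sum(lls_f >= max(lls_f) - protocol$replication_tolerance)
    # quasi-Newton polish of the full likelihood
    if (isTRUE(protocol$polish)) {
      par0 <- pack_params(spec_s, best$state)
      opt <- tryCatch(
        optim(par0, negloglik_packed, spec = spec_s, wide = wide_s,
              method = "BFGS",
              control = list(maxit = protocol$polish_maxit, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value) && -opt$value > best$loglik) {
        st <- unpack_params(spec_s, opt$par)
        pol <- em_fit(spec_s, wide_s, st, 2L, protocol$tol, var_floor)
        if (pol$loglik >= best$loglik) best <- pol
      }
    }
    build_lgm_fit(spec, spec_s, wide, best,
                  n_starts = n_starts, n_repl = n_repl, seed = seed,
                  protocol = protocol)
  })
}

build_lgm_fit <- function(spec, spec_s, wide, best, n_starts, n_repl, seed,
                          protocol, replicated_between = NA,
                          n_doublings = NA_integer_) {
  params_s <- em_state_to_params(spec_s, best$state)
  # back-transform from scaled time to month units: beta_j / TIME_SCALE^j,
  # psi conjugated by diag(1, 1/TIME_SCALE)
  params <- growth_parameters(
    spec,
    params_s$pi,
    lapply(params_s$beta, function(b) b / TIME_SCALE^(seq_along(b) - 1L)),
    rescale_month_psi(spec, best$state$psi),
    params_s$theta)
  post <- best$posteriors
  rownames(post) <- as.character(wide$subject_ids)
  modal <- modal_assignment(post)
  counts <- tabulate(modal, nbins = spec$n_classes)
  fi <- list(
    bic = bic(best$loglik, count_parameters(spec), nrow(post)),
    scaled_entropy = if (spec$n_classes > 1L) scaled_entropy(post) else NA_real_,
    appa = appa(post, modal),
    class_counts = counts,
    class_proportions_modal = counts / nrow(post))
  degenerate <- which(params$pi < 1 / nrow(post))
  if (length(degenerate)) {
    warn(sprintf("Degenerate class proportions (< 1/N) for class(es) %s.",
                 paste(degenerate, collapse = ", ")))
  }
  structure(
    list(spec = spec, params = params, loglik = best$loglik,
         posteriors = post, modal = setNames(modal, rownames(post)),
         fit_indices = fi,
         convergence = list(n_starts = n_starts,
                            best_loglik_replications = n_repl,
                            replicated_between_runs = replicated_between,
                            n_doublings_used = n_doublings,
                            em_iterations = best$n_iter,
                            converged = best$converged,
                            variance_floor_active = best$floor_active,
                            degenerate_classes = degenerate),
         n_subjects = nrow(post),
         subject_ids = rownames(post),
         seed = seed, protocol = protocol,
         state_scaled = best$state),
    class = "lgm_fit")
}

rescale_month_psi <- function(spec, psi_scaled_list) {
  r <- n_random_effects(spec)
  if (r == 0L) return(NULL)
  d <- c(intercept = 1, linear_slope = 1 / TIME_SCALE)[spec$random_effects]
  D <- diag(d, r)
  out <- lapply(psi_scaled_list, function(m) D %*% m %*% D)
  if (spec$family == "GMM_CLASS_VARIANT") out else out[[1L]]
}

#' Fit with the between-run replication rule
#'
#' Runs [fit_lgm()] twice with independent seeds; if the best log
#' likelihoods do not agree within `protocol$replication_tolerance`, the
#' number of random starts is doubled and both runs repeated, up to
#' `protocol$max_doublings` times (mirroring the "rerun with twice the
#' number of random starts until the best log likelihood replicates within
#' and between two runs" rule). Returns the better solution with the
#' replication status recorded in its convergence report.
#'
#' @inheritParams fit_lgm
#' @return An `lgm_fit` whose `convergence` reports
#'   `replicated_between_runs` and `n_doublings_used`.
#' @export
fit_lgm_replicated <- function(data, spec, protocol = default_protocol(),
                               seed = 1L) {
  best_overall <- NULL
  for (d in 0:protocol$max_doublings) {
    proto_d <- protocol
    proto_d$n_starts <- as.integer(protocol$n_starts * 2^d)
    proto_d$n_final_stage <- max(1L, proto_d$n_starts %/% 4L)
    f1 <- fit_lgm(data, spec, proto_d, seed = seed + 1000L * (2L * d + 1L))
    f2 <- fit_lgm(data, spec, proto_d, seed = seed + 1000L * (2L * d + 2L))
    cand <- if (f1$loglik >= f2$loglik) f1 else f2
    if (is.null(best_overall) || cand$loglik > best_overall$loglik) {
      best_overall <- cand
    }
    if (abs(f1$loglik - f2$loglik) <= protocol$replication_tolerance) {
      best_overall$convergence$replicated_between_runs <- TRUE
      best_overall$convergence$n_doublings_used <- d
      return(best_overall)
    }
  }
  warn("Best log likelihood did not replicate between runs within the doubling budget.")
  best_overall$convergence$replicated_between_runs <- FALSE
  best_overall$convergence$n_doublings_used <- protocol$max_doublings
  best_overall
}
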