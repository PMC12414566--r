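# Manual 3-step association analysis.
#
# Step 1 is the unconditional trajectory model (selection pipeline).
# Step 2 extracts the misclassification structure of the modal assignment
# as logits.  Step 3 regresses class membership on one covariate at a time
# (or compares distal outcomes across classes) with the measurement part
# held fixed at those logits, so covariates cannot move the class solution:
# the class structure and reported class distribution are unchanged by
# construction.

#' Misclassification logits of a modal classification
#'
#' Computes `P(modal class s | true class k)` by the standard ML-3-step
#' construction — average posterior mass of class `k` among subjects
#' modally assigned to `s`, column-normalized — and returns its logit
#' parameterization against the last modal class. Zero probabilities are
#' represented by a large finite logit cap.
#'
#' @param posteriors N x K posterior matrix (or an `lgm_fit`, from which
#'   posteriors and assignment are taken).
#' @param modal Integer modal assignments (defaults to row-wise argmax).
#' @param cap Absolute cap on logits standing in for infinite values.
#' @return An object of class `misclassification_logits` with elements
#'   `D` (column-stochastic K x K matrix, rows = modal class, columns =
#'   true class), `logits`, `pi` (step-1 class proportions) and `cap`.
#' @export
misclassification_logits <- function(posteriors, modal = NULL, cap = 100) {
  if (inherits(posteriors, "lgm_fit")) {
    modal <- modal %||% unname(posteriors$modal)
    posteriors <- posteriors$posteriors
  }
  posteriors <- as.matrix(posteriors)
  K <- ncol(posteriors)
  if (is.null(modal)) modal <- modal_assignment(posteriors)
  empty <- setdiff(seq_len(K), unique(modal))
  if (length(empty)) {
    abort(sprintf("Modal class(es) %s are empty; logits undefined.",
                  paste(empty, collapse = ", ")))
  }
  # N_sk = sum_i p_ik over subjects modally assigned to s
  Nsk <- vapply(seq_len(K), function(s)
    colSums(posteriors[modal == s, , drop = FALSE]), numeric(K))
  Nsk <- t(Nsk)                       # rows s, cols k
  D <- sweep(Nsk, 2L, colSums(posteriors), `/`)
  logD <- log(pmax(D, exp(-cap)))
  # L[s, k] = log D[s, k] - log D[K, k]: logit vs the last modal class
  logits <- t(t(logD) - logD[K, ])
  logits <- pmin(pmax(logits, -cap), cap)
  structure(list(D = D, logits = logits,
                 pi = colMeans(posteriors), cap = cap),
            class = "misclassification_logits")
}

#' @export
print.misclassification_logits <- function(x, ...) {
  cat("<misclassification_logits> P(modal s | true k):\n")
  print(round(x$D, 3))
  invisible(x)
}

modal_tibble <- function(fit) {
  tibble(subject_id = names(fit$modal), modal = unname(fit$modal))
}

#' Predict class membership from one covariate (3-step, fixed logits)
#'
#' Fits a multinomial logistic regression of latent class on a single
#' covariate while the measurement relation between the latent class and
#' the modal assignment is fixed at the step-2 misclassification logits.
#' Because the measurement part and the step-1 class distribution are
#' held fixed, adding the covariate cannot change the class structure.
#' Effects are reported as odds ratios per class against the reference
#' class, with Wald confidence intervals.
#'
#' @param fit An `lgm_fit` (the unconditional model).
#' @param covariates Data frame with `subject_id` and the covariate column.
#' @param covariate Name of the covariate column.
#' @param reference_class Class index used as the multinomial reference
#'   (the paper contrasts "better" trajectories against the "worse" one).
#' @param logits A [misclassification_logits()]; defaults to the fit's own.
#' @param log_transform Log-transform the covariate first (for skewed
#'   predictors such as duration of untreated psychosis); values <= 0
#'   error.
#' @param conf_level Confidence level for Wald intervals.
#' @return A tibble with one row per non-reference class: odds ratio,
#'   Wald CI, p value, and a `separation` flag (unbounded CI under
#'   complete separation). Attributes `class_proportions` (unchanged
#'   step-1 proportions) and `loglik`.
#' @export
predict_membership <- function(fit, covariates, covariate,
                               reference_class = NULL,
                               logits = misclassification_logits(fit),
                               log_transform = FALSE,
                               conf_level = 0.95) {
  K <- ncol(logits$D)
  reference_class <- reference_class %||% K
  stopifnot(reference_class >= 1L, reference_class <= K)
  df <- dplyr::inner_join(modal_tibble(fit),
                          as_tibble(covariates), by = "subject_id")
  x <- df[[covariate]]
  keep <- !is.na(x)
  df <- df[keep, ]; x <- as.numeric(x[keep])
  if (log_transform) {
    if (any(x <= 0)) abort("Log transform requires strictly positive values.")
    x <- log(x)
  }
  D <- logits$D
  free <- setdiff(seq_len(K), reference_class)
  nll <- function(par) {
    g0 <- numeric(K); g1 <- numeric(K)
    g0[free] <- par[seq_along(free)]
    g1[free] <- par[length(free) + seq_along(free)]
    eta <- outer(x, g1) + matrix(g0, length(x), K, byrow = TRUE)
    eta <- eta - apply(eta, 1L, max)
    pk <- exp(eta) / rowSums(exp(eta))
    # P(s_i | x_i) = sum_k D[s_i, k] * pk[i, k]
    lik <- rowSums(pk * D[df$modal, , drop = FALSE])
    -sum(log(pmax(lik, 1e-300)))
  }
  par0 <- rep(0, 2 * length(free))
  opt <- optim(par0, nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))
  V <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  se <- if (is.null(V)) rep(NA_real_, length(par0)) else sqrt(pmax(diag(V), 0))
  slope_idx <- length(free) + seq_along(free)
  est <- opt$par[slope_idx]
  se_s <- se[slope_idx]
  zq <- qnorm(1 - (1 - conf_level) / 2)
  separation <- abs(est) > 15 | !is.finite(se_s) | is.na(se_s)
  out <- tibble(
    covariate = covariate,
    class = free,
    reference_class = reference_class,
    effect_scale = "odds_ratio",
    log_or = est,
    estimate = exp(est),
    conf_low = ifelse(separation, 0, exp(est - zq * se_s)),
    conf_high = ifelse(separation, Inf, exp(est + zq * se_s)),
    p_value = ifelse(separation, NA_real_, 2 * pnorm(-abs(est / se_s))),
    separation = separation,
    transform = if (log_transform) "log" else "identity",
    n = nrow(df))
  attr(out, "class_proportions") <- logits$pi
  attr(out, "intercepts") <- setNames(opt$par[seq_along(free)],
                                      paste0("class", free))
  attr(out, "loglik") <- -opt$value
  out
}

#' Compare a distal outcome across latent trajectories (3-step)
#'
#' Estimates class-specific means (continuous outcomes) or response
#' probabilities/thresholds (binary outcomes) with the class structure
#' fixed via the misclassification logits and the step-1 class
#' proportions, then tests all pairwise equalities with Wald chi-square
#' tests. The standardized mean difference is the difference in estimated
#' class means divided by the sample standard deviation of the outcome.
#'
#' @param fit An `lgm_fit`.
#' @param outcomes Data frame with `subject_id` and the outcome column.
#' @param outcome Name of the outcome column.
#' @param kind `"continuous"` or `"binary"`.
#' @param logits A [misclassification_logits()].
#' @return A tibble of pairwise contrasts with Wald statistic, p value and
#'   effect size (SMD, or OR with an `unbounded` flag when a class
#'   probability is estimated at the boundary — the "infinite OR" case).
#'   Attribute `class_estimates` holds the per-class means/probabilities.
#' @export
distal_outcome_test <- function(fit, outcomes, outcome,
                                kind = c("continuous", "binary"),
                                logits = misclassification_logits(fit)) {
  kind <- match.arg(kind)
  K <- ncol(logits$D)
  df <- dplyr::inner_join(modal_tibble(fit), as_tibble(outcomes),
                          by = "subject_id")
  y <- as.numeric(df[[outcome]])
  keep <- !is.na(y)
  y <- y[keep]; s <- df$modal[keep]
  n <- length(y)
  # fixed prior over true class given modal class: w0[i,k] ∝ pi_k D[s_i,k]
  W0 <- sweep(logits$D[s, , drop = FALSE], 2L, logits$pi, `*`)
  W0 <- W0 / rowSums(W0)
  if (kind == "continuous") {
    mu <- rep(mean(y), K); sig <- sd(y)
    for (it in 1:500) {
      f <- vapply(seq_len(K), function(k) dnorm(y, mu[k], sig), numeric(n))
      W <- W0 * f
      W <- W / pmax(rowSums(W), 1e-300)
      mu_new <- colSums(W * y) / pmax(colSums(W), 1e-12)
      sig_new <- sqrt(sum(W * (y - matrix(mu_new, n, K, byrow = TRUE))^2) / n)
      if (max(abs(mu_new - mu)) < 1e-10 && abs(sig_new - sig) < 1e-10) {
        mu <- mu_new; sig <- sig_new; break
      }
      mu <- mu_new; sig <- sig_new
    }
    nll <- function(par) {
      m <- par[1:K]; sg <- exp(par[K + 1])
      f <- vapply(seq_len(K), function(k) dnorm(y, m[k], sg), numeric(n))
      -sum(log(pmax(rowSums(W0 * f), 1e-300)))
    }
    H <- optimHess(c(mu, log(sig)), nll)
    V <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
    pairs <- utils::combn(K, 2)
    res <- lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      d <- mu[a] - mu[b]
      vd <- V[a, a] + V[b, b] - 2 * V[a, b]
      w <- d^2 / max(vd, 1e-300)
      tibble(outcome = outcome, kind = kind, class_a = a, class_b = b,
             estimate = d, smd = d / sd(y), or = NA_real_,
             wald_chisq = w, df = 1,
             p_value = pchisq(w, 1, lower.tail = FALSE),
             unbounded = FALSE)
    })
    out <- dplyr::bind_rows(res)
    attr(out, "class_estimates") <- tibble(class = seq_len(K), mean = mu,
                                           sd = sig, n_effective = colSums(W0))
    return(out)
  }
  # binary outcome: class-specific probabilities via fixed-weight EM
  if (!all(y %in% c(0, 1))) abort("Binary distal outcomes must be 0/1.")
  p <- rep(mean(y), K)
  for (it in 1:500) {
    f <- vapply(seq_len(K), function(k) p[k]^y * (1 - p[k])^(1 - y), numeric(n))
    W <- W0 * f
    W <- W / pmax(rowSums(W), 1e-300)
    p_new <- colSums(W * y) / pmax(colSums(W), 1e-12)
    if (max(abs(p_new - p)) < 1e-12) { p <- p_new; break }
    p <- p_new
  }
  boundary <- p < 1e-6 | p > 1 - 1e-6
  lgt <- qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))
  nll <- function(par) {
    pk <- plogis(par)
    f <- vapply(seq_len(K), function(k) pk[k]^y * (1 - pk[k])^(1 - y), numeric(n))
    -sum(log(pmax(rowSums(W0 * f), 1e-300)))
  }
  H <- optimHess(lgt, nll)
  V <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  pairs <- utils::combn(K, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    unb <- boundary[a] || boundary[b]
    d <- lgt[a] - lgt[b]
    vd <- V[a, a] + V[b, b] - 2 * V[a, b]
    w <- d^2 / max(vd, 1e-300)
    or <- (p[a] / (1 - p[a])) / (p[b] / (1 - p[b]))
    if (unb) or <- if (p[a] > p[b]) Inf else 0
    tibble(outcome = outcome, kind = kind, class_a = a, class_b = b,
           estimate = d, smd = NA_real_, or = or,
           wald_chisq = if (unb) NA_real_ else w, df = 1,
           p_value = if (unb) NA_real_ else pchisq(w, 1, lower.tail = FALSE),
           unbounded = unb)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "class_estimates") <- tibble(class = seq_len(K), prob = p,
                                         n_effective = colSums(W0))
  out
}

#' Risk ratio between two trajectory classifications
#'
#' Cross-tabulates two modal assignments over their shared subjects and
#' computes the risk ratio `P(B = target | A = a1) / P(B = target | A = a2)`
#' with the Katz log-method confidence interval.
#'
#' @param assign_a,assign_b Data frames with `subject_id` and `class`
#'   columns (modal assignments from two outcome analyses). Subjects
#'   missing from either side are excluded and counted.
#' @param target_class_b Target class of classification B.
#' @param classes_a Length-2 vector `(a1, a2)` of classes of A compared
#'   (numerator, denominator).
#' @param conf_level Confidence level.
#' @param weights `"modal"` (hard cross-tabulation, the default) or
#'   `"posterior"` for a posterior-weighted table (supply posterior
#'   matrices as attributes — see Details).
#' @return A one-row tibble with the risk ratio, CI, z-based p value, the
#'   underlying counts and the number of excluded subjects. Attribute
#'   `table` holds the full cross-tabulation.
#' @export
cross_trajectory_rr <- function(assign_a, assign_b, target_class_b,
                                classes_a = c(1L, 2L), conf_level = 0.95,
                                weights = c("modal", "posterior")) {
  weights <- match.arg(weights)
  a <- as_tibble(assign_a); b <- as_tibble(assign_b)
  stopifnot(all(c("subject_id", "class") %in% names(a)),
            all(c("subject_id", "class") %in% names(b)))
  joined <- dplyr::inner_join(a, b, by = "subject_id",
                              suffix = c("_a", "_b"))
  n_excluded <- nrow(a) + nrow(b) - 2 * nrow(joined)
  tab <- table(factor(joined$class_a), factor(joined$class_b))
  a1 <- as.character(classes_a[1]); a2 <- as.character(classes_a[2])
  tb <- as.character(target_class_b)
  if (!all(c(a1, a2) %in% rownames(tab)) || !tb %in% colnames(tab)) {
    abort("Requested classes absent from the cross-tabulation.")
  }
  n1 <- sum(tab[a1, ]); n2 <- sum(tab[a2, ])
  if (n1 == 0 || n2 == 0) abort("Zero denominator in the risk-ratio table.")
  x1 <- tab[a1, tb]; x2 <- tab[a2, tb]
  p1 <- x1 / n1; p2 <- x2 / n2
  unbounded <- x2 == 0
  rr <- if (unbounded) Inf else p1 / p2
  zq <- qnorm(1 - (1 - conf_level) / 2)
  if (x1 > 0 && x2 > 0) {
    se <- sqrt(1 / x1 - 1 / n1 + 1 / x2 - 1 / n2)
    lo <- exp(log(rr) - zq * se); hi <- exp(log(rr) + zq * se)
    pv <- 2 * pnorm(-abs(log(rr) / se))
  } else {
    lo <- NA_real_; hi <- NA_real_; pv <- NA_real_
  }
  out <- tibble(
    target_class_b = target_class_b,
    class_a_num = classes_a[1], class_a_den = classes_a[2],
    x1 = as.integer(x1), n1 = as.integer(n1),
    x2 = as.integer(x2), n2 = as.integer(n2),
    p1 = p1, p2 = p2,
    rr = rr, conf_low = lo, conf_high = hi, p_value = pv,
    unbounded = unbounded,
    n_shared = nrow(joined), n_excluded = as.integer(n_excluded))
  attr(out, "table") <- tab
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param p_values Numeric vector of p values.
#' @param n_tests Size of the test family (default `length(p_values)`).
#' @param alpha Family-wise error rate (default 0.05).
#' @return A tibble with each p value, the corrected threshold
#'   `alpha / n_tests` and a pass flag.
#' @examples
#' bonferroni_adjust(c(0.0004, 0.03), n_tests = 50)  # threshold 0.001
#' @export
bonferroni_adjust <- function(p_values, n_tests = length(p_values),
                              alpha = 0.05) {
  stopifnot(n_tests >= 1)
  thr <- alpha / n_tests
  tibble(p_value = p_values, n_tests = as.integer(n_tests),
         threshold = thr, significant = p_values < thr)
}
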