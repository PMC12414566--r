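#' Mardia's multivariate skewness and kurtosis test
#'
#' Classical moment-based test of multivariate normality: skewness
#' `b1p = mean((x_i - xbar)' S^-1 (x_j - xbar))^3` with
#' `n b1p / 6 ~ chi2(p(p+1)(p+2)/6)`, and kurtosis
#' `b2p = mean(d_ii^2)` with `(b2p - p(p+2)) / sqrt(8 p (p+2) / n) ~ N(0,1)`,
#' using the ML (divide-by-n) covariance.
#'
#' @param x Numeric matrix, observations in rows.
#' @return A one-row tibble with the two statistics, degrees of freedom and
#'   p values.
#' @export
mardia_test <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n <= p + 1L) abort("Mardia's test needs more observations than variables.")
  xc <- scale(x, center = TRUE, scale = FALSE)
  S <- crossprod(xc) / n
  Sinv <- tryCatch(solve(S), error = function(e)
    abort("Singular covariance; Mardia's test not computable."))
  D <- xc %*% Sinv %*% t(xc)
  b1 <- mean(D^3)
  b2 <- mean(diag(D)^2)
  skew_stat <- n * b1 / 6
  skew_df <- p * (p + 1) * (p + 2) / 6
  kurt_z <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  tibble(
    n = n, dim = p,
    skewness = b1, skew_stat = skew_stat, skew_df = skew_df,
    skew_p = pchisq(skew_stat, skew_df, lower.tail = FALSE),
    kurtosis = b2, kurt_z = kurt_z,
    kurt_p = 2 * pnorm(-abs(kurt_z)))
}

#' Within-class multivariate normality check
#'
#' Applies Mardia's multivariate skewness and kurtosis tests to the
#' complete-case outcome vectors of each modal class of a fitted model
#' (subjects with every scheduled visit observed). Classes too small for
#' the test are flagged "not assessable" rather than erroring.
#'
#' @param fit An `lgm_fit`.
#' @param data The data the model was fitted to.
#' @param alpha Flagging level for either test (default 0.05).
#' @param min_class_size Smallest complete-case class size considered
#'   assessable (must also exceed the number of visits).
#' @return A tibble with one row per class: complete-case `n`, Mardia
#'   statistics and p values (NA when not assessable), `assessable`, and
#'   `flagged` (either test rejecting at `alpha`).
#' @export
check_class_normality <- function(fit, data, alpha = 0.05,
                                  min_class_size = 10L) {
  data <- if (inherits(data, "lgm_data")) data else
    lgm_data(data, times = fit$spec$times)
  wide <- as_lgm_wide(data, times = fit$spec$times)
  modal <- fit$modal[match(as.character(wide$subject_ids), names(fit$modal))]
  complete <- rowSums(wide$obs) == ncol(wide$Y)
  K <- fit$spec$n_classes
  p <- ncol(wide$Y)
  rows <- lapply(seq_len(K), function(k) {
    sel <- which(modal == k & complete)
    n_k <- length(sel)
    if (n_k < max(min_class_size, p + 2L)) {
      return(tibble(class = k, n = n_k, dim = p,
                    skewness = NA_real_, skew_stat = NA_real_,
                    skew_df = NA_real_, skew_p = NA_real_,
                    kurtosis = NA_real_, kurt_z = NA_real_, kurt_p = NA_real_,
                    assessable = FALSE, flagged = NA))
    }
    m <- mardia_test(wide$Y[sel, , drop = FALSE])
    tibble(class = k, n = n_k, dim = p,
           skewness = m$skewness, skew_stat = m$skew_stat,
           skew_df = m$skew_df, skew_p = m$skew_p,
           kurtosis = m$kurtosis, kurt_z = m$kurt_z, kurt_p = m$kurt_p,
           assessable = TRUE,
           flagged = m$skew_p < alpha | m$kurt_p < alpha)
  })
  dplyr::bind_rows(rows)
}
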