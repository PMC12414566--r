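#' Bayesian information criterion
#'
#' `-2 * loglik + n_params * log(n_subjects)`; lower values indicate a more
#' parsimonious model.
#'
#' @param loglik Maximized log likelihood.
#' @param n_params Number of free parameters (see [count_parameters()]).
#' @param n_subjects Number of subjects.
#' @return The BIC value.
#' @export
bic <- function(loglik, n_params, n_subjects) {
  stopifnot(n_subjects >= 1)
  -2 * loglik + n_params * log(n_subjects)
}

#' Scaled entropy of a posterior classification
#'
#' `1 - sum_i sum_k (-p_ik log p_ik) / (N log K)`, ranging from 0 (uniform,
#' uninformative posteriors) to 1 (one-hot, perfectly certain). Values
#' above 0.5 are conventionally read as adequate classification certainty.
#'
#' @param posteriors N x K posterior probability matrix with K >= 2.
#' @return Scaled entropy in `[0, 1]`.
#' @export
scaled_entropy <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  K <- ncol(posteriors)
  if (K < 2L) abort("Scaled entropy is undefined for a single class.")
  N <- nrow(posteriors)
  p <- pmin(pmax(posteriors, 0), 1)
  h <- -p * log(p)
  h[p == 0] <- 0
  1 - sum(h) / (N * log(K))
}

#' Average posterior probability of assignment (APPA)
#'
#' For each class, the mean posterior probability of that class among the
#' subjects modally assigned to it. Values above 0.7 are conventionally
#' read as good classification. Classes with no modally assigned subject
#' get `NA` (undefined).
#'
#' @param posteriors N x K posterior probability matrix.
#' @param modal Optional integer vector of modal assignments; defaults to
#'   the row-wise argmax (ties to the lowest index).
#' @return Numeric vector of length K.
#' @export
appa <- function(posteriors, modal = NULL) {
  posteriors <- as.matrix(posteriors)
  K <- ncol(posteriors)
  if (is.null(modal)) modal <- modal_assignment(posteriors)
  vapply(seq_len(K), function(k) {
    in_k <- modal == k
    if (!any(in_k)) return(NA_real_)
    mean(posteriors[in_k, k])
  }, numeric(1))
}
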