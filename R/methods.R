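#' @export
print.lgm_fit <- function(x, ...) {
  fi <- x$fit_indices
  cat(sprintf("<lgm_fit> %s, K = %d, N = %d\n", x$spec$family,
              x$spec$n_classes, x$n_subjects))
  cat(sprintf("  loglik %.2f | BIC %.1f | entropy %s | params %d\n",
              x$loglik, fi$bic,
              ifelse(is.na(fi$scaled_entropy), "-",
                     sprintf("%.2f", fi$scaled_entropy)),
              count_parameters(x$spec)))
  cat("  class counts:",
      paste(sprintf("%d (%.0f%%)", fi$class_counts,
                    100 * fi$class_proportions_modal), collapse = ", "), "\n")
  cv <- x$convergence
  cat(sprintf("  %d starts, best LL replicated by %d start(s)%s\n",
              cv$n_starts, cv$best_loglik_replications,
              if (isTRUE(cv$replicated_between_runs)) ", replicated between runs"
              else ""))
  invisible(x)
}

#' Tidy a fitted latent growth mixture
#'
#' One row per class and growth coefficient, month-unit scale, broom
#' style.
#'
#' @param x An `lgm_fit`.
#' @param ... Unused.
#' @return A tibble with `class`, `term`, `estimate`, plus the class
#'   proportion.
#' @export
tidy.lgm_fit <- function(x, ...) {
  purrr::map_dfr(seq_len(x$spec$n_classes), function(k) {
    b <- x$params$beta[[k]]
    tibble(class = k,
           proportion = x$params$pi[k],
           term = paste0("t^", seq_along(b) - 1L),
           estimate = unname(b))
  })
}

#' One-row model summary of a fitted latent growth mixture
#'
#' @param x An `lgm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: family, classes, parameters, log likelihood,
#'   BIC, scaled entropy, minimum APPA, smallest class share, convergence.
#' @export
glance.lgm_fit <- function(x, ...) {
  fi <- x$fit_indices
  tibble(family = x$spec$family,
         n_classes = x$spec$n_classes,
         n_subjects = x$n_subjects,
         n_params = count_parameters(x$spec),
         loglik = x$loglik,
         bic = fi$bic,
         entropy = fi$scaled_entropy,
         appa_min = suppressWarnings(min(fi$appa, na.rm = TRUE)),
         min_class_share = min(fi$class_proportions_modal),
         converged = x$convergence$converged)
}

#' Per-subject classification table
#'
#' @param x An `lgm_fit`.
#' @param ... Unused.
#' @return A tibble with `subject_id`, `modal_class` and posterior
#'   probability columns `p1..pK`.
#' @export
augment.lgm_fit <- function(x, ...) {
  post <- as_tibble(x$posteriors, .name_repair = ~ paste0("p", seq_along(.x)))
  dplyr::bind_cols(
    tibble(subject_id = x$subject_ids, modal_class = unname(x$modal)),
    post)
}

#' @export
tidy.lgm_selection <- function(x, ...) x$audit

#' @export
glance.lgm_selection <- function(x, ...) glance(x$fit)

#' Plot estimated class trajectories
#'
#' Estimated class mean curves on a fine time grid, optionally over the
#' observed individual trajectories (spaghetti background), mirroring the
#' usual latent-trajectory figure.
#'
#' @param object An `lgm_fit`.
#' @param data Optional [lgm_data()] to draw observed trajectories behind
#'   the curves.
#' @param n_grid Grid resolution for the curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lgm_fit <- function(object, data = NULL, n_grid = 101L, ...) {
  grid <- seq(min(object$spec$times), max(object$spec$times),
              length.out = n_grid)
  curves <- trajectory_table(object, grid) |>
    dplyr::mutate(class = factor(.data$class))
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_line(
      data = as_tibble(data),
      ggplot2::aes(.data$time, .data$value, group = .data$subject_id),
      colour = "grey80", linewidth = 0.2, alpha = 0.5)
  }
  p +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(.data$time, .data$mean, colour = .data$class),
      linewidth = 1.1) +
    ggplot2::labs(x = "Months", y = "Outcome score", colour = "Class") +
    ggplot2::theme_minimal()
}

#' Plot the model-selection audit
#'
#' BIC of every fitted candidate by pipeline stage, with the selected
#' model highlighted.
#'
#' @param object An `lgm_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lgm_selection <- function(object, ...) {
  aud <- dplyr::filter(object$audit, !is.na(.data$bic))
  ggplot2::ggplot(aud, ggplot2::aes(.data$label, .data$bic)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$stage,
                                     shape = .data$selected), size = 2.5) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "BIC") +
    ggplot2::theme_minimal()
}
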