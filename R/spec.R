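#' Declare the structure of a latent growth model
#'
#' A model specification fixes everything about a latent growth model except
#' the values of its free parameters: the model family, the number of latent
#' classes, the polynomial order of each class mean curve, which growth
#' factors carry random effects, and how residual variances are structured
#' over time and classes.
#'
#' The supported families follow the standard trajectory-modeling taxonomy:
#'
#' * `"GCM"` — single-class growth curve model (sample mean trajectory with
#'   random effects); requires `n_classes = 1`.
#' * `"GBTM"` — group-based trajectory model: latent classes, no random
#'   effects, a single residual variance shared across time and classes.
#' * `"LCGA"` — latent class growth analysis: GBTM with the residual
#'   variance relaxed over time, classes, or both.
#' * `"GMM_CLASS_INVARIANT"` — growth mixture model with one random-effect
#'   covariance matrix shared by all classes.
#' * `"GMM_CLASS_VARIANT"` — growth mixture model with a separate
#'   random-effect covariance matrix per class.
#'
#' @param family One of `"GCM"`, `"GBTM"`, `"LCGA"`, `"GMM_CLASS_INVARIANT"`,
#'   `"GMM_CLASS_VARIANT"`.
#' @param n_classes Number of latent classes, an integer >= 1.
#' @param poly_order Polynomial order of the class mean curves: 1 (linear),
#'   2 (quadratic) or 3 (cubic). A single value is recycled to all classes;
#'   a vector of length `n_classes` gives per-class orders (as arises after
#'   Wald-based pruning).
#' @param random_effects Character subset of `c("intercept", "linear_slope")`
#'   naming the growth factors with random effects. Must be empty for
#'   GBTM/LCGA and non-empty for GMM families.
#' @param residuals Residual-variance structure: `"FIXED"` (one variance),
#'   `"FREE_OVER_TIME"` (one per visit), `"FREE_OVER_CLASSES"` (one per
#'   class) or `"FREE_BOTH"` (one per class and visit).
#' @param times Ordered numeric vector of scheduled assessment times in
#'   months, e.g. `c(0, 1, 2, 3, 6, 9, 12, 18, 24)`.
#'
#' @return An object of class `lgm_spec`.
#'
#' @examples
#' # the 2-class cubic class-variant growth mixture model used for
#' # positive-symptom trajectories over 9 visits
#' lgm_spec("GMM_CLASS_VARIANT", n_classes = 2, poly_order = 3,
#'          random_effects = c("intercept", "linear_slope"),
#'          residuals = "FREE_BOTH",
#'          times = c(0, 1, 2, 3, 6, 9, 12, 18, 24))
#' @export
lgm_spec <- function(family = c("GBTM", "GCM", "LCGA", "GMM_CLASS_INVARIANT",
                                "GMM_CLASS_VARIANT"),
                     n_classes = 1L,
                     poly_order = 2L,
                     random_effects = character(),
                     residuals = c("FIXED", "FREE_OVER_TIME",
                                   "FREE_OVER_CLASSES", "FREE_BOTH"),
                     times) {
  family <- match.arg(family)
  residuals <- match.arg(residuals)
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 1L) {
    abort("`n_classes` must be an integer >= 1.")
  }
  if (missing(times) || length(times) < 2L) {
    abort("`times` must give at least two scheduled assessment times.")
  }
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing.")
  }
  poly_order <- as.integer(poly_order)
  if (length(poly_order) == 1L) poly_order <- rep(poly_order, n_classes)
  if (length(poly_order) != n_classes) {
    abort("`poly_order` must have length 1 or `n_classes`.")
  }
  if (any(!poly_order %in% 1:3)) {
    abort("Polynomial orders must be 1 (linear), 2 (quadratic) or 3 (cubic).")
  }
  # identifiability: a curve of order q needs q+1 distinct visit times
  if (any(poly_order + 1L > length(times))) {
    abort(sprintf(
      "Polynomial order %d requires at least %d visit times; schedule has %d.",
      max(poly_order), max(poly_order) + 1L, length(times)))
  }
  random_effects <- as.character(random_effects)
  bad_re <- setdiff(random_effects, c("intercept", "linear_slope"))
  if (length(bad_re)) {
    abort(paste0("Unknown random-effect terms: ",
                 paste(bad_re, collapse = ", ")))
  }
  random_effects <- intersect(c("intercept", "linear_slope"), random_effects)
  if (family == "GCM" && n_classes != 1L) {
    abort("A GCM is single-class by definition; use a mixture family for K > 1.")
  }
  if (family %in% c("GBTM", "LCGA") && length(random_effects) > 0L) {
    abort(sprintf("%s models have no random effects.", family))
  }
  if (family %in% c("GMM_CLASS_INVARIANT", "GMM_CLASS_VARIANT") &&
      length(random_effects) == 0L) {
    abort("GMM families require at least one random-effect term.")
  }
  if (family == "GBTM" && residuals != "FIXED") {
    abort("GBTM uses a single residual variance; relaxed residuals define an LCGA.")
  }
  if ("linear_slope" %in% random_effects && any(poly_order < 1L)) {
    abort("A random linear slope requires at least a linear mean curve.")
  }
  structure(
    list(family = family,
         n_classes = n_classes,
         poly_order = poly_order,
         random_effects = random_effects,
         residuals = residuals,
         times = times),
    class = "lgm_spec")
}

#' @export
print.lgm_spec <- function(x, ...) {
  cat(sprintf("<lgm_spec> %s, K = %d\n", x$family, x$n_classes))
  cat("  polynomial order: ", paste(x$poly_order, collapse = ", "), "\n", sep = "")
  cat("  random effects:   ",
      if (length(x$random_effects)) paste(x$random_effects, collapse = " + ")
      else "none", "\n", sep = "")
  cat("  residuals:        ", x$residuals, "\n", sep = "")
  cat("  visits (months):  ", paste(x$times, collapse = ", "), "\n", sep = "")
  cat("  free parameters:  ", count_parameters(x), "\n", sep = "")
  invisible(x)
}

n_random_effects <- function(spec) length(spec$random_effects)

#' Count the free parameters of a latent growth model
#'
#' The count is the sum of: per-class growth coefficients
#' (polynomial order + 1 each); random-effect (co)variances
#' (`r(r+1)/2` for `r` random effects — once if class-invariant, once per
#' class if class-variant, none for GBTM/LCGA); residual variances (1 if
#' fixed, one per visit, one per class, or one per class and visit); and
#' `K - 1` free class proportions.
#'
#' @param spec An [lgm_spec()].
#' @return Integer number of free parameters.
#' @examples
#' sched9 <- c(0, 1, 2, 3, 6, 9, 12, 18, 24)
#' count_parameters(lgm_spec("GMM_CLASS_VARIANT", 2, 3,
#'   c("intercept", "linear_slope"), "FREE_BOTH", sched9))  # 33
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "lgm_spec"))
  K <- spec$n_classes
  T_ <- length(spec$times)
  r <- n_random_effects(spec)
  n_beta <- sum(spec$poly_order + 1L)
  n_psi <- if (r == 0L) 0L else {
    per <- r * (r + 1L) / 2L
    if (spec$family == "GMM_CLASS_VARIANT") per * K else per
  }
  n_theta <- switch(spec$residuals,
    FIXED = 1L,
    FREE_OVER_TIME = T_,
    FREE_OVER_CLASSES = K,
    FREE_BOTH = K * T_)
  as.integer(n_beta + n_psi + n_theta + (K - 1L))
}

# polynomial design matrix at given times (raw powers, month units)
design_matrix <- function(times, order) {
  outer(as.numeric(times), 0:order, `^`)
}

# random-effect design columns: subset of (1, t)
re_design <- function(times, random_effects) {
  cols <- c(intercept = 1L, linear_slope = 2L)[random_effects]
  design_matrix(times, 1L)[, cols, drop = FALSE]
}
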