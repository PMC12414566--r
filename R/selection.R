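# Four-stage model-building strategy:
#   (1) single-class growth curve baseline;
#   (2) class enumeration with group-based trajectory models, chosen by BIC
#       subject to the bootstrap LRT, the <5% smallest-class rule and
#       (optionally hard) entropy/APPA floors;
#   (3) residual-variance relaxation over time, classes, or both;
#   (4) stepwise addition of class-invariant then class-variant random
#       effects; followed by Wald-based polynomial pruning and a
#       within-class multivariate normality check.

#' Configuration of the model-selection pipeline
#'
#' @param max_classes Largest class count enumerated (default 6).
#' @param min_class_proportion Models whose smallest class holds less than
#'   this share of the sample are rejected (default 0.05).
#' @param entropy_floor,appa_floor Advisory classification-quality floors
#'   (scaled entropy > 0.5, APPA > 0.7 by convention). Reported always;
#'   enforced as admissibility rules only when `floors_hard = TRUE`.
#' @param floors_hard Treat the entropy/APPA floors as hard rejection
#'   rules rather than advisory flags.
#' @param lrt_replicates Bootstrap replicates for the K vs K-1 likelihood
#'   ratio test; 0 disables the LRT (BIC-only enumeration).
#' @param alpha_lrt Significance level for the LRT.
#' @param alpha_wald Two-sided level for Wald polynomial pruning.
#' @param bic_tie Within this BIC difference two models are considered
#'   tied and the more parsimonious one preferred (default 2).
#' @return A `selection_config` list.
#' @export
selection_config <- function(max_classes = 6L,
                             min_class_proportion = 0.05,
                             entropy_floor = 0.5,
                             appa_floor = 0.7,
                             floors_hard = FALSE,
                             lrt_replicates = 49L,
                             alpha_lrt = 0.05,
                             alpha_wald = 0.05,
                             bic_tie = 2) {
  stopifnot(max_classes >= 1L,
            min_class_proportion > 0, min_class_proportion < 1)
  structure(list(max_classes = as.integer(max_classes),
                 min_class_proportion = min_class_proportion,
                 entropy_floor = entropy_floor,
                 appa_floor = appa_floor,
                 floors_hard = floors_hard,
                 lrt_replicates = as.integer(lrt_replicates),
                 alpha_lrt = alpha_lrt,
                 alpha_wald = alpha_wald,
                 bic_tie = bic_tie),
            class = "selection_config")
}

audit_row <- function(stage, label, fit = NULL, spec = NULL, lrt_p = NA_real_,
                      decision = "", selected = FALSE, error = NA_character_) {
  if (!is.null(fit)) spec <- fit$spec
  tibble(
    stage = stage,
    label = label,
    family = if (!is.null(spec)) spec$family else NA_character_,
    n_classes = if (!is.null(spec)) spec$n_classes else NA_integer_,
    poly = if (!is.null(spec)) paste(spec$poly_order, collapse = "/") else NA,
    random_effects = if (!is.null(spec)) {
      if (length(spec$random_effects)) paste(spec$random_effects, collapse = "+")
      else "none"
    } else NA,
    residuals = if (!is.null(spec)) spec$residuals else NA_character_,
    n_params = if (!is.null(spec)) count_parameters(spec) else NA_integer_,
    loglik = if (!is.null(fit)) fit$loglik else NA_real_,
    bic = if (!is.null(fit)) fit$fit_indices$bic else NA_real_,
    entropy = if (!is.null(fit)) fit$fit_indices$scaled_entropy else NA_real_,
    appa_min = if (!is.null(fit)) suppressWarnings(min(fit$fit_indices$appa,
                                                       na.rm = TRUE)) else NA_real_,
    min_class_share = if (!is.null(fit))
      min(fit$fit_indices$class_proportions_modal) else NA_real_,
    lrt_p = lrt_p,
    decision = decision,
    selected = selected,
    error = error)
}

admissible <- function(fit, config) {
  share_ok <- min(fit$fit_indices$class_proportions_modal) >=
    config$min_class_proportion
  if (fit$spec$n_classes == 1L) return(TRUE)
  if (!share_ok) return(FALSE)
  if (config$floors_hard) {
    ent_ok <- is.na(fit$fit_indices$scaled_entropy) ||
      fit$fit_indices$scaled_entropy > config$entropy_floor
    ap <- fit$fit_indices$appa
    appa_ok <- all(is.na(ap)) || min(ap, na.rm = TRUE) > config$appa_floor
    return(ent_ok && appa_ok)
  }
  TRUE
}

# BIC-best with parsimony tie-break: within `bic_tie` of the minimum,
# prefer the fewest-parameter model
pick_best <- function(fits, config) {
  bics <- vapply(fits, function(f) f$fit_indices$bic, numeric(1))
  npar <- vapply(fits, function(f) count_parameters(f$spec), numeric(1))
  near <- which(bics <= min(bics) + config$bic_tie)
  near[order(npar[near], bics[near])][1L]
}

#' Systematic four-stage trajectory model selection
#'
#' Executes the full model-building ladder on one longitudinal outcome:
#' single-class growth-curve baseline; class enumeration with group-based
#' trajectory models (BIC plus bootstrap LRT, smallest-class and
#' classification-quality rules); residual-variance relaxation; stepwise
#' random-effect addition; then Wald-based polynomial pruning and a
#' within-class multivariate normality check. Every fitted candidate is
#' recorded in the audit table with the decision taken.
#'
#' @param data An [lgm_data()] table.
#' @param preset_poly_order Pre-set polynomial order for the mean curves
#'   (cubic for 9-visit symptom schedules, quadratic for a 3-visit
#'   functioning schedule; the schedule must allow `order + 1` visits).
#' @param config A [selection_config()].
#' @param protocol A [start_protocol()] used for candidate fits.
#' @param seed Integer master seed.
#' @return An object of class `lgm_selection`: `fit` (the selected and
#'   pruned model), `audit` (one row per fitted candidate), `normality`
#'   (per-class Mardia tests of the final model) and `config`.
#' @export
select_trajectory_model <- function(data, preset_poly_order = 2L,
                                    config = selection_config(),
                                    protocol = default_protocol(),
                                    seed = 1L) {
  data <- if (inherits(data, "lgm_data")) data else lgm_data(data)
  times <- schedule_times(data)
  if (preset_poly_order + 1L > length(times)) {
    abort(sprintf("Pre-set order %d needs at least %d visits.",
                  preset_poly_order, preset_poly_order + 1L))
  }
  audit <- list()
  seed <- as.integer(seed)

  # ---- stage 1: single-class growth curve baseline -----------------------
  spec_gcm <- lgm_spec("GCM", 1L, preset_poly_order,
                       c("intercept", "linear_slope"), "FIXED", times)
  fit_gcm <- fit_lgm(data, spec_gcm, protocol, seed = seed + 10L)
  audit <- c(audit, list(audit_row(
    "1_baseline", "GCM", fit_gcm,
    decision = "single-class mean-trajectory baseline")))

  # ---- stage 2: class enumeration with GBTMs -----------------------------
  gbtm_fits <- list()
  prev_bic <- Inf
  rising <- 0L
  for (K in seq_len(config$max_classes)) {
    spec_k <- lgm_spec("GBTM", K, preset_poly_order, character(),
                       "FIXED", times)
    fk <- tryCatch(fit_lgm(data, spec_k, protocol, seed = seed + 20L + K),
                   error = function(e) e)
    if (inherits(fk, "error")) {
      audit <- c(audit, list(audit_row("2_enumeration", paste0("GBTM-K", K),
                                       spec = spec_k,
                                       decision = "fit failed",
                                       error = conditionMessage(fk))))
      break
    }
    gbtm_fits[[K]] <- fk
    adm <- admissible(fk, config)
    audit <- c(audit, list(audit_row(
      "2_enumeration", paste0("GBTM-K", K), fk,
      decision = if (adm) "candidate" else
        sprintf("rejected: smallest class %.1f%% < %.0f%% (or quality floor)",
                100 * min(fk$fit_indices$class_proportions_modal),
                100 * config$min_class_proportion))))
    if (!adm) break
    if (fk$fit_indices$bic > prev_bic) rising <- rising + 1L else rising <- 0L
    prev_bic <- fk$fit_indices$bic
    if (rising >= 1L && K >= 2L) break
  }
  adm_idx <- which(vapply(gbtm_fits, function(f)
    !is.null(f) && admissible(f, config), logical(1)))
  if (!length(adm_idx)) adm_idx <- 1L
  K_best <- adm_idx[pick_best(gbtm_fits[adm_idx], config)]

  # LRT confirmation: K must beat K-1; otherwise fall back
  while (K_best > 1L && config$lrt_replicates > 0L) {
    lrt <- bootstrap_lrt(
      data, gbtm_fits[[K_best]]$spec, gbtm_fits[[K_best - 1L]]$spec,
      replicates = config$lrt_replicates, seed = seed + 300L + K_best,
      protocol = protocol,
      fit_k = gbtm_fits[[K_best]], fit_km1 = gbtm_fits[[K_best - 1L]])
    # bootstrap p values live on the grid 1/(R+1), ..., 1: reject at p <= alpha
    sig <- lrt$p_value <= config$alpha_lrt
    audit <- c(audit, list(audit_row(
      "2_enumeration", sprintf("LRT %d vs %d", K_best, K_best - 1L),
      gbtm_fits[[K_best]], lrt_p = lrt$p_value,
      decision = if (sig) sprintf("K = %d supported (p = %.3f)", K_best,
                                  lrt$p_value)
      else sprintf("K = %d not supported (p = %.3f), falling back", K_best,
                   lrt$p_value))))
    if (sig) break
    K_best <- K_best - 1L
  }
  stage2 <- gbtm_fits[[K_best]]
  audit <- c(audit, list(audit_row(
    "2_enumeration", sprintf("selected K = %d", K_best), stage2,
    decision = "class structure fixed for stages 3-4")))

  # ---- stage 3: residual-variance relaxation -----------------------------
  K <- K_best
  relax <- c("FREE_OVER_TIME", if (K > 1L) c("FREE_OVER_CLASSES", "FREE_BOTH"))
  cands3 <- list(stage2)
  for (res in relax) {
    fam <- if (K > 1L) "LCGA" else "LCGA"
    spec_r <- lgm_spec(fam, K, preset_poly_order, character(), res, times)
    fr <- tryCatch(fit_lgm(data, spec_r, protocol,
                           seed = seed + 40L + match(res, relax)),
                   error = function(e) e)
    if (inherits(fr, "error")) {
      audit <- c(audit, list(audit_row("3_residuals", paste0("LCGA-", res),
                                       spec = spec_r, decision = "fit failed",
                                       error = conditionMessage(fr))))
      next
    }
    adm <- admissible(fr, config)
    audit <- c(audit, list(audit_row(
      "3_residuals", paste0("LCGA-", res), fr,
      decision = if (adm) "candidate" else "rejected: admissibility")))
    if (adm) cands3 <- c(cands3, list(fr))
  }
  stage3 <- cands3[[pick_best(cands3, config)]]
  audit <- c(audit, list(audit_row(
    "3_residuals", "stage 3 winner", stage3,
    decision = sprintf("residuals: %s", stage3$spec$residuals))))

  # ---- stage 4: random-effect addition -----------------------------------
  res_kept <- stage3$spec$residuals
  re_ladder <- list(
    list(fam = if (K > 1L) "GMM_CLASS_INVARIANT" else "GCM",
         re = "intercept", tag = "CI-int"),
    list(fam = if (K > 1L) "GMM_CLASS_INVARIANT" else "GCM",
         re = c("intercept", "linear_slope"), tag = "CI-int+slope"))
  if (K > 1L) {
    re_ladder <- c(re_ladder, list(
      list(fam = "GMM_CLASS_VARIANT", re = "intercept", tag = "CV-int"),
      list(fam = "GMM_CLASS_VARIANT", re = c("intercept", "linear_slope"),
           tag = "CV-int+slope")))
  }
  cands4 <- list(stage3)
  for (j in seq_along(re_ladder)) {
    rl <- re_ladder[[j]]
    spec_g <- tryCatch(
      lgm_spec(rl$fam, K, preset_poly_order, rl$re, res_kept, times),
      error = function(e) e)
    if (inherits(spec_g, "error")) next
    fg <- tryCatch(fit_lgm(data, spec_g, protocol, seed = seed + 60L + j),
                   error = function(e) e)
    if (inherits(fg, "error")) {
      audit <- c(audit, list(audit_row("4_random_effects", rl$tag,
                                       spec = spec_g, decision = "fit failed",
                                       error = conditionMessage(fg))))
      next
    }
    adm <- admissible(fg, config)
    audit <- c(audit, list(audit_row(
      "4_random_effects", rl$tag, fg,
      decision = if (adm) "candidate" else "rejected: admissibility")))
    if (adm) cands4 <- c(cands4, list(fg))
  }
  stage4 <- cands4[[pick_best(cands4, config)]]
  audit <- c(audit, list(audit_row(
    "4_random_effects", "stage 4 winner", stage4,
    decision = sprintf("%s selected", stage4$spec$family))))

  # ---- polynomial pruning and normality check ----------------------------
  pruned <- refine_polynomial(stage4, data, alpha_wald = config$alpha_wald,
                              protocol = protocol, seed = seed + 90L)
  audit <- c(audit, lapply(seq_len(nrow(pruned$audit)), function(i) {
    r <- pruned$audit[i, ]
    audit_row("5_pruning", r$label, decision = r$decision,
              spec = NULL)
  }))
  final <- pruned$fit
  audit <- c(audit, list(audit_row(
    "5_pruning", "final model", final, selected = TRUE,
    decision = sprintf("per-class orders %s",
                       paste(final$spec$poly_order, collapse = "/")))))
  normality <- tryCatch(check_class_normality(final, data),
                        error = function(e) tibble())
  structure(
    list(fit = final, audit = dplyr::bind_rows(audit),
         normality = normality, config = config, seed = seed),
    class = "lgm_selection")
}

# ---- Wald machinery and polynomial pruning --------------------------------

# Wald table for all growth coefficients via the observed information of
# the packed (scaled-time) likelihood; z statistics are invariant to the
# time rescaling so p values can be computed on the scaled parameters.
coef_wald <- function(fit, data) {
  spec <- fit$spec
  spec_s <- scale_spec(spec)
  wide <- as_lgm_wide(data, times = spec$times)
  wide$times <- wide$times / TIME_SCALE
  par <- pack_params(spec_s, fit$state_scaled)
  H <- tryCatch(
    optimHess(par, negloglik_packed, spec = spec_s, wide = wide),
    error = function(e) NULL)
  V <- NULL
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V)) V <- tryCatch(MASS::ginv(H), error = function(e) NULL)
  }
  idx <- grep("^beta", names(par))
  out <- tibble(
    term = names(par)[idx],
    class = as.integer(sub("^beta(\\d+)\\..*$", "\\1", names(par)[idx])),
    order = as.integer(sub("^beta\\d+\\.(\\d+)$", "\\1", names(par)[idx])),
    estimate_scaled = unname(par[idx]),
    se_scaled = if (is.null(V)) NA_real_ else sqrt(pmax(diag(V)[idx], 0)))
  out$estimate <- out$estimate_scaled / TIME_SCALE^out$order
  out$se <- out$se_scaled / TIME_SCALE^out$order
  out$z <- out$estimate_scaled / out$se_scaled
  out$p_value <- 2 * pnorm(-abs(out$z))
  out
}

#' Prune non-significant polynomial terms by Wald tests
#'
#' Iteratively tests the highest-order growth coefficient of each class
#' (Wald z from the observed information) and drops the least significant
#' non-significant top term, refitting after each drop — so the class
#' structure is re-estimated at every step — until every class's top term
#' is significant at `alpha_wald` or linear order is reached.
#'
#' @param fit An `lgm_fit`.
#' @param data The data the model was fitted to.
#' @param alpha_wald Two-sided significance level (default 0.05).
#' @param protocol,seed Refitting protocol and seed.
#' @return A list with `fit` (the pruned model) and `audit` (a tibble of
#'   pruning steps).
#' @export
refine_polynomial <- function(fit, data, alpha_wald = 0.05,
                              protocol = default_protocol(), seed = 1L) {
  data <- if (inherits(data, "lgm_data")) data else
    lgm_data(data, times = fit$spec$times)
  steps <- list()
  current <- fit
  for (it in seq_len(sum(fit$spec$poly_order))) {
    w <- coef_wald(current, data)
    top <- w |>
      dplyr::group_by(.data$class) |>
      dplyr::filter(.data$order == max(.data$order)) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$order >= 2L)   # never prune below linear
    cand <- top |>
      dplyr::filter(is.na(.data$p_value) | .data$p_value >= alpha_wald)
    if (nrow(cand) == 0L) break
    drop_row <- cand[order(-ifelse(is.na(cand$p_value), 1, cand$p_value)), ][1L, ]
    spec2 <- current$spec
    spec2$poly_order[drop_row$class] <- spec2$poly_order[drop_row$class] - 1L
    spec2 <- lgm_spec(spec2$family, spec2$n_classes, spec2$poly_order,
                      spec2$random_effects, spec2$residuals, spec2$times)
    # warm start: previous solution with the dropped coefficient removed
    st <- current$state_scaled
    st$beta[[drop_row$class]] <-
      st$beta[[drop_row$class]][-(drop_row$order + 1L)]
    refit <- tryCatch(
      fit_lgm(data, spec2, protocol, seed = seed + it, init = list(st)),
      error = function(e) NULL)
    steps <- c(steps, list(tibble(
      label = sprintf("drop t^%d in class %d", drop_row$order, drop_row$class),
      decision = if (is.null(refit))
        "refit failed; keeping previous model"
      else sprintf("Wald p = %.3f >= %.2f; term dropped",
                   drop_row$p_value, alpha_wald))))
    if (is.null(refit)) break
    current <- refit
  }
  list(fit = current,
       audit = if (length(steps)) dplyr::bind_rows(steps) else
         tibble(label = character(), decision = character()))
}

#' @export
print.lgm_selection <- function(x, ...) {
  cat("<lgm_selection>\n")
  cat(sprintf("  selected: %s, K = %d, orders %s, residuals %s\n",
              x$fit$spec$family, x$fit$spec$n_classes,
              paste(x$fit$spec$poly_order, collapse = "/"),
              x$fit$spec$residuals))
  cat(sprintf("  loglik %.2f, BIC %.1f, entropy %s\n",
              x$fit$loglik, x$fit$fit_indices$bic,
              format(x$fit$fit_indices$scaled_entropy, digits = 3)))
  cat(sprintf("  audit: %d candidates/decisions recorded\n", nrow(x$audit)))
  invisible(x)
}
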