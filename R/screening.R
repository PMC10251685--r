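#' Screen a baseline variable as a confounder of cost-effectiveness
#'
#' Applies the three-criterion operational rule on multiply imputed data.
#' A candidate is a confounder when it (1) differs between arms (pooled p of
#' the arm coefficient in `candidate ~ arm` below 0.05), (2) changes the
#' intervention coefficient of the net-benefit model by at least 10% when
#' added to it, and (3) is associated with the net benefit (pooled p of its
#' own coefficient in `nb ~ arm + candidate` below 0.05). Criteria 2 and 3
#' depend on the WTP threshold; they are evaluated at each `lambdas` value
#' and trigger if met at any of them (defaults: the $0 and $100 grid
#' endpoints).
#'
#' @param imps An `nbr_imputations` object.
#' @param variable Candidate baseline column name.
#' @param perspective Costing perspective.
#' @param lambdas WTP thresholds at which criteria 2 and 3 are evaluated.
#' @param alpha Significance level for criteria 1 and 3.
#' @param change_threshold Relative change in the intervention coefficient
#'   triggering criterion 2 (default 0.10).
#' @param period_days Optional override of the AFD period lengths.
#' @return A list of class `confounder_decision` with per-criterion flags
#'   and evidence. If the unadjusted intervention coefficient is exactly
#'   zero at some threshold, criterion 2 is indeterminate there and the
#'   decision's `status` is `"indeterminate"` rather than an error.
#' @export
screen_confounder <- function(imps, variable,
                              perspective = c("health_system",
                                              "limited_societal"),
                              lambdas = c(0, 100), alpha = 0.05,
                              change_threshold = 0.10, period_days = NULL) {
  perspective <- match.arg(perspective)
  if (!variable %in% names(imps$completed[[1]])) {
    stop("candidate variable not found: ", variable)
  }
  if (imps$m < 2) stop("confounder screening pools over m >= 2 imputations")

  # criterion 1: candidate ~ arm, pooled (lambda-free)
  c1_fits <- lapply(imps$completed, function(d) {
    f <- stats::lm(stats::reformulate("arm", response = variable), data = d)
    # a candidate perfectly determined by arm is legitimate input here;
    # it fails later (criterion 2) with a rank-deficiency error
    list(est = stats::coef(f), var = diag(suppressWarnings(stats::vcov(f))),
         df = stats::df.residual(f))
  })
  c1_pool <- rubin_pool(do.call(rbind, lapply(c1_fits, `[[`, "est")),
                        do.call(rbind, lapply(c1_fits, `[[`, "var")),
                        dfcom = c1_fits[[1]]$df)
  arm_term <- grep("^arm", c1_pool$term, value = TRUE)[1]
  c1_p <- c1_pool$p.value[c1_pool$term == arm_term]

  per_lambda <- lapply(lambdas, function(l) {
    unadj <- nb_regression_mi(imps, l, perspective, period_days = period_days)
    adj <- nb_regression_mi(imps, l, perspective, covariates = variable,
                            period_days = period_days)
    iv <- unadj$intervention_term
    b_un <- unadj$pooled$estimate[unadj$pooled$term == iv]
    b_ad <- adj$pooled$estimate[adj$pooled$term == iv]
    cand_rows <- setdiff(adj$pooled$term,
                         c("(Intercept)", iv))
    c3_p <- min(adj$pooled$p.value[adj$pooled$term %in% cand_rows])
    pct <- if (b_un == 0) NA_real_ else abs((b_ad - b_un) / b_un)
    list(lambda = l, beta_unadjusted = b_un, beta_adjusted = b_ad,
         pct_change = pct, outcome_p = c3_p)
  })
  pct <- vapply(per_lambda, `[[`, numeric(1), "pct_change")
  c3p <- vapply(per_lambda, `[[`, numeric(1), "outcome_p")

  c1 <- c1_p < alpha
  c2 <- if (all(is.na(pct))) NA else any(pct >= change_threshold, na.rm = TRUE)
  c3 <- any(c3p < alpha)
  status <- if (anyNA(pct)) "indeterminate" else "determined"
  structure(list(variable = variable, perspective = perspective,
                 lambdas = lambdas,
                 criterion1_groups_differ = c1, criterion1_p = c1_p,
                 criterion2_beta_change = c2,
                 criterion2_pct_change = pct,
                 criterion3_outcome_assoc = c3, criterion3_p = c3p,
                 detail = per_lambda,
                 status = status,
                 is_confounder = if (is.na(c2)) NA else c1 && c2 && c3),
            class = "confounder_decision")
}

#' @export
print.confounder_decision <- function(x, ...) {
  cat("Confounder screen for `", x$variable, "` (", x$perspective, ")\n",
      sep = "")
  cat(sprintf("  (1) arm imbalance: %s (p = %.4g)\n",
              x$criterion1_groups_differ, x$criterion1_p))
  cat(sprintf("  (2) >=10%% beta change: %s (max %.1f%%)\n",
              x$criterion2_beta_change,
              100 * suppressWarnings(max(x$criterion2_pct_change,
                                         na.rm = TRUE))))
  cat(sprintf("  (3) outcome association: %s (min p = %.4g)\n",
              x$criterion3_outcome_assoc, min(x$criterion3_p)))
  cat("  confounder:", x$is_confounder, "\n")
  invisible(x)
}

#' Screen a baseline variable as a moderator of cost-effectiveness
#'
#' Fits `nb ~ arm + variable + arm:variable` at each WTP grid threshold on
#' each completion, pools by Rubin's rules, and records the two-sided pooled
#' p-value of the interaction per threshold (for a multi-level variable, the
#' minimum over the level-specific interaction terms). The variable is
#' flagged as a moderator when any pooled interaction p-value on the grid is
#' below `alpha`. No multiplicity correction is applied across grid points
#' (an exploratory screen; interpret accordingly).
#'
#' @inheritParams screen_confounder
#' @param grid WTP grid over which the interaction is tested.
#' @return A list of class `moderator_decision` with the per-threshold
#'   pooled interaction p-values, their minimum, and the flag.
#' @export
screen_moderator <- function(imps, variable,
                             perspective = c("health_system",
                                             "limited_societal"),
                             grid = wtp_grid_coarse(), alpha = 0.05,
                             period_days = NULL) {
  perspective <- match.arg(perspective)
  check_wtp_grid(grid)
  if (!variable %in% names(imps$completed[[1]])) {
    stop("candidate variable not found: ", variable)
  }
  if (imps$m < 2) stop("moderator screening pools over m >= 2 imputations")
  p_per_lambda <- vapply(grid, function(l) {
    fit <- nb_regression_mi(imps, l, perspective, moderator = variable,
                            period_days = period_days)
    its <- if (!is.null(fit$interaction_terms)) fit$interaction_terms
           else grep(paste0("^", fit$intervention_term, ":"),
                     fit$pooled$term, value = TRUE)
    min(fit$pooled$p.value[fit$pooled$term %in% its])
  }, numeric(1))
  structure(list(variable = variable, perspective = perspective,
                 grid = grid,
                 interaction_p = stats::setNames(p_per_lambda,
                                                 as.character(grid)),
                 min_p = min(p_per_lambda),
                 is_moderator = min(p_per_lambda) < alpha),
            class = "moderator_decision")
}

#' @export
print.moderator_decision <- function(x, ...) {
  cat("Moderator screen for `", x$variable, "` (", x$perspective, ")\n",
      sep = "")
  print(round(x$interaction_p, 4))
  cat(sprintf("  min p = %.4g -> moderator: %s\n", x$min_p, x$is_moderator))
  invisible(x)
}

#' Screening report over a set of candidate variables
#'
#' @param imps An `nbr_imputations` object.
#' @param confounder_candidates,moderator_candidates Character vectors of
#'   baseline column names.
#' @param perspective Costing perspective.
#' @param grid Moderator-screen WTP grid.
#' @param lambdas Confounder-screen WTP thresholds.
#' @param period_days Optional override of the AFD period lengths.
#' @return A list with `confounders` (list of decisions), `moderators`
#'   (list of decisions) and `table` (one row per candidate with flags and
#'   minimal p-values), of class `nbr_screening`.
#' @export
screen_candidates <- function(imps, confounder_candidates = character(),
                              moderator_candidates = character(),
                              perspective = c("health_system",
                                              "limited_societal"),
                              grid = wtp_grid_coarse(),
                              lambdas = c(0, 100), period_days = NULL) {
  perspective <- match.arg(perspective)
  confounders <- lapply(confounder_candidates, screen_confounder,
                        imps = imps, perspective = perspective,
                        lambdas = lambdas, period_days = period_days)
  names(confounders) <- confounder_candidates
  moderators <- lapply(moderator_candidates, screen_moderator,
                       imps = imps, perspective = perspective, grid = grid,
                       period_days = period_days)
  names(moderators) <- moderator_candidates
  rows <- list()
  for (d in confounders) {
    rows[[length(rows) + 1]] <- data.frame(
      variable = d$variable, role = "confounder",
      flag = d$is_confounder,
      evidence = sprintf("c1_p=%.4g;max_pct=%.3g;min_c3_p=%.4g",
                         d$criterion1_p,
                         suppressWarnings(max(d$criterion2_pct_change,
                                              na.rm = TRUE)),
                         min(d$criterion3_p)))
  }
  for (d in moderators) {
    rows[[length(rows) + 1]] <- data.frame(
      variable = d$variable, role = "moderator", flag = d$is_moderator,
      evidence = sprintf("min_interaction_p=%.4g", d$min_p))
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(), role = character(),
               flag = logical(), evidence = character())
  structure(list(confounders = confounders, moderators = moderators,
                 table = tab, perspective = perspective),
            class = "nbr_screening")
}
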