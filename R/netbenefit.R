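#' Willingness-to-pay grids
#'
#' `wtp_grid_coarse()` is the inference-table grid ($0-$60 by 10, then 80
#' and 100 per anxiety-free day); `wtp_grid_fine()` is the $1-step plotting
#' grid used for acceptability curves. Any strictly increasing nonnegative
#' vector is a valid grid.
#'
#' @return Numeric vector of WTP thresholds ($/AFD).
#' @export
wtp_grid_coarse <- function() c(0, 10, 20, 30, 40, 50, 60, 80, 100)

#' @rdname wtp_grid_coarse
#' @export
wtp_grid_fine <- function() 0:100

check_wtp_grid <- function(grid) {
  if (!length(grid) || any(grid < 0) || is.unsorted(grid, strictly = TRUE)) {
    stop("a WTP grid must be nonnegative and strictly increasing")
  }
  grid
}

#' Individual net benefits over a willingness-to-pay grid
#'
#' For each participant `i` and threshold `lambda`, the individual net
#' benefit is `nb_i(lambda) = lambda * E_i - C_i`, where `E_i` is total
#' anxiety-free days and `C_i` total cost. Each participant's row is exactly
#' affine in `lambda`, with slope `E_i` and intercept `-C_i`.
#'
#' @param afd Numeric vector of total AFDs per participant.
#' @param cost Numeric vector of total costs per participant ($), same
#'   order and length as `afd`.
#' @param grid WTP grid ($/AFD).
#' @param ids Optional participant identifiers (default positions).
#' @param perspective Costing perspective label.
#' @return An object of class `nb_matrix`: a list with the `ids x grid`
#'   matrix `nb`, the grid, and the inputs.
#' @export
compute_nb_matrix <- function(afd, cost, grid = wtp_grid_coarse(),
                              ids = NULL,
                              perspective = c("health_system",
                                              "limited_societal")) {
  perspective <- match.arg(perspective)
  check_wtp_grid(grid)
  if (length(afd) != length(cost)) {
    stop("`afd` and `cost` must describe the same participants")
  }
  if (anyNA(afd) || anyNA(cost)) {
    stop("`afd` and `cost` must be complete; impute before building ",
         "net benefits")
  }
  if (is.null(ids)) ids <- seq_along(afd)
  if (anyDuplicated(ids)) stop("participant ids must be unique")
  nb <- outer(afd, grid) - cost
  dimnames(nb) <- list(as.character(ids), as.character(grid))
  structure(list(nb = nb, grid = grid, ids = ids, afd = afd, cost = cost,
                 perspective = perspective),
            class = "nb_matrix")
}

#' Fit an OLS net-benefit regression at one WTP threshold
#'
#' Ordinary least squares of the individual net benefit on the arm
#' indicator, optional baseline covariates, and optionally a moderator with
#' its arm interaction: `nb ~ arm + covariates + moderator + arm:moderator`.
#' With the arm indicator alone, the intervention coefficient is the
#' difference in arm means of `nb` (the incremental net benefit) and the
#' intercept is the control-arm mean.
#'
#' @param nb Numeric vector of individual net benefits at one threshold.
#' @param arm Two-level factor (or vector coercible to one) with the control
#'   arm as reference level.
#' @param covariates Optional data.frame of baseline covariates (numeric or
#'   factor columns).
#' @param moderator Optional moderator vector. Values with at most
#'   `max_factor_levels` distinct values are indicator-coded against the
#'   lowest level as reference; otherwise the moderator enters linearly.
#' @param moderator_name Column label for the moderator in coefficient
#'   tables.
#' @param max_factor_levels See `moderator`.
#' @return An object of class `nb_fit` wrapping the `lm` fit, with
#'   coefficients, their covariance matrix, residual df, `n`, R-squared,
#'   the intervention-term name and the map from moderator level to
#'   interaction-term name.
#' @export
fit_nb_regression <- function(nb, arm, covariates = NULL, moderator = NULL,
                              moderator_name = "moderator",
                              max_factor_levels = 10) {
  arm <- as.factor(arm)
  if (nlevels(arm) != 2 || any(table(arm) < 2)) {
    stop("`arm` must have two levels with at least 2 participants each")
  }
  if (anyNA(nb)) stop("`nb` must be complete")
  df <- data.frame(nb = nb, arm = arm)
  rhs <- "arm"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (!nrow(covariates)) stop("`covariates` is empty")
    bad <- intersect(names(covariates), names(df))
    if (length(bad)) stop("reserved covariate names: ", paste(bad, collapse = ", "))
    df <- cbind(df, covariates)
    rhs <- c(rhs, sprintf("`%s`", names(covariates)))
  }
  mod_levels <- NULL
  if (!is.null(moderator)) {
    if (is.factor(moderator) || is.character(moderator) ||
        length(unique(moderator)) <= max_factor_levels) {
      moderator <- as.factor(moderator)
      mod_levels <- levels(moderator)
    }
    df[[moderator_name]] <- moderator
    rhs <- c(rhs, sprintf("`%s`", moderator_name),
             sprintf("arm:`%s`", moderator_name))
  }
  fml <- stats::as.formula(paste("nb ~", paste(rhs, collapse = " + ")))
  X <- stats::model.matrix(fml, df)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(fml, data = df)
  iv_term <- paste0("arm", levels(arm)[2])
  interaction_terms <- NULL
  if (!is.null(mod_levels)) {
    interaction_terms <- stats::setNames(
      paste0(iv_term, ":`", moderator_name, "`", mod_levels[-1]),
      mod_levels[-1])
    # lm may emit names without backticks depending on the label
    have <- names(stats::coef(fit))
    alt <- stats::setNames(paste0(iv_term, ":", moderator_name,
                                  mod_levels[-1]), mod_levels[-1])
    interaction_terms <- ifelse(interaction_terms %in% have,
                                interaction_terms, alt)
    names(interaction_terms) <- mod_levels[-1]
    if (!all(interaction_terms %in% have)) {
      stop("internal error: interaction terms not found in the fit")
    }
  }
  # a constant response makes summary()/vcov() warn about a perfect fit;
  # that degenerate case is legitimate here (all coefficients but the
  # intercept are zero)
  structure(list(lm = fit,
                 coefficients = stats::coef(fit),
                 vcov = suppressWarnings(stats::vcov(fit)),
                 df = stats::df.residual(fit),
                 n = nrow(df),
                 r.squared = suppressWarnings(summary(fit)$r.squared),
                 residuals = stats::residuals(fit),
                 intervention_term = iv_term,
                 interaction_terms = interaction_terms,
                 moderator_name = if (!is.null(moderator)) moderator_name,
                 moderator_levels = mod_levels,
                 arm = arm),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("Net-benefit regression (n =", x$n, ", residual df =", x$df, ")\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Incremental net benefit from a fitted model
#'
#' The intervention coefficient is the INB at the moderator reference level;
#' at level `k` the stratified INB is the intervention coefficient plus the
#' level-`k` interaction coefficient, with the standard error from the
#' stored coefficient covariance (for pooled fits, the linear combination is
#' pooled across imputations by Rubin's rules).
#'
#' @param fit An `nb_fit` or `nb_pooled` object.
#' @param moderator_level Optional moderator level label; `NULL` or the
#'   reference level gives the intervention coefficient itself.
#' @return A list with `estimate`, `se` and `df`.
#' @export
inb <- function(fit, moderator_level = NULL) UseMethod("inb")

# (estimate, variance) of beta1 [+ beta3k] from one fit
inb_combo <- function(fit, moderator_level) {
  iv <- fit$intervention_term
  b <- fit$coefficients
  V <- fit$vcov
  if (is.null(moderator_level) ||
      (!is.null(fit$moderator_levels) &&
       as.character(moderator_level) == fit$moderator_levels[1])) {
    return(c(b[[iv]], V[iv, iv]))
  }
  key <- as.character(moderator_level)
  if (is.null(fit$interaction_terms) || !key %in% names(fit$interaction_terms)) {
    stop("unknown moderator level: ", key)
  }
  it <- fit$interaction_terms[[key]]
  c(b[[iv]] + b[[it]], V[iv, iv] + V[it, it] + 2 * V[iv, it])
}

#' @export
inb.nb_fit <- function(fit, moderator_level = NULL) {
  ev <- inb_combo(fit, moderator_level)
  list(estimate = ev[1], se = sqrt(ev[2]), df = fit$df)
}

#' Cost-effectiveness acceptability curve
#'
#' For each WTP threshold, the probability that the (stratified) incremental
#' net benefit exceeds zero, computed from the one-sided t probability
#' `pt(estimate / se, df)` of the fitted (or Rubin-pooled) model — the
#' complement of the one-sided p-value against a positive intervention
#' effect.
#'
#' @param fits Named list of `nb_fit` or `nb_pooled` objects, names being
#'   the WTP thresholds.
#' @param moderator_level Optional level at which to stratify the curve.
#' @param stratum_label Label stored with the curve (defaults to the level).
#' @return A data.frame of class `nbr_ceac` with columns `wtp`,
#'   `probability` and `stratum`.
#' @seealso [ceac_threshold()]
#' @export
ceac <- function(fits, moderator_level = NULL, stratum_label = NULL) {
  if (!length(fits) || is.null(names(fits))) {
    stop("`fits` must be a list named by WTP threshold")
  }
  wtp <- as.numeric(names(fits))
  if (anyNA(wtp)) stop("names of `fits` must be numeric WTP values")
  prob <- vapply(fits, function(f) {
    v <- inb(f, moderator_level)
    stats::pt(v$estimate / v$se, df = v$df)
  }, numeric(1))
  if (is.null(stratum_label)) {
    stratum_label <- if (is.null(moderator_level)) "overall"
                     else as.character(moderator_level)
  }
  out <- data.frame(wtp = wtp, probability = unname(prob),
                    stratum = stratum_label)
  out <- out[order(out$wtp), ]
  rownames(out) <- NULL
  class(out) <- c("nbr_ceac", "data.frame")
  out
}

#' Smallest WTP at which the acceptability probability reaches a threshold
#'
#' @param x An `nbr_ceac` data.frame.
#' @param prob Probability threshold (default 0.95, the conventional
#'   decision rule).
#' @return The smallest grid WTP with probability at or above `prob`, or
#'   `NA` if none.
#' @export
ceac_threshold <- function(x, prob = 0.95) {
  hit <- x$wtp[x$probability >= prob]
  if (length(hit)) min(hit) else NA_real_
}
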