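#' Per-observation influence measures for a net-benefit regression
#'
#' Hat-matrix leverages, Cook's distances, standardized residuals and
#' DFBETAS from the standard leave-one-out closed forms, with the usual
#' size-adjusted flags: leverage above `3p/n` (p counting the intercept),
#' absolute DFBETAS at or above `2/sqrt(n)`, Cook's distance above `4/n`,
#' plus a secondary absolute Cook's threshold of 1.
#'
#' @param fit An `nb_fit` object.
#' @param ids Optional observation identifiers (defaults to the model-frame
#'   row names).
#' @param leverage_factor Multiplier of `p/n` for the leverage flag.
#' @param dfbetas_threshold Cutoff for |DFBETAS| (default `2/sqrt(n)`).
#' @param cooks_factor Numerator of the relative Cook's cutoff (default 4,
#'   i.e. `4/n`).
#' @param cooks_absolute Secondary absolute Cook's cutoff.
#' @return A list of class `nbr_influence`: `observations` (a data.frame of
#'   per-observation measures and flags), `thresholds`, and `flagged_ids`
#'   (ids flagged by any criterion).
#' @export
influence_measures <- function(fit, ids = NULL, leverage_factor = 3,
                               dfbetas_threshold = NULL, cooks_factor = 4,
                               cooks_absolute = 1) {
  if (!inherits(fit, "nb_fit")) stop("`fit` must be an nb_fit object")
  lmobj <- fit$lm
  n <- fit$n
  p <- length(fit$coefficients)
  if (n < p + 2) stop("influence measures need n >= p + 2 observations")
  if (is.null(ids)) ids <- rownames(stats::model.frame(lmobj))
  if (is.null(dfbetas_threshold)) dfbetas_threshold <- 2 / sqrt(n)

  lev <- unname(stats::hatvalues(lmobj))
  cd <- unname(stats::cooks.distance(lmobj))
  rs <- unname(stats::rstandard(lmobj))
  dfb <- stats::dfbetas(lmobj)
  colnames(dfb) <- paste0("dfbetas_", colnames(dfb))

  lev_cut <- leverage_factor * p / n
  cooks_cut <- cooks_factor / n
  flag_lev <- lev > lev_cut
  flag_dfb <- apply(abs(dfb) >= dfbetas_threshold, 1, any)
  flag_cd <- cd > cooks_cut | cd > cooks_absolute
  obs <- data.frame(id = ids, leverage = lev, cooks_d = cd,
                    std_residual = rs, dfb,
                    flag_leverage = flag_lev, flag_dfbetas = unname(flag_dfb),
                    flag_cooks = flag_cd,
                    flagged = flag_lev | unname(flag_dfb) | flag_cd,
                    check.names = FALSE)
  rownames(obs) <- NULL
  structure(list(observations = obs,
                 thresholds = c(leverage = lev_cut,
                                dfbetas = dfbetas_threshold,
                                cooks_relative = cooks_cut,
                                cooks_absolute = cooks_absolute),
                 flagged_ids = ids[obs$flagged],
                 n = n, p = p),
            class = "nbr_influence")
}

# SPSS-convention skewness/kurtosis z statistics (G1/G2 over their
# large-sample standard errors).
moments_z <- function(x) {
  n <- length(x)
  if (n < 8) stop("normality z-statistics need at least 8 residuals")
  g1 <- e1071::skewness(x, type = 2)
  g2 <- e1071::kurtosis(x, type = 2)
  se_skew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  se_kurt <- 2 * se_skew * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
  c(skewness = g1, skew_z = g1 / se_skew,
    kurtosis = g2, kurt_z = g2 / se_kurt)
}

#' Per-model regression checks
#'
#' Residual normality via skewness and kurtosis z-statistics against the
#' conventional |z| cutoff of 3.29; multicollinearity via variance inflation
#' factors against a cutoff of 10 (generalized VIFs for factor terms are
#' reported as the squared df-adjusted GVIF, comparable to a VIF);
#' homoscedasticity via Levene's test of net-benefit variance across arms
#' (mean-centered by default, the convention of mainstream commercial
#' statistics software; median-centering available).
#'
#' @param fit An `nb_fit` object.
#' @param z_threshold Normality flag cutoff (default 3.29).
#' @param vif_threshold Collinearity flag cutoff (default 10).
#' @param levene_center `mean` (default) or `median` centering for Levene's
#'   test.
#' @return A list of class `nbr_model_checks` with the normality
#'   statistics, the VIF table, the Levene statistic and p-value, and flags.
#' @export
model_checks <- function(fit, z_threshold = 3.29, vif_threshold = 10,
                         levene_center = c("mean", "median")) {
  if (!inherits(fit, "nb_fit")) stop("`fit` must be an nb_fit object")
  levene_center <- match.arg(levene_center)
  res <- fit$residuals
  mz <- moments_z(res)

  # VIFs need at least two non-intercept model terms
  n_terms <- length(attr(stats::terms(fit$lm), "term.labels"))
  vif_tab <- NULL
  if (n_terms >= 2) {
    v <- car::vif(fit$lm)
    if (is.matrix(v)) {
      vif_tab <- data.frame(term = rownames(v),
                            vif = v[, "GVIF^(1/(2*Df))"]^2)
    } else {
      vif_tab <- data.frame(term = names(v), vif = unname(v))
    }
    rownames(vif_tab) <- NULL
    vif_tab$flagged <- vif_tab$vif > vif_threshold
  }

  if (nlevels(fit$arm) < 2) stop("Levene's test needs at least 2 groups")
  nb_values <- stats::model.frame(fit$lm)$nb
  lev <- car::leveneTest(nb_values, fit$arm,
                         center = if (levene_center == "mean") mean
                                  else stats::median)
  structure(list(skewness = unname(mz["skewness"]),
                 skew_z = unname(mz["skew_z"]),
                 kurtosis = unname(mz["kurtosis"]),
                 kurt_z = unname(mz["kurt_z"]),
                 normality_flagged = any(abs(mz[c("skew_z", "kurt_z")]) >
                                           z_threshold),
                 z_threshold = z_threshold,
                 vif = vif_tab,
                 collinearity_flagged = !is.null(vif_tab) &&
                   any(vif_tab$flagged),
                 levene_statistic = lev[1, "F value"],
                 levene_p = lev[1, "Pr(>F)"],
                 levene_center = levene_center),
            class = "nbr_model_checks")
}

#' Aggregate influence flags across imputed datasets
#'
#' An observation is escalated when it is flagged (by any influence
#' criterion) in at least `min_count` completed datasets. Flagged points are
#' reported for inspection, never removed.
#'
#' @param reports List of `nbr_influence` reports, one per completion,
#'   sharing the same id universe.
#' @param min_count Minimum number of completions in which an observation
#'   must be flagged (default 5).
#' @return A data.frame with `id`, `count` (completions in which flagged)
#'   and `escalated`; ids meeting the rule are in attribute
#'   `escalated_ids`.
#' @export
flag_across_imputations <- function(reports, min_count = 5) {
  if (!length(reports)) stop("no diagnostics reports supplied")
  universe <- reports[[1]]$observations$id
  for (r in reports) {
    if (!identical(sort(r$observations$id), sort(universe))) {
      stop("diagnostics reports do not share the same id universe")
    }
  }
  counts <- table(unlist(lapply(reports, `[[`, "flagged_ids")))
  out <- data.frame(id = universe,
                    count = as.integer(counts[universe]))
  out$count[is.na(out$count)] <- 0L
  out$escalated <- out$count >= min_count
  attr(out, "escalated_ids") <- out$id[out$escalated]
  out
}

#' Residual-vs-fitted table for external linearity checks
#'
#' Exports standardized residuals against standardized fitted values so the
#' visual linearity/homoscedasticity inspection (smoother overlays) can be
#' done in any plotting tool.
#'
#' @param fit An `nb_fit` object.
#' @return data.frame with `fitted_std` and `residual_std`.
#' @export
residual_fitted_table <- function(fit) {
  f <- stats::fitted(fit$lm)
  data.frame(fitted_std = as.numeric(scale(f)),
             residual_std = unname(stats::rstandard(fit$lm)))
}
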