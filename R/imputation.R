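# ---- EM for the mean and covariance of a multivariate normal with
# ---- missing values, computed pattern-wise on standardized data.

solve_psd <- function(A, B) {
  out <- tryCatch(solve(A, B), error = function(e) NULL)
  if (is.null(out)) {  # ridge retry for near-singular observed blocks
    out <- solve(A + diag(1e-8 * mean(diag(A)) + 1e-12, nrow(A)), B)
  }
  out
}

em_mvnorm <- function(Y, tol = 1e-6, max_iter = 500) {
  p <- ncol(Y)
  n <- nrow(Y)
  all_missing <- colSums(!is.na(Y)) == 0
  if (any(all_missing)) {
    stop("variable(s) with zero observed values: ",
         paste(colnames(Y)[all_missing], collapse = ", "))
  }
  mu <- colMeans(Y, na.rm = TRUE)
  S <- stats::cov(Y, use = "pairwise.complete.obs")
  S[!is.finite(S)] <- 0
  ev <- eigen(S, symmetric = TRUE)
  floor_ev <- max(ev$values, 1e-6) * 1e-6
  S <- ev$vectors %*% diag(pmax(ev$values, floor_ev), p) %*% t(ev$vectors)

  pat <- apply(is.na(Y), 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat)
  miss_of <- lapply(groups, function(idx) which(is.na(Y[idx[1], ])))

  for (iter in seq_len(max_iter)) {
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      m <- miss_of[[g]]
      Yg <- Y[idx, , drop = FALSE]
      if (!length(m)) {
        T1 <- T1 + colSums(Yg)
        T2 <- T2 + crossprod(Yg)
        next
      }
      o <- setdiff(seq_len(p), m)
      B <- solve_psd(S[o, o, drop = FALSE], S[o, m, drop = FALSE])
      resid_o <- sweep(Yg[, o, drop = FALSE], 2, mu[o])
      Yg[, m] <- matrix(mu[m], length(idx), length(m), byrow = TRUE) +
        resid_o %*% B
      Cmm <- S[m, m, drop = FALSE] - crossprod(B, S[o, m, drop = FALSE])
      T1 <- T1 + colSums(Yg)
      TT <- crossprod(Yg)
      TT[m, m] <- TT[m, m] + length(idx) * Cmm
      T2 <- T2 + TT
    }
    mu_new <- T1 / n
    S_new <- T2 / n - tcrossprod(mu_new)
    delta <- max(abs(mu_new - mu), abs(S_new - S))
    mu <- mu_new
    S <- S_new
    if (delta < tol) {
      return(list(mu = mu, sigma = S, iterations = iter))
    }
  }
  stop("EM did not converge within the iteration cap of ", max_iter)
}

# Draw missing cells of Y from their conditional normal given the observed
# values, under (mu, S).
impute_from_mvnorm <- function(Y, mu, S) {
  p <- ncol(Y)
  pat <- apply(is.na(Y), 1, function(r) paste(as.integer(r), collapse = ""))
  for (key in unique(pat)) {
    idx <- which(pat == key)
    m <- which(is.na(Y[idx[1], ]))
    if (!length(m)) next
    o <- setdiff(seq_len(p), m)
    B <- solve_psd(S[o, o, drop = FALSE], S[o, m, drop = FALSE])
    resid_o <- sweep(Y[idx, o, drop = FALSE], 2, mu[o])
    cond_mean <- matrix(mu[m], length(idx), length(m), byrow = TRUE) +
      resid_o %*% B
    Cmm <- S[m, m, drop = FALSE] - crossprod(B, S[o, m, drop = FALSE])
    Cmm <- (Cmm + t(Cmm)) / 2
    ch <- tryCatch(chol(Cmm), error = function(e) {
      chol(Cmm + diag(1e-10 * (mean(diag(Cmm)) + 1), nrow(Cmm)))
    })
    draws <- matrix(stats::rnorm(length(idx) * length(m)), length(idx)) %*% ch
    Y[idx, m] <- cond_mean + draws
  }
  Y
}

follow_up_columns <- function() {
  c("bai_t1", "bai_t2", "cost_p1_hs", "cost_p2_hs", "cost_p1_soc",
    "cost_p2_soc")
}

default_imputation_vars <- function(trial) {
  base <- setdiff(names(trial), c("id", "arm", follow_up_columns()))
  c("arm", base, follow_up_columns()[follow_up_columns() %in% names(trial)])
}

#' Bootstrap-EM multiple imputation of missing follow-up data
#'
#' For each of `m` imputations: resample participants with replacement, run
#' EM to convergence for the mean and covariance of the joint variable set
#' under a multivariate-normal working model, then fill each missing cell of
#' the *original* data with a draw from its conditional distribution given
#' that participant's observed values. Draws are untransformed and
#' unbounded: negative imputed costs are possible by design and should be
#' audited with [audit_negative_costs()], not clipped.
#'
#' Binary covariates enter as 0/1 and are left continuous in the
#' completions (they are only ever used as regressors downstream, where
#' rounding would bias estimates).
#'
#' @param trial An `nbr_trial` data.frame; missingness must be confined to
#'   follow-up BAI and cost fields.
#' @param m Number of imputations (default 20).
#' @param model_vars Variables in the imputation model. Defaults to the arm
#'   indicator, all baseline covariates (including baseline BAI) and the
#'   follow-up outcome fields.
#' @param seed Integer seed; imputation `j` uses sub-stream `seed + j`.
#' @param tol,max_iter EM convergence control: stop when the largest
#'   absolute change in any (standardized-scale) mean or covariance entry
#'   falls below `tol`, error past `max_iter` sweeps.
#' @return An object of class `nbr_imputations`: list with `m`, `completed`
#'   (list of completed datasets), `model_vars`, `seed` and the original
#'   data.
#' @export
em_bootstrap_impute <- function(trial, m = 20, model_vars = NULL, seed = 1,
                                tol = 1e-6, max_iter = 500) {
  if (m < 1) stop("`m` must be at least 1 (>= 2 for pooling)")
  if (is.null(model_vars)) model_vars <- default_imputation_vars(trial)
  missing_vars <- setdiff(model_vars, names(trial))
  if (length(missing_vars)) {
    stop("model variables absent from the data: ",
         paste(missing_vars, collapse = ", "))
  }
  fup <- intersect(follow_up_columns(), names(trial))
  base_vars <- setdiff(model_vars, fup)
  if (anyNA(trial[base_vars])) {
    stop("missingness must be confined to follow-up fields; baseline ",
         "model variables are incomplete")
  }
  if (anyNA(trial[setdiff(names(trial), c(model_vars, fup))])) {
    stop("columns outside the imputation model contain missing values")
  }
  to_numeric <- function(x, nm) {
    if (is.numeric(x)) return(x)
    if (is.factor(x) && nlevels(x) == 2) return(as.numeric(x) - 1)
    if (is.logical(x)) return(as.numeric(x))
    stop("imputation model variable `", nm, "` is not numeric or binary")
  }
  Y <- vapply(model_vars, function(nm) to_numeric(trial[[nm]], nm),
              numeric(nrow(trial)))
  colnames(Y) <- model_vars

  has_missing <- anyNA(Y)
  # standardize (scale-free EM tolerance); constants get unit scale
  ctr <- colMeans(Y, na.rm = TRUE)
  scl <- apply(Y, 2, stats::sd, na.rm = TRUE)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Z <- sweep(sweep(Y, 2, ctr), 2, scl, "/")

  completed <- vector("list", m)
  for (j in seq_len(m)) {
    comp <- trial
    if (has_missing) {
      set.seed(seed + j)
      boot <- Z[sample(nrow(Z), replace = TRUE), , drop = FALSE]
      fitem <- em_mvnorm(boot, tol = tol, max_iter = max_iter)
      Zj <- impute_from_mvnorm(Z, fitem$mu, fitem$sigma)
      Yj <- sweep(sweep(Zj, 2, scl, "*"), 2, ctr, "+")
      for (nm in fup) {
        filled <- is.na(comp[[nm]])
        comp[[nm]][filled] <- Yj[filled, nm]
      }
    }
    completed[[j]] <- comp
  }
  structure(list(m = m, completed = completed, model_vars = model_vars,
                 seed = seed, original = trial),
            class = "nbr_imputations")
}

#' @export
print.nbr_imputations <- function(x, ...) {
  cat("Multiple imputation set: m =", x$m, ", n =", nrow(x$original),
      "participants,", length(x$model_vars), "model variables\n")
  invisible(x)
}

#' Fraction of negative imputed total costs
#'
#' Imputation draws are not bounded below, so some completed total costs can
#' be negative; this audit reports their share over all participant-by-
#' completion totals for one perspective (it never alters the completions).
#'
#' @param imps An `nbr_imputations` object.
#' @param perspective Costing perspective.
#' @return Fraction in \[0, 1\].
#' @export
audit_negative_costs <- function(imps,
                                 perspective = c("health_system",
                                                 "limited_societal")) {
  perspective <- match.arg(perspective)
  sfx <- if (perspective == "health_system") "hs" else "soc"
  totals <- unlist(lapply(imps$completed, function(d) {
    d[[paste0("cost_p1_", sfx)]] + d[[paste0("cost_p2_", sfx)]]
  }))
  mean(totals < 0)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate = mean of the per-imputation estimates; within-imputation
#' variance `W` = mean of the per-imputation variances; between-imputation
#' variance `B` = sample variance of the estimates; total variance
#' `T = W + (1 + 1/m) B`. Degrees of freedom use the Barnard-Rubin
#' small-sample adjustment when the complete-data residual df is finite.
#'
#' @param estimates m-by-p matrix (or vector for p = 1) of per-imputation
#'   coefficient estimates, columns aligned by name.
#' @param variances Matching m-by-p matrix of squared standard errors.
#' @param dfcom Complete-data residual degrees of freedom (scalar;
#'   `Inf` gives the classic large-sample df).
#' @return A data.frame of class `nbr_pooled_est` with one row per
#'   coefficient: `estimate`, `W`, `B`, `T`, `se`, `df`, `statistic`,
#'   `p.value` (two-sided).
#' @export
rubin_pool <- function(estimates, variances, dfcom = Inf) {
  if (is.null(dim(estimates))) estimates <- cbind(estimate = estimates)
  if (is.null(dim(variances))) variances <- cbind(estimate = variances)
  m <- nrow(estimates)
  if (m < 2) stop("pooling requires m >= 2 imputations")
  if (!identical(dim(estimates), dim(variances))) {
    stop("`estimates` and `variances` must have matching dimensions")
  }
  if (!is.null(colnames(estimates)) && !is.null(colnames(variances)) &&
      !identical(colnames(estimates), colnames(variances))) {
    stop("coefficient names of `estimates` and `variances` are misaligned")
  }
  qbar <- colMeans(estimates)
  W <- colMeans(variances)
  B <- apply(estimates, 2, stats::var)
  Tv <- W + (1 + 1 / m) * B
  lambda <- (1 + 1 / m) * B / Tv
  lambda <- pmin(pmax(lambda, 0), 1 - 1e-12)
  df_old <- ifelse(lambda > 0, (m - 1) / lambda^2, Inf)
  if (is.finite(dfcom)) {
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df <- 1 / (1 / df_old + 1 / df_obs)
  } else {
    df <- df_old
  }
  se <- sqrt(Tv)
  stat <- qbar / se
  out <- data.frame(term = if (is.null(colnames(estimates)))
                      paste0("q", seq_along(qbar)) else colnames(estimates),
                    estimate = unname(qbar), W = unname(W), B = unname(B),
                    T = unname(Tv), se = unname(se), df = unname(df),
                    statistic = unname(stat),
                    p.value = unname(2 * stats::pt(-abs(stat), df)))
  attr(out, "m") <- m
  class(out) <- c("nbr_pooled_est", "data.frame")
  out
}

#' Multiply-imputed net-benefit regression at one WTP threshold
#'
#' Computes total AFDs and total costs on every completed dataset, builds
#' the individual net benefit at `lambda`, fits the requested model on each
#' completion with [fit_nb_regression()], and pools coefficients by Rubin's
#' rules.
#'
#' @param imps An `nbr_imputations` object.
#' @param lambda WTP threshold ($/AFD).
#' @param perspective Costing perspective.
#' @param covariates Optional character vector of covariate column names.
#' @param moderator Optional moderator column name (indicator-coded with its
#'   arm interaction).
#' @param period_days Optional override of the AFD period lengths.
#' @return An object of class `nb_pooled`: per-completion `nb_fit`s plus the
#'   pooled coefficient table.
#' @export
nb_regression_mi <- function(imps, lambda,
                             perspective = c("health_system",
                                             "limited_societal"),
                             covariates = NULL, moderator = NULL,
                             period_days = NULL) {
  perspective <- match.arg(perspective)
  sfx <- if (perspective == "health_system") "hs" else "soc"
  fits <- lapply(imps$completed, function(d) {
    eff <- afd_table(d, period_days = period_days, clip = TRUE)$afd_total
    cost <- d[[paste0("cost_p1_", sfx)]] + d[[paste0("cost_p2_", sfx)]]
    nb <- lambda * eff - cost
    fit_nb_regression(
      nb, d$arm,
      covariates = if (!is.null(covariates)) d[covariates],
      moderator = if (!is.null(moderator)) d[[moderator]],
      moderator_name = if (!is.null(moderator)) moderator else "moderator")
  })
  est <- do.call(rbind, lapply(fits, function(f) f$coefficients))
  vars <- do.call(rbind, lapply(fits, function(f) diag(f$vcov)))
  pooled <- if (imps$m >= 2) rubin_pool(est, vars, dfcom = fits[[1]]$df)
            else NULL
  structure(list(lambda = lambda, perspective = perspective,
                 fits = fits, pooled = pooled, m = imps$m,
                 intervention_term = fits[[1]]$intervention_term,
                 interaction_terms = fits[[1]]$interaction_terms,
                 moderator_levels = fits[[1]]$moderator_levels,
                 dfcom = fits[[1]]$df),
            class = "nb_pooled")
}

#' @export
inb.nb_pooled <- function(fit, moderator_level = NULL) {
  if (fit$m < 2) return(inb(fit$fits[[1]], moderator_level))
  ev <- vapply(fit$fits, inb_combo, numeric(2),
               moderator_level = moderator_level)
  pooled <- rubin_pool(cbind(inb = ev[1, ]), cbind(inb = ev[2, ]),
                       dfcom = fit$dfcom)
  list(estimate = pooled$estimate, se = pooled$se, df = pooled$df)
}

#' @export
print.nb_pooled <- function(x, ...) {
  cat("Pooled net-benefit regression at WTP $", x$lambda, "/AFD (",
      x$perspective, ", m = ", x$m, ")\n", sep = "")
  if (!is.null(x$pooled)) print(x$pooled)
  invisible(x)
}

#' Round-trip completed datasets as one long CSV
#'
#' Writes completions as a single CSV with an `imputation` column;
#' `read_imputations()` restores the `nbr_imputations` structure (without
#' the original incomplete data unless supplied).
#'
#' @param imps An `nbr_imputations` object.
#' @param path CSV path.
#' @param original Optional original dataset to re-attach on read.
#' @return The path (write) or an `nbr_imputations` object (read).
#' @export
write_imputations <- function(imps, path) {
  long <- do.call(rbind, lapply(seq_len(imps$m), function(j) {
    cbind(imputation = j, as.data.frame(imps$completed[[j]]))
  }))
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_imputations
#' @export
read_imputations <- function(path, original = NULL) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  long$arm <- factor(long$arm, levels = c("control", "treatment"))
  completed <- lapply(split(long, long$imputation), function(d) {
    d$imputation <- NULL
    rownames(d) <- NULL
    class(d) <- c("nbr_trial", "data.frame")
    d
  })
  structure(list(m = length(completed), completed = unname(completed),
                 model_vars = NULL, seed = NULL,
                 original = original),
            class = "nbr_imputations")
}
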