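#' Configuration for a synthetic two-arm trial
#'
#' Defines the data-generating conditions for a synthetic randomized trial
#' with known cost and effectiveness structure, so downstream net-benefit
#' analyses have a parameter-recovery oracle ([true_inb()]).
#'
#' Costs are gamma-distributed by arm, perspective and period (right-skewed,
#' nonnegative), parameterized by the control-arm mean total and a shape;
#' the gamma scale is derived as mean/shape so configured mean contrasts
#' hold exactly in expectation. BAI trajectories are truncated normal on the
#' 0-63 instrument range; the treatment-arm post-baseline means are
#' calibrated numerically so that the expected anxiety-free-day contrast
#' equals `true_delta_afd` (plus the per-level moderator interaction)
#' exactly.
#'
#' The moderator is a single ordinal baseline covariate with integer levels
#' `0 .. moderator_levels - 1` (the comorbid-anxiety-count coding:
#' none/one/two/three). Its interactions shift the treatment-arm mean total
#' cost by `moderator_cost_interaction` dollars per level and the expected
#' treatment-arm AFD total by `moderator_afd_interaction` days per level.
#'
#' @param n_treat,n_control Arm sizes (defaults 117 and 114).
#' @param period_days Two between-assessment period lengths in days.
#' @param true_delta_cost Treatment-minus-control mean total cost ($) at the
#'   moderator reference level, applied to both perspectives.
#' @param true_delta_afd Treatment-minus-control expected total AFDs (days)
#'   at the moderator reference level.
#' @param moderator_levels Number of ordinal moderator levels.
#' @param moderator_prevalence Probability of each moderator level
#'   (length `moderator_levels`, sums to 1).
#' @param moderator_cost_interaction $ added to the treatment-arm mean total
#'   cost per moderator level (negative values mean larger savings with more
#'   comorbidity).
#' @param moderator_afd_interaction Days added to the treatment-arm expected
#'   AFD total per moderator level.
#' @param cost_shape Gamma shape for per-period costs (< 3 gives the right
#'   skew typical of mental-health cost data).
#' @param cost_mean_control Named control-arm mean total costs per
#'   perspective (`health_system`, `limited_societal`).
#' @param cost_period_split Fraction of the mean total cost accruing in each
#'   period (length 2, sums to 1).
#' @param bai_mean_control Control-arm mean BAI at T0, T1, T2 (the treatment
#'   arm shares the T0 mean; its T1/T2 means are calibrated).
#' @param bai_sd BAI standard deviation (scale-score units) before
#'   truncation to \[0, 63\].
#' @param covariate_prevalences Named probabilities of binary baseline
#'   covariates.
#' @param covariate_arm_shift Optional named treatment-minus-control
#'   prevalence differences (residual randomization imbalance); each half of
#'   the shift is applied symmetrically around the marginal prevalence.
#' @param covariate_cost_effect Optional named $ shifts of the mean total
#'   cost per unit of the covariate, applied in both arms (a covariate with
#'   both an arm shift and a cost effect is a true confounder).
#' @param age_mean,age_sd Continuous age covariate parameters (clamped to
#'   the 18-65 eligibility window).
#' @param missing_rate_t1,missing_rate_t2 Marginal probabilities that an
#'   assessment (BAI and that period's costs jointly) is missing.
#' @param mar_coefficients Named log-odds-per-unit coefficients of baseline
#'   variables in the missingness model; the intercept is calibrated so the
#'   marginal rate matches `missing_rate_*` (MAR mechanism; empty vector
#'   gives MCAR).
#' @param seed Master seed; covariates, outcomes and missingness use
#'   distinct sub-streams derived from it.
#' @return An object of class `trial_config`.
#' @seealso [generate_trial()], [impose_missingness()], [true_inb()]
#' @export
trial_config <- function(n_treat = 117,
                         n_control = 114,
                         period_days = c(122, 122),
                         true_delta_cost = 2200,
                         true_delta_afd = 34,
                         moderator_levels = 4,
                         moderator_prevalence = c(0.25, 0.40, 0.25, 0.10),
                         moderator_cost_interaction = -2000,
                         moderator_afd_interaction = 4,
                         cost_shape = 1.5,
                         cost_mean_control = c(health_system = 2500,
                                               limited_societal = 5000),
                         cost_period_split = c(0.5, 0.5),
                         bai_mean_control = c(22, 18, 17),
                         bai_sd = 10,
                         covariate_prevalences = c(female = 0.857,
                                                   principal_gad = 0.528,
                                                   principal_sad = 0.15,
                                                   comorbid_pd = 0.30,
                                                   comorbid_depression = 0.24),
                         covariate_arm_shift = c(principal_gad = 0.10,
                                                 principal_sad = -0.06,
                                                 comorbid_pd = 0.08),
                         covariate_cost_effect = NULL,
                         age_mean = 37, age_sd = 12,
                         missing_rate_t1 = 0.19,
                         missing_rate_t2 = 0.23,
                         mar_coefficients = c(bai_t0 = 0.03),
                         seed = 1L) {
  cfg <- list(n_treat = n_treat, n_control = n_control,
              period_days = period_days,
              true_delta_cost = true_delta_cost,
              true_delta_afd = true_delta_afd,
              moderator_levels = moderator_levels,
              moderator_prevalence = moderator_prevalence,
              moderator_cost_interaction = moderator_cost_interaction,
              moderator_afd_interaction = moderator_afd_interaction,
              cost_shape = cost_shape,
              cost_mean_control = cost_mean_control,
              cost_period_split = cost_period_split,
              bai_mean_control = bai_mean_control,
              bai_sd = bai_sd,
              covariate_prevalences = covariate_prevalences,
              covariate_arm_shift = covariate_arm_shift,
              covariate_cost_effect = covariate_cost_effect,
              age_mean = age_mean, age_sd = age_sd,
              missing_rate_t1 = missing_rate_t1,
              missing_rate_t2 = missing_rate_t2,
              mar_coefficients = mar_coefficients,
              seed = as.integer(seed))
  class(cfg) <- "trial_config"
  validate_trial_config(cfg)
  cfg
}

validate_trial_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid trial configuration: `", field, "` ", why, call. = FALSE)
  }
  if (!is.numeric(cfg$n_treat) || cfg$n_treat < 2) fail("n_treat", "must be >= 2")
  if (!is.numeric(cfg$n_control) || cfg$n_control < 2) fail("n_control", "must be >= 2")
  if (length(cfg$period_days) != 2 || any(cfg$period_days <= 0)) {
    fail("period_days", "must be two positive day counts")
  }
  if (cfg$moderator_levels < 1) fail("moderator_levels", "must be >= 1")
  mp <- cfg$moderator_prevalence
  if (length(mp) != cfg$moderator_levels || any(mp < 0) ||
      abs(sum(mp) - 1) > 1e-8) {
    fail("moderator_prevalence",
         "must be `moderator_levels` probabilities summing to 1")
  }
  if (cfg$cost_shape <= 0) fail("cost_shape", "must be strictly positive")
  if (any(cfg$cost_mean_control <= 0)) {
    fail("cost_mean_control", "must be strictly positive")
  }
  if (!all(c("health_system", "limited_societal") %in%
           names(cfg$cost_mean_control))) {
    fail("cost_mean_control",
         "must name `health_system` and `limited_societal`")
  }
  if (length(cfg$cost_period_split) != 2 || any(cfg$cost_period_split <= 0) ||
      abs(sum(cfg$cost_period_split) - 1) > 1e-8) {
    fail("cost_period_split", "must be two positive fractions summing to 1")
  }
  if (length(cfg$bai_mean_control) != 3) {
    fail("bai_mean_control", "must give means at T0, T1 and T2")
  }
  if (cfg$bai_sd <= 0) fail("bai_sd", "must be strictly positive")
  pv <- cfg$covariate_prevalences
  if (length(pv) && (is.null(names(pv)) || any(pv < 0 | pv > 1))) {
    fail("covariate_prevalences", "must be named probabilities in [0, 1]")
  }
  shift <- cfg$covariate_arm_shift
  if (length(shift)) {
    if (is.null(names(shift)) || !all(names(shift) %in% names(pv))) {
      fail("covariate_arm_shift", "names must match covariate_prevalences")
    }
    p_t <- pv[names(shift)] + shift / 2
    p_c <- pv[names(shift)] - shift / 2
    if (any(c(p_t, p_c) < 0 | c(p_t, p_c) > 1)) {
      fail("covariate_arm_shift", "pushes an arm prevalence outside [0, 1]")
    }
  }
  eff <- cfg$covariate_cost_effect
  if (length(eff) && (is.null(names(eff)) ||
                      !all(names(eff) %in% c(names(pv), "age")))) {
    fail("covariate_cost_effect",
         "names must match covariate_prevalences (or `age`)")
  }
  for (f in c("missing_rate_t1", "missing_rate_t2")) {
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) fail(f, "must lie in [0, 1)")
  }
  if (!is.finite(cfg$seed) || abs(cfg$seed) > 2^31 - 10) {
    fail("seed", "must be an integer below 2^31")
  }
  invisible(cfg)
}

# Truncated-normal draws on [lo, hi] by inverse-CDF (vectorized in `mean`).
rtnorm <- function(n, mean, sd, lo = 0, hi = 63) {
  pa <- stats::pnorm(lo, mean, sd)
  pb <- stats::pnorm(hi, mean, sd)
  x <- stats::qnorm(pa + stats::runif(n) * (pb - pa), mean, sd)
  pmin(hi, pmax(lo, x))
}

# E[AFD weight] when BAI ~ TruncNormal(mu, sd) on [0, 63].
expected_afd_weight <- function(mu, sd, cutoff_free = 7, cutoff_anxious = 26) {
  denom <- stats::pnorm(63, mu, sd) - stats::pnorm(0, mu, sd)
  f <- function(x) {
    bai_to_afd_weight(x, cutoff_free, cutoff_anxious) * stats::dnorm(x, mu, sd)
  }
  stats::integrate(f, 0, 63, rel.tol = 1e-10)$value / denom
}

# Expected total AFD for a (mu0, mu1, mu2) truncated-normal BAI trajectory.
expected_total_afd <- function(mu, sd, period_days) {
  m <- vapply(mu, expected_afd_weight, numeric(1), sd = sd)
  period_days[1] * (m[1] + m[2]) / 2 + period_days[2] * (m[2] + m[3]) / 2
}

# Uniform shift of the T1/T2 BAI means achieving a target expected AFD total.
calibrate_bai_shift <- function(target_afd, mu, sd, period_days) {
  g <- function(delta) {
    expected_total_afd(c(mu[1], mu[2] + delta, mu[3] + delta), sd,
                       period_days) - target_afd
  }
  lo <- -90; hi <- 90
  if (g(lo) * g(hi) > 0) {
    stop("configured AFD contrast is unattainable on the 0-",
         sum(period_days), " day range for this BAI trajectory")
  }
  stats::uniroot(g, c(lo, hi), tol = 1e-9)$root
}

#' Generate a complete synthetic trial
#'
#' Draws baseline covariates, the ordinal moderator, truncated-normal BAI
#' trajectories and gamma per-period costs under two perspectives, per the
#' configuration. The output carries no missing values; apply
#' [impose_missingness()] to degrade follow-ups under a MAR mechanism.
#'
#' @param config A [trial_config()].
#' @return A data.frame of class `nbr_trial` with one row per participant:
#'   `id`, `arm` (factor, control reference), binary covariates, `age`,
#'   `n_comorbid_anx` (the moderator), `bai_t0/t1/t2` and per-period costs
#'   `cost_p1_hs`, `cost_p2_hs`, `cost_p1_soc`, `cost_p2_soc`. The
#'   configuration is attached as attribute `config`.
#' @export
generate_trial <- function(config) {
  if (!inherits(config, "trial_config")) {
    stop("`config` must be a trial_config object")
  }
  validate_trial_config(config)
  n_t <- config$n_treat
  n_c <- config$n_control
  n <- n_t + n_c
  arm <- factor(rep(c("treatment", "control"), c(n_t, n_c)),
                levels = c("control", "treatment"))
  is_t <- arm == "treatment"

  # sub-stream 1: baseline covariates and moderator
  set.seed(config$seed)
  dat <- data.frame(id = sprintf("P%04d", seq_len(n)), arm = arm)
  pv <- config$covariate_prevalences
  shift <- config$covariate_arm_shift
  for (nm in names(pv)) {
    p <- rep(pv[[nm]], n)
    if (nm %in% names(shift)) {
      p <- p + ifelse(is_t, shift[[nm]] / 2, -shift[[nm]] / 2)
    }
    dat[[nm]] <- as.integer(stats::runif(n) < p)
  }
  dat$age <- pmin(65, pmax(18, stats::rnorm(n, config$age_mean, config$age_sd)))
  lev <- 0:(config$moderator_levels - 1)
  dat$n_comorbid_anx <- sample(lev, n, replace = TRUE,
                               prob = config$moderator_prevalence)

  # sub-stream 2: BAI trajectories (treatment T1/T2 means calibrated per level)
  set.seed(config$seed + 1L)
  mu_c <- config$bai_mean_control
  sd_b <- config$bai_sd
  base_afd <- expected_total_afd(mu_c, sd_b, config$period_days)
  shift_by_level <- vapply(lev, function(k) {
    target <- base_afd + config$true_delta_afd +
      k * config$moderator_afd_interaction
    calibrate_bai_shift(target, mu_c, sd_b, config$period_days)
  }, numeric(1))
  mu1 <- ifelse(is_t, mu_c[2] + shift_by_level[dat$n_comorbid_anx + 1], mu_c[2])
  mu2 <- ifelse(is_t, mu_c[3] + shift_by_level[dat$n_comorbid_anx + 1], mu_c[3])
  dat$bai_t0 <- rtnorm(n, mu_c[1], sd_b)
  dat$bai_t1 <- rtnorm(n, mu1, sd_b)
  dat$bai_t2 <- rtnorm(n, mu2, sd_b)

  # sub-stream 3: gamma costs per perspective x period
  set.seed(config$seed + 2L)
  cov_shift <- rep(0, n)
  eff <- config$covariate_cost_effect
  for (nm in names(eff)) cov_shift <- cov_shift + eff[[nm]] * dat[[nm]]
  suffix <- c(health_system = "hs", limited_societal = "soc")
  for (persp in names(suffix)) {
    mean_total <- config$cost_mean_control[[persp]] + cov_shift +
      ifelse(is_t,
             config$true_delta_cost +
               dat$n_comorbid_anx * config$moderator_cost_interaction,
             0)
    for (p in 1:2) {
      mu_p <- pmax(mean_total * config$cost_period_split[p], 1e-8)
      col <- paste0("cost_p", p, "_", suffix[[persp]])
      dat[[col]] <- stats::rgamma(n, shape = config$cost_shape,
                                  scale = mu_p / config$cost_shape)
    }
  }
  attr(dat, "config") <- config
  class(dat) <- c("nbr_trial", "data.frame")
  dat
}

#' Degrade follow-up assessments under a missing-at-random mechanism
#'
#' Sets T1 and/or T2 assessments missing jointly (the BAI score and that
#' period's costs under both perspectives) with probability given by a
#' logistic model on baseline variables. The intercept is calibrated on the
#' dataset at hand so the marginal missingness rate matches the configured
#' `missing_rate_t1` / `missing_rate_t2`; covariate log-odds come from
#' `mar_coefficients`. Baseline fields are never degraded.
#'
#' @param trial A complete `nbr_trial` data.frame.
#' @param config A [trial_config()]; defaults to the one attached to
#'   `trial`.
#' @return The trial with follow-up cells set to `NA`; deterministic given
#'   the configuration seed (uses its own sub-stream, so it is reproducible
#'   independently of generation).
#' @export
impose_missingness <- function(trial, config = attr(trial, "config")) {
  if (is.null(config)) stop("no trial_config supplied or attached")
  validate_trial_config(config)
  t1_cols <- c("bai_t1", "cost_p1_hs", "cost_p1_soc")
  t2_cols <- c("bai_t2", "cost_p2_hs", "cost_p2_soc")
  if (anyNA(trial[c(t1_cols, t2_cols)])) {
    stop("`trial` already has missing follow-ups; supply the complete dataset")
  }
  coefs <- config$mar_coefficients
  if (length(coefs)) {
    bad <- setdiff(names(coefs), names(trial))
    if (length(bad)) {
      stop("mar_coefficients name baseline variables absent from the data: ",
           paste(bad, collapse = ", "))
    }
    if (anyNA(trial[names(coefs)])) {
      stop("baseline variables used in the missingness model must be complete")
    }
    lp <- as.matrix(trial[names(coefs)]) %*% coefs
  } else {
    lp <- rep(0, nrow(trial))
  }
  draw_missing <- function(rate) {
    if (rate == 0) return(rep(FALSE, nrow(trial)))
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lp)) - rate,
                         c(-40, 40), tol = 1e-10)$root
    stats::runif(nrow(trial)) < stats::plogis(b0 + lp)
  }
  set.seed(config$seed + 3L)  # dedicated missingness sub-stream
  miss1 <- draw_missing(config$missing_rate_t1)
  miss2 <- draw_missing(config$missing_rate_t2)
  trial[miss1, t1_cols] <- NA_real_
  trial[miss2, t2_cols] <- NA_real_
  trial
}

#' True incremental net benefit implied by a configuration
#'
#' Closed form, no simulation: at willingness-to-pay `wtp` ($/AFD) the
#' incremental net benefit is `wtp * delta_AFD - delta_cost`, with the
#' per-level moderator interactions added when `moderator_level` is given.
#'
#' @param config A [trial_config()].
#' @param wtp Willingness-to-pay threshold(s), $ per anxiety-free day
#'   (nonnegative; vectorized).
#' @param moderator_level Optional moderator level (0-based). `NULL` gives
#'   the reference-level contrast.
#' @return INB in dollars.
#' @export
true_inb <- function(config, wtp, moderator_level = NULL) {
  validate_trial_config(config)
  if (any(wtp < 0)) stop("`wtp` must be nonnegative")
  k <- 0
  if (!is.null(moderator_level)) {
    if (!moderator_level %in% 0:(config$moderator_levels - 1)) {
      stop("`moderator_level` must be in 0..", config$moderator_levels - 1)
    }
    k <- moderator_level
  }
  d_afd <- config$true_delta_afd + k * config$moderator_afd_interaction
  d_cost <- config$true_delta_cost + k * config$moderator_cost_interaction
  wtp * d_afd - d_cost
}

#' Write / read a trial dataset as CSV with a YAML configuration sidecar
#'
#' One participant per row; missing values as empty cells. When the dataset
#' carries a generating configuration it is written alongside as YAML so a
#' run can be reproduced from disk.
#'
#' @param trial An `nbr_trial` data.frame.
#' @param path CSV path.
#' @param config_path YAML sidecar path (default `<path>.config.yaml`);
#'   `NA` suppresses the sidecar.
#' @return `write_trial()` returns `path` invisibly; `read_trial()` returns
#'   an `nbr_trial` data.frame (with the configuration re-attached when the
#'   sidecar is found).
#' @export
write_trial <- function(trial, path,
                        config_path = paste0(path, ".config.yaml")) {
  utils::write.csv(as.data.frame(trial), path, row.names = FALSE, na = "")
  cfg <- attr(trial, "config")
  if (!is.null(cfg) && !is.na(config_path)) {
    out <- lapply(unclass(cfg), function(x) {
      # yaml drops names of atomic vectors; store named ones as maps
      if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
    })
    yaml::write_yaml(out, config_path)
  }
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path, config_path = paste0(path, ".config.yaml")) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  dat$arm <- factor(dat$arm, levels = c("control", "treatment"))
  if (!is.na(config_path) && file.exists(config_path)) {
    cfg <- yaml::read_yaml(config_path)
    for (nm in c("cost_mean_control", "covariate_prevalences",
                 "covariate_arm_shift", "covariate_cost_effect",
                 "mar_coefficients")) {
      if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
    }
    if (!"covariate_cost_effect" %in% names(cfg)) {
      cfg["covariate_cost_effect"] <- list(NULL)
    }
    cfg$seed <- as.integer(cfg$seed)
    class(cfg) <- "trial_config"
    attr(dat, "config") <- validate_trial_config(cfg)
  }
  class(dat) <- c("nbr_trial", "data.frame")
  dat
}

#' Complete-case availability by arm and assessment
#'
#' Counts participants with an available BAI score and cost data at each
#' follow-up, by arm, with percentages of those randomized (the
#' complete-case attrition summary usually reported alongside imputation).
#'
#' @param trial An `nbr_trial` data.frame (possibly with missing follow-ups).
#' @return data.frame with columns `arm`, `assessment`, `n_randomized`,
#'   `n_observed`, `pct_observed` (one decimal).
#' @export
attrition_summary <- function(trial) {
  obs_t1 <- stats::complete.cases(trial[c("bai_t1", "cost_p1_hs")])
  obs_t2 <- stats::complete.cases(trial[c("bai_t2", "cost_p2_hs")])
  out <- do.call(rbind, lapply(levels(trial$arm), function(a) {
    sel <- trial$arm == a
    data.frame(arm = a, assessment = c("T1", "T2"),
               n_randomized = sum(sel),
               n_observed = c(sum(obs_t1 & sel), sum(obs_t2 & sel)))
  }))
  out$pct_observed <- round(100 * out$n_observed / out$n_randomized, 1)
  out
}
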