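#' Convert a BAI total into an anxiety-free-day weight
#'
#' Maps a Beck Anxiety Inventory (BAI) total score to the fraction of a day
#' considered free of anxiety. A score at or below the minimal-anxiety cutoff
#' counts as a full anxiety-free day (weight 1); a score at or above the
#' severe-anxiety cutoff counts as a day with anxiety (weight 0); scores in
#' between are weighted linearly, the standard symptom-free-day convention.
#'
#' @param score Numeric vector of BAI totals. The instrument range is 0-63.
#' @param cutoff_free Minimal-anxiety cutoff (default 7): scores at or below
#'   map to weight 1.
#' @param cutoff_anxious Severe-anxiety cutoff (default 26): scores at or
#'   above map to weight 0.
#' @param clip If `FALSE` (default), scores outside \[0, 63\] or missing
#'   scores are an error: missingness must be resolved by imputation before
#'   effectiveness is computed. If `TRUE`, out-of-range scores (e.g.
#'   unbounded multiply-imputed draws) are accepted; the weight saturates at
#'   the cutoffs so any score at or below `cutoff_free` still maps to 1 and
#'   any score at or above `cutoff_anxious` maps to 0.
#' @return Numeric vector of weights in \[0, 1\], non-increasing in `score`.
#' @examples
#' bai_to_afd_weight(c(0, 7, 16.5, 26, 63))
#' @export
bai_to_afd_weight <- function(score, cutoff_free = 7, cutoff_anxious = 26,
                              clip = FALSE) {
  if (!is.numeric(cutoff_free) || !is.numeric(cutoff_anxious) ||
      cutoff_free >= cutoff_anxious) {
    stop("`cutoff_free` must be strictly below `cutoff_anxious`")
  }
  if (anyNA(score)) {
    stop("BAI scores must not be missing; impute missing assessments first")
  }
  if (!clip && any(score < 0 | score > 63)) {
    stop("BAI totals must lie in [0, 63] (set `clip = TRUE` to saturate ",
         "out-of-range values at the cutoffs)")
  }
  w <- (cutoff_anxious - score) / (cutoff_anxious - cutoff_free)
  pmin(1, pmax(0, w))
}

#' Anxiety-free days accrued over one between-assessment period
#'
#' Integrates the linearly interpolated anxiety-free-day weight between two
#' assessments, giving the trapezoid `n_days * (w_start + w_end) / 2`.
#'
#' @param w_start,w_end AFD weights in \[0, 1\] at the period's two
#'   assessments.
#' @param n_days Length of the period in days (> 0).
#' @return Days free of anxiety over the period, in \[0, n_days\].
#' @export
afd_for_period <- function(w_start, w_end, n_days) {
  if (any(n_days <= 0)) stop("`n_days` must be positive")
  if (any(w_start < 0 | w_start > 1 | w_end < 0 | w_end > 1)) {
    stop("AFD weights must lie in [0, 1]")
  }
  n_days * (w_start + w_end) / 2
}

#' Total anxiety-free days over the full assessment horizon
#'
#' Composes [bai_to_afd_weight()] and [afd_for_period()] over the two
#' between-assessment periods (baseline to post-treatment, post-treatment to
#' follow-up). With the default 122-day periods the attainable range is
#' exactly 0 to 244 days.
#'
#' @param bai_t0,bai_t1,bai_t2 BAI totals at the three assessments
#'   (vectorized; recycled to a common length).
#' @param period_days Length-2 vector of period lengths in days
#'   (default `c(122, 122)`, the 8-month horizon).
#' @param clip Passed to [bai_to_afd_weight()].
#' @inheritParams bai_to_afd_weight
#' @return A data.frame with columns `afd_p1`, `afd_p2` and
#'   `afd_total = afd_p1 + afd_p2`.
#' @examples
#' total_afd(5, 3, 7)          # maximal: 244 anxiety-free days
#' total_afd(30, 40, 26)       # all weights zero
#' @export
total_afd <- function(bai_t0, bai_t1, bai_t2, period_days = c(122, 122),
                      cutoff_free = 7, cutoff_anxious = 26, clip = FALSE) {
  if (length(period_days) != 2 || any(period_days <= 0)) {
    stop("`period_days` must be two positive day counts")
  }
  w0 <- bai_to_afd_weight(bai_t0, cutoff_free, cutoff_anxious, clip)
  w1 <- bai_to_afd_weight(bai_t1, cutoff_free, cutoff_anxious, clip)
  w2 <- bai_to_afd_weight(bai_t2, cutoff_free, cutoff_anxious, clip)
  p1 <- afd_for_period(w0, w1, period_days[1])
  p2 <- afd_for_period(w1, w2, period_days[2])
  data.frame(afd_p1 = p1, afd_p2 = p2, afd_total = p1 + p2)
}

#' Per-participant anxiety-free days for a trial dataset
#'
#' @param trial A trial data.frame (see [generate_trial()] or
#'   [read_trial()]) with columns `id`, `bai_t0`, `bai_t1`, `bai_t2`.
#' @param period_days Length-2 period lengths in days; defaults to the
#'   generating configuration's value when the dataset carries one.
#' @param clip Passed to [bai_to_afd_weight()]; use `TRUE` on multiply
#'   imputed completions, whose draws are not range-restricted.
#' @return data.frame with columns `id`, `afd_p1`, `afd_p2`, `afd_total`.
#' @export
afd_table <- function(trial, period_days = NULL, clip = FALSE) {
  need <- c("id", "bai_t0", "bai_t1", "bai_t2")
  if (!all(need %in% names(trial))) {
    stop("`trial` must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(period_days)) {
    cfg <- attr(trial, "config")
    period_days <- if (!is.null(cfg)) cfg$period_days else c(122, 122)
  }
  out <- total_afd(trial$bai_t0, trial$bai_t1, trial$bai_t2,
                   period_days = period_days, clip = clip)
  cbind(data.frame(id = trial$id), out)
}
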