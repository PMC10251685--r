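test_that("generated trials have the configured arm sizes and valid fields", {
  cfg <- trial_config(seed = 5)
  tr <- generate_trial(cfg)
  expect_equal(nrow(tr), 231)
  expect_equal(as.integer(table(tr$arm)), c(114L, 117L))
  expect_false(anyDuplicated(tr$id) > 0)
  expect_false(anyNA(tr))
  bai <- c(tr$bai_t0, tr$bai_t1, tr$bai_t2)
  expect_true(all(bai >= 0 & bai <= 63))
  costs <- unlist(tr[grep("^cost_", names(tr))])
  expect_true(all(costs >= 0))
  expect_true(all(tr$n_comorbid_anx %in% 0:3))
})

test_that("generation is bit-identical under one seed and differs across seeds", {
  cfg <- test_config(seed = 21)
  expect_identical(generate_trial(cfg), generate_trial(cfg))
  tr2 <- generate_trial(test_config(seed = 22))
  expect_false(identical(generate_trial(cfg)$bai_t0, tr2$bai_t0))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(trial_config(n_treat = 1), "n_treat")
  expect_error(trial_config(cost_shape = 0), "cost_shape")
  expect_error(trial_config(moderator_prevalence = c(0.5, 0.5)),
               "moderator_prevalence")
  expect_error(trial_config(missing_rate_t1 = 1.2), "missing_rate_t1")
  expect_error(trial_config(covariate_arm_shift = c(nonexistent = 0.1)),
               "covariate_arm_shift")
})

test_that("costs are right-skewed for gamma shapes below 3", {
  tr <- generate_trial(test_config(n = 2000, seed = 8))
  total <- tr$cost_p1_hs + tr$cost_p2_hs
  expect_gt(e1071::skewness(total), 0)
})

test_that("arm contrasts converge to the configured cost and AFD deltas", {
  cfg <- trial_config(n_treat = 20000, n_control = 20000,
                      true_delta_cost = 1500, true_delta_afd = 25,
                      moderator_cost_interaction = 0,
                      moderator_afd_interaction = 0,
                      covariate_arm_shift = NULL, seed = 91)
  tr <- generate_trial(cfg)
  treat <- tr$arm == "treatment"
  contrast_se <- function(x) {
    sqrt(var(x[treat]) / sum(treat) + var(x[!treat]) / sum(!treat))
  }
  cost <- tr$cost_p1_hs + tr$cost_p2_hs
  d_cost <- mean(cost[treat]) - mean(cost[!treat])
  expect_lt(abs(d_cost - 1500), 3 * contrast_se(cost))
  afd <- afd_table(tr)$afd_total
  d_afd <- mean(afd[treat]) - mean(afd[!treat])
  expect_lt(abs(d_afd - 25), 3 * contrast_se(afd))
  # societal costs carry the same configured delta
  soc <- tr$cost_p1_soc + tr$cost_p2_soc
  expect_lt(abs(mean(soc[treat]) - mean(soc[!treat]) - 1500),
            3 * contrast_se(soc))
})

test_that("a null configuration yields a null AFD contrast", {
  cfg <- trial_config(n_treat = 5000, n_control = 5000, true_delta_afd = 0,
                      true_delta_cost = 0, moderator_cost_interaction = 0,
                      moderator_afd_interaction = 0,
                      covariate_arm_shift = NULL, seed = 13)
  tr <- generate_trial(cfg)
  afd <- afd_table(tr)$afd_total
  treat <- tr$arm == "treatment"
  se <- sqrt(var(afd[treat]) / 5000 + var(afd[!treat]) / 5000)
  expect_lt(abs(mean(afd[treat]) - mean(afd[!treat])), 3 * se)
})

test_that("per-level arm AFD contrasts track the configured interaction", {
  cfg <- trial_config(n_treat = 5000, n_control = 5000, true_delta_afd = 10,
                      moderator_afd_interaction = 10,
                      moderator_prevalence = rep(0.25, 4),
                      moderator_cost_interaction = 0,
                      covariate_arm_shift = NULL, seed = 17)
  tr <- generate_trial(cfg)
  afd <- afd_table(tr)$afd_total
  fit <- lm(afd ~ arm * n_comorbid_anx, data = cbind(tr, afd = afd))
  slope <- coef(fit)[["armtreatment:n_comorbid_anx"]]
  se <- sqrt(vcov(fit)["armtreatment:n_comorbid_anx",
                       "armtreatment:n_comorbid_anx"])
  expect_lt(abs(slope - 10), 3 * se)
})

test_that("missingness hits the configured marginal rate and is MAR-faithful", {
  cfg <- trial_config(n_treat = 5000, n_control = 5000,
                      missing_rate_t1 = 0.20, missing_rate_t2 = 0,
                      mar_coefficients = c(female = 0.8), seed = 41)
  tr <- impose_missingness(generate_trial(cfg), cfg)
  miss <- is.na(tr$bai_t1)
  # binomial tolerance around the calibrated marginal rate
  expect_lt(abs(mean(miss) - 0.20), 3 * sqrt(0.2 * 0.8 / nrow(tr)))
  # BAI and that period's costs go missing jointly
  expect_identical(miss, is.na(tr$cost_p1_hs))
  expect_identical(miss, is.na(tr$cost_p1_soc))
  expect_false(anyNA(tr$bai_t2))
  # log-odds on the binary covariate is recovered
  or_fit <- glm(miss ~ female, family = binomial, data = tr)
  expect_lt(abs(coef(or_fit)[["female"]] - 0.8),
            3 * sqrt(vcov(or_fit)["female", "female"]))
})

test_that("zero missingness rates are a no-op and baselines are never degraded", {
  cfg <- test_config(missing_rate_t1 = 0, missing_rate_t2 = 0)
  tr <- generate_trial(cfg)
  expect_identical(impose_missingness(tr, cfg), tr)
  cfg2 <- test_config(missing_rate_t1 = 0.4, missing_rate_t2 = 0.4)
  tr2 <- impose_missingness(generate_trial(cfg2), cfg2)
  expect_false(anyNA(tr2[c("bai_t0", "age", "n_comorbid_anx")]))
  # reproducible independently of generation
  expect_identical(tr2, impose_missingness(generate_trial(cfg2), cfg2))
  bad <- test_config(mar_coefficients = c(not_a_column = 1))
  expect_error(impose_missingness(generate_trial(test_config()), bad),
               "not_a_column")
})

test_that("true_inb reduces to the closed-form INB arithmetic", {
  cfg <- trial_config(true_delta_afd = 20, true_delta_cost = 400,
                      moderator_afd_interaction = 3,
                      moderator_cost_interaction = -100)
  expect_equal(true_inb(cfg, 0), -400)
  expect_equal(true_inb(cfg, 20), 0)
  expect_equal(true_inb(cfg, 50), 600)
  expect_equal(true_inb(cfg, 50, moderator_level = 2),
               50 * 26 - 200)
  expect_error(true_inb(cfg, -1), "nonnegative")
  expect_error(true_inb(cfg, 10, moderator_level = 9), "moderator_level")
})

test_that("trial CSV and configuration sidecar round-trip", {
  cfg <- test_config(n = 15, missing_rate_t1 = 0.3)
  tr <- impose_missingness(generate_trial(cfg), cfg)
  path <- file.path(tempdir(), "trial-roundtrip.csv")
  write_trial(tr, path)
  back <- read_trial(path)
  expect_equal(as.data.frame(tr), as.data.frame(back))
  cfg_back <- attr(back, "config")
  expect_equal(cfg_back$missing_rate_t1, 0.3)
  expect_identical(generate_trial(cfg_back), generate_trial(cfg))
  unlink(c(path, paste0(path, ".config.yaml")))
})
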