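test_that("Rubin pooling reproduces the two-point worked example", {
  pooled <- rubin_pool(c(1, 3), c(1, 1), dfcom = 100)
  expect_equal(pooled$estimate, 2)
  expect_equal(pooled$W, 1)
  expect_equal(pooled$B, 2)
  expect_equal(pooled$T, 1 + 1.5 * 2)
  # identical estimates: no between-imputation variance
  same <- rubin_pool(rep(5, 4), rep(2, 4), dfcom = 50)
  expect_equal(same$estimate, 5)
  expect_equal(same$B, 0)
  expect_equal(same$T, 2)
})

test_that("Rubin pooling matches the textbook-formula oracle", {
  set.seed(61)
  for (i in 1:25) {
    m <- sample(3:20, 1)
    q <- rnorm(m, 10, 2)
    u <- rgamma(m, 3, rate = 2)
    dfcom <- sample(c(20, 200, Inf), 1)
    got <- rubin_pool(q, u, dfcom = dfcom)
    want <- rubin_oracle(q, u, dfcom = dfcom)
    expect_equal(got$estimate, want$estimate, tolerance = 1e-12)
    expect_equal(got$W, want$W, tolerance = 1e-12)
    expect_equal(got$B, want$B, tolerance = 1e-12)
    expect_equal(got$T, want$T, tolerance = 1e-12)
    expect_equal(got$df, want$df, tolerance = 1e-9)
    expect_equal(got$p.value, want$p, tolerance = 1e-9)
    # invariance to permuting completions, and T >= W always
    perm <- sample(m)
    expect_equal(rubin_pool(q[perm], u[perm], dfcom = dfcom), got)
    expect_gte(got$T, got$W)
  }
  expect_error(rubin_pool(1, 1), "m >= 2")
  expect_error(rubin_pool(cbind(a = 1:3, b = 1:3),
                          cbind(a = rep(1, 3), c = rep(1, 3))), "misaligned")
})

test_that("complete data passes through imputation unchanged", {
  tr <- generate_trial(test_config(n = 25, seed = 62))
  imps <- em_bootstrap_impute(tr, m = 3, seed = 7)
  for (j in 1:3) expect_identical(imps$completed[[j]], tr)
  expect_equal(audit_negative_costs(imps), 0)
  expect_equal(audit_negative_costs(imps, "limited_societal"), 0)
})

test_that("bootstrap-EM fills every missing follow-up cell plausibly", {
  cfg <- test_config(n = 80, seed = 63, missing_rate_t1 = 0.25,
                     missing_rate_t2 = 0.25)
  tr <- impose_missingness(generate_trial(cfg), cfg)
  imps <- em_bootstrap_impute(tr, m = 4, seed = 3)
  miss_t1 <- is.na(tr$bai_t1)
  for (comp in imps$completed) {
    expect_false(anyNA(comp))
    # baseline fields identical across completions
    expect_identical(comp$bai_t0, tr$bai_t0)
    expect_identical(comp$arm, tr$arm)
    # observed cells untouched
    expect_identical(comp$bai_t1[!miss_t1], tr$bai_t1[!miss_t1])
  }
  # stochastic draws differ across completions on imputed cells
  expect_false(identical(imps$completed[[1]]$bai_t1[miss_t1],
                         imps$completed[[2]]$bai_t1[miss_t1]))
  # deterministic given the seed
  imps2 <- em_bootstrap_impute(tr, m = 4, seed = 3)
  expect_identical(lapply(imps$completed, as.data.frame),
                   lapply(imps2$completed, as.data.frame))
  # audit is a read-only fraction in [0, 1]
  frac <- audit_negative_costs(imps)
  expect_gte(frac, 0)
  expect_lte(frac, 1)
})

test_that("EM errors on unusable inputs", {
  cfg <- test_config(n = 30, seed = 64, missing_rate_t1 = 0.3)
  tr <- impose_missingness(generate_trial(cfg), cfg)
  tr$bai_t1 <- NA_real_
  expect_error(em_bootstrap_impute(tr, m = 2, seed = 1),
               "zero observed values")
  tr2 <- impose_missingness(generate_trial(cfg), cfg)
  tr2$age[3] <- NA
  expect_error(em_bootstrap_impute(tr2, m = 2, seed = 1), "baseline")
  tr3 <- impose_missingness(generate_trial(cfg), cfg)
  expect_error(em_bootstrap_impute(tr3, m = 2, seed = 1, max_iter = 1),
               "iteration cap")
})

test_that("EM recovers the mean and covariance under MCAR at scale", {
  set.seed(65)
  n <- 3000
  mu <- c(2, -1)
  S <- matrix(c(4, 1.5, 1.5, 2), 2)
  Y <- MASS::mvrnorm(n, mu, S)
  Y[runif(n) < 0.3, 1] <- NA
  Y[runif(n) < 0.2, 2] <- NA
  Y <- Y[rowSums(is.na(Y)) < 2, ]
  fit <- nbreg:::em_mvnorm(Y)
  expect_equal(unname(fit$mu), mu, tolerance = 0.15)
  expect_equal(unname(fit$sigma), unname(S), tolerance = 0.2)
})

test_that("pooled results converge to the complete-data fit as missingness vanishes", {
  cfg <- test_config(n = 150, seed = 66, missing_rate_t1 = 0,
                     missing_rate_t2 = 0)
  tr <- generate_trial(cfg)
  imps <- em_bootstrap_impute(tr, m = 2, seed = 5)
  pooled <- nb_regression_mi(imps, 50, "health_system")
  single <- pooled$fits[[1]]
  iv <- single$intervention_term
  expect_equal(pooled$pooled$estimate[pooled$pooled$term == iv],
               unname(single$coefficients[iv]), tolerance = 1e-12)
  expect_equal(pooled$pooled$B, rep(0, nrow(pooled$pooled)))
  v <- inb(pooled)
  expect_equal(v$estimate, inb(single)$estimate, tolerance = 1e-12)
  expect_equal(v$se, inb(single)$se, tolerance = 1e-12)
})

test_that("imputed BAI draws are unbounded but saturate in the AFD mapping", {
  cfg <- trial_config(n_treat = 150, n_control = 150, seed = 67,
                      bai_mean_control = c(10, 8, 8), bai_sd = 9,
                      missing_rate_t1 = 0.3, missing_rate_t2 = 0.3)
  tr <- impose_missingness(generate_trial(cfg), cfg)
  imps <- em_bootstrap_impute(tr, m = 5, seed = 11)
  all_bai <- unlist(lapply(imps$completed, function(d) c(d$bai_t1, d$bai_t2)))
  # near-floor trajectories push some normal draws below 0: kept, not clipped
  expect_true(any(all_bai < 0))
  tab <- afd_table(imps$completed[[1]], clip = TRUE)
  expect_true(all(tab$afd_total >= 0 & tab$afd_total <= 244))
  expect_error(afd_table(imps$completed[[1]]), "\\[0, 63\\]")
})

test_that("completions round-trip through the long-CSV interchange format", {
  cfg <- test_config(n = 50, seed = 68, missing_rate_t1 = 0.3)
  tr <- impose_missingness(generate_trial(cfg), cfg)
  imps <- em_bootstrap_impute(tr, m = 3, seed = 2,
                              model_vars = c("arm", "bai_t0", "bai_t1",
                                             "bai_t2", "cost_p1_hs",
                                             "cost_p2_hs", "cost_p1_soc",
                                             "cost_p2_soc"))
  path <- file.path(tempdir(), "imps-roundtrip.csv")
  write_imputations(imps, path)
  back <- read_imputations(path, original = tr)
  expect_equal(back$m, 3)
  strip <- function(d) {
    attr(d, "config") <- NULL
    as.data.frame(d)
  }
  for (j in 1:3) {
    expect_equal(strip(back$completed[[j]]), strip(imps$completed[[j]]),
                 tolerance = 1e-12)
  }
  unlink(path)
})
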