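test_that("individual net benefits are exactly affine in the threshold", {
  m <- compute_nb_matrix(afd = 100, cost = 500, grid = c(0, 10, 100),
                         ids = "a")
  expect_equal(unname(m$nb["a", ]), c(-500, 500, 9500))
  m2 <- compute_nb_matrix(afd = 244, cost = 0, grid = c(100), ids = "b")
  expect_equal(unname(m2$nb["b", "100"]), 24400)
  set.seed(51)
  afd <- runif(40, 0, 244)
  cost <- rgamma(40, 2, scale = 1500)
  grid <- sort(sample(0:100, 6))
  nbm <- compute_nb_matrix(afd, cost, grid)
  for (j in 2:length(grid)) {
    expect_equal(unname(nbm$nb[, j] - nbm$nb[, 1]),
                 (grid[j] - grid[1]) * afd, tolerance = 1e-12)
  }
  expect_error(compute_nb_matrix(afd[1:3], cost[1:2], grid), "same")
  expect_error(compute_nb_matrix(c(1, NA), c(1, 1), grid), "complete")
  expect_error(compute_nb_matrix(afd, cost, c(10, 5)), "increasing")
})

test_that("the unadjusted fit recovers arm means and the INB", {
  nb <- c(10, 20, 0, 2)
  arm <- factor(c("treatment", "treatment", "control", "control"),
                levels = c("control", "treatment"))
  fit <- fit_nb_regression(nb, arm)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 1)
  expect_equal(unname(fit$coefficients["armtreatment"]), 14)
  # degenerate constant response
  fit0 <- fit_nb_regression(rep(3, 10), rep(c("control", "treatment"), 5))
  expect_equal(unname(fit0$coefficients), c(3, 0))
})

test_that("OLS coefficients match the normal-equations oracle", {
  set.seed(52)
  for (i in 1:20) {
    n <- 30
    arm <- factor(rep(c("control", "treatment"), n / 2))
    covs <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
    nb <- rnorm(n, 100, 50)
    fit <- fit_nb_regression(nb, arm, covariates = covs)
    X <- cbind(1, as.numeric(arm) - 1, covs$x1, covs$x2)
    expect_equal(unname(fit$coefficients), ols_normal_equations(X, nb),
                 tolerance = 1e-10)
  }
})

test_that("rank-deficient designs fail naming the collinear column", {
  set.seed(53)
  n <- 20
  arm <- factor(rep(c("control", "treatment"), n / 2))
  covs <- data.frame(dup = as.numeric(arm) - 1)
  expect_error(fit_nb_regression(rnorm(n), arm, covariates = covs),
               "collinear.*dup")
})

test_that("stratified INB matches the re-parameterization oracle", {
  set.seed(54)
  n <- 120
  arm <- factor(sample(c("control", "treatment"), n, TRUE),
                levels = c("control", "treatment"))
  mod <- factor(sample(0:2, n, TRUE))
  nb <- rnorm(n, 500, 300) + 200 * (arm == "treatment") * as.numeric(mod)
  fit <- fit_nb_regression(nb, arm, moderator = mod)
  for (k in c("1", "2")) {
    target <- inb(fit, moderator_level = k)
    refit <- fit_nb_regression(nb, arm, moderator = relevel(mod, ref = k))
    oracle <- inb(refit)
    expect_equal(target$estimate, oracle$estimate, tolerance = 1e-10)
    expect_equal(target$se, oracle$se, tolerance = 1e-10)
  }
  expect_error(inb(fit, moderator_level = "7"), "unknown moderator level")
  # explicit sum rule on a synthetic covariance
  f2 <- fit
  f2$coefficients <- c("(Intercept)" = 0, armtreatment = 5,
                       mod1 = 0, mod2 = 0,
                       "armtreatment:moderator1" = 3,
                       "armtreatment:moderator2" = 0)
  f2$vcov <- diag(1, 6)
  dimnames(f2$vcov) <- list(names(f2$coefficients), names(f2$coefficients))
  f2$interaction_terms <- c("1" = "armtreatment:moderator1",
                            "2" = "armtreatment:moderator2")
  v <- inb(f2, "1")
  expect_equal(v$estimate, 8)
  expect_equal(v$se, sqrt(2))
})

test_that("the acceptability curve is the one-sided t probability", {
  # estimate zero -> probability one half
  nb <- c(-1, 1, 1, -1)
  arm <- factor(rep(c("control", "treatment"), 2))
  fit <- fit_nb_regression(nb, arm)
  cc <- ceac(list("0" = fit))
  expect_equal(cc$probability, 0.5)
  # t of 1.645 with large df approaches 0.95
  set.seed(55)
  n <- 4000
  arm2 <- factor(rep(c("control", "treatment"), n / 2))
  y <- rnorm(n)
  fit2 <- fit_nb_regression(y, arm2)
  iv <- fit2$intervention_term
  shift <- 1.645 * sqrt(fit2$vcov[iv, iv]) - fit2$coefficients[[iv]]
  fit3 <- fit_nb_regression(y + shift * (arm2 == "treatment"), arm2)
  cc3 <- ceac(list("10" = fit3))
  expect_equal(cc3$probability, 0.95, tolerance = 1e-3)
})

test_that("unadjusted CEAC equals the pooled-variance t-test probability", {
  tr <- generate_trial(test_config(n = 80, seed = 56))
  afd <- afd_table(tr)$afd_total
  cost <- tr$cost_p1_hs + tr$cost_p2_hs
  grid <- wtp_grid_coarse()
  fits <- lapply(grid, function(l) fit_nb_regression(l * afd - cost, tr$arm))
  names(fits) <- grid
  cc <- ceac(fits)
  for (j in seq_along(grid)) {
    nb <- grid[j] * afd - cost
    tt <- t.test(nb[tr$arm == "treatment"], nb[tr$arm == "control"],
                 var.equal = TRUE, alternative = "greater")
    expect_equal(cc$probability[j], unname(1 - tt$p.value),
                 tolerance = 1e-6)
  }
})

test_that("unadjusted INB limits match the closed forms exactly", {
  tr <- generate_trial(test_config(n = 50, seed = 57))
  afd <- afd_table(tr)$afd_total
  cost <- tr$cost_p1_hs + tr$cost_p2_hs
  treat <- tr$arm == "treatment"
  d_e <- mean(afd[treat]) - mean(afd[!treat])
  d_c <- mean(cost[treat]) - mean(cost[!treat])
  inb_at <- function(l) {
    inb(fit_nb_regression(l * afd - cost, tr$arm))$estimate
  }
  expect_equal(inb_at(0), -d_c, tolerance = 1e-10)           # lambda -> 0
  expect_equal(inb_at(1) - inb_at(0), d_e, tolerance = 1e-10) # slope in lambda
  # break-even threshold equals the classical ICER when delta-E > 0
  expect_gt(d_e, 0)
  icer <- d_c / d_e
  expect_equal(inb_at(icer), 0, tolerance = 1e-8)
})

test_that("acceptability probability rises with the INB t-statistic", {
  probs <- sapply(seq(-3, 3, by = 0.5), function(t) pt(t, df = 40))
  expect_true(all(diff(probs) > 0))
  cc <- data.frame(wtp = c(0, 10, 20), probability = c(0.5, 0.96, 0.99))
  class(cc) <- c("nbr_ceac", "data.frame")
  expect_equal(ceac_threshold(cc), 10)
  expect_true(is.na(ceac_threshold(cc, prob = 0.999)))
})
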