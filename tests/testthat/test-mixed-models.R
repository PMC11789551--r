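test_that("Laplace GLMM collapses to plain logistic regression at zero brood variance", {
  # zero-variance data: fixed effects must match a hand-rolled IRLS fit
  for (s in 1:5) {
    cfg <- study_config(seed = 200 + s, sigma_origin = 0, sigma_rearing = 0,
                        n_cpgs = 1)
    d <- simulate_design(cfg)
    sim <- simulate_methylation(cfg, d)
    obs <- which(!is.na(sim$matrix$cov[1, ]))
    m <- sim$matrix$meth[1, obs]
    n <- sim$matrix$cov[1, obs]
    # held at the zero boundary, the Laplace fit IS logistic regression
    fit0 <- fit_glmm(m, n, d[obs, ], sigma_fixed = c(1e-6, 1e-6))
    X <- nestmeth:::build_fixed_X(~ treatment * sex, d[obs, ])
    oracle <- irls_logistic(X, m, n)
    expect_lt(max(abs(fit0$beta - oracle$beta)), 1e-3)
    expect_lt(abs(fit0$loglik - oracle$loglik), 1e-3)
    expect_true(fit0$singular)
    # the free ML fit may put small positive mass on the SDs (sampling
    # noise), moving the fixed effects only slightly
    fit <- fit_glmm(m, n, d[obs, ])
    expect_lt(max(abs(fit$beta - oracle$beta)), 0.05)
    expect_true(all(fit$sigma < 0.25))
  }
})

test_that("Laplace GLMM agrees with the independent lme4 implementation", {
  skip_if_not_installed("lme4")
  cfg <- study_config(seed = 211, sigma_origin = 0.4, sigma_rearing = 0.3,
                      n_cpgs = 3)
  d <- simulate_design(cfg)
  sim <- simulate_methylation(cfg, d)
  dd <- transform(d,
                  treatment = factor(treatment,
                                     c("control", "testosterone")),
                  sex = factor(sex, c("F", "M")))
  for (i in 1:3) {
    obs <- which(!is.na(sim$matrix$cov[i, ]))
    m <- sim$matrix$meth[i, obs]
    n <- sim$matrix$cov[i, obs]
    fit <- fit_glmm(m, n, d[obs, ])
    ref <- lme4::glmer(cbind(m, n - m) ~ treatment * sex +
                         (1 | brood_origin) + (1 | brood_rearing),
                       data = dd[obs, ], family = binomial, nAGQ = 0)
    expect_lt(max(abs(fit$beta - lme4::fixef(ref))), 1e-3)
    expect_lt(abs(fit$loglik - as.numeric(logLik(ref))), 1e-3)
    ref1 <- lme4::glmer(cbind(m, n - m) ~ treatment * sex +
                          (1 | brood_origin) + (1 | brood_rearing),
                        data = dd[obs, ], family = binomial)
    expect_lt(max(abs(fit$beta - lme4::fixef(ref1))), 0.05)
  }
})

test_that("degenerate responses are flagged as separation, not returned as estimates", {
  d <- manual_design(n_per_cell = 8)
  n <- rep(20, nrow(d))
  fit0 <- fit_glmm(rep(0, nrow(d)), n, d)
  expect_false(fit0$converged)
  expect_equal(fit0$reason, "separation")
  fit1 <- fit_glmm(n, n, d)
  expect_false(fit1$converged)
  expect_equal(fit1$reason, "separation")
})

test_that("likelihood-ratio test follows the chi-square reference", {
  mk <- function(ll, p) structure(list(loglik = ll, p_fixed = p,
                                       converged = TRUE, n_obs = 50,
                                       response_checksum = c(1, 2),
                                       beta = setNames(rep(0, p),
                                                       paste0("b", 1:p))),
                                  class = "glmm_fit")
  expect_equal(lrt(mk(-10, 4), mk(-10, 3)),
               list(statistic = 0, df = 1, p = 1))
  out <- lrt(mk(-10, 4), mk(-10 - 3.841 / 2, 3))
  expect_equal(out$statistic, 3.841)
  expect_equal(out$p, 0.05, tolerance = 1e-3)
  # numerical noise below the floor is clamped to zero
  out0 <- lrt(mk(-10 - 1e-9, 4), mk(-10, 3))
  expect_equal(out0$statistic, 0)
  expect_equal(out0$p, 1)
  expect_error(lrt(mk(-10, 3), mk(-10, 3)), "same number")
  bad <- mk(-10, 3); bad$converged <- FALSE
  expect_error(lrt(mk(-10, 4), bad), "converged")
})

test_that("Pearson dispersion is calibrated for binomial data and large for beta-binomial", {
  cfg <- sim_config(seed = 221, n_brood_pairs = 16, brood_size_mean = 16,
                    sigma_origin = 0.3, sigma_rearing = 0.2, n_cpgs = 16,
                    coverage_mean = 30)
  d <- simulate_design(cfg)                 # ~500 observations per site
  sim <- simulate_methylation(cfg, d)
  phis <- vapply(1:16, function(i) {
    obs <- which(!is.na(sim$matrix$cov[i, ]))
    fit <- fit_glmm(sim$matrix$meth[i, obs], sim$matrix$cov[i, obs],
                    d[obs, ])
    pearson_dispersion(fit)
  }, 0)
  expect_lt(abs(mean(phis) - 1), 0.1)
  cfg_bb <- sim_config(seed = 223, n_brood_pairs = 16, brood_size_mean = 4,
                       n_cpgs = 4, frac_extreme_dispersion = 1,
                       rho_overdispersion = 0.3, coverage_mean = 30)
  d_bb <- simulate_design(cfg_bb)
  sim_bb <- simulate_methylation(cfg_bb, d_bb)
  phis_bb <- vapply(1:4, function(i) {
    obs <- which(!is.na(sim_bb$matrix$cov[i, ]))
    fit <- fit_glmm(sim_bb$matrix$meth[i, obs], sim_bb$matrix$cov[i, obs],
                    d_bb[obs, ])
    pearson_dispersion(fit)
  }, 0)
  expect_true(all(phis_bb > 2))
})

test_that("ML linear mixed model matches closed-form OLS without random variance", {
  cfg <- tiny_config(seed = 231, weight_sigma_origin = 0,
                     weight_sigma_rearing = 0)
  d <- simulate_design(cfg)
  ph <- simulate_phenotypes(cfg, d)
  y <- ph$individuals$weight_d14
  X <- nestmeth:::build_fixed_X(~ treatment * sex, d)
  beta_ols <- drop(solve(crossprod(X), crossprod(X, y)))
  fit0 <- fit_lmm(y, d, ~ treatment * sex, list())
  expect_lt(max(abs(fit0$beta - beta_ols)), 1e-6)
  fit <- fit_lmm(y, d, ~ treatment * sex,
                 list("brood_origin", "brood_rearing"))
  expect_lt(max(abs(fit$beta - beta_ols)), 0.05)
  expect_true(all(fit$sigma[c("brood_origin", "brood_rearing")] < 0.3))
})

test_that("ML linear mixed model matches the independent lme4 implementation", {
  skip_if_not_installed("lme4")
  cfg <- tiny_config(seed = 233, weight_trt_female_d14 = -1)
  d <- simulate_design(cfg)
  ph <- simulate_phenotypes(cfg, d)
  y <- ph$individuals$weight_d14
  fit <- fit_lmm(y, d)
  dd <- transform(d,
                  treatment = factor(treatment,
                                     c("control", "testosterone")),
                  sex = factor(sex, c("F", "M")))
  ref <- lme4::lmer(y ~ treatment * sex + (1 | brood_origin) +
                      (1 | brood_rearing), data = dd, REML = FALSE)
  expect_lt(max(abs(fit$beta - lme4::fixef(ref))), 1e-4)
  expect_lt(abs(fit$loglik - as.numeric(logLik(ref))), 1e-5)
  expect_lt(max(abs(fit$se_beta - sqrt(diag(as.matrix(vcov(ref)))))), 1e-4)
})

test_that("constant responses give a degenerate flag", {
  d <- manual_design(8)
  fit <- fit_lmm(rep(3.2, nrow(d)), d, ~ treatment * sex,
                 list("brood_origin"))
  expect_true(fit$degenerate)
  expect_lt(max(abs(fit$beta[-1])), 1e-8)
})

test_that("marginal-means contrasts recover cell differences with adjustment", {
  # a null fit built by hand: all contrasts zero, all p = 1
  d <- manual_design(12)
  set.seed(241)
  y <- rnorm(nrow(d))
  fit <- fit_lmm(y, d, ~ treatment * sex, list())
  fit$beta[] <- 0
  cs <- marginal_means_contrasts(fit, "all", "bonferroni")
  expect_equal(cs$estimate, rep(0, 6))
  expect_equal(cs$p_adjusted, rep(1, 6))
  # Bonferroni multiplies by the family size and caps at 1
  fit2 <- fit
  fit2$beta <- setNames(c(0, 1, 0, -1), names(fit$beta))
  cs2 <- marginal_means_contrasts(fit2, "all", "bonferroni")
  expect_equal(cs2$p_adjusted, pmin(1, cs2$p_raw * 6))
  # linear-combination arithmetic: F contrast = beta_T, M = beta_T + beta_TS
  expect_equal(cs2$estimate[cs2$label == "F: T-C"], 1)
  expect_equal(cs2$estimate[cs2$label == "M: T-C"], 0)
  expect_equal(cs2$estimate[cs2$label == "T: M-F"], -1)
})

test_that("female-only simulated effects land in the female contrast", {
  cfg <- sim_config(seed = 243, n_brood_pairs = 16, brood_size_mean = 6,
                    n_cpgs = 6,
                    n_dms_per_category = c(female_specific = 6,
                                           male_specific = 0,
                                           antagonistic = 0),
                    effect_logit = 1.5)
  d <- simulate_design(cfg)
  sim <- simulate_methylation(cfg, d)
  ests <- t(vapply(1:6, function(i) {
    obs <- which(!is.na(sim$matrix$cov[i, ]))
    fit <- fit_glmm(sim$matrix$meth[i, obs], sim$matrix$cov[i, obs],
                    d[obs, ])
    cs <- marginal_means_contrasts(fit, "within_sex", "none")
    setNames(cs$estimate, cs$label)
  }, c("F: T-C" = 0, "M: T-C" = 0)))
  truth <- sim$truth$sites$contrast_f[sim$truth$sites$is_dms]
  expect_lt(mean(abs(ests[, 1] - truth)), 0.4)
  expect_lt(abs(mean(ests[, 2])), 0.3)
})

test_that("random-slope BLUPs shrink, centre at zero, and vanish for parallel trajectories", {
  # parallel trajectories: exact zeros
  ids <- sprintf("i%02d", 1:30)
  long0 <- data.frame(individual = rep(ids, each = 4), bout = rep(1:4, 30))
  long0$count <- 20 - 1.5 * (long0$bout - 1) + rep(rnorm(30, 0, 2), each = 4)
  fit0 <- fit_lmm(long0$count, long0, ~ bout,
                  list(list(factor = "individual", slope = "bout")))
  expect_lt(max(abs(random_slope_blups(fit0))), 1e-6)
  # heterogeneous slopes: BLUPs track truth and shrink versus OLS
  set.seed(251)
  slopes <- rnorm(60, 0, 1.2)
  long <- data.frame(individual = rep(sprintf("j%02d", 1:60), each = 4),
                     bout = rep(1:4, 60))
  long$count <- 25 + (-1 + rep(slopes, each = 4)) * (long$bout - 1) +
    rnorm(240, 0, 1.5)
  fit <- fit_lmm(long$count, long, ~ bout,
                 list(list(factor = "individual", slope = "bout")))
  bl <- random_slope_blups(fit)
  expect_lt(abs(mean(bl)), 0.05)
  expect_gt(cor(bl, slopes, method = "spearman"), 0.5)
  ols <- vapply(split(long, long$individual), function(g)
    coef(lm(count ~ bout, g))[2], 0)
  ols_dev <- ols - mean(ols)
  expect_lt(mean(abs(bl[names(ols_dev)])), mean(abs(ols_dev)))
})
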