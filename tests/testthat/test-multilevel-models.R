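test_that("standardize uses the population-SD convention and inverts", {
  d <- data.frame(x = c(0, 2))
  z <- standardize(d, "x")
  expect_equal(z$x, c(-1, 1))
  expect_equal(standardize(d, "x", sd_type = "sample")$x,
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  set.seed(2)
  d2 <- data.frame(x = rnorm(50, 5, 3))
  z2 <- standardize(d2, "x")
  expect_equal(standardize(z2, "x")$x, z2$x, tolerance = 1e-12)  # idempotent
  expect_equal(unstandardize(z2, "x")$x, d2$x, tolerance = 1e-12)
  expect_error(standardize(data.frame(x = rep(1, 5)), "x"), "zero variance")
})

test_that("within-school centering zeroes every school mean", {
  d <- data.frame(school_id = c(1, 1), y = c(10, 14))
  expect_equal(center_within_school(d, "y")$y, c(-2, 2))
  set.seed(3)
  d2 <- data.frame(school_id = rep(1:7, times = sample(2:9, 7, TRUE)))
  d2$y <- rnorm(nrow(d2), 14, 2)
  c1 <- center_within_school(d2, "y")
  expect_true(all(abs(tapply(c1$y, c1$school_id, mean)) < 1e-12))
  expect_equal(center_within_school(c1, "y")$y, c1$y)  # idempotent
})

test_that("indirect fit reproduces a deterministic noiseless relationship", {
  set.seed(4)
  n <- 400
  d <- data.frame(school_id = rep(1:40, each = 10), pgs = rnorm(n),
                  sex = rbinom(n, 1, 0.5),
                  birth_year = sample(1976:1982, n, TRUE))
  d$pgs <- (d$pgs - mean(d$pgs)) / sqrt(mean((d$pgs - mean(d$pgs))^2))
  d$y <- 0.25 * d$pgs
  fit <- fit_indirect(d, "y", "pgs", standardize_outcome = FALSE)
  expect_equal(fit$beta1, 0.25, tolerance = 1e-6)
  expect_lt(fit$sigma_mu, 1e-6)
  expect_lt(fit$sigma_delta, 1e-6)
})

test_that("indirect fit recovers generating parameters", {
  # null slope variance: sigma_delta estimates at/near the boundary
  cfg <- cohort_config(n_students = 10000, n_schools = 200, beta1 = 0.3,
                       beta2 = 0, sigma_mu = 0.2, sigma_delta = 0,
                       rho_mu_delta = 0, rge_weight = 0, seed = 15)
  co <- generate_cohort(cfg)
  fit <- fit_indirect(co, "edu_years", "pgs", standardize_outcome = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta1 / cfg$edu_sd - 0.3), 0.02)
  expect_lt(fit$sigma_delta / cfg$edu_sd, 0.02)
  # non-null components, moderate n
  cfg2 <- cohort_config(n_students = 6000, n_schools = 150, beta1 = 0.3,
                        beta2 = 0, sigma_mu = 0.3, sigma_delta = 0.15,
                        rho_mu_delta = 0.5, rge_weight = 0, seed = 16)
  co2 <- generate_cohort(cfg2)
  fit2 <- fit_indirect(co2, "edu_years", "pgs", standardize_outcome = FALSE)
  expect_lt(abs(fit2$sigma_mu / cfg2$edu_sd - 0.3), 0.06)
  expect_lt(abs(fit2$sigma_delta / cfg2$edu_sd - 0.15), 0.05)
  expect_lt(abs(fit2$rho_mu_delta - 0.5), 0.35)
})

test_that("mean-centered variant equals internal centering on raw data", {
  co <- generate_cohort(quick_config())
  pre <- center_within_school(co$students, "edu_years")
  f_pre <- fit_indirect(pre, "edu_years", "pgs", variant = "mean_centered",
                        standardize_outcome = FALSE)
  f_raw <- fit_indirect(co$students, "edu_years", "pgs",
                        variant = "mean_centered",
                        standardize_outcome = FALSE)
  expect_equal(f_pre$beta1, f_raw$beta1, tolerance = 1e-8)
  expect_equal(f_pre$sigma_delta, f_raw$sigma_delta, tolerance = 1e-8)
  expect_true(is.na(f_pre$sigma_mu))  # no random intercept by construction
})

test_that("family random effect is fit when requested", {
  cfg <- quick_config(family_pair_fraction = 0.6, sigma_family = 0.4)
  co <- generate_cohort(cfg)
  fit <- fit_indirect(co, "edu_years", "pgs", include_family = TRUE)
  expect_false(is.na(fit$sigma_family))
  expect_gt(fit$sigma_family, 0)
})

test_that("binary outcomes run as linear probability models on the 0/1 scale", {
  co <- generate_cohort(cohort_config(n_students = 3000, n_schools = 60,
                                      beta1 = 0.3, sigma_mu = 0.3,
                                      seed = 17))
  fit <- fit_indirect(co, "any_postsec", "pgs")
  expect_equal(unname(fit$outcome_scale[["scale"]]), 1)  # not standardized
  expect_gt(fit$beta1, 0.02)
  expect_lt(fit$beta1, 0.3)
  # predicted probabilities are not clamped: raw-scale predictions can
  # leave [0,1] at extreme PGS without error
  sp <- school_predictions(fit, pgs_values = c(-4, 4))
  expect_true(is.data.frame(sp$summary))
})

test_that("direct fit recovers the interaction and guards are present", {
  cfg <- cohort_config(n_students = 20000, n_schools = 200, beta1 = 0.2,
                       beta2 = 0.2, beta3 = 0.10, sigma_mu = 0.1,
                       sigma_delta = 0, rge_weight = 0,
                       env_reliability_alpha = 1, seed = 18)
  co <- generate_cohort(cfg)
  fit <- fit_direct(co, "edu_years", "pgs", environments = co$schools,
                    env = "env_obs", standardize_outcome = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta3 / cfg$edu_sd - 0.10), 0.01)
  expect_gt(fit$se_beta3, 0)
  expect_true(fit$p_beta3 >= 0 && fit$p_beta3 <= 1)
  guard_terms <- rownames(fit$guards)
  expect_equal(nrow(fit$guards), 4)   # sex and birth year x both predictors
  expect_true(any(grepl("sex", guard_terms)) &&
                any(grepl("birth_year_z", guard_terms)))
  # a constant environment is a degenerate design, not a silent fit
  env_const <- co$schools
  env_const$env_obs <- 1
  expect_error(fit_direct(co, "edu_years", "pgs", environments = env_const,
                          env = "env_obs"), "zero variance")
})

test_that("school predictions are BLUP-based and degenerate correctly", {
  # no school variation: every school predicts the same line
  cfg0 <- cohort_config(n_students = 2000, n_schools = 50, sigma_mu = 0,
                        sigma_delta = 0, rho_mu_delta = 0, beta2 = 0,
                        rge_weight = 0, seed = 19)
  f0 <- fit_indirect(generate_cohort(cfg0), "edu_years", "pgs")
  sp0 <- school_predictions(f0)
  # cross-school spread reflects only REML sampling noise at 50 schools
  expect_true(all(sp0$summary$sd < 0.1))
  # at p = 0 the prediction minus the fixed intercept is exactly mu_hat
  co <- generate_cohort(quick_config())
  f1 <- fit_indirect(co, "edu_years", "pgs")
  sp1 <- school_predictions(f1, pgs_values = 0)
  expect_equal(sp1$per_school$pred_0 - f1$beta0, sp1$per_school$mu_hat,
               tolerance = 1e-10)
  # mean-centered fits return slope-only trajectories, flagged
  fmc <- fit_indirect(co, "edu_years", "pgs", variant = "mean_centered")
  spmc <- school_predictions(fmc)
  expect_true(spmc$slope_only)
  expect_true(all(spmc$per_school$mu_hat == 0))
})

test_that("empirical-Bayes slopes shrink toward the pooled estimate", {
  cfg <- cohort_config(n_students = 6000, n_schools = 60, beta1 = 0.3,
                       beta2 = 0, sigma_mu = 0.3, sigma_delta = 0.2,
                       rho_mu_delta = 0, rge_weight = 0, seed = 20)
  co <- generate_cohort(cfg)
  fit <- fit_indirect(co, "edu_years", "pgs", standardize_outcome = FALSE)
  sp <- school_predictions(fit, pgs_values = 0)
  ols <- per_school_ols_slopes(co$students)
  ols_dev <- ols - mean(ols)
  eb <- sp$per_school$delta_hat[match(names(ols), sp$per_school$school_id)]
  expect_gt(cor(eb, ols_dev, method = "spearman"), 0.9)
  expect_lt(sd(eb), sd(ols_dev))   # shrinkage compresses the spread
})
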