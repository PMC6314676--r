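test_that("invalid generator configurations are rejected", {
  expect_error(cohort_config(n_schools = 1), "n_schools")
  expect_error(cohort_config(pgs_between_share = 1), "\\[0, 1\\)")
  expect_error(cohort_config(rho_mu_delta = 1.2), "rho_mu_delta")
  expect_error(cohort_config(env_reliability_alpha = 0), "env_reliability_alpha")
  expect_error(cohort_config(sigma_delta = -0.1), "non-negative")
  # a multinomial size spec that starves one school
  expect_error(cohort_config(n_students = 10, n_schools = 3,
                             school_size_spec = "multinomial",
                             school_size_probs = c(0.5, 0.5, 0)),
               "0 students")
})

test_that("school sizes are conserved and equal-split is deterministic", {
  cfg <- cohort_config(n_students = 103, n_schools = 10, seed = 1)
  co <- generate_cohort(cfg)
  expect_equal(sum(co$schools$n_students), 103)
  expect_equal(as.integer(table(co$students$school_id)),
               co$schools$n_students)
  expect_equal(sort(unique(co$schools$n_students)), c(10L, 11L))
})

test_that("generating slope is recovered by pooled OLS with no clustering", {
  cfg <- cohort_config(n_students = 50000, n_schools = 100,
                       beta1 = 0.3, beta2 = 0, beta3 = 0,
                       sigma_mu = 0, sigma_delta = 0, rho_mu_delta = 0,
                       pgs_between_share = 0, rge_weight = 0,
                       beta_sex = 0, beta_birth_year = 0, seed = 11)
  co <- generate_cohort(cfg)
  # edu_years = 14 + 2 * latent, so the generating-scale slope is coef / 2
  slope <- unname(coef(lm(edu_years ~ pgs, data = co$students))[2]) /
    cfg$edu_sd
  expect_lt(abs(slope - 0.3), 0.01)
})

test_that("between-school PGS share is recovered at large n", {
  cfg <- cohort_config(n_students = 100000, n_schools = 200,
                       pgs_between_share = 0.065, seed = 3)
  co <- generate_cohort(cfg)
  share <- between_school_share(co, "pgs")
  expect_lt(abs(share - 0.065), 0.005)
})

test_that("education floor truncates and thresholds define the binaries", {
  cfg <- quick_config(truncation_floor_years = 12, sigma_mu = 0.4)
  co <- generate_cohort(cfg)
  edu <- co$students$edu_years
  expect_gte(min(edu), 12)
  expect_gt(mean(edu == 12), 0)            # mass piles up on the floor
  expect_equal(co$students$any_postsec, as.integer(edu > 12))
  expect_equal(co$students$college, as.integer(edu >= 16))
})

test_that("sibling pairs share school and family; others have unique families", {
  cfg <- quick_config(family_pair_fraction = 0.5, sigma_family = 0.3)
  co <- generate_cohort(cfg)
  s <- co$students
  fam_sizes <- table(s$family_id)
  expect_true(all(fam_sizes %in% 1:2))
  expect_gt(sum(fam_sizes == 2), 0)
  pairs <- names(fam_sizes)[fam_sizes == 2]
  for (f in pairs) {
    expect_equal(length(unique(s$school_id[s$family_id == f])), 1)
  }
  expect_true(!any(duplicated(s$student_id)))
  expect_true(all(s$school_id %in% co$schools$school_id))
})

test_that("the generator is bit-reproducible under a fixed seed", {
  cfg <- quick_config(family_pair_fraction = 0.3, sigma_family = 0.2)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$students, b$students)
  expect_identical(a$schools, b$schools)
})

test_that("realized school effects converge to the generating Omega", {
  cfg <- cohort_config(n_students = 6000, n_schools = 2000,
                       sigma_mu = 0.3, sigma_delta = 0.2,
                       rho_mu_delta = 0.5, seed = 8)
  co <- generate_cohort(cfg)
  expect_lt(abs(sd(co$schools$mu) - 0.3), 0.02)
  expect_lt(abs(sd(co$schools$delta) - 0.2), 0.02)
  expect_lt(abs(cor(co$schools$mu, co$schools$delta) - 0.5), 0.06)
})

test_that("noisy environment observation has the stated reliability", {
  # alpha = 1: observed equals the standardized truth exactly
  truth <- rnorm(50, mean = 3, sd = 2)
  obs <- observe_noisy_environment(truth, alpha = 1, seed = 4)
  expect_equal(obs, (truth - mean(truth)) /
                 sqrt(mean((truth - mean(truth))^2)), tolerance = 1e-12)
  # alpha = 0.4 over many schools: squared correlation ~ 0.4
  truth <- rnorm(10000)
  obs <- observe_noisy_environment(truth, alpha = 0.4, seed = 5)
  expect_lt(abs(cor(obs, truth)^2 - 0.4), 0.02)
  # determinism and domain errors
  expect_identical(observe_noisy_environment(truth, 0.4, seed = 7),
                   observe_noisy_environment(truth, 0.4, seed = 7))
  expect_error(observe_noisy_environment(truth, 0), "alpha")
  expect_error(observe_noisy_environment(truth, 1.5), "alpha")
})

test_that("cohort round-trips through the CSV writer", {
  co <- generate_cohort(quick_config())
  stem <- file.path(tempdir(), "cohort_rt")
  paths <- write_cohort(co, stem)
  back <- read_cohort_csv(paths[["students"]])
  expect_equal(back$edu_years, co$students$edu_years, tolerance = 1e-9)
  cfg_echo <- jsonlite::read_json(paths[["config"]])
  expect_equal(cfg_echo$n_students, co$config$n_students)
  unlink(paths)
})
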