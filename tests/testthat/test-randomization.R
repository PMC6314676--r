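test_that("permutation conserves the school-size multiset exactly", {
  d <- data.frame(student_id = 1:15,
                  school_id = rep(c("a", "b", "c"), times = c(3, 5, 7)),
                  pgs = rnorm(15))
  for (s in 1:5) {
    p <- permute_school_assignment(d, seed = s)
    expect_equal(sort(as.integer(table(p$school_id))), c(3, 5, 7))
    # every non-school column untouched
    expect_identical(p$pgs, d$pgs)
    expect_identical(p$student_id, d$student_id)
  }
  expect_identical(permute_school_assignment(d, seed = 9),
                   permute_school_assignment(d, seed = 9))
})

test_that("permutation is uniform over student-school pairings", {
  d <- data.frame(student_id = 1:4, school_id = c(1, 1, 2, 2))
  hits <- 0
  withr::with_seed(100, {
    for (i in 1:10000) {
      p <- data.frame(student_id = d$student_id,
                      school_id = sample(d$school_id))
      hits <- hits + (p$school_id[1] == 1)
    }
  })
  expect_lt(abs(hits / 10000 - 0.5), 0.02)
})

test_that("family-block permutation keeps siblings together", {
  co <- generate_cohort(quick_config(family_pair_fraction = 0.5,
                                     sigma_family = 0.2))
  p <- permute_school_assignment(co$students, seed = 3,
                                 keep_families_together = TRUE)
  expect_equal(sort(as.integer(table(p$school_id))),
               sort(co$schools$n_students))
  fam_sizes <- table(p$family_id)
  for (f in names(fam_sizes)[fam_sizes == 2])
    expect_equal(length(unique(p$school_id[p$family_id == f])), 1)
  # a family bigger than every school cannot be placed
  bad <- data.frame(student_id = 1:6, school_id = rep(1:2, each = 3),
                    family_id = c(1, 1, 1, 1, 2, 3))
  expect_error(permute_school_assignment(bad, seed = 1,
                                         keep_families_together = TRUE),
               "larger than the largest school")
})

test_that("add-one permutation p-values are valid and monotone", {
  pv <- schoolgxe:::perm_pvalue
  draws <- seq_len(999) / 1000
  expect_equal(pv(2, draws), 1 / 1000)     # observed above every null draw
  expect_equal(pv(-1, draws), 1)           # observed below every null draw
  expect_gt(pv(0.5, draws), 0)             # never exactly 0
  # monotone: a larger observed value never gets a larger p
  obs <- sort(runif(20))
  p <- sapply(obs, pv, null_draws = draws)
  expect_true(all(diff(p) <= 0))
})

test_that("the fast null sampler matches fit_indirect exactly", {
  co <- generate_cohort(quick_config())
  for (variant in c("mean_centered", "random_intercept")) {
    sam <- schoolgxe:::null_component_sampler(co$students, "edu_years",
                                              "pgs", variant)
    for (s in 1:3) {
      p <- permute_school_assignment(co$students, seed = s)
      a <- sam(p$school_id)
      b <- fit_indirect(p, "edu_years", "pgs", variant = variant,
                        fast = TRUE)
      expect_equal(a[["sigma_delta"]], b$sigma_delta, tolerance = 1e-8)
      if (variant == "random_intercept")
        expect_equal(a[["sigma_mu"]], b$sigma_mu, tolerance = 1e-8)
    }
  }
})

test_that("permutation destroys real slope variation but the observed data keep it", {
  cfg <- cohort_config(n_students = 5000, n_schools = 100, beta1 = 0.3,
                       sigma_mu = 0.2, sigma_delta = 0.2, rho_mu_delta = 0,
                       seed = 23)
  co <- generate_cohort(cfg)
  rt <- randomization_test(co$students, "edu_years", "pgs",
                           variant = "mean_centered", R = 100, seed = 5)
  expect_lt(rt$components$sigma_delta$p_value, 0.05)
  expect_false(rt$unreliable)
  expect_equal(length(rt$components$sigma_delta$null_draws) +
                 rt$components$sigma_delta$n_failed_fits, 100)
  # determinism of the whole test under a fixed seed
  rt2 <- randomization_test(co$students, "edu_years", "pgs",
                            variant = "mean_centered", R = 100, seed = 5)
  expect_identical(rt$components$sigma_delta$null_draws,
                   rt2$components$sigma_delta$null_draws)
})

test_that("intercept variation always exceeds its permutation null", {
  cfg <- cohort_config(n_students = 1200, n_schools = 40, beta1 = 0.2,
                       sigma_mu = 0.4, sigma_delta = 0, rho_mu_delta = 0,
                       seed = 24)
  co <- generate_cohort(cfg)
  rt <- randomization_test(co$students, "edu_years", "pgs",
                           variant = "random_intercept",
                           components = "sigma_mu", R = 100, seed = 6)
  cm <- rt$components$sigma_mu
  expect_gt(cm$observed_value, max(cm$null_draws))
  expect_equal(cm$p_value, 1 / (length(cm$null_draws) + 1))
})

test_that("randomization test enforces its preconditions", {
  co <- generate_cohort(quick_config())
  expect_error(randomization_test(co$students, "edu_years", "pgs", R = 50),
               "R must be >= 100")
  expect_error(randomization_test(co$students, "edu_years", "pgs",
                                  variant = "mean_centered",
                                  components = "sigma_mu", R = 100),
               "no sigma_mu")
})
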