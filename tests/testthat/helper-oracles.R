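# independent O(n^2) pairwise-difference Gini oracle
gini_bruteforce <- function(x, denominator = "population") {
  x <- x[!is.na(x)]
  n <- length(x)
  num <- sum(abs(outer(x, x, "-")))
  den <- if (denominator == "population") 2 * n^2 * mean(x)
         else 2 * n * (n - 1) * mean(x)
  num / den
}

# per-school OLS slopes of outcome on the standardized predictor, with the
# same covariate adjustment as the mixed model; independent of lme4
per_school_ols_slopes <- function(students, outcome = "edu_years",
                                  predictor = "pgs") {
  x <- (students[[predictor]] - mean(students[[predictor]])) /
    sqrt(mean((students[[predictor]] - mean(students[[predictor]]))^2))
  y <- students[[outcome]]
  sapply(split(seq_len(nrow(students)), students$school_id), function(idx) {
    unname(coef(lm(y[idx] ~ x[idx] + students$sex[idx]))[2])
  })
}

# small quick cohort config used across tests
quick_config <- function(...) {
  args <- utils::modifyList(
    list(n_students = 360, n_schools = 30, beta1 = 0.3,
         sigma_mu = 0.2, sigma_delta = 0.1, seed = 42),
    list(...))
  do.call(cohort_config, args)
}
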