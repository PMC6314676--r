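#' Generator templates for the two study-sized power designs
#'
#' Returns a [cohort_config()] sized like the two cohorts the power analysis
#' targets: `"wls_like"` (n = 8,494 students in 300 equal schools) and
#' `"addhealth_like"` (n = 4,915 in 100 equal schools). Both use main
#' effects 0.2 for the PGS and the moderator, no school random effects, a
#' perfectly measured independent moderator, and no truncation — the clean
#' design under which fixed-effect interaction power is governed by total n.
#' Any field can be overridden through `...`.
#'
#' @param design `"wls_like"`, `"addhealth_like"` or `"custom"` (requires
#'   `n_students`/`n_schools` in `...`).
#' @param ... overrides passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
power_design <- function(design = c("wls_like", "addhealth_like", "custom"),
                         ...) {
  design <- match.arg(design)
  base <- switch(design,
    wls_like = list(n_students = 8494L, n_schools = 300L),
    addhealth_like = list(n_students = 4915L, n_schools = 100L),
    custom = list())
  defaults <- list(beta1 = 0.2, beta2 = 0.2, beta3 = 0,
                   sigma_mu = 0, sigma_delta = 0, rho_mu_delta = 0,
                   pgs_between_share = 0, rge_weight = 0,
                   env_reliability_alpha = 1,
                   family_pair_fraction = 0, sigma_family = 0,
                   truncation_floor_years = NULL)
  args <- utils::modifyList(c(base, defaults), list(...))
  cfg <- do.call(cohort_config, args)
  attr(cfg, "design") <- design
  cfg
}

#' Closed-form Wald approximation to direct-interaction power
#'
#' For standardized, mutually independent predictor and moderator and
#' residual SD `sigma_eps`, the two-sided Wald test of the interaction
#' coefficient has approximate power
#' \eqn{\Phi(|\beta_3|\sqrt{n}/\sigma_\epsilon - z_{1-\alpha/2}) +
#'      \Phi(-|\beta_3|\sqrt{n}/\sigma_\epsilon - z_{1-\alpha/2})}.
#' With moderator reliability `alpha_reliability` the effective coefficient
#' is attenuated by its square root.
#'
#' @param beta3 interaction coefficient (standardized scale).
#' @param n total number of students.
#' @param sigma_eps residual SD (default 1, the generating scale).
#' @param alpha_level test size (default 0.05).
#' @param alpha_reliability moderator reliability (default 1).
#' @return approximate power.
#' @export
wald_power <- function(beta3, n, sigma_eps = 1, alpha_level = 0.05,
                       alpha_reliability = 1) {
  z <- stats::qnorm(1 - alpha_level / 2)
  lam <- abs(beta3) * sqrt(alpha_reliability) * sqrt(n) / sigma_eps
  stats::pnorm(lam - z) + stats::pnorm(-lam - z)
}

#' Monte-Carlo power curves for direct and indirect GxE detection
#'
#' For each interaction coefficient in `beta3_grid`, simulates cohorts from
#' the design template, observes the school moderator at the requested
#' reliability, runs the chosen test, and records the rejection proportion
#' at `alpha_level`:
#' \describe{
#'   \item{direct}{the two-sided Wald test of \eqn{\beta_3} from
#'     [fit_direct()] on the observed moderator;}
#'   \item{indirect}{the randomization test of the slope-variance component
#'     \eqn{\sigma_\delta} (mean-centered variant, `R_indirect`
#'     reassignments per replicate).}
#' }
#' The incremental explained variance of the interaction term (model
#' \eqn{r^2} with minus without it) is averaged over the same replicates;
#' for independent standardized predictors it converges to
#' \eqn{\beta_3^2}.
#'
#' @param config a [power_design()] / [cohort_config()] template (its
#'   `beta3`, `env_reliability_alpha` and `seed` fields are overridden per
#'   grid point and replicate).
#' @param approach `"direct"` or `"indirect"`.
#' @param beta3_grid interaction coefficients to scan.
#' @param alpha_reliability moderator reliability used when simulating the
#'   observed moderator.
#' @param n_reps Monte-Carlo replicates per grid point (>= 100 for smoke
#'   runs; 10,000 for full fidelity).
#' @param alpha_level nominal test size.
#' @param seed root seed; replicate seeds derive from it.
#' @param R_indirect randomizations per replicate for the indirect approach.
#' @param compute_r2 also estimate incremental r-squared (direct machinery;
#'   cheap).
#' @return an object of class `power_result`: a data.frame with one row per
#'   grid point (`design`, `approach`, `beta3`, `alpha_reliability`,
#'   `power`, `mc_se`, `incremental_r2`, `wald_power`, `n_reps`,
#'   `n_students`, `alpha_level`, `seed`).
#' @export
run_power_curve <- function(config, approach = c("direct", "indirect"),
                            beta3_grid, alpha_reliability = 1,
                            n_reps = 500, alpha_level = 0.05, seed = 1L,
                            R_indirect = 199, compute_r2 = TRUE) {
  approach <- match.arg(approach)
  stopifnot(inherits(config, "cohort_config"))
  if (n_reps < 2) stop("n_reps too small", call. = FALSE)
  if (approach == "indirect" && config$n_schools < 10)
    stop("indirect approach requires at least 10 schools", call. = FALSE)
  design <- attr(config, "design")
  if (is.null(design)) design <- "custom"

  rows <- lapply(seq_along(beta3_grid), function(g) {
    b3 <- beta3_grid[g]
    seeds <- derive_seeds(seed + g - 1L, n_reps)
    rej <- logical(n_reps)
    r2 <- rep(NA_real_, n_reps)
    for (r in seq_len(n_reps)) {
      cfg <- config
      cfg$beta3 <- b3
      cfg$env_reliability_alpha <- alpha_reliability
      cfg$seed <- seeds[r]
      cohort <- generate_cohort(cfg)
      if (approach == "direct") {
        f <- fit_direct(cohort$students, "edu_years", "pgs",
                        environments = cohort$schools, env = "env_obs",
                        fast = TRUE)
        rej[r] <- is.finite(f$p_beta3) && f$p_beta3 < alpha_level
      } else {
        rt <- randomization_test(cohort$students, "edu_years", "pgs",
                                 variant = "mean_centered",
                                 components = "sigma_delta",
                                 R = R_indirect, seed = seeds[r])
        rej[r] <- rt$components$sigma_delta$p_value < alpha_level
      }
      if (compute_r2) r2[r] <- one_rep_incremental_r2(cohort)
    }
    p <- mean(rej)
    data.frame(design = design, approach = approach, beta3 = b3,
               alpha_reliability = alpha_reliability,
               power = p, mc_se = sqrt(p * (1 - p) / n_reps),
               incremental_r2 = if (compute_r2) mean(r2) else NA_real_,
               wald_power = wald_power(b3, config$n_students,
                                       alpha_level = alpha_level,
                                       alpha_reliability = alpha_reliability),
               n_reps = n_reps, n_students = config$n_students,
               alpha_level = alpha_level, seed = seed)
  })
  structure(do.call(rbind, rows), class = c("power_result", "data.frame"))
}

# incremental r^2 of the interaction term in one simulated cohort
one_rep_incremental_r2 <- function(cohort) {
  s <- cohort$students
  e <- cohort$schools$env_obs[match(s$school_id, cohort$schools$school_id)]
  y <- zscore(s$edu_years)
  x <- zscore(s$pgs)
  e <- zscore(e)
  base <- stats::lm(y ~ x + e + sex + birth_year, data =
                      data.frame(y, x, e, sex = s$sex,
                                 birth_year = s$birth_year))
  full <- stats::update(base, . ~ . + x:e)
  summary(full)$r.squared - summary(base)$r.squared
}

#' Incremental explained variance of the GxE interaction term
#'
#' Average difference in model \eqn{r^2} with vs. without the interaction
#' term over simulated cohorts at a given interaction coefficient. For
#' independent standardized PGS and moderator this converges to
#' \eqn{\beta_3^2 \mathrm{Var}(PGS \cdot E) / \mathrm{Var}(Y) \approx
#' \beta_3^2}: the added variance at detectable coefficients is tiny.
#'
#' @param config a [power_design()] / [cohort_config()] template.
#' @param beta3 interaction coefficient.
#' @param n_reps simulation replicates (default 20).
#' @param seed root seed.
#' @return list with `mc` (Monte-Carlo estimate), `analytic`
#'   (\eqn{\beta_3^2}) and `n_reps`.
#' @export
incremental_r2 <- function(config, beta3, n_reps = 20, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- derive_seeds(seed, n_reps)
  vals <- vapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$beta3 <- beta3
    cfg$seed <- seeds[r]
    one_rep_incremental_r2(generate_cohort(cfg))
  }, 0)
  list(mc = mean(vals), analytic = beta3^2, n_reps = n_reps)
}
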