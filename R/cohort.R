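#' Configuration for the synthetic school-clustered cohort generator
#'
#' Collects the generating truths of the two-level random-slope model and the
#' structural features of school-clustered attainment data: between-school
#' variance shares in the individual predictors (gene-environment
#' correlation), a school-level moderator observed with a chosen reliability,
#' sibling pairs sharing a family effect, and an optional left floor on years
#' of education emulating cohorts empaneled conditional on high-school
#' graduation.
#'
#' The latent outcome for student \eqn{i} in school \eqn{j} is
#' \deqn{y^*_{ij} = \beta_0 + \mu_j + f_{ij} +
#'   (\beta_1 + \delta_j + \beta_3 E_j)\,PGS_{ij} + \beta_2 E_j +
#'   \gamma_s\,sex_{ij} + \gamma_b\,z(by_{ij}) + \epsilon_{ij}}
#' with \eqn{(\mu_j, \delta_j)} bivariate normal with SDs `sigma_mu`,
#' `sigma_delta` and correlation `rho_mu_delta`, \eqn{f} a family intercept
#' shared by sibling pairs, and \eqn{\epsilon} standard normal. Years of
#' education are `edu_mean + edu_sd * y*`, floored at
#' `truncation_floor_years` when set; the binary outcomes threshold years at
#' \eqn{>12} (any postsecondary) and \eqn{\ge 16} (college).
#'
#' The true moderator \eqn{E_j} mixes the standardized realized school-mean
#' PGS (weight `rge_weight`) with an independent school factor, so the
#' generator can span weak to strong school-mean-PGS/status correlations.
#' The observed moderator has reliability `env_reliability_alpha`: squared
#' correlation with the truth approaching alpha as the number of schools
#' grows.
#'
#' @param n_students total number of students.
#' @param n_schools number of schools (>= 2).
#' @param school_size_spec `"equal"` or `"multinomial"`.
#' @param school_size_probs proportions (length `n_schools`) used when
#'   `school_size_spec = "multinomial"`; sizes are the largest-remainder
#'   apportionment of `n_students`.
#' @param beta0,beta1,beta2,beta3 fixed effects on the latent (unit residual
#'   SD) scale: intercept, PGS main effect, environment main effect, GxE
#'   interaction.
#' @param sigma_mu,sigma_delta,rho_mu_delta SDs of the school random
#'   intercepts and PGS slopes and their correlation (the 2x2 covariance
#'   Omega).
#' @param pgs_between_share,ses_between_share,cog_between_share fraction of
#'   each predictor's unit variance lying between schools, in `[0, 1)`.
#' @param rge_weight weight in `[0, 1]` of the standardized school-mean PGS
#'   in the true moderator.
#' @param family_pair_fraction fraction of students belonging to sibling
#'   pairs (pairs share school and family effect).
#' @param sigma_family SD of the family intercept.
#' @param env_reliability_alpha reliability of the observed moderator,
#'   in `(0, 1]`.
#' @param truncation_floor_years optional floor applied to years of
#'   education (12 emulates graduation-conditional empanelment); `NULL`
#'   disables it.
#' @param sex_prob probability of `sex == 1`.
#' @param birth_year_range integer range birth years are drawn from
#'   (uniform).
#' @param beta_sex,beta_birth_year covariate effects on the latent scale
#'   (birth year enters z-scored).
#' @param edu_mean,edu_sd affine map from the latent outcome to years of
#'   education.
#' @param job_attenuation factor applied to the systematic part of the
#'   latent outcome when generating the job-status index, so occupation
#'   shares the school intercepts/slopes at reduced strength.
#' @param seed integer root seed; all draws derive from it.
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_students = 5000L,
                          n_schools = 100L,
                          school_size_spec = c("equal", "multinomial"),
                          school_size_probs = NULL,
                          beta0 = 0, beta1 = 0.2, beta2 = 0.2, beta3 = 0,
                          sigma_mu = 0.2, sigma_delta = 0.1,
                          rho_mu_delta = 0.3,
                          pgs_between_share = 0.065,
                          ses_between_share = 0.20,
                          cog_between_share = 0.08,
                          rge_weight = 0.5,
                          family_pair_fraction = 0,
                          sigma_family = 0,
                          env_reliability_alpha = 1,
                          truncation_floor_years = NULL,
                          sex_prob = 0.5,
                          birth_year_range = c(1976L, 1982L),
                          beta_sex = 0.1, beta_birth_year = 0.05,
                          edu_mean = 14, edu_sd = 2,
                          job_attenuation = 0.6,
                          seed = 1L) {
  cfg <- list(
    n_students = as.integer(n_students), n_schools = as.integer(n_schools),
    school_size_spec = match.arg(school_size_spec),
    school_size_probs = school_size_probs,
    beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
    sigma_mu = sigma_mu, sigma_delta = sigma_delta,
    rho_mu_delta = rho_mu_delta,
    pgs_between_share = pgs_between_share,
    ses_between_share = ses_between_share,
    cog_between_share = cog_between_share,
    rge_weight = rge_weight,
    family_pair_fraction = family_pair_fraction,
    sigma_family = sigma_family,
    env_reliability_alpha = env_reliability_alpha,
    truncation_floor_years = truncation_floor_years,
    sex_prob = sex_prob,
    birth_year_range = as.integer(birth_year_range),
    beta_sex = beta_sex, beta_birth_year = beta_birth_year,
    edu_mean = edu_mean, edu_sd = edu_sd,
    job_attenuation = job_attenuation,
    seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_students >= 2)
  if (cfg$n_schools < 2) stop("n_schools must be >= 2", call. = FALSE)
  for (v in c("pgs_between_share", "ses_between_share", "cog_between_share")) {
    if (cfg[[v]] < 0 || cfg[[v]] >= 1)
      stop(v, " must lie in [0, 1)", call. = FALSE)
  }
  if (abs(cfg$rho_mu_delta) > 1)
    stop("rho_mu_delta must lie in [-1, 1]", call. = FALSE)
  if (cfg$sigma_mu < 0 || cfg$sigma_delta < 0 || cfg$sigma_family < 0)
    stop("random-effect SDs must be non-negative", call. = FALSE)
  if (cfg$env_reliability_alpha <= 0 || cfg$env_reliability_alpha > 1)
    stop("env_reliability_alpha must lie in (0, 1]", call. = FALSE)
  if (cfg$family_pair_fraction < 0 || cfg$family_pair_fraction > 1)
    stop("family_pair_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$rge_weight < 0 || cfg$rge_weight > 1)
    stop("rge_weight must lie in [0, 1]", call. = FALSE)
  sizes <- school_sizes(cfg)
  if (any(sizes <= 0))
    stop("school size specification assigns 0 students to a school",
         call. = FALSE)
  if (sum(sizes) != cfg$n_students)
    stop("school sizes do not sum to n_students", call. = FALSE)
  invisible(cfg)
}

# deterministic apportionment of n_students over n_schools
school_sizes <- function(cfg) {
  n <- cfg$n_students
  J <- cfg$n_schools
  if (cfg$school_size_spec == "equal") {
    sizes <- rep(n %/% J, J)
    rem <- n %% J
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  } else {
    p <- cfg$school_size_probs
    if (is.null(p) || length(p) != J || any(p < 0) || sum(p) == 0)
      stop("school_size_probs must be ", J, " non-negative proportions",
           call. = FALSE)
    p <- p / sum(p)
    raw <- n * p
    sizes <- floor(raw)
    rem <- n - sum(sizes)
    if (rem > 0) {
      idx <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[idx] <- sizes[idx] + 1L
    }
  }
  as.integer(sizes)
}

#' Generate a synthetic school-clustered cohort
#'
#' Draws a cohort under the model described in [cohort_config()], returning
#' student records together with the per-school generating truths (random
#' intercepts and slopes, true and observed moderator). Deterministic under
#' the config seed; the caller's RNG state is untouched.
#'
#' @param config a [cohort_config()] object.
#' @return an object of class `gxe_cohort`: a list with
#'   \describe{
#'     \item{students}{one row per student: `student_id`, `school_id`,
#'       `family_id`, `pgs`, `ses`, `cognition`, `sex`, `birth_year`,
#'       `edu_years`, `any_postsec`, `college`, `job_status`, `mother_hs`,
#'       `parent_edu_years`.}
#'     \item{schools}{one row per school: `school_id`, `n_students`, `mu`,
#'       `delta`, `env_true`, `env_obs`.}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  cfg <- config
  sizes <- school_sizes(cfg)
  J <- cfg$n_schools
  n <- cfg$n_students
  school <- rep.int(seq_len(J), sizes)

  withr::with_seed(cfg$seed, {
    # school random effects (mu_j, delta_j) ~ MVN(0, Omega)
    z1 <- stats::rnorm(J)
    z2 <- stats::rnorm(J)
    mu <- cfg$sigma_mu * z1
    delta <- cfg$sigma_delta *
      (cfg$rho_mu_delta * z1 + sqrt(1 - cfg$rho_mu_delta^2) * z2)

    # individual predictors: between-school + within-school components
    draw_pred <- function(share) {
      sqrt(share) * stats::rnorm(J)[school] +
        sqrt(1 - share) * stats::rnorm(n)
    }
    pgs <- draw_pred(cfg$pgs_between_share)
    ses <- draw_pred(cfg$ses_between_share)
    cognition <- draw_pred(cfg$cog_between_share)

    # true moderator: standardized realized school-mean PGS mixed with an
    # independent school factor (rGE by construction)
    mean_pgs <- as.numeric(tapply(pgs, school, mean))
    w <- cfg$rge_weight
    env_raw <- w * zscore(mean_pgs) + sqrt(1 - w^2) * stats::rnorm(J)
    env_true <- zscore(env_raw)
    env_obs <- observe_noisy_environment(env_true,
                                         alpha = cfg$env_reliability_alpha,
                                         seed = NULL)

    # sibling pairs within school, sharing a family intercept
    family <- seq_len(n)   # default: singleton families
    if (cfg$family_pair_fraction > 0) {
      start <- cumsum(c(1L, sizes))[seq_len(J)]
      for (j in seq_len(J)) {
        npair <- floor(cfg$family_pair_fraction * sizes[j] / 2)
        if (npair < 1) next
        idx <- start[j] + seq_len(2L * npair) - 1L
        family[idx] <- rep(idx[c(TRUE, FALSE)], each = 2L)
      }
    }
    fam_codes <- match(family, unique(family))
    fam_eff <- (cfg$sigma_family * stats::rnorm(length(unique(family))))[fam_codes]

    sex <- stats::rbinom(n, 1L, cfg$sex_prob)
    byr <- cfg$birth_year_range
    birth_year <- if (byr[1] == byr[length(byr)]) rep(byr[1], n) else
      sample(seq(byr[1], byr[2]), n, replace = TRUE)
    byz <- if (stats::sd(birth_year) == 0) rep(0, n) else zscore(birth_year)

    ej <- env_true[school]
    systematic <- mu[school] + fam_eff +
      (cfg$beta1 + delta[school] + cfg$beta3 * ej) * pgs + cfg$beta2 * ej
    covpart <- cfg$beta_sex * sex + cfg$beta_birth_year * byz
    latent <- cfg$beta0 + systematic + covpart + stats::rnorm(n)

    edu_years <- cfg$edu_mean + cfg$edu_sd * latent
    if (!is.null(cfg$truncation_floor_years))
      edu_years <- pmax(edu_years, cfg$truncation_floor_years)

    job_status <- cfg$beta0 + cfg$job_attenuation * systematic + covpart +
      stats::rnorm(n)

    # school SES microdata tied to the true moderator, so the school
    # environment measures can be rebuilt from student records
    p_hs <- stats::plogis(0.8 + 0.9 * ej)
    mother_hs <- stats::rbinom(n, 1L, p_hs)
    parent_edu_years <- pmax(0, 12 + 1.2 * ej + stats::rnorm(n, 0, 2.2))

    students <- data.frame(
      student_id = seq_len(n),
      school_id = school,
      family_id = fam_codes,
      pgs = pgs, ses = ses, cognition = cognition,
      sex = sex, birth_year = birth_year,
      edu_years = edu_years,
      any_postsec = as.integer(edu_years > 12),
      college = as.integer(edu_years >= 16),
      job_status = job_status,
      mother_hs = mother_hs,
      parent_edu_years = parent_edu_years)

    schools <- data.frame(
      school_id = seq_len(J), n_students = sizes,
      mu = mu, delta = delta,
      env_true = env_true, env_obs = env_obs)

    structure(list(students = students, schools = schools, config = cfg),
              class = "gxe_cohort")
  })
}

#' @export
print.gxe_cohort <- function(x, ...) {
  cat("Synthetic school-clustered cohort\n")
  cat("  students:", nrow(x$students), " schools:", nrow(x$schools), "\n")
  cat(sprintf("  generating: beta1 = %.3g, beta3 = %.3g, sigma_mu = %.3g, sigma_delta = %.3g, rho = %.3g\n",
              x$config$beta1, x$config$beta3, x$config$sigma_mu,
              x$config$sigma_delta, x$config$rho_mu_delta))
  if (!is.null(x$config$truncation_floor_years))
    cat("  education floored at", x$config$truncation_floor_years, "years\n")
  invisible(x)
}

#' Add classical measurement noise to a school-level moderator
#'
#' Returns `sqrt(alpha) * z(truth) + sqrt(1 - alpha) * noise`, restandardized,
#' so the squared correlation between observed and true moderator converges
#' to the reliability `alpha` as the number of schools grows.
#'
#' @param env_true per-school true moderator values.
#' @param alpha reliability in `(0, 1]`.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return per-school observed (standardized) moderator values.
#' @export
observe_noisy_environment <- function(env_true, alpha, seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  draw <- function() {
    noise <- stats::rnorm(length(env_true))
    obs <- sqrt(alpha) * zscore(env_true) + sqrt(1 - alpha) * noise
    zscore(obs)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Write a cohort to plain-text files
#'
#' Writes the student table as CSV and echoes the generating configuration
#' as JSON alongside (`<stem>.csv`, `<stem>_schools.csv`,
#' `<stem>_config.json`).
#'
#' @param cohort a `gxe_cohort`.
#' @param stem path stem (no extension).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, stem) {
  stopifnot(inherits(cohort, "gxe_cohort"))
  paths <- c(students = paste0(stem, ".csv"),
             schools = paste0(stem, "_schools.csv"),
             config = paste0(stem, "_config.json"))
  utils::write.csv(cohort$students, paths[["students"]], row.names = FALSE)
  utils::write.csv(cohort$schools, paths[["schools"]], row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Read a student table written by [write_cohort()] (or any compatible CSV)
#'
#' @param path path to the student-level CSV.
#' @return data.frame of student records.
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path)
}
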