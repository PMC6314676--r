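#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles the cohort source (a generator config or a CSV of student
#' records), the outcome/predictor/environment/variant cross to run, and the
#' randomization settings. All randomness derives from `seed`.
#'
#' @param generator a [cohort_config()] (ignored when `input` is given).
#' @param input optional path to a student-level CSV (see
#'   [read_cohort_csv()] for the expected columns).
#' @param outcomes subset of `c("edu_years", "any_postsec", "college",
#'   "job_status")`.
#' @param predictors subset of `c("pgs", "ses", "cognition")`.
#' @param environments subset of `c("status", "stratification")`.
#' @param variants subset of `c("random_intercept", "mean_centered")`.
#' @param R randomizations per indirect fit (>= 100 when randomization is
#'   requested).
#' @param randomization run the randomization test in the indirect suite.
#' @param include_family add the nested family random effect.
#' @param min_school_size school-inclusion threshold for environment-based
#'   analyses.
#' @param seed root seed.
#' @param output_dir optional directory for cached stage outputs (CSV).
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(generator = cohort_config(),
                            input = NULL,
                            outcomes = c("edu_years", "any_postsec",
                                         "college", "job_status"),
                            predictors = c("pgs", "ses", "cognition"),
                            environments = c("status", "stratification"),
                            variants = c("random_intercept", "mean_centered"),
                            R = 1000, randomization = TRUE,
                            include_family = FALSE,
                            min_school_size = 10,
                            seed = 1L, output_dir = NULL) {
  if (length(outcomes) == 0 || length(predictors) == 0)
    stop("outcomes and predictors must be non-empty", call. = FALSE)
  if (randomization && R < 100)
    stop("R must be >= 100 when randomization is requested", call. = FALSE)
  structure(list(generator = generator, input = input,
                 outcomes = outcomes, predictors = predictors,
                 environments = environments, variants = variants,
                 R = R, randomization = randomization,
                 include_family = include_family,
                 min_school_size = min_school_size,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "analysis_config")
}

pipeline_students <- function(config) {
  if (!is.null(config$input)) return(read_cohort_csv(config$input))
  gen <- config$generator
  gen$seed <- config$seed
  generate_cohort(gen)$students
}

pipeline_provenance <- function(config) {
  cfg <- config
  cfg$output_dir <- NULL
  list(seed = config$seed,
       version = as.character(utils::packageVersion("schoolgxe")),
       config_hash = config_hash(unclass(cfg)))
}

# stage cache: reuse <output_dir>/<stage>.csv when the stored config hash
# matches, so an unchanged rerun performs no refits
cache_lookup <- function(config, stage, prov) {
  if (is.null(config$output_dir)) return(NULL)
  csv <- file.path(config$output_dir, paste0(stage, ".csv"))
  meta <- file.path(config$output_dir, paste0(stage, ".meta.json"))
  if (file.exists(csv) && file.exists(meta)) {
    m <- jsonlite::read_json(meta)
    if (identical(m$config_hash, prov$config_hash)) {
      message("reusing cached ", stage, " results (config hash match)")
      return(utils::read.csv(csv))
    }
  }
  NULL
}

cache_store <- function(config, stage, prov, result) {
  if (is.null(config$output_dir)) return(invisible(NULL))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result,
                   file.path(config$output_dir, paste0(stage, ".csv")),
                   row.names = FALSE)
  jsonlite::write_json(prov,
                       file.path(config$output_dir,
                                 paste0(stage, ".meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Run the indirect (random-slope) analysis suite
#'
#' Fits the indirect model for every outcome x predictor x variant in the
#' config and, when requested, runs the randomization test on the variance
#' components, yielding a variance-component report: one row per
#' combination with the fixed slope, its SE, the intercept- and
#' slope-variance components with their randomization p-values, convergence
#' diagnostics and full provenance (seed, package version, config hash).
#'
#' Non-converged primary fits abort the affected row (with the reason in the
#' `note` column), not the suite. Results are cached in `output_dir` keyed
#' on the config hash; an unchanged rerun performs no refits.
#'
#' @param config an [analysis_config()].
#' @return data.frame report.
#' @export
run_indirect_suite <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  prov <- pipeline_provenance(config)
  cached <- cache_lookup(config, "indirect_suite", prov)
  if (!is.null(cached)) return(cached)
  students <- pipeline_students(config)

  grid <- expand.grid(outcome = config$outcomes,
                      predictor = config$predictors,
                      variant = config$variants,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    row <- data.frame(outcome = g$outcome, predictor = g$predictor,
                      variant = g$variant,
                      beta1 = NA_real_, se_beta1 = NA_real_,
                      sigma_mu = NA_real_, pv_sigma_mu = NA_real_,
                      sigma_delta = NA_real_, pv_sigma_delta = NA_real_,
                      converged = NA, note = "",
                      seed = prov$seed, version = prov$version,
                      config_hash = prov$config_hash)
    fit <- tryCatch(fit_indirect(students, g$outcome, g$predictor,
                                 variant = g$variant,
                                 include_family = config$include_family),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      row$note <- conditionMessage(fit)
      return(row)
    }
    row$beta1 <- fit$beta1; row$se_beta1 <- fit$se_beta1
    row$sigma_mu <- fit$sigma_mu; row$sigma_delta <- fit$sigma_delta
    row$converged <- fit$converged
    if (!fit$converged) {
      row$note <- "primary fit did not converge; randomization skipped"
      return(row)
    }
    if (config$randomization) {
      comps <- if (g$variant == "random_intercept")
        c("sigma_mu", "sigma_delta") else "sigma_delta"
      rt <- randomization_test(students, g$outcome, g$predictor,
                               variant = g$variant, components = comps,
                               R = config$R, seed = prov$seed + i,
                               include_family = config$include_family,
                               observed_fit = fit)
      if ("sigma_mu" %in% comps)
        row$pv_sigma_mu <- rt$components$sigma_mu$p_value
      row$pv_sigma_delta <- rt$components$sigma_delta$p_value
      if (rt$unreliable) row$note <- "randomization unreliable (>20% failed fits)"
    }
    row
  })
  out <- do.call(rbind, rows)
  cache_store(config, "indirect_suite", prov, out)
  out
}

#' Run the direct (named-moderator) analysis suite
#'
#' Builds the school-environment table from the student microdata, applies
#' the minimum-size filter, and fits the direct GxE model for every outcome
#' x predictor x environment in the config: one row per combination with
#' the interaction coefficient, its SE and two-sided p-value, plus
#' provenance. Cached like [run_indirect_suite()].
#'
#' @param config an [analysis_config()].
#' @return data.frame report.
#' @export
run_direct_suite <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  prov <- pipeline_provenance(config)
  cached <- cache_lookup(config, "direct_suite", prov)
  if (!is.null(cached)) return(cached)
  students <- pipeline_students(config)
  env <- school_environments(students, min_size = config$min_school_size)
  message(sum(!env$included), " of ", nrow(env),
          " schools excluded by the size-", config$min_school_size,
          " filter")

  grid <- expand.grid(outcome = config$outcomes,
                      predictor = config$predictors,
                      environment = config$environments,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    row <- data.frame(outcome = g$outcome, predictor = g$predictor,
                      environment = g$environment,
                      beta3 = NA_real_, se_beta3 = NA_real_,
                      p_beta3 = NA_real_, converged = NA, note = "",
                      seed = prov$seed, version = prov$version,
                      config_hash = prov$config_hash)
    fit <- tryCatch(fit_direct(students, g$outcome, g$predictor,
                               environments = env, env = g$environment,
                               min_school_size = config$min_school_size,
                               include_family = config$include_family),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      row$note <- conditionMessage(fit)
      return(row)
    }
    row$beta3 <- fit$beta3; row$se_beta3 <- fit$se_beta3
    row$p_beta3 <- fit$p_beta3; row$converged <- fit$converged
    if (!fit$converged) row$note <- "fit did not converge"
    row
  })
  out <- do.call(rbind, rows)
  cache_store(config, "direct_suite", prov, out)
  out
}
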