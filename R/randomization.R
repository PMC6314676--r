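#' Randomly reassign students to schools of fixed sizes
#'
#' Permutes the `school_id` column uniformly over students while conserving
#' the observed multiset of school sizes exactly; every other column is
#' untouched. With `keep_families_together = TRUE` the unit of reassignment
#' is the family: whole families are placed into schools with remaining
#' capacity (probability proportional to remaining slots), so siblings stay
#' together under the null.
#'
#' @param students data.frame with `school_id` (and `family_id` when
#'   permuting family blocks).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param keep_families_together move sibling groups as blocks.
#' @return `students` with permuted `school_id`.
#' @export
permute_school_assignment <- function(students, seed = NULL,
                                      keep_families_together = FALSE) {
  do_permute <- function() {
    if (!keep_families_together) {
      students$school_id <- sample(students$school_id)
      return(students)
    }
    if (is.null(students$family_id))
      stop("keep_families_together = TRUE requires family_id", call. = FALSE)
    sizes <- table(students$school_id)
    school_ids <- names(sizes)
    fam_sizes <- table(students$family_id)
    if (max(fam_sizes) > max(sizes))
      stop("a family is larger than the largest school", call. = FALSE)
    for (attempt in 1:25) {
      cap <- as.integer(sizes)
      # place larger families first so pairs are never stranded among
      # single leftover slots; random order within each size class
      fams <- sample(names(fam_sizes))
      fams <- fams[order(fam_sizes[fams], decreasing = TRUE)]
      assign_to <- character(length(fams))
      ok <- TRUE
      for (k in seq_along(fams)) {
        fs <- fam_sizes[[fams[k]]]
        fit <- which(cap >= fs)
        if (!length(fit)) { ok <- FALSE; break }
        j <- if (length(fit) == 1) fit else
          sample(fit, 1, prob = cap[fit])
        assign_to[k] <- school_ids[j]
        cap[j] <- cap[j] - fs
      }
      if (ok) {
        new_school <- assign_to[match(as.character(students$family_id), fams)]
        if (is.numeric(students$school_id))
          new_school <- as.numeric(new_school)
        students$school_id <- new_school
        return(students)
      }
    }
    stop("could not place all families into school slots", call. = FALSE)
  }
  if (is.null(seed)) do_permute() else withr::with_seed(seed, do_permute())
}

# add-one permutation p-value: (1 + #{null >= observed}) / (successful + 1).
# One-sided (>=): variance components are non-negative and the alternative
# is "more between-school variation than chance". Equals one minus the
# empirical quantile rank up to the finite-sample correction, and is never 0.
perm_pvalue <- function(observed, null_draws) {
  draws <- null_draws[!is.na(null_draws)]
  (1 + sum(draws >= observed)) / (length(draws) + 1)
}

#' Randomization (Fisher-style) test for school-level moderation
#'
#' Compares observed variance components of the indirect random-slope model
#' against their distribution over `R` random reassignments of students to
#' schools of fixed sizes. The null hypothesis is that there is no
#' school-level structure: school assignment carries no information about
#' either the level of the outcome (\eqn{\sigma_\mu}) or the strength of the
#' predictor's association (\eqn{\sigma_\delta}). Each permuted data set is
#' refit with the same model specification and the permutation p-value is
#' the add-one estimator \eqn{(1 + \#\{\hat\sigma^{(r)} \ge
#' \hat\sigma^{obs}\}) / (R_{ok} + 1)}.
#'
#' Null fits that error or fail to converge are dropped and counted; a
#' result with more than 20% failures is flagged unreliable.
#'
#' @param data a `gxe_cohort` or student data.frame.
#' @param outcome,predictor,variant,include_family model specification
#'   passed to [fit_indirect()].
#' @param components which components to test; defaults to
#'   `c("sigma_mu", "sigma_delta")` for the random-intercept variant and
#'   `"sigma_delta"` for the mean-centered variant.
#' @param R number of randomizations (>= 100).
#' @param seed root seed; per-replicate seeds derive from it, so results are
#'   reproducible and replicates could be distributed.
#' @param keep_families_together permute whole families.
#' @param observed_fit optionally, a pre-computed [fit_indirect()] result for
#'   the observed data (must match the specification).
#' @return an object of class `randomization_result`: per component, the
#'   observed value, the vector of null draws, the failure count and the
#'   p-value; plus `R`, `seed` and an `unreliable` flag.
#' @export
randomization_test <- function(data, outcome, predictor = "pgs",
                               variant = c("random_intercept",
                                           "mean_centered"),
                               components = NULL,
                               R = 1000, seed = 1L,
                               include_family = FALSE,
                               keep_families_together = FALSE,
                               observed_fit = NULL) {
  variant <- match.arg(variant)
  if (R < 100) stop("R must be >= 100", call. = FALSE)
  students <- as_students(data)
  if (is.null(components))
    components <- if (variant == "random_intercept")
      c("sigma_mu", "sigma_delta") else "sigma_delta"
  if (variant == "mean_centered" && "sigma_mu" %in% components)
    stop("mean_centered variant has no sigma_mu component", call. = FALSE)

  if (is.null(observed_fit))
    observed_fit <- fit_indirect(students, outcome, predictor,
                                 variant = variant,
                                 include_family = include_family)
  if (!observed_fit$converged)
    stop("observed fit did not converge; randomization test aborted",
         call. = FALSE)

  seeds <- derive_seeds(seed, R)
  draws <- matrix(NA_real_, nrow = R, ncol = length(components),
                  dimnames = list(NULL, components))
  sampler <- null_component_sampler(students, outcome, predictor,
                                    variant = variant,
                                    include_family = include_family)
  withr::with_preserve_seed({
    for (r in seq_len(R)) {
      set.seed(seeds[r])
      perm_school <- if (keep_families_together)
        permute_school_assignment(students,
                                  keep_families_together = TRUE)$school_id
      else sample(students$school_id)
      comps <- sampler(perm_school)
      if (!is.null(comps)) draws[r, ] <- comps[components]
    }
  })

  results <- lapply(components, function(cm) {
    obs <- observed_fit[[cm]]
    nd <- draws[, cm]
    ok <- !is.na(nd)
    list(component_name = cm,
         observed_value = obs,
         null_draws = nd[ok],
         n_failed_fits = sum(!ok),
         p_value = perm_pvalue(obs, nd))
  })
  names(results) <- components
  n_failed <- max(vapply(results, `[[`, 0L, "n_failed_fits"))
  structure(list(components = results,
                 outcome = outcome, predictor = predictor, variant = variant,
                 R = R, seed = seed,
                 unreliable = n_failed > 0.2 * R),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat("Randomization test (", x$R, " reassignments): ",
      x$outcome, " ~ ", x$predictor, " [", x$variant, "]\n", sep = "")
  for (cm in x$components)
    cat(sprintf("  %-12s observed = %.4f  p = %.4g  (failed fits: %d)\n",
                cm$component_name, cm$observed_value, cm$p_value,
                cm$n_failed_fits))
  if (x$unreliable)
    cat("  WARNING: > 20% of null fits failed; result unreliable\n")
  invisible(x)
}

# Closure that refits the indirect model under a permuted school assignment
# and returns the variance components, via lme4's modular API: the model
# frame and fixed-effect design are built once; each call rebuilds only the
# random-effect terms for the new grouping (and re-demeans the outcome for
# the mean-centered variant), then optimizes the same REML deviance lmer
# would. Agreement with fit_indirect() is pinned by tests. Returns NULL for
# failed or non-converged fits.
null_component_sampler <- function(students, outcome, predictor,
                                   variant, include_family = FALSE) {
  fr0 <- model_frame(students, outcome, predictor,
                     standardize_outcome = NULL)
  d <- fr0$data
  covs <- fr0$covariates
  re <- if (variant == "random_intercept") "(1 + x | school_id)"
        else "(0 + x | school_id)"
  if (include_family) re <- paste(re, "+ (1 | school_id:family_id)")
  form <- stats::as.formula(
    paste("y ~ x", if (length(covs)) paste("+", paste(covs, collapse = " + "))
          else "", "+", re))
  y_raw <- d$y
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  lmod <- lme4::lFormula(form, data = d, REML = TRUE, control = ctrl)
  bars <- lme4::findbars(form)

  function(perm_school) {
    fr <- lmod$fr
    fr$school_id <- factor(perm_school)
    if (variant == "mean_centered")
      fr$y <- y_raw - stats::ave(y_raw, perm_school)
    out <- tryCatch({
      reTrms <- lme4::mkReTrms(bars, fr)
      devfun <- lme4::mkLmerDevfun(fr = fr, X = lmod$X, reTrms = reTrms,
                                   REML = TRUE, control = ctrl)
      opt <- lme4::optimizeLmer(devfun, control = ctrl$optCtrl)
      if (!is.null(opt$conv) && opt$conv != 0) return(NULL)
      # theta holds the lower-Cholesky factor of each block of the relative
      # covariance matrix (column-wise); components are theta scaled by the
      # REML residual SD. Locate the school block by the reTrms term names.
      rho <- environment(devfun)
      n <- nrow(fr); p <- ncol(lmod$X)
      sigma <- sqrt((rho$resp$wrss() + rho$pp$sqrL(1)) / (n - p))
      cn <- reTrms$cnms
      sizes <- vapply(cn, function(z) length(z) * (length(z) + 1) / 2, 0)
      off <- cumsum(c(0, sizes))[match("school_id", names(cn))]
      th <- opt$par
      if (variant == "random_intercept")
        c(sigma_mu = sigma * th[off + 1],
          sigma_delta = sigma * sqrt(th[off + 2]^2 + th[off + 3]^2))
      else c(sigma_delta = sigma * th[off + 1])
    }, error = function(e) NULL)
    out
  }
}

#' Tidy one-row-per-component summary of a randomization result
#'
#' @param x a `randomization_result`.
#' @return data.frame with component, observed value, R, failures, p.
#' @export
as.data.frame.randomization_result <- function(x, ...) {
  do.call(rbind, lapply(x$components, function(cm)
    data.frame(outcome = x$outcome, predictor = x$predictor,
               variant = x$variant, component = cm$component_name,
               observed = cm$observed_value, R = x$R,
               n_failed_fits = cm$n_failed_fits, p_value = cm$p_value)))
}
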