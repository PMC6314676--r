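#' Fit the indirect (random-slope) moderation model
#'
#' Estimates, for student \eqn{i} in school \eqn{j},
#' \deqn{y_{ij} = \beta_0 + \mu_j + (\beta_1 + \delta_j)\,x_{ij} +
#'   X'\beta + \epsilon_{ij}, \qquad (\mu_j, \delta_j) \sim N(0, \Omega)}
#' by REML (lme4). The focal quantity is \eqn{\sigma_\delta}, the SD of the
#' school-specific slopes: between-school variation in the predictor's
#' association without naming a moderator. The `mean_centered` variant first
#' school-demeans the outcome and drops the random intercept, fitting a
#' random slope only; this removes between-school level differences (and with
#' them intercept-slope covariance pathways) by construction.
#'
#' Continuous outcomes are standardized (population SD) before fitting;
#' binary outcomes are kept on the 0/1 probability scale (linear probability
#' model) with standardized predictors. Sex and z-scored birth year enter as
#' covariates. Variance components are bounded at 0 by the estimator;
#' boundary estimates are reported as exact 0 with a `boundary` flag.
#'
#' @param data a `gxe_cohort` or student data.frame.
#' @param outcome outcome column name.
#' @param predictor focal predictor column (`"pgs"`, `"ses"` or
#'   `"cognition"`).
#' @param variant `"random_intercept"` (random intercept + slope) or
#'   `"mean_centered"` (school-demeaned outcome, random slope only).
#' @param include_family add a family random intercept nested within school
#'   (sibling relatedness).
#' @param standardize_outcome `NULL` (auto: standardize unless the outcome
#'   is 0/1), or a logical.
#' @param reml use REML (default) or ML.
#' @param fast skip the finite-difference convergence-check derivatives
#'   (used inside permutation and power loops).
#' @return an object of class `indirect_fit`: fixed effects with SEs, the
#'   estimated components `sigma_mu`, `sigma_delta`, `sigma_mu_delta` (with
#'   implied correlation), `sigma_family`, `sigma_eps`, log-likelihood,
#'   convergence and boundary flags, outcome scaling parameters, and the
#'   underlying `merMod` in `$model`.
#' @export
fit_indirect <- function(data, outcome, predictor = "pgs",
                         variant = c("random_intercept", "mean_centered"),
                         include_family = FALSE,
                         standardize_outcome = NULL,
                         reml = TRUE, fast = FALSE) {
  variant <- match.arg(variant)
  students <- as_students(data)
  if (length(unique(students$school_id)) < 2)
    stop("need at least 2 schools", call. = FALSE)

  fr <- model_frame(students, outcome, predictor, standardize_outcome)
  if (variant == "mean_centered")
    fr$data <- center_within_school(fr$data, "y")

  covs <- fr$covariates
  re <- if (variant == "random_intercept") "(1 + x | school_id)"
        else "(0 + x | school_id)"
  if (include_family) {
    if (!"family_id" %in% names(fr$data))
      stop("include_family = TRUE but no family_id column", call. = FALSE)
    re <- paste(re, "+ (1 | school_id:family_id)")
  }
  form <- stats::as.formula(
    paste("y ~ x", if (length(covs)) paste("+", paste(covs, collapse = " + "))
          else "", "+", re))

  fit <- fit_lmer(form, fr$data, reml = reml, fast = fast)
  m <- fit$model

  fe <- fixef_table(m)
  vc <- lme4::VarCorr(m)
  sch <- vc[["school_id"]]
  if (variant == "random_intercept") {
    sds <- attr(sch, "stddev")
    sigma_mu <- unname(sds["(Intercept)"])
    sigma_delta <- unname(sds["x"])
    sigma_mu_delta <- sch["(Intercept)", "x"]
  } else {
    sigma_mu <- NA_real_
    sigma_delta <- unname(attr(sch, "stddev")["x"])
    sigma_mu_delta <- NA_real_
  }
  rho <- if (!is.na(sigma_mu) && sigma_mu > 0 && sigma_delta > 0)
    sigma_mu_delta / (sigma_mu * sigma_delta) else NA_real_
  sigma_family <- if (include_family)
    unname(attr(vc[["school_id:family_id"]], "stddev")[1]) else NA_real_

  structure(list(
    outcome = outcome, predictor = predictor, variant = variant,
    beta0 = fe["(Intercept)", "estimate"],
    se_beta0 = fe["(Intercept)", "se"],
    beta1 = fe["x", "estimate"], se_beta1 = fe["x", "se"],
    sigma_mu = sigma_mu, sigma_delta = sigma_delta,
    sigma_mu_delta = sigma_mu_delta, rho_mu_delta = rho,
    sigma_family = sigma_family,
    sigma_eps = stats::sigma(m),
    loglik = as.numeric(stats::logLik(m)),
    converged = fit$converged,
    boundary = lme4::isSingular(m),
    messages = fit$messages,
    n = nrow(fr$data), n_schools = length(unique(fr$data$school_id)),
    outcome_scale = fr$outcome_scale,
    include_family = include_family,
    model = m), class = "indirect_fit")
}

#' @export
print.indirect_fit <- function(x, ...) {
  cat("Indirect (random-slope) moderation fit —", x$variant, "\n")
  cat(sprintf("  outcome: %s  predictor: %s  n = %d in %d schools\n",
              x$outcome, x$predictor, x$n, x$n_schools))
  cat(sprintf("  beta1 = %.4f (SE %.4f)\n", x$beta1, x$se_beta1))
  if (!is.na(x$sigma_mu))
    cat(sprintf("  sigma_mu = %.4f  sigma_delta = %.4f  rho = %s\n",
                x$sigma_mu, x$sigma_delta,
                ifelse(is.na(x$rho_mu_delta), "NA",
                       sprintf("%.3f", x$rho_mu_delta))))
  else
    cat(sprintf("  sigma_delta = %.4f (mean-centered: no random intercept)\n",
                x$sigma_delta))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  if (x$boundary) cat("  note: variance estimate on the boundary (reported as 0)\n")
  invisible(x)
}

#' Fit the direct (named-moderator) GxE model
#'
#' Estimates
#' \deqn{y_{ij} = \beta_0 + u_j + \beta_1 x_{ij} + \beta_2 E_j +
#'   \beta_3\, x_{ij} E_j + X'\beta + \epsilon_{ij}}
#' with a school random intercept \eqn{u_j}. Interest lies in \eqn{\beta_3},
#' the cross-level interaction. To guard against spurious interaction
#' findings, the covariate block always includes the interactions of both
#' key predictors with sex and (z-scored) birth year.
#'
#' Only schools meeting the minimum-size rule enter; the environment is
#' z-scored over included schools (an error if it is constant). Outcome and
#' focal predictor are standardized as in [fit_indirect()]. Fixed-effect
#' p-values are two-sided Wald (normal) tests.
#'
#' @param data a `gxe_cohort` or student data.frame.
#' @param outcome outcome column name.
#' @param predictor focal predictor column.
#' @param environments per-school table with `school_id`, `n_students` and
#'   the environment column (e.g. from [school_environments()], or the
#'   generator's truth table).
#' @param env name of the environment column (e.g. `"status"`,
#'   `"stratification"`).
#' @param min_school_size schools below this size are excluded (default 10).
#' @param include_family add a family random intercept nested within school.
#' @param standardize_outcome,reml,fast as in [fit_indirect()].
#' @return an object of class `direct_fit`: the full fixed-effect table
#'   (`$coefficients`), the focal `beta3`/`se_beta3`/`p_beta3`, main effects,
#'   guard-interaction estimates, `sigma_u`, `sigma_eps`, convergence flags,
#'   and the `merMod` in `$model`.
#' @export
fit_direct <- function(data, outcome, predictor = "pgs", environments,
                       env = "status", min_school_size = 10,
                       include_family = FALSE, standardize_outcome = NULL,
                       reml = TRUE, fast = FALSE) {
  students <- as_students(data)
  if (!env %in% names(environments))
    stop("no environment column '", env, "'", call. = FALSE)
  keep <- environments$n_students >= min_school_size &
    !is.na(environments[[env]])
  inc <- environments[keep, , drop = FALSE]
  if (nrow(inc) < 2) stop("fewer than 2 included schools", call. = FALSE)
  evals <- inc[[env]]
  if (pop_sd(evals) == 0 || is.na(pop_sd(evals)))
    stop("environment '", env, "' has zero variance across included schools",
         call. = FALSE)
  ez <- zscore(evals)
  students <- students[students$school_id %in% inc$school_id, , drop = FALSE]

  fr <- model_frame(students, outcome, predictor, standardize_outcome)
  d <- fr$data
  d$e <- ez[match(d$school_id, inc$school_id)]

  covs <- fr$covariates
  guards <- unlist(lapply(covs, function(cv) paste0(cv, c(":x", ":e"))))
  rhs <- c("x", "e", "x:e", covs, guards, "(1 | school_id)")
  if (include_family) rhs <- c(rhs, "(1 | school_id:family_id)")
  form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))

  fit <- fit_lmer(form, d, reml = reml, fast = fast)
  m <- fit$model
  fe <- fixef_table(m)

  pick <- function(term, col) {
    i <- match(term, rownames(fe))
    if (is.na(i)) {
      i <- match(paste(rev(strsplit(term, ":")[[1]]), collapse = ":"),
                 rownames(fe))
    }
    if (is.na(i)) NA_real_ else fe[i, col]
  }
  vc <- lme4::VarCorr(m)

  structure(list(
    outcome = outcome, predictor = predictor, environment = env,
    coefficients = fe,
    beta1 = pick("x", "estimate"), se_beta1 = pick("x", "se"),
    p_beta1 = pick("x", "p"),
    beta2 = pick("e", "estimate"), se_beta2 = pick("e", "se"),
    p_beta2 = pick("e", "p"),
    beta3 = pick("x:e", "estimate"), se_beta3 = pick("x:e", "se"),
    p_beta3 = pick("x:e", "p"),
    guards = fe[intersect(rownames(fe),
                          c(guards, sapply(strsplit(guards, ":"), function(g)
                            paste(rev(g), collapse = ":")))), , drop = FALSE],
    sigma_u = unname(attr(vc[["school_id"]], "stddev")[1]),
    sigma_eps = stats::sigma(m),
    converged = fit$converged,
    boundary = lme4::isSingular(m),
    n = nrow(d), n_schools = nrow(inc),
    outcome_scale = fr$outcome_scale,
    model = m), class = "direct_fit")
}

#' @export
print.direct_fit <- function(x, ...) {
  cat("Direct GxE fit:", x$outcome, "~", x$predictor, "x", x$environment, "\n")
  cat(sprintf("  n = %d in %d included schools\n", x$n, x$n_schools))
  cat(sprintf("  beta1 = %.4f (SE %.4f)   beta2 = %.4f (SE %.4f)\n",
              x$beta1, x$se_beta1, x$beta2, x$se_beta2))
  cat(sprintf("  beta3 = %.4f (SE %.4f, p = %.4g)\n",
              x$beta3, x$se_beta3, x$p_beta3))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' Per-school predicted outcomes at fixed predictor values
#'
#' For each school and each predictor value \eqn{p}, computes
#' \eqn{\hat y_j(p) = \hat\beta_0 + \hat\mu_j + (\hat\beta_1 + \hat\delta_j) p}
#' using the empirical-Bayes (BLUP) school effects, plus the cross-school
#' distribution of the prediction at each \eqn{p}. For a standardized
#' continuous outcome, `scale = "raw"` maps predictions back to the original
#' units (e.g. years of education). Mean-centered fits have no intercept
#' distribution and return slope-only trajectories with `slope_only = TRUE`.
#'
#' @param fit an `indirect_fit`.
#' @param pgs_values predictor values on the standardized scale (default
#'   `c(-2, 0, 2)`).
#' @param scale `"standardized"` or `"raw"` (back-transformed outcome units).
#' @return a list with `per_school` (school_id, mu_hat, delta_hat, and one
#'   prediction column per value), `summary` (cross-school mean, SD, range
#'   and quartiles at each value) and `slope_only`.
#' @export
school_predictions <- function(fit, pgs_values = c(-2, 0, 2),
                               scale = c("standardized", "raw")) {
  stopifnot(inherits(fit, "indirect_fit"))
  scale <- match.arg(scale)
  if (!fit$converged)
    warning("fit did not converge; predictions may be unreliable",
            call. = FALSE)
  if (any(!is.finite(pgs_values))) stop("pgs_values must be finite",
                                        call. = FALSE)
  re <- lme4::ranef(fit$model)$school_id
  slope_only <- fit$variant == "mean_centered"
  mu_hat <- if (slope_only) rep(0, nrow(re)) else re[["(Intercept)"]]
  delta_hat <- re[["x"]]
  beta0 <- if (slope_only) 0 else fit$beta0

  per_school <- data.frame(school_id = rownames(re),
                           mu_hat = mu_hat, delta_hat = delta_hat)
  backmap <- function(y) {
    if (scale == "raw" && !is.null(fit$outcome_scale))
      y * fit$outcome_scale[["scale"]] + fit$outcome_scale[["center"]]
    else y
  }
  summ <- lapply(pgs_values, function(p) {
    yhat <- beta0 + mu_hat + (fit$beta1 + delta_hat) * p
    if (scale == "raw" && slope_only)
      yhat <- yhat * fit$outcome_scale[["scale"]]  # deviations only
    else yhat <- backmap(yhat)
    per_school[[sprintf("pred_%g", p)]] <<- yhat
    q <- stats::quantile(yhat, c(.25, .5, .75))
    data.frame(pgs = p, mean = mean(yhat), sd = stats::sd(yhat),
               min = min(yhat), q25 = q[[1]], median = q[[2]],
               q75 = q[[3]], max = max(yhat))
  })
  list(per_school = per_school, summary = do.call(rbind, summ),
       slope_only = slope_only, scale = scale)
}

# ---- internal helpers -------------------------------------------------------

# assemble analysis frame: y (standardized unless binary), x (z-scored
# predictor), covariates sex and z-scored birth year when non-constant
model_frame <- function(students, outcome, predictor, standardize_outcome) {
  y <- students[[outcome]]
  if (is.null(y)) stop("no outcome column '", outcome, "'", call. = FALSE)
  x <- students[[predictor]]
  if (is.null(x)) stop("no predictor column '", predictor, "'", call. = FALSE)
  if (is.na(pop_sd(y)) || pop_sd(y) == 0)
    stop("outcome '", outcome, "' has zero variance", call. = FALSE)
  binary <- all(y %in% c(0, 1))
  if (is.null(standardize_outcome)) standardize_outcome <- !binary
  outcome_scale <- c(center = 0, scale = 1)
  if (standardize_outcome) {
    m <- mean(y); s <- pop_sd(y)
    if (s == 0) stop("outcome '", outcome, "' has zero variance", call. = FALSE)
    y <- (y - m) / s
    outcome_scale <- c(center = m, scale = s)
  }
  if (pop_sd(x) == 0) stop("predictor '", predictor, "' has zero variance",
                           call. = FALSE)
  d <- data.frame(y = y, x = zscore(x),
                  school_id = factor(students$school_id))
  if (!is.null(students$family_id)) d$family_id <- factor(students$family_id)
  covs <- character()
  if (!is.null(students$sex) && pop_sd(students$sex) > 0) {
    d$sex <- students$sex
    covs <- c(covs, "sex")
  }
  if (!is.null(students$birth_year) && pop_sd(students$birth_year) > 0) {
    d$birth_year_z <- zscore(students$birth_year)
    covs <- c(covs, "birth_year_z")
  }
  list(data = d, covariates = covs, outcome_scale = outcome_scale)
}

fit_lmer <- function(form, data, reml = TRUE, fast = FALSE) {
  ctrl <- lme4::lmerControl(calc.derivs = !fast,
                            check.conv.singular = "ignore")
  msgs <- character()
  m <- withCallingHandlers(
    lme4::lmer(form, data = data, REML = reml, control = ctrl),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(cnd) {
      msgs <<- c(msgs, conditionMessage(cnd))
      invokeRestart("muffleMessage")
    })
  opt_ok <- isTRUE(m@optinfo$conv$opt == 0)
  lme4_msgs <- unlist(m@optinfo$conv$lme4$messages)
  conv_bad <- any(grepl("failed to converge", c(msgs, lme4_msgs),
                        ignore.case = TRUE))
  list(model = m, converged = opt_ok && !conv_bad,
       messages = unique(c(msgs, lme4_msgs)))
}

fixef_table <- function(m) {
  est <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(stats::vcov(m))))
  z <- est / se
  data.frame(estimate = est, se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)),
             row.names = names(est))
}
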