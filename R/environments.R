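#' School status: proportion of mothers with at least a high-school diploma
#'
#' @param mother_hs 0/1 vector for one school; `NA`s are excluded.
#' @return the proportion, or `NA` (with a warning) when all values are
#'   missing.
#' @export
school_status <- function(mother_hs) {
  x <- mother_hs[!is.na(mother_hs)]
  if (length(x) == 0) {
    warning("school has no non-missing mother_hs values; status set to NA",
            call. = FALSE)
    return(NA_real_)
  }
  mean(x)
}

#' School stratification: Gini coefficient of parental education
#'
#' Computes \eqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x)} (the
#' population denominator; `denominator = "sample"` replaces \eqn{n^2} with
#' \eqn{n(n-1)}). Uses the sorted-order identity, which is algebraically
#' exact, rather than the O(n^2) double sum. G lies in \eqn{[0, 1 - 1/n]}
#' and is 0 iff all values are equal.
#'
#' @param x non-negative parental-education values for one school; `NA`s
#'   are excluded.
#' @param denominator `"population"` (default) or `"sample"`.
#' @return the Gini coefficient, or `NA` (with a warning) when undefined
#'   (no data or zero mean).
#' @export
school_gini <- function(x, denominator = c("population", "sample")) {
  denominator <- match.arg(denominator)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) {
    warning("school has no non-missing parental-education values; Gini NA",
            call. = FALSE)
    return(NA_real_)
  }
  if (any(x < 0)) stop("parental-education values must be non-negative",
                       call. = FALSE)
  total <- sum(x)
  if (total == 0) {
    warning("all parental-education values are zero; Gini undefined",
            call. = FALSE)
    return(NA_real_)
  }
  if (n == 1) return(0)
  xs <- sort(x)
  g <- sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mean(xs))
  if (denominator == "sample") g <- g * n / (n - 1)
  g
}

#' Build the per-school environment table from student microdata
#'
#' Computes, for every school, its size, the school-status measure (mean of
#' `mother_hs` over non-missing values) and the school-stratification measure
#' (Gini of `parent_edu_years`), and flags schools meeting the minimum-size
#' inclusion rule.
#'
#' @param students data.frame with `school_id`, `mother_hs`,
#'   `parent_edu_years` columns (a `gxe_cohort` is also accepted).
#' @param min_size minimum number of students for a school to be included
#'   (default 10).
#' @param gini_denominator passed to [school_gini()].
#' @return data.frame with columns `school_id`, `n_students`, `status`,
#'   `stratification`, `included`, ordered by `school_id`.
#' @export
school_environments <- function(students, min_size = 10,
                                gini_denominator = "population") {
  students <- as_students(students)
  ids <- sort(unique(students$school_id))
  rows <- lapply(ids, function(j) {
    s <- students[students$school_id == j, ]
    data.frame(school_id = j,
               n_students = nrow(s),
               status = suppressWarnings(school_status(s$mother_hs)),
               stratification = suppressWarnings(
                 school_gini(s$parent_edu_years,
                             denominator = gini_denominator)))
  })
  env <- do.call(rbind, rows)
  env$included <- env$n_students >= min_size
  rownames(env) <- NULL
  env
}

#' Keep schools meeting a minimum-size threshold
#'
#' @param environments per-school table with an `n_students` column.
#' @param threshold minimum size (default 10); the boundary is inclusive.
#' @param quiet suppress the excluded-school count message.
#' @return the included subset.
#' @export
filter_min_size <- function(environments, threshold = 10, quiet = FALSE) {
  stopifnot(threshold >= 1)
  keep <- environments$n_students >= threshold
  if (!quiet)
    message(sum(!keep), " of ", length(keep),
            " schools excluded by the size-", threshold, " filter")
  out <- environments[keep, , drop = FALSE]
  if ("included" %in% names(out)) out$included <- TRUE
  rownames(out) <- NULL
  out
}

#' Between-school share of a variable's variance
#'
#' Fits a random-intercept-only (unconditional means) model of the variable
#' by REML and returns \eqn{\sigma^2_B / (\sigma^2_B + \sigma^2_W)}, the
#' intraclass correlation. This is the gene-environment-correlation
#' descriptive when applied to a polygenic score: the fraction of PGS
#' variation lying between schools.
#'
#' @param students data.frame (or `gxe_cohort`) with `school_id`.
#' @param variable column name to decompose.
#' @return the between-school share, in `[0, 1)`.
#' @export
between_school_share <- function(students, variable) {
  students <- as_students(students)
  x <- students[[variable]]
  if (is.null(x)) stop("no column '", variable, "'", call. = FALSE)
  ok <- !is.na(x)
  d <- data.frame(x = x[ok], school_id = factor(students$school_id[ok]))
  if (nlevels(d$school_id) < 2)
    stop("need at least 2 schools", call. = FALSE)
  if (stats::var(d$x) == 0)
    stop("'", variable, "' has zero total variance", call. = FALSE)
  fit <- lme4::lmer(x ~ 1 + (1 | school_id), data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vb <- vc$vcov[vc$grp == "school_id"]
  vw <- vc$vcov[vc$grp == "Residual"]
  vb / (vb + vw)
}

#' Correlation between school-mean PGS and a school environment
#'
#' Pearson correlation, over included schools, between the per-school mean
#' polygenic score and the chosen environment measure — the descriptive used
#' to quantify sorting of genotype across school contexts.
#'
#' @param students data.frame (or `gxe_cohort`).
#' @param environments per-school table with `school_id`, `included`, and
#'   the environment column.
#' @param env environment column name (default `"status"`).
#' @return the correlation, or `NA` (with a warning) when the environment
#'   has zero variance across included schools.
#' @export
schoolmean_pgs_env_correlation <- function(students, environments,
                                           env = "status") {
  students <- as_students(students)
  inc <- environments[environments$included %in% TRUE, , drop = FALSE]
  if (nrow(inc) < 3) stop("need at least 3 included schools", call. = FALSE)
  mean_pgs <- tapply(students$pgs, students$school_id, mean)
  m <- mean_pgs[as.character(inc$school_id)]
  e <- inc[[env]]
  if (stats::sd(e, na.rm = TRUE) == 0 || stats::sd(m) == 0) {
    warning("zero variance in '", env,
            "' or school-mean PGS; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(as.numeric(m), e, use = "complete.obs")
}

# accept either a gxe_cohort or a bare student data.frame
as_students <- function(x) {
  if (inherits(x, "gxe_cohort")) x$students else as.data.frame(x)
}
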