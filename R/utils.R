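#' Standardize columns of a student table
#'
#' Z-scores the named columns in place using the population-SD convention
#' (divide by \eqn{\sqrt{\sum (x_i - \bar x)^2 / n}}), so a two-point column
#' \code{c(0, 2)} maps to \code{c(-1, 1)}. The centering/scale parameters are
#' recorded in \code{attr(x, "standardize_params")} so the transformation can
#' be inverted with [unstandardize()].
#'
#' @param data data.frame of student records.
#' @param vars character vector of column names to z-score.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return `data` with the named columns z-scored and the parameters attached.
#' @export
standardize <- function(data, vars, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  params <- attr(data, "standardize_params")
  if (is.null(params)) params <- list()
  for (v in vars) {
    x <- data[[v]]
    if (!is.numeric(x)) stop("column '", v, "' is not numeric", call. = FALSE)
    m <- mean(x, na.rm = TRUE)
    s <- pop_sd(x, sd_type)
    if (!is.finite(s) || s == 0)
      stop("column '", v, "' has zero variance; cannot standardize",
           call. = FALSE)
    data[[v]] <- (x - m) / s
    params[[v]] <- c(center = m, scale = s)
  }
  attr(data, "standardize_params") <- params
  data
}

#' Invert a standardization
#'
#' @param data data.frame previously passed through [standardize()].
#' @param vars columns to back-transform (default: all recorded).
#' @return `data` with the columns on their original scale.
#' @export
unstandardize <- function(data, vars = NULL) {
  params <- attr(data, "standardize_params")
  if (is.null(params)) stop("no standardize_params attribute", call. = FALSE)
  if (is.null(vars)) vars <- names(params)
  for (v in vars) {
    p <- params[[v]]
    if (is.null(p)) stop("no recorded parameters for '", v, "'", call. = FALSE)
    data[[v]] <- data[[v]] * p[["scale"]] + p[["center"]]
    params[[v]] <- NULL
  }
  attr(data, "standardize_params") <- if (length(params)) params else NULL
  data
}

pop_sd <- function(x, sd_type = "population") {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) return(NA_real_)
  if (sd_type == "population") sqrt(sum((x - mean(x))^2) / n) else stats::sd(x)
}

# z-score a vector with the population-SD convention
zscore <- function(x) {
  s <- pop_sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance in zscore()", call. = FALSE)
  (x - mean(x)) / s
}

#' Mean-center an outcome within each school
#'
#' Subtracts the school mean from the named column, in place, so that the
#' per-school means of the result are exactly zero. Used by the mean-centered
#' variant of the indirect model, which drops the school random intercept
#' because between-school level differences have been removed by construction.
#'
#' @param data data.frame with a `school_id` column.
#' @param outcome name of the column to demean.
#' @return `data` with the outcome column school-demeaned.
#' @export
center_within_school <- function(data, outcome) {
  if (!"school_id" %in% names(data)) stop("school_id column required", call. = FALSE)
  x <- data[[outcome]]
  data[[outcome]] <- x - stats::ave(x, data$school_id)
  data
}

# stable hash of an R object via its canonical JSON serialization
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

# draw k reproducible sub-seeds from a root seed (kept < 2^31)
derive_seeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}
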