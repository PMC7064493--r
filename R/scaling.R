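#' Fit a log-log power law of shift duration against system size
#'
#' Fits `log10(duration) ~ log10(size)` by ordinary least squares,
#' optionally with additive untransformed covariates (for example the
#' grass-regrowth rate in wolf-sheep sweeps, so the effect of the swept
#' variable is assessed at a given disturbance rate). On the original
#' scale the model is the allometric power law `duration = 10^a * size^b`.
#'
#' @param size Positive sizes (km2, cells, nodes, carrying capacity, ...).
#' @param duration Positive shift durations (years or ticks).
#' @param covariates Optional data frame of additional regressors, entered
#'   untransformed and additively on the log10-duration scale.
#' @return An object of class `scaling_fit` with elements `b` (slope), `a`
#'   (intercept), `r_squared`, `p_slope` (two-sided t-test of b = 0), `df`
#'   (residual degrees of freedom), `n`, `residual_sd` (log10 units),
#'   `covariates` (named coefficients, or NULL) and the underlying `lm`
#'   fit in `$model`.
#' @examples
#' fit_power_law(c(1, 100, 10000), c(1, 10, 100))  # exact half-power line
#' @export
fit_power_law <- function(size, duration, covariates = NULL) {
  stopifnot(length(size) == length(duration))
  if (length(size) < 3) stop("need at least 3 records", call. = FALSE)
  bad <- which(!is.finite(size) | size <= 0)
  if (length(bad))
    stop(sprintf("record %d: size must be positive, got %s", bad[1],
                 size[bad[1]]), call. = FALSE)
  bad <- which(!is.finite(duration) | duration <= 0)
  if (length(bad))
    stop(sprintf("record %d: duration must be positive, got %s", bad[1],
                 duration[bad[1]]), call. = FALSE)
  dat <- data.frame(log_duration = log10(duration), log_size = log10(size))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(size))
    if (any(names(covariates) %in% names(dat)))
      stop("covariate names clash with 'log_duration'/'log_size'",
           call. = FALSE)
    dat <- cbind(dat, covariates)
  }
  fit <- stats::lm(log_duration ~ ., data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  # a constant response has zero total variance; report R^2 = 0, not NaN
  r2 <- if (is.finite(sm$r.squared)) sm$r.squared else 0
  p_slope <- unname(co["log_size", "Pr(>|t|)"])
  if (!is.finite(p_slope)) p_slope <- 1  # zero-variance response
  cov_names <- setdiff(rownames(co), c("(Intercept)", "log_size"))
  structure(list(
    b = unname(co["log_size", "Estimate"]),
    a = unname(co["(Intercept)", "Estimate"]),
    r_squared = r2,
    p_slope = p_slope,
    df = fit$df.residual,
    n = nrow(dat),
    residual_sd = sm$sigma,
    covariates = if (length(cov_names))
      stats::setNames(co[cov_names, "Estimate"], cov_names) else NULL,
    covariate_means = if (!is.null(covariates)) colMeans(covariates) else NULL,
    model = fit), class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<scaling_fit> log10(duration) = %.3f + %.3f * log10(size)\n", x$a, x$b))
  cat(sprintf("  n = %d, df = %d, R^2 = %.3f, p(slope) = %.3g, sigma = %.3f\n",
              x$n, x$df, x$r_squared, x$p_slope, x$residual_sd))
  if (!is.null(x$covariates)) {
    cat("  covariates:",
        paste(sprintf("%s = %.4g", names(x$covariates), x$covariates),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify a fitted scaling law
#'
#' A scaling relationship is `positive` when the slope exceeds zero,
#' `sublinear` when the point estimate of the slope is below one (duration
#' grows less than proportionally with size), and `significant` when the
#' two-sided p-value of the slope falls below `alpha`.
#'
#' @param fit A `scaling_fit`.
#' @param alpha Significance level for the slope test.
#' @return Named logical vector `c(positive, sublinear, significant)`.
#' @export
classify_fit <- function(fit, alpha = 0.001) {
  stopifnot(inherits(fit, "scaling_fit"))
  c(positive = fit$b > 0,
    sublinear = fit$b < 1,
    significant = fit$p_slope < alpha)
}

#' Predict shift duration for a system of given size
#'
#' Back-transforms the t-based interval around the fitted log10 duration.
#' The default is a prediction interval (the spread of an individual new
#' system around the power law); `interval = "confidence"` gives the
#' narrower interval on the mean trend.
#'
#' @param fit A `scaling_fit` without covariates, or with covariate values
#'   supplied through `covariates` (defaults to their training means).
#' @param size Positive size(s) at which to predict.
#' @param level Interval coverage, e.g. 0.95.
#' @param interval `"prediction"` or `"confidence"`.
#' @param covariates Optional one-row data frame of covariate values.
#' @return Tibble with columns `size`, `fit`, `lwr`, `upr` on the duration
#'   scale (years).
#' @export
predict_duration <- function(fit, size, level = 0.95,
                             interval = c("prediction", "confidence"),
                             covariates = NULL) {
  stopifnot(inherits(fit, "scaling_fit"), all(size > 0))
  interval <- match.arg(interval)
  newdata <- data.frame(log_size = log10(size))
  if (!is.null(fit$covariates)) {
    vals <- covariates %||% as.data.frame(as.list(fit$covariate_means))
    newdata <- cbind(newdata, vals[rep(1, nrow(newdata)), , drop = FALSE])
  }
  pr <- stats::predict(fit$model, newdata = newdata, interval = interval,
                       level = level)
  tibble::tibble(size = size,
                 fit = unname(10^pr[, "fit"]),
                 lwr = unname(10^pr[, "lwr"]),
                 upr = unname(10^pr[, "upr"]))
}

#' Leave-one-out sensitivity of the scaling law
#'
#' Refits the power law once per record, each time with that record
#' removed, to assess the influence of any single observed shift on the
#' fitted exponent.
#'
#' @param records Record table (see [generate_records()]).
#' @return Tibble with one row per omitted record: its name, the refitted
#'   `slope`, `intercept`, `r_squared`, `p_slope`, `df`, the
#'   positive/sublinear/significant flags, and the full `scaling_fit` in
#'   list-column `fit`.
#' @export
jackknife_fits <- function(records) {
  validate_records(records)
  if (nrow(records) < 4) stop("need at least 4 records", call. = FALSE)
  fits <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[-i, ]
    fit_power_law(r$area_km2, r$duration_yr)
  })
  flags <- t(vapply(fits, classify_fit, logical(3)))
  tibble::tibble(
    omitted = records$name,
    slope = vapply(fits, `[[`, numeric(1), "b"),
    intercept = vapply(fits, `[[`, numeric(1), "a"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    p_slope = vapply(fits, `[[`, numeric(1), "p_slope"),
    df = vapply(fits, `[[`, integer(1), "df"),
    positive = flags[, "positive"],
    sublinear = flags[, "sublinear"],
    significant = flags[, "significant"],
    fit = fits)
}

#' Monte Carlo sensitivity of the scaling law to duration uncertainty
#'
#' Shift durations compiled from the literature carry substantial
#' measurement error; areas are comparatively well known. Each replicate
#' multiplies every duration by an independent uniform draw on
#' `[error_low, error_high]` (areas untouched) and refits the power law.
#'
#' @param records Record table.
#' @param n_sims Number of replicates (the reference analysis uses 5000).
#' @param error_low,error_high Multiplicative error bounds; defaults mean
#'   durations are perturbed to 50--150% of their recorded values.
#' @param seed Optional integer seed.
#' @return Tibble with one row per replicate: `sim`, `slope`, `intercept`,
#'   `r_squared`, `p_slope`, and positive/sublinear/significant flags.
#' @export
monte_carlo_fits <- function(records, n_sims = 5000, error_low = 0.5,
                             error_high = 1.5, seed = NULL) {
  validate_records(records)
  check_scalar(n_sims, "n_sims", lo = 1, integer = TRUE)
  if (!(error_low > 0 && error_low <= error_high))
    stop("need 0 < error_low <= error_high", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  rows <- lapply(seq_len(n_sims), function(s) {
    err <- stats::runif(n, error_low, error_high)
    fit <- fit_power_law(records$area_km2, records$duration_yr * err)
    fl <- classify_fit(fit)
    tibble::tibble(sim = s, slope = fit$b, intercept = fit$a,
                   r_squared = fit$r_squared, p_slope = fit$p_slope,
                   positive = fl[["positive"]], sublinear = fl[["sublinear"]],
                   significant = fl[["significant"]])
  })
  dplyr::bind_rows(rows)
}

#' Serialize a scaling fit to JSON
#'
#' @param fit A `scaling_fit`.
#' @param path Optional output path; if NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
scaling_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "scaling_fit"))
  obj <- list(b = fit$b, a = fit$a, r2 = fit$r_squared, p = fit$p_slope,
              df = fit$df, n = fit$n, residual_sd = fit$residual_sd,
              covariates = as.list(fit$covariates))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
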