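## Statistical layer: lightbar fPAR, zero-intercept calibration against the
## 1:1 line, predictive R^2 via leave-one-out PRESS, potential-yield ratios.

#' Lightbar fPAR from paired PAR readings
#'
#' Midday fractional PAR interception measured beneath and above the canopy:
#' `fPAR = 1 - PAR_below / PAR_above`. Values are clamped to `[0, 1]`, with
#' a warning when `PAR_below > PAR_above` (sensor noise).
#'
#' @param par_below,par_above photosynthetic photon flux density readings
#'   (μmol·m⁻²·s⁻¹); `par_above` must be positive.
#' @return fPAR as a fraction in `[0, 1]`.
#' @export
#' @examples
#' lightbar_fpar(100, 400)  # 0.75
lightbar_fpar <- function(par_below, par_above) {
  if (any(par_above <= 0)) stop("par_above must be positive")
  if (any(par_below < 0)) stop("par_below must be non-negative")
  f <- 1 - par_below / par_above
  if (any(f < 0))
    warning("PAR_below exceeds PAR_above for some records; fPAR clamped to 0")
  pmin(pmax(f, 0), 1)
}

#' Zero-intercept calibration slope with a test against the 1:1 line
#'
#' Fits `y = b x` through the origin: `b = sum(xy) / sum(x^2)`, standard
#' error `sqrt(sum((y - b x)^2) / ((n - 1) * sum(x^2)))`, and a two-sided t
#' test of `H0: b = 1` on `n - 1` degrees of freedom (one fitted
#' parameter). Both the centered and uncentered R² of the through-origin fit
#' are reported, labelled, since the two conventions differ for
#' zero-intercept models.
#'
#' @param x,y numeric vectors of equal length (n ≥ 3), e.g. lightbar fPAR
#'   and aerial canopy cover, both in percent.
#' @return list with `slope`, `se`, `t`, `p_vs_1`, `df`, `n`,
#'   `r2_uncentered` (`1 - RSS/sum(y^2)`), `r2_centered`
#'   (`1 - RSS/sum((y-mean(y))^2)`).
#' @export
#' @examples
#' zero_intercept_slope(c(1, 2, 3), c(2, 4, 6))$slope  # 2
zero_intercept_slope <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 points for a zero-intercept calibration")
  sxx <- sum(x^2)
  if (sxx <= 0) stop("all x are zero: slope undefined")
  b <- sum(x * y) / sxx
  rss <- sum((y - b * x)^2)
  se <- sqrt(rss / ((n - 1) * sxx))
  tt <- if (se > 0) (b - 1) / se else if (b == 1) 0 else Inf * sign(b - 1)
  list(slope = b, se = se, t = tt,
       p_vs_1 = 2 * pt(-abs(tt), df = n - 1),
       df = n - 1, n = n,
       r2_uncentered = 1 - rss / sum(y^2),
       r2_centered = 1 - rss / sum((y - mean(y))^2))
}

#' Adjusted potential-yield ratio
#'
#' Rescales a published potential-yield base ratio (dry kernel lb·acre⁻¹ per
#' % fPAR) by the zero-intercept calibration slope between the aerial and
#' lightbar fPAR estimates: `adjusted = base_ratio * slope`. The returned
#' value is unrounded; tables display it rounded half-up to 2 decimals (see
#' [adjusted_ratio_table()]).
#'
#' @param base_ratio base ratio, lb·acre⁻¹ per % fPAR (> 0).
#' @param slope zero-intercept calibration slope.
#' @return adjusted ratio (unrounded).
#' @export
#' @examples
#' round_half_up(adjusted_ratio(57.70, 0.87), 2)  # 50.20
adjusted_ratio <- function(base_ratio, slope) {
  if (any(base_ratio <= 0)) stop("base_ratio must be positive")
  base_ratio * slope
}

#' Table of adjusted potential-yield ratios
#'
#' Builds the display table pairing each calibration slope with its adjusted
#' ratio (rounded half-up to 2 decimals), one row per variety scope and
#' date.
#'
#' @param scopes character vector of variety-scope labels.
#' @param base_ratios numeric vector of base ratios, parallel to `scopes`.
#' @param slopes a matrix or data.frame of slopes, rows parallel to
#'   `scopes`, columns named by date.
#' @return data.frame with `scope`, `base_ratio`, `date`, `slope`,
#'   `adjusted_ratio`.
#' @export
adjusted_ratio_table <- function(scopes, base_ratios, slopes) {
  slopes <- as.matrix(slopes)
  stopifnot(length(scopes) == length(base_ratios),
            nrow(slopes) == length(scopes))
  dates <- colnames(slopes) %||% paste0("t", seq_len(ncol(slopes)))
  out <- do.call(rbind, lapply(seq_along(scopes), function(i) {
    data.frame(scope = scopes[i], base_ratio = base_ratios[i],
               date = dates, slope = as.numeric(slopes[i, ]),
               adjusted_ratio = round_half_up(
                 adjusted_ratio(base_ratios[i], as.numeric(slopes[i, ])), 2))
  }))
  rownames(out) <- NULL
  out
}

#' Potential yield from fPAR
#'
#' `Y_potential = ratio * fPAR%`: the maximum dry-kernel yield implied by
#' midday fPAR interception under a fixed per-percent ratio.
#'
#' @param fpar_pct fPAR in percent, `[0, 100]`.
#' @param ratio lb·acre⁻¹ per % fPAR.
#' @return potential yield, lb·acre⁻¹.
#' @export
#' @examples
#' potential_yield(50, 57.7)  # 2885
potential_yield <- function(fpar_pct, ratio) {
  if (any(fpar_pct < 0 | fpar_pct > 100))
    stop("fpar_pct must lie in [0, 100]")
  ratio * fpar_pct
}

#' Calibration statistics between two measurement series
#'
#' Ordinary least squares `y = a + b x` plus the error metrics used to
#' compare an aerial fPAR estimate against lightbar fPAR: R², Pearson's r,
#' RMSE to the fitted regression line (`sqrt(mean(residual^2))`), RMSE to
#' the 1:1 identity line (`sqrt(mean((y - x)^2))`; no fitted parameters, so
#' both RMSEs use denominator n), predictive R² `1 - PRESS/SST` where PRESS
#' is computed by literal leave-one-out refits, and the zero-intercept
#' calibration of [zero_intercept_slope()].
#'
#' @param x,y numeric vectors (n ≥ 4), same units (percent fPAR).
#' @return object of class `calibration_stats`: list with `n`, `intercept`,
#'   `slope_ols`, `r2`, `predictive_r2`, `pearson_r`, `press`, `sst`,
#'   `rmse_to_identity`, `rmse_to_regression`, `mean_abs_err_identity`,
#'   `mean_abs_err_regression`, `slope0` (zero-intercept slope), `slope0_se`,
#'   `slope0_vs_1_pvalue`.
#' @export
calibration_stats <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need at least 4 points for predictive R^2")
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate data: zero variance in x or y")
  fit <- lm(y ~ x)
  res <- resid(fit)
  r <- cor(x, y)
  sst <- sum((y - mean(y))^2)
  press <- sum(vapply(seq_len(n), function(i) {
    f <- lm(y[-i] ~ x[-i])
    (y[i] - (coef(f)[1] + coef(f)[2] * x[i]))^2
  }, numeric(1)))
  z <- zero_intercept_slope(x, y)
  structure(list(
    n = n,
    intercept = unname(coef(fit)[1]),
    slope_ols = unname(coef(fit)[2]),
    r2 = r^2,
    predictive_r2 = 1 - press / sst,
    pearson_r = r,
    press = press,
    sst = sst,
    rmse_to_identity = sqrt(mean((y - x)^2)),
    rmse_to_regression = sqrt(mean(res^2)),
    mean_abs_err_identity = mean(abs(y - x)),
    mean_abs_err_regression = mean(abs(res)),
    slope0 = z$slope, slope0_se = z$se, slope0_vs_1_pvalue = z$p_vs_1
  ), class = "calibration_stats")
}

#' @export
print.calibration_stats <- function(x, ...) {
  cat(sprintf(
    paste0("<calibration_stats n=%d>\n",
           "  OLS y = %.4f + %.4f x | R2 %.4f | predictive R2 %.4f | r %.4f\n",
           "  RMSE to 1:1 %.4f | RMSE to regression %.4f\n",
           "  zero-intercept slope %.4f (se %.4f, p vs 1:1 %.4g)\n"),
    x$n, x$intercept, x$slope_ols, x$r2, x$predictive_r2, x$pearson_r,
    x$rmse_to_identity, x$rmse_to_regression,
    x$slope0, x$slope0_se, x$slope0_vs_1_pvalue))
  invisible(x)
}

#' Regression of actual yield on fPAR
#'
#' OLS fit of dry-kernel yield (lb·acre⁻¹) on fPAR (%), with the standard
#' fit statistics, leave-one-out predictive R², and — when a potential-yield
#' `ratio` is supplied — diagnostics of the residuals about the potential
#' line `yield = ratio * fPAR`.
#'
#' @param fpar_pct fPAR in percent.
#' @param yield_lb_acre matched dry-kernel yields, lb·acre⁻¹ (n ≥ 4).
#' @param ratio optional potential-yield base ratio for the potential-line
#'   diagnostics.
#' @return object of class `yield_model`: list with `fit` (the `lm`),
#'   `intercept`, `slope`, `r2`, `predictive_r2`, `pearson_r`,
#'   `rmse_to_regression`, `n`, and (if `ratio` given) `ratio`,
#'   `rmse_to_potential`, `mean_gap_to_potential` (mean of
#'   `potential - actual`). `predict()` works on new fPAR values.
#' @export
yield_regression <- function(fpar_pct, yield_lb_acre, ratio = NULL) {
  stopifnot(length(fpar_pct) == length(yield_lb_acre))
  n <- length(fpar_pct)
  if (n < 4) stop("need at least 4 points")
  if (sd(fpar_pct) == 0) stop("degenerate data: zero variance in fPAR")
  x <- fpar_pct; y <- yield_lb_acre
  fit <- lm(y ~ x)
  res <- resid(fit)
  sst <- sum((y - mean(y))^2)
  press <- sum(vapply(seq_len(n), function(i) {
    f <- lm(y[-i] ~ x[-i])
    (y[i] - (coef(f)[1] + coef(f)[2] * x[i]))^2
  }, numeric(1)))
  out <- list(
    fit = fit, n = n,
    intercept = unname(coef(fit)[1]),
    slope = unname(coef(fit)[2]),
    r2 = if (sd(y) > 0) cor(x, y)^2 else 0,
    predictive_r2 = if (sst > 0) 1 - press / sst else NA_real_,
    pearson_r = if (sd(y) > 0) cor(x, y) else 0,
    rmse_to_regression = sqrt(mean(res^2)),
    ci95 = {
      sxx <- sum((x - mean(x))^2)
      se <- sqrt(sum(res^2) / (n - 2) / sxx)
      unname(coef(fit)[2]) + c(-1, 1) * stats::qt(0.975, df = n - 2) * se
    }
  )
  if (!is.null(ratio)) {
    pot <- potential_yield(pmin(pmax(x, 0), 100), ratio)
    out$ratio <- ratio
    out$rmse_to_potential <- sqrt(mean((y - pot)^2))
    out$mean_gap_to_potential <- mean(pot - y)
  }
  structure(out, class = "yield_model")
}

#' @export
predict.yield_model <- function(object, fpar_pct, ...) {
  object$intercept + object$slope * fpar_pct
}

#' @export
print.yield_model <- function(x, ...) {
  cat(sprintf(
    "<yield_model n=%d> yield = %.2f + %.2f * fPAR%% | R2 %.3f | predictive R2 %.3f | RMSE %.2f lb/acre\n",
    x$n, x$intercept, x$slope, x$r2, x$predictive_r2, x$rmse_to_regression))
  if (!is.null(x$ratio))
    cat(sprintf("  potential line ratio %.2f | RMSE to potential %.2f | mean gap %.2f lb/acre\n",
                x$ratio, x$rmse_to_potential, x$mean_gap_to_potential))
  invisible(x)
}
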