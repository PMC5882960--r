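#' Detrending curve
#'
#' The per-specimen expected-growth curve removed during standardization.
#'
#' @param method one of `"spline"`, `"negexp"`, `"linear"`, `"mean"`.
#' @param first_year calendar year of the first fitted value.
#' @param fitted_values numeric vector of per-year expected widths.
#' @param params method-specific parameter list.
#' @return An object of class `detrend_curve`.
#' @export
detrend_curve <- function(method, first_year, fitted_values, params = list()) {
  stopifnot(method %in% c("spline", "negexp", "linear", "mean"))
  structure(list(method = method, first_year = as.integer(first_year),
                 fitted_values = as.numeric(fitted_values), params = params),
            class = "detrend_curve")
}

#' @export
print.detrend_curve <- function(x, ...) {
  cat(sprintf("<detrend_curve> %s over %d years from %d\n",
              x$method, length(x$fitted_values), x$first_year))
  invisible(x)
}

# roughness weight of a discrete cubic smoothing spline at angular
# frequency w (radians / year); the response ratio g(w)/g(w0) fixes the
# curve's amplitude attenuation relative to the 50%-cutoff frequency w0
spline_roughness <- function(w) 6 * (1 - cos(w))^2 / (2 + cos(w))

#' Amplitude frequency response of the cutoff-parameterized smoothing spline
#'
#' The spline stiffness convention used throughout dendro- and
#' sclerochronology: the smoothing parameter is chosen so a sinusoid whose
#' wavelength equals `cutoff_years` is attenuated to exactly 50% amplitude.
#' This function evaluates the resulting response at any other wavelength.
#'
#' @param cutoff_years 50%-cutoff wavelength in years.
#' @param period_years wavelength(s) at which to evaluate the response.
#' @return Amplitude fraction(s) in `[0, 1]`; exactly 0.5 at
#'   `period_years == cutoff_years`, monotone nondecreasing in the period.
#' @export
spline_frequency_response <- function(cutoff_years, period_years) {
  if (cutoff_years <= 0 || any(period_years <= 0))
    stop("cutoff_years and period_years must be positive")
  g0 <- spline_roughness(2 * pi / cutoff_years)
  1 / (1 + spline_roughness(2 * pi / period_years) / g0)
}

# fit the cutoff-parameterized cubic smoothing spline to values at unit
# spacing; returns fitted values.  The continuous-frequency penalty
# mu = (cutoff / 2 pi)^4 gives amplitude response 1 / (1 + mu w^4), i.e.
# 0.5 at the cutoff wavelength; smooth.spline penalizes curvature on x
# rescaled to [0, 1], hence the range^3 conversion.
spline_fit_values <- function(y, cutoff_years) {
  n <- length(y)
  mu <- (cutoff_years / (2 * pi))^4
  sf <- stats::smooth.spline(seq_len(n), y, lambda = mu / (n - 1)^3,
                             all.knots = TRUE, keep.data = FALSE)
  stats::predict(sf, seq_len(n))$y
}

#' Cubic smoothing spline with a 50% frequency cutoff
#'
#' Fits each specimen's flexible growth curve for the crossdating-QC path:
#' a cubic smoothing spline whose stiffness is set so the amplitude response
#' is 0.5 at wavelength `cutoff_years` (see
#' [spline_frequency_response()]).
#'
#' @param series an `increment_series` (length at least 5).
#' @param cutoff_years 50%-cutoff wavelength in years; default 15.
#' @return A `detrend_curve` with `method = "spline"`.
#' @export
smoothing_spline_fit <- function(series, cutoff_years = 15) {
  if (cutoff_years <= 0) stop("cutoff_years must be positive")
  y <- series_values(series)
  if (length(y) < 5L) stop("series too short for spline fit (need >= 5)")
  detrend_curve("spline", series$first_year,
                spline_fit_values(y, cutoff_years),
                params = list(cutoff_years = cutoff_years))
}

#' Adaptive power transform for variance stabilization
#'
#' Estimates the power that makes year-to-year spread independent of growth
#' level: local spread (absolute first difference) is regressed on local
#' level (mean of adjacent values) on log-log axes, and the transform
#' exponent is `p = 1 - slope`, clamped to `[0, 1]`; `|p| < 0.05` snaps to
#' the log transform. Homoscedastic series keep `p ~ 1` (no change);
#' multiplicative-noise series get `p ~ 0` (log).
#'
#' @param series an `increment_series` with at least 10 positive widths.
#' @return List with `series` (a transformed `increment_series`-like object
#'   whose `widths` hold the transformed values) and `exponent`.
#' @export
adaptive_power_transform <- function(series) {
  x <- series_values(series)
  if (any(x <= 0)) stop("power transform requires strictly positive widths")
  if (length(x) < 10L) stop("series too short for power transform (need >= 10)")
  spread <- abs(diff(x))
  level <- (x[-1] + x[-length(x)]) / 2
  ok <- spread > 0
  if (sum(ok) < 3L) {
    warning("local spread degenerate; exponent defaults to 1 for ",
            series$specimen_id)
    p <- 1
  } else {
    b <- stats::coef(stats::lm(log(spread[ok]) ~ log(level[ok])))[2]
    p <- 1 - as.numeric(b)
    p <- min(max(p, 0), 1)
    if (abs(p) < 0.05) p <- 0
  }
  values <- if (p == 0) log(x) else x^p
  out <- series
  out$widths <- NULL
  out$indices <- NULL
  if (!is.null(series$widths)) out$widths <- values else out$indices <- values
  list(series = out, exponent = p)
}

#' Negative-exponential ontogenetic trend
#'
#' Fits the classic age-trend model `w(age) = a exp(-b age) + k` with
#' `a > 0`, `b > 0`, `k >= 0` by bounded least squares. When the fit fails
#' or collapses onto a constraint boundary, falls back to a straight line
#' with nonpositive slope, and if even that slope comes out positive, to the
#' horizontal mean — a growth curve is never allowed to increase with age.
#' Series on a shifted scale (e.g. log-transformed widths with nonpositive
#' values) are shifted internally so the exponential model applies; the
#' returned curve is on the input scale.
#'
#' @param series an `increment_series` or transformed series (length >= 5).
#' @return A `detrend_curve` (`method` records which model was kept).
#' @export
fit_age_trend <- function(series) {
  y <- series_values(series)
  n <- length(y)
  if (n < 5L) stop("series too short for age-trend fit (need >= 5)")
  age <- seq_len(n)
  shift <- if (min(y) <= 0) 1 - min(y) else 0
  ys <- y + shift

  fit <- tryCatch({
    start <- list(a = max(ys[1:3]) - min(ys),
                  b = 0.1,
                  k = max(min(ys) * 0.5, 1e-6))
    m <- minpack.lm::nlsLM(ys ~ a * exp(-b * age) + k,
                           start = start,
                           lower = c(a = 1e-8, b = 1e-8, k = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(m)
    if (cf[["a"]] <= 1e-6 || cf[["b"]] <= 1e-6) NULL else m
  }, error = function(e) NULL)

  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    fitted <- cf[["a"]] * exp(-cf[["b"]] * age) + cf[["k"]] - shift
    return(detrend_curve("negexp", series$first_year, fitted,
                         params = list(a = cf[["a"]], b = cf[["b"]],
                                       k = cf[["k"]] - shift)))
  }

  lf <- stats::lm(y ~ age)
  slope <- stats::coef(lf)[2]
  if (slope <= 0) {
    fitted <- as.numeric(stats::fitted(lf))
    if (shift == 0 && any(fitted <= 0)) {
      # widths are positive; a line crossing zero is not a usable curve
      return(detrend_curve("mean", series$first_year, rep(mean(y), n),
                           params = list(mean = mean(y))))
    }
    return(detrend_curve("linear", series$first_year, fitted,
                         params = list(intercept = stats::coef(lf)[1],
                                       slope = slope)))
  }
  detrend_curve("mean", series$first_year, rep(mean(y), n),
                params = list(mean = mean(y)))
}

#' Standardize one series against its growth curve
#'
#' @param series the series the curve was fitted to (raw or transformed).
#' @param curve a `detrend_curve` aligned to the series years.
#' @param mode `"ratio"` (observed / fitted; requires strictly positive
#'   fitted values) or `"residual"` (observed - fitted).
#' @param power_exponent exponent of any power transform already applied to
#'   `series`, recorded in the result.
#' @return A `detrended_series`.
#' @export
detrend_series <- function(series, curve, mode = c("ratio", "residual"),
                           power_exponent = 1) {
  mode <- match.arg(mode)
  y <- series_values(series)
  if (curve$first_year != series$first_year ||
      length(curve$fitted_values) != length(y))
    stop("curve is not aligned to the series years")
  f <- curve$fitted_values
  if (mode == "ratio") {
    if (any(f <= 0))
      stop("ratio detrending requires strictly positive fitted values (",
           series$specimen_id, ")")
    idx <- y / f
  } else {
    idx <- y - f
  }
  detrended_series(series$specimen_id, series$first_year, idx,
                   mode = mode, power_exponent = power_exponent)
}

#' Standardize a whole collection
#'
#' Two canonical paths. The QC path (`"spline_ratio"`) fits each series its
#' own cubic smoothing spline at the 50% frequency cutoff and divides
#' observed by fitted, isolating high-frequency variability for crossdating
#' statistics. The chronology path (`"powt_negexp"`) first applies the
#' adaptive power transform, then removes a negative-exponential (with
#' linear/mean fallback) age curve by subtraction in transformed space.
#'
#' @param collection a `series_collection` of `increment_series`.
#' @param path `"spline_ratio"` or `"powt_negexp"`.
#' @param cutoff_years spline cutoff for the QC path.
#' @param mode override the path's default index mode.
#' @return A `series_collection` of `detrended_series`.
#' @export
standardize_collection <- function(collection,
                                   path = c("spline_ratio", "powt_negexp"),
                                   cutoff_years = 15,
                                   mode = NULL) {
  path <- match.arg(path)
  out <- lapply(collection, function(s) {
    if (path == "spline_ratio") {
      curve <- smoothing_spline_fit(s, cutoff_years)
      detrend_series(s, curve, mode = if (is.null(mode)) "ratio" else mode)
    } else {
      pt <- adaptive_power_transform(s)
      curve <- fit_age_trend(pt$series)
      detrend_series(pt$series, curve,
                     mode = if (is.null(mode)) "residual" else mode,
                     power_exponent = pt$exponent)
    }
  })
  series_collection(out)
}
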