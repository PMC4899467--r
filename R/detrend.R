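#' Detrending configuration
#'
#' @param segment_length_years Segment length for the power regression
#'   (default 10, non-overlapping).
#' @param spline_wavelength_years Wavelength at which the smoothing spline's
#'   amplitude transfer equals `frequency_response` (default 30).
#' @param frequency_response Amplitude transfer at the cutoff wavelength,
#'   in (0, 1) (default 0.5, the classic 50% frequency cutoff).
#' @param power Optional fixed power `p` overriding [optimal_power()]
#'   estimation; `1` disables the transform (used for climate series).
#' @return List of class `detrend_config`.
#' @export
detrend_config <- function(segment_length_years = 10,
                           spline_wavelength_years = 30,
                           frequency_response = 0.5,
                           power = NULL) {
  stopifnot(segment_length_years > 0, spline_wavelength_years > 0,
            frequency_response > 0, frequency_response < 1)
  structure(list(segment_length_years = segment_length_years,
                 spline_wavelength_years = spline_wavelength_years,
                 frequency_response = frequency_response,
                 power = power),
            class = "detrend_config")
}

#' Mean sensitivity of an increment series
#'
#' The standard dendrochronological measure of inter-annual (year-to-year)
#' relative variability: the mean over consecutive pairs of
#' `2 |x_i - x_{i-1}| / (x_i + x_{i-1})`. For non-negative series it is
#' bounded in `[0, 2]` and invariant under positive rescaling. Pairs whose
#' sum is zero are skipped with a warning.
#'
#' @param x Numeric series (ring widths or biomass increments).
#' @return Scalar mean sensitivity.
#' @export
mean_sensitivity <- function(x) {
  stopifnot(length(x) >= 2L)
  num <- 2 * abs(diff(x))
  den <- x[-1] + x[-length(x)]
  skip <- den == 0
  if (all(skip)) stop("all consecutive pairs sum to zero")
  if (any(skip)) warning(sum(skip), " zero-sum pair(s) skipped")
  mean(num[!skip] / den[!skip])
}

#' Lag-1 Pearson autocorrelation
#'
#' Correlation between the series and itself shifted by one year. Returns
#' `NA` with a warning for zero-variance input.
#'
#' @param x Numeric series, length >= 3.
#' @return Scalar in `[-1, 1]`, or `NA`.
#' @export
first_order_autocorrelation <- function(x) {
  stopifnot(length(x) >= 3L)
  a <- x[-1]; b <- x[-length(x)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance; autocorrelation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Optimal variance-stabilizing power
#'
#' Estimates the adaptive power transform exponent `p = 1 - m`, where `m`
#' is the least-squares slope of `log10(IQR)` on `log10(median)` over the
#' pooled non-overlapping segments (default 10 yr) of all series. When
#' spread is independent of level, `m ~ 0` and `p ~ 1` (no transform);
#' when spread is proportional to level, `p` approaches the lower clip
#' 0.05 (near-logarithmic). `p` is clipped to `[0.05, 1]`. Trailing
#' segments shorter than the segment length and segments with non-positive
#' median or zero IQR are dropped (the latter with a warning).
#'
#' @param series_list List of numeric series (or [ring_width_series]
#'   objects, in which case their widths are used).
#' @param config A [detrend_config].
#' @param orientation Which variable is the regression response:
#'   `"iqr_on_median"` (default) or `"median_on_iqr"` (in which case
#'   `m` is the reciprocal slope's counterpart, i.e. the fitted slope of
#'   the reversed regression is used directly).
#' @return Scalar `p` with attributes `m` (slope), `n_segments` and `r`
#'   (correlation of the pooled log-log cloud).
#' @export
optimal_power <- function(series_list, config = detrend_config(),
                          orientation = c("iqr_on_median", "median_on_iqr")) {
  orientation <- match.arg(orientation)
  if (inherits(series_list, "ring_width_series")) series_list <- list(series_list)
  len <- config$segment_length_years
  med <- numeric(); iqr <- numeric()
  for (s in series_list) {
    x <- if (inherits(s, "ring_width_series")) s$widths else as.numeric(s)
    nseg <- length(x) %/% len
    if (nseg < 1L) next
    for (k in seq_len(nseg)) {
      seg <- x[((k - 1L) * len + 1L):(k * len)]
      med <- c(med, stats::median(seg))
      iqr <- c(iqr, stats::IQR(seg))
    }
  }
  drop <- med <= 0 | iqr <= 0
  if (any(iqr <= 0)) warning(sum(iqr <= 0), " zero-IQR segment(s) dropped")
  med <- med[!drop]; iqr <- iqr[!drop]
  if (length(med) < 2L) stop("need >= 2 usable segments for the power regression")
  if (orientation == "iqr_on_median") {
    fit <- stats::lm(log10(iqr) ~ log10(med))
    m <- unname(stats::coef(fit)[2])
  } else {
    fit <- stats::lm(log10(med) ~ log10(iqr))
    m <- unname(stats::coef(fit)[2])
  }
  p <- min(max(1 - m, 0.05), 1)
  structure(p, m = m, n_segments = length(med),
            r = stats::cor(log10(med), log10(iqr)))
}

# cache of calibrated smoothing parameters keyed by grid length and cutoff
.spline_cache <- new.env(parent = emptyenv())

# amplitude transfer of smooth.spline with penalty lam at the target
# wavelength, measured on an interior window to exclude edge effects
.spline_response <- function(lam, years, wavelength) {
  ph <- 2 * pi * (years - years[1]) / wavelength
  s <- sin(ph); cc <- cos(ph)
  fs <- stats::smooth.spline(years, s, lambda = lam, all.knots = TRUE)$y
  n <- length(years)
  margin <- min(floor(wavelength / 2), floor((n - 10) / 2))
  idx <- if (margin > 0) (margin + 1):(n - margin) else seq_len(n)
  fit <- stats::lm.fit(cbind(s[idx], cc[idx]), fs[idx])
  sqrt(sum(fit$coefficients^2))
}

#' Cubic smoothing spline with a frequency-response cutoff
#'
#' Fits a cubic smoothing spline whose smoothing parameter is chosen so
#' that a sinusoid of period `wavelength_years` is attenuated to
#' `frequency_response` of its amplitude (measured over the interior of the
#' series, away from the boundary where any smoother is less stiff). The
#' parameter is found by bisection on the log smoothing penalty, making the
#' criterion reproducible across series lengths; the result is
#' deterministic for fixed input.
#'
#' @param values Numeric series.
#' @param years Evenly spaced years, same length; at least
#'   `wavelength_years / 2` observations.
#' @param wavelength_years Cutoff wavelength (default 30).
#' @param frequency_response Target amplitude transfer at the cutoff
#'   (default 0.5).
#' @return Numeric vector of fitted trend values.
#' @export
smoothing_spline <- function(values, years = seq_along(values),
                             wavelength_years = 30,
                             frequency_response = 0.5) {
  n <- length(values)
  stopifnot(length(years) == n)
  if (n < wavelength_years / 2)
    stop("series too short: need >= ", ceiling(wavelength_years / 2),
         " observations")
  if (length(unique(round(diff(years), 8))) != 1L)
    stop("years must be evenly spaced")
  key <- sprintf("n%d_w%g_f%g_s%g", n, wavelength_years, frequency_response,
                 diff(years[1:2]))
  lam <- .spline_cache[[key]]
  if (is.null(lam)) {
    lo <- -12; hi <- 6
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      r <- .spline_response(10^mid, years, wavelength_years)
      if (r > frequency_response) lo <- mid else hi <- mid
    }
    lam <- 10^((lo + hi) / 2)
    .spline_cache[[key]] <- lam
  }
  stats::smooth.spline(years, values, lambda = lam, all.knots = TRUE)$y
}

#' Power-transform and spline-detrend a series
#'
#' The residual detrending used throughout the pipeline: the series is
#' raised to the power `p` (variance stabilization; `p = 1` leaves it
#' unchanged, as for climate series), a cutoff smoothing spline is fitted
#' to the transformed series, and the spline is subtracted. The residual
#' index retains inter-annual variation while decadal and longer trends
#' (age, competition, slow climate drift) are removed.
#'
#' @param values Numeric series (e.g. annual biomass increments).
#' @param years Matching years.
#' @param p Power exponent; defaults to `config$power`, or 1 if unset.
#' @param config A [detrend_config].
#' @return `data.frame` with columns `year,raw,transformed,spline,residual`
#'   and attribute `p`. `residual + spline == transformed` exactly.
#' @export
detrend_series <- function(values, years = seq_along(values), p = NULL,
                           config = detrend_config()) {
  if (is.null(p)) p <- if (is.null(config$power)) 1 else config$power
  stopifnot(p > 0, p <= 1)
  if (p != 1 && any(values < 0))
    stop("power transform undefined for negative values; use p = 1")
  tr <- if (p == 1) values else values^p
  sp <- smoothing_spline(tr, years,
                         wavelength_years = config$spline_wavelength_years,
                         frequency_response = config$frequency_response)
  structure(data.frame(year = years, raw = values, transformed = tr,
                       spline = sp, residual = tr - sp),
            p = p)
}
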