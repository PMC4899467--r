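#' Season definition for climate aggregation
#'
#' A season is a set of months, each tagged with a year lag (0 = calendar
#' year of ring formation, 1 = previous year), and an aggregator. Monthly
#' values of lagged months attach to the ring year they influence.
#'
#' @param variable Climate variable name.
#' @param months Integer months 1-12.
#' @param lags Integer vector of the same length (0 or 1); scalar recycled.
#' @param aggregator `"mean"` or `"sum"`.
#' @param label Optional label for reporting.
#' @return List of class `season_definition`.
#' @export
season_definition <- function(variable, months, lags = 0,
                              aggregator = c("mean", "sum"),
                              label = NULL) {
  aggregator <- match.arg(aggregator)
  lags <- rep_len(as.integer(lags), length(months))
  stopifnot(length(months) >= 1L, all(months %in% 1:12), all(lags %in% 0:1))
  structure(list(variable = variable, months = as.integer(months),
                 lags = lags, aggregator = aggregator,
                 label = if (is.null(label)) variable else label),
            class = "season_definition")
}

#' Default seasonal windows for the growth-climate analysis
#'
#' The four windows with the strongest increment-climate association in
#' cold, humid mountain spruce forests: growing-season temperature
#' (May-September mean), early-growing-season cloud cover (May-July mean),
#' previous-year late-growing-season precipitation (July-September sum)
#' and previous-September drought (PDSI).
#'
#' @return Named list of [season_definition] objects.
#' @export
default_seasons <- function() {
  list(temperature = season_definition("temperature", 5:9, 0, "mean",
                                       "T May-Sep"),
       cloud_cover = season_definition("cloud_cover", 5:7, 0, "mean",
                                       "cloud May-Jul"),
       precipitation = season_definition("precipitation", 7:9, 1, "sum",
                                         "P prev Jul-Sep"),
       pdsi = season_definition("pdsi", 9, 1, "mean", "PDSI prev Sep"))
}

#' Aggregate monthly climate into a seasonal annual series
#'
#' @param climate Long-format `data.frame` `variable,year,month,value`
#'   (see [read_climate_csv()]).
#' @param season A [season_definition].
#' @return `data.frame` with `year,value`; years with any missing month
#'   get `NA`.
#' @export
aggregate_season <- function(climate, season) {
  cl <- climate[climate$variable == season$variable, , drop = FALSE]
  if (nrow(cl) == 0L) stop("no climate rows for variable ", season$variable)
  # ring year t draws on month m of calendar year t - lag
  years <- sort(unique(cl$year))
  agg <- vapply(years, function(t) {
    src <- cl$value[match(paste(t - season$lags, season$months),
                          paste(cl$year, cl$month))]
    if (anyNA(src)) return(NA_real_)
    if (season$aggregator == "sum") sum(src) else mean(src)
  }, numeric(1))
  data.frame(year = years, value = agg)
}

# Spearman rho with average-rank ties
.spearman <- function(x, y) stats::cor(x, y, method = "spearman")

# two-sided p-value via the asymptotic t approximation
.spearman_p <- function(rho, n) {
  if (is.na(rho) || n < 3) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Preliminary single-month climate screening
#'
#' Spearman correlation of a site mean chronology (typically the mean
#' detrended biomass-increment index) against every single month of every
#' climate variable, current and previous year (24 candidates per
#' variable), over a fixed window. Used to choose the seasonal windows;
#' exploratory, so p-values carry no multiplicity correction (flagged in
#' the output).
#'
#' @param chronology `data.frame` with `year,value`.
#' @param climate Long-format monthly climate `data.frame`.
#' @param window Length-2 year window (default `c(1901, 2007)`).
#' @param min_overlap Minimum overlapping years (default 30).
#' @return `data.frame` `variable,month,lag,rho,n,p` with attribute
#'   `multiplicity = "none"`.
#' @export
screen_months <- function(chronology, climate, window = c(1901, 2007),
                          min_overlap = 30) {
  chron <- chronology[chronology$year >= window[1] &
                        chronology$year <= window[2], , drop = FALSE]
  out <- list()
  for (v in unique(climate$variable)) {
    cl <- climate[climate$variable == v, , drop = FALSE]
    for (lag in 0:1) for (m in 1:12) {
      val <- cl$value[match(paste(chron$year - lag, m), paste(cl$year, cl$month))]
      keep <- !is.na(val) & !is.na(chron$value)
      n <- sum(keep)
      if (n < min_overlap) next
      rho <- .spearman(chron$value[keep], val[keep])
      out[[length(out) + 1L]] <- data.frame(variable = v, month = m,
                                            lag = lag, rho = rho, n = n,
                                            p = .spearman_p(rho, n))
    }
  }
  if (length(out) == 0L) stop("insufficient overlap between chronology and climate")
  structure(do.call(rbind, out), multiplicity = "none")
}

#' Per-tree, per-period Spearman correlations
#'
#' Spearman rank correlation (average-rank tie handling) between each
#' tree's detrended increment index and a detrended seasonal climate
#' series, computed separately within each calendar period. Periods with
#' fewer than `min_years` overlapping years yield `NA` rho, flagged in the
#' output rather than dropped.
#'
#' @param tree_series `data.frame` with `tree_id,year,value` (detrended
#'   residual index per tree).
#' @param climate_annual `data.frame` with `year,value` (detrended
#'   seasonal climate).
#' @param periods `data.frame` from [default_periods()] or
#'   [period_definition()].
#' @param variable Label stored in the output.
#' @param min_years Minimum overlap for a reported rho (default 5).
#' @return `data.frame` `tree_id,period,variable,rho,n`.
#' @export
spearman_by_period <- function(tree_series, climate_annual, periods,
                               variable = "climate", min_years = 5) {
  out <- list()
  for (id in unique(tree_series$tree_id)) {
    tr <- tree_series[tree_series$tree_id == id, , drop = FALSE]
    for (k in seq_len(nrow(periods))) {
      yrs <- periods$start_year[k]:periods$end_year[k]
      x <- tr$value[match(yrs, tr$year)]
      y <- climate_annual$value[match(yrs, climate_annual$year)]
      keep <- !is.na(x) & !is.na(y)
      n <- sum(keep)
      rho <- if (n >= min_years) .spearman(x[keep], y[keep]) else NA_real_
      out[[length(out) + 1L]] <- data.frame(tree_id = id,
                                            period = periods$label[k],
                                            variable = variable,
                                            rho = rho, n = n)
    }
  }
  do.call(rbind, out)
}

#' Running (moving-window) Spearman correlation
#'
#' Centred moving-window Spearman correlation between two annual series,
#' used to display the temporal stability of a growth-climate relationship.
#'
#' @param x,y `data.frame`s with `year,value`.
#' @param window_years Odd window length, >= 11 (default 31).
#' @return `data.frame` `year` (window centre), `rho`, `n`.
#' @export
running_correlation <- function(x, y, window_years = 31) {
  if (window_years %% 2 == 0 || window_years < 11)
    stop("window must be odd and >= 11")
  yrs <- intersect(x$year, y$year)
  yrs <- sort(yrs)
  if (length(yrs) < window_years)
    stop("window (", window_years, ") exceeds overlapping series length (",
         length(yrs), ")")
  xv <- x$value[match(yrs, x$year)]
  yv <- y$value[match(yrs, y$year)]
  half <- (window_years - 1) / 2
  centres <- (half + 1):(length(yrs) - half)
  data.frame(year = yrs[centres],
             rho = vapply(centres, function(i) {
               idx <- (i - half):(i + half)
               .spearman(xv[idx], yv[idx])
             }, numeric(1)),
             n = window_years)
}
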