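#' Ring-width series
#'
#' Container for a single tree's dated ring-width measurements, the basic
#' unit of the biomass reconstruction. Widths are stored in mm at 0.01 mm
#' precision, one value per calendar year from `first_year` to `last_year`
#' inclusive. `pith_offset_mm` is the estimated radial distance from the
#' innermost measured ring to the stem centre (0 when the core intersected
#' the pith); it enters both the diameter reconstruction and the cambial-age
#' estimate. A ring dated to year Y is taken to have formed in the growing
#' season of year Y; rings of exactly 0 mm are legal (locally absent rings).
#'
#' @param tree_id Character scalar, unique sample identifier.
#' @param site Character scalar, catchment label (e.g. `"Certovo"`,
#'   `"Plesne"`).
#' @param first_year First (innermost) measured calendar year.
#' @param widths Numeric vector of ring widths in mm, one per year.
#' @param pith_offset_mm Estimated distance to pith in mm, `>= 0`.
#' @return An object of class `ring_width_series`: a list with the fields
#'   above plus `last_year`.
#' @export
ring_width_series <- function(tree_id, site, first_year, widths,
                              pith_offset_mm = 0) {
  stopifnot(is.character(tree_id), length(tree_id) == 1L, nzchar(tree_id),
            length(first_year) == 1L, is.finite(first_year),
            is.numeric(widths), length(widths) >= 1L)
  if (any(!is.finite(widths)) || any(widths < 0))
    stop("ring widths must be finite and >= 0 (tree ", tree_id, ")")
  if (!is.finite(pith_offset_mm) || pith_offset_mm < 0)
    stop("pith_offset_mm must be >= 0 (tree ", tree_id, ")")
  structure(list(tree_id = tree_id,
                 site = as.character(site),
                 first_year = as.integer(first_year),
                 last_year = as.integer(first_year) + length(widths) - 1L,
                 widths = as.numeric(widths),
                 pith_offset_mm = as.numeric(pith_offset_mm)),
            class = "ring_width_series")
}

#' @export
print.ring_width_series <- function(x, ...) {
  cat(sprintf("ring_width_series %s [%s] %d-%d (%d rings, pith offset %.2f mm)\n",
              x$tree_id, x$site, x$first_year, x$last_year,
              length(x$widths), x$pith_offset_mm))
  invisible(x)
}

#' Years covered by a ring-width series
#' @param series A `ring_width_series`.
#' @return Integer vector of calendar years.
#' @export
series_years <- function(series) series$first_year:series$last_year

#' Read a Tucson-format (.rwl) ring-width file
#'
#' Parses the decadal Tucson layout: an 8-character series id followed by a
#' decade-stamp year and up to ten integer values in units of 0.01 mm, with
#' the series terminated by a 999 (0.01 mm precision) or -9999 marker.
#' Widths are returned in mm. The first row of a series may start mid-decade.
#'
#' @param path Path to the `.rwl` file.
#' @param site Site/catchment label attached to every series, or a named
#'   character vector mapping `tree_id` to site.
#' @param pith_offsets Optional named numeric vector of pith offsets in mm,
#'   indexed by series id (default 0).
#' @return Named list of [ring_width_series] objects.
#' @export
read_rwl <- function(path, site = "", pith_offsets = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty rwl file: ", path)
    return(list())
  }
  out <- list()
  cur_id <- NULL; cur_first <- NULL; cur_vals <- NULL; closed <- character()
  finish <- function() {
    if (is.null(cur_id)) return()
    if (cur_id %in% names(out)) stop("duplicated series id: ", cur_id)
    s <- if (length(site) > 1L || !is.null(names(site))) {
      if (!cur_id %in% names(site)) stop("no site mapping for id ", cur_id)
      site[[cur_id]]
    } else site
    po <- if (!is.null(pith_offsets) && cur_id %in% names(pith_offsets))
      pith_offsets[[cur_id]] else 0
    out[[cur_id]] <<- ring_width_series(cur_id, s, cur_first,
                                        cur_vals / 100, po)
    closed <<- c(closed, cur_id)
    cur_id <<- NULL; cur_first <<- NULL; cur_vals <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    # id occupies the first 8 columns; in fixed-width files an 8-character
    # id abuts the decade year, so split an over-long first token
    if (nchar(tok[1]) > 8L) {
      tok <- c(substr(tok[1], 1L, 8L),
               substr(tok[1], 9L, nchar(tok[1])), tok[-1])
    }
    if (length(tok) < 3L) stop("malformed rwl line ", i, ": ", ln)
    id <- tok[1]
    nums <- suppressWarnings(as.numeric(tok[-1]))
    if (any(is.na(nums))) stop("malformed rwl line ", i, ": ", ln)
    yr <- nums[1]; vals <- nums[-1]
    if (yr != round(yr)) stop("malformed rwl line ", i, ": non-integer year")
    if (!identical(id, cur_id)) {
      finish()
      if (id %in% closed) stop("duplicated series id: ", id)
      cur_id <- id; cur_first <- yr; cur_vals <- numeric()
    } else {
      expected <- cur_first + length(cur_vals)
      if (yr != expected)
        stop("malformed rwl line ", i, ": decade stamp ", yr,
             " does not continue series ", id, " (expected ", expected, ")")
    }
    term <- which(vals == 999 | vals == -9999)
    if (length(term)) {
      cur_vals <- c(cur_vals, vals[seq_len(term[1] - 1L)])
      finish()
    } else {
      cur_vals <- c(cur_vals, vals)
    }
  }
  finish()
  out
}

#' Write ring-width series to a Tucson-format (.rwl) file
#'
#' Decade-aligned rows, values rounded to 0.01 mm and written as integer
#' hundredths, terminated by 999. Round-trips losslessly through
#' [read_rwl()] at 0.01 mm precision.
#'
#' @param series_list List of [ring_width_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(series_list, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (s in series_list) {
    if (nchar(s$tree_id) > 8L) stop("tree_id longer than 8 characters: ", s$tree_id)
    vals <- as.integer(round(s$widths * 100))
    if (any(vals == 999L))
      stop("width of 9.99 mm collides with the Tucson stop marker ",
           "(tree ", s$tree_id, ")")
    yrs <- series_years(s)
    i <- 1L
    while (i <= length(vals)) {
      yr <- yrs[i]
      # fill to the end of the decade
      n_dec <- 10L - (yr %% 10L)
      take <- min(n_dec, length(vals) - i + 1L)
      row <- vals[i:(i + take - 1L)]
      if (i + take - 1L == length(vals)) row <- c(row, 999L)
      writeLines(sprintf("%-8s%4d%s", s$tree_id, yr,
                         paste(sprintf("%6d", row), collapse = "")), con)
      i <- i + take
    }
  }
  invisible(path)
}

#' Read a wood delta-13C segment table
#'
#' Expects columns `tree_id,start_year,end_year,d13c_wood`; each row is a
#' bulk-wood delta-13C measurement (permil VPDB) for a contiguous block of
#' 1-5 rings. Values outside the plausible wood range (-35, -15) permil
#' trigger a warning, as do overlapping segments within a tree (overlap is
#' tolerated, not rejected: whether field segments are strictly contiguous
#' is not guaranteed).
#'
#' @param path CSV path.
#' @return `data.frame` with the four columns, validated.
#' @export
read_isotope_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_isotope_segments(d)
}

#' Validate wood-isotope segments
#' @param d `data.frame` with `tree_id,start_year,end_year,d13c_wood`.
#' @return The validated `data.frame`.
#' @export
validate_isotope_segments <- function(d) {
  need <- c("tree_id", "start_year", "end_year", "d13c_wood")
  if (!all(need %in% names(d)))
    stop("isotope table must have columns ", paste(need, collapse = ","))
  span <- d$end_year - d$start_year + 1
  if (any(span < 1 | span > 5))
    stop("isotope segments must span 1-5 years; offending rows: ",
         paste(which(span < 1 | span > 5), collapse = ","))
  bad <- d$d13c_wood <= -35 | d$d13c_wood >= -15
  if (any(bad))
    warning(sum(bad), " d13c_wood value(s) outside plausible wood range (-35,-15) permil")
  for (id in unique(d$tree_id)) {
    seg <- d[d$tree_id == id, , drop = FALSE]
    seg <- seg[order(seg$start_year), , drop = FALSE]
    if (nrow(seg) > 1L && any(seg$start_year[-1] <= seg$end_year[-nrow(seg)]))
      warning("overlapping isotope segments for tree ", id)
  }
  d
}

#' Read an annual atmospheric CO2 / delta-13C record
#'
#' Expects columns `year,d13c_air,ca_ppm` (an ice-core-style annual table).
#' Years must be strictly increasing, `ca_ppm > 0`, `d13c_air < 0`.
#'
#' @param path CSV path.
#' @return Validated `data.frame`.
#' @export
read_atmosphere_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "d13c_air", "ca_ppm")
  if (!all(need %in% names(d)))
    stop("atmosphere table must have columns ", paste(need, collapse = ","))
  if (any(diff(d$year) <= 0)) stop("atmosphere years must be strictly increasing")
  if (any(d$ca_ppm <= 0)) stop("ca_ppm must be > 0")
  if (any(d$d13c_air >= 0)) stop("d13c_air must be < 0")
  d
}

#' Read a monthly climate table
#'
#' Long format `variable,year,month,value` with `variable` one of
#' `temperature` (deg C), `cloud_cover` (percent, 0-100), `precipitation`
#' (mm, >= 0) or `pdsi` (unitless).
#'
#' @param path CSV path.
#' @return Validated `data.frame`.
#' @export
read_climate_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variable", "year", "month", "value")
  if (!all(need %in% names(d)))
    stop("climate table must have columns ", paste(need, collapse = ","))
  ok <- c("temperature", "cloud_cover", "precipitation", "pdsi")
  if (!all(d$variable %in% ok))
    stop("unknown climate variable(s): ",
         paste(setdiff(unique(d$variable), ok), collapse = ","))
  if (any(d$month < 1 | d$month > 12)) stop("month must be in 1..12")
  key <- paste(d$variable, d$year, d$month)
  if (anyDuplicated(key)) stop("duplicated (variable, year, month) rows")
  if (any(d$value[d$variable == "precipitation"] < 0))
    stop("precipitation must be >= 0")
  cc <- d$value[d$variable == "cloud_cover"]
  if (length(cc) && any(cc < 0 | cc > 100)) stop("cloud cover must be in [0,100]")
  d
}

#' Interpolate an atmospheric record to arbitrary years
#'
#' Linear interpolation between tabulated years; exact at the knots.
#' Requests outside the tabulated range are an error -- the record is never
#' silently extrapolated.
#'
#' @param atmosphere `data.frame` with `year,d13c_air,ca_ppm`.
#' @param years Numeric vector of (possibly fractional) years.
#' @return `data.frame` with columns `year,d13c_air,ca_ppm`.
#' @export
interpolate_atmosphere <- function(atmosphere, years) {
  rng <- range(atmosphere$year)
  if (any(years < rng[1] | years > rng[2]))
    stop("atmospheric record covers ", rng[1], "-", rng[2],
         "; cannot extrapolate to ",
         paste(years[years < rng[1] | years > rng[2]], collapse = ","))
  data.frame(year = years,
             d13c_air = stats::approx(atmosphere$year, atmosphere$d13c_air,
                                      xout = years)$y,
             ca_ppm = stats::approx(atmosphere$year, atmosphere$ca_ppm,
                                    xout = years)$y)
}
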