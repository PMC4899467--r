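#' Read a coefficient table from CSV
#'
#' Expects columns `response,term,estimate` and optionally `r2m,r2c,aic`.
#' Estimates written with decimal commas (`-1,876`) are accepted alongside
#' decimal points, as is common in continental-European tables. Terms use
#' the canonical vocabulary of [coefficient_table()].
#'
#' @param path CSV path.
#' @param response Optional single response to extract; if `NULL`, a named
#'   list of [coefficient_table]s for every response in the file.
#' @return A [coefficient_table] or a named list of them.
#' @export
read_coefficient_table <- function(path, response = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("response", "term", "estimate")
  if (!all(need %in% names(d)))
    stop("coefficient CSV must have columns ", paste(need, collapse = ","))
  num <- function(x) as.numeric(gsub(",", ".", x, fixed = TRUE))
  d$estimate <- num(d$estimate)
  if (any(is.na(d$estimate))) stop("non-numeric estimate(s) in ", path)
  build <- function(rs) {
    dd <- d[d$response == rs, , drop = FALSE]
    grab <- function(col) if (col %in% names(dd)) num(dd[[col]][1]) else NA_real_
    coefficient_table(dd[, c("term", "estimate")], rs,
                      r2m = grab("r2m"), r2c = grab("r2c"),
                      aic = grab("aic"))
  }
  if (!is.null(response)) {
    if (!response %in% d$response)
      stop("response '", response, "' not present in ", path)
    return(build(response))
  }
  resp <- unique(d$response)
  stats::setNames(lapply(resp, build), resp)
}

#' Published case-study coefficient tables
#'
#' The fixed-effect estimates of the best period mixed models reported for
#' the Bohemian Forest mountain Norway spruce case study (two catchments,
#' pollution-defined periods with `pre` = 1900-1935 as reference), bundled
#' with the package. These printed estimates are the input to the
#' percent-change report arithmetic; responses include discrimination
#' (`d13c`, permil), intercellular CO2 (`ci`, ppm), intrinsic water-use
#' efficiency (`iwue`, umol/mol), biomass increment (kg/yr), its
#' inter-annual variability, the four seasonal climate correlations, and
#' the increment-on-discrimination model
#' (`increment_vs_discrimination`). Blank cells of the published table are
#' absent terms (dropped from the best model), not zeros.
#'
#' @param response Optional single response name.
#' @return A [coefficient_table] or named list of them.
#' @export
reference_coefficients <- function(response = NULL) {
  read_coefficient_table(
    system.file("extdata", "bohemian_spruce_period_models.csv",
                package = "ringphys", mustWork = TRUE),
    response = response)
}

#' Model prediction for a period and catchment
#'
#' Assembles `intercept + period effect (+ catchment effect + interaction)`
#' from a [coefficient_table]. The reference period (`pre`) and reference
#' catchment (`Certovo`) contribute zero. A requested non-reference period
#' or catchment whose main-effect term is absent is an error naming the
#' term (absent means "not estimated in the best model"); an absent
#' interaction contributes zero, since dropping an interaction from a
#' model states that the effect is additive.
#'
#' @param coeffs A [coefficient_table].
#' @param period Period label (`"pre"` for reference).
#' @param catchment `NULL` (pooled reference scope), `"Certovo"` or
#'   `"Plesne"`.
#' @return Scalar prediction.
#' @export
predict_period <- function(coeffs, period, catchment = NULL) {
  terms <- coeffs$terms
  get <- function(tm) terms$estimate[terms$term == tm]
  val <- get("intercept")
  if (period != "pre") {
    e <- get(period)
    if (length(e) == 0L)
      stop("term '", period, "' absent from coefficient table '",
           coeffs$response, "'")
    val <- val + e
  }
  if (!is.null(catchment) && catchment != "Certovo") {
    e <- get(catchment)
    if (length(e) == 0L)
      stop("term '", catchment, "' absent from coefficient table '",
           coeffs$response, "'")
    val <- val + e
    if (period != "pre") {
      ie <- get(paste0(period, ":", catchment))
      if (length(ie) == 1L) val <- val + ie
    }
  }
  val
}

#' Percent change (or absolute difference) between period predictions
#'
#' The coefficient arithmetic behind the headline figures of a period
#' analysis: predictions for a baseline and a target period are assembled
#' with [predict_period()] and compared. Percent changes are rounded to
#' the nearest integer and absolute differences to one decimal, the
#' printing convention of the case study; the unrounded value is kept in
#' the `raw` attribute.
#'
#' @param coeffs A [coefficient_table].
#' @param from Baseline period label.
#' @param to Target period label.
#' @param catchment Optional catchment scope (see [predict_period()]).
#' @param type `"percent"` or `"absolute"`.
#' @return Rounded scalar with attributes `raw`, `baseline` and `target`.
#' @export
percent_change_report <- function(coeffs, from, to, catchment = NULL,
                                  type = c("percent", "absolute")) {
  type <- match.arg(type)
  b <- predict_period(coeffs, from, catchment)
  t <- predict_period(coeffs, to, catchment)
  raw <- if (type == "percent") (t - b) / b * 100 else t - b
  val <- if (type == "percent") round(raw) else round(raw, 1)
  structure(val, raw = raw, baseline = b, target = t)
}

#' Headline report of the case-study percent changes
#'
#' Recomputes, from the bundled published coefficient tables (or any
#' compatible set), the full collection of headline period-change figures:
#' the pollution-period drop and post-pollution recovery of discrimination,
#' the Ci and iWUE trajectories (with both the pre-pollution and
#' pollution-period baselines, which the published narrative mixes), the
#' catchment-specific recent biomass-increment increases and the
#' inter-annual-variability changes. Pure arithmetic on the coefficient
#' tables; no refitting.
#'
#' @param coeffs Named list of [coefficient_table]s as returned by
#'   [reference_coefficients()] (needs responses `d13c`, `ci`, `iwue`,
#'   `biomass_increment`, `interannual_variability`).
#' @return Named list of numbers: percents rounded to integers, permil and
#'   umol/mol differences unrounded.
#' @export
headline_report <- function(coeffs = reference_coefficients()) {
  pc <- function(tab, from, to, catchment = NULL)
    as.numeric(percent_change_report(coeffs[[tab]], from, to, catchment))
  ab <- function(tab, from, to)
    attr(percent_change_report(coeffs[[tab]], from, to, type = "absolute"),
         "raw")
  list(
    delta13c_pollution_change_pct = pc("d13c", "pre", "pollution"),
    delta13c_recovery_pct = pc("d13c", "pollution", "post1"),
    delta13c_reduction_permil = -ab("d13c", "pre", "pollution"),
    ci_pollution_change_pct = pc("ci", "pre", "pollution"),
    ci_post1_increase_pct = pc("ci", "pre", "post1"),
    ci_post2_increase_pct = pc("ci", "pollution", "post2"),
    iwue_pollution_increase_pct = pc("iwue", "pre", "pollution"),
    iwue_post_change_pct = pc("iwue", "pollution", "post1"),
    iwue_pre_to_post2_increase_pct = pc("iwue", "pre", "post2"),
    iwue_pollution_minus_post2 = -ab("iwue", "pollution", "post2"),
    biomass_recent_increase_certovo_pct =
      pc("biomass_increment", "pollution", "post1", "Certovo"),
    biomass_recent_increase_plesne_pct =
      pc("biomass_increment", "pollution", "post1", "Plesne"),
    variability_pollution_increase_pct =
      pc("interannual_variability", "pre", "pollution"),
    variability_post_change_pct =
      pc("interannual_variability", "pollution", "post1"))
}

#' Write a coefficient table (or list of them) to CSV
#' @param coeffs A [coefficient_table] or named list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coefficient_table <- function(coeffs, path) {
  if (inherits(coeffs, "coefficient_table")) coeffs <- list(coeffs)
  rows <- do.call(rbind, lapply(coeffs, function(ct)
    data.frame(response = ct$response, term = ct$terms$term,
               estimate = ct$terms$estimate, r2m = ct$r2m, r2c = ct$r2c,
               aic = ct$aic)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
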