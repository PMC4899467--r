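#' Estimate the pith (germination-at-core-height) year of a series
#'
#' The number of rings missing between the innermost measured ring and the
#' pith is estimated as the distance to the pith divided by the mean width
#' of the five innermost rings, rounded to the nearest ring; a further
#' `stump_age_years` (default 10) accounts for the time a spruce takes to
#' grow from stump height (30 cm) to coring height (130 cm). Cambial age in
#' year t is then `t - pith_year + 1`.
#'
#' @param series A [ring_width_series] with at least 5 rings.
#' @param stump_age_years Additional years for growth to coring height.
#' @return Integer calendar year.
#' @export
estimate_pith_year <- function(series, stump_age_years = 10) {
  if (length(series$widths) < 5L) stop("need >= 5 rings (tree ", series$tree_id, ")")
  inner <- mean(series$widths[1:5])
  if (inner <= 0) stop("five innermost rings have zero mean width (tree ",
                       series$tree_id, ")")
  as.integer(series$first_year - round(series$pith_offset_mm / inner) -
               stump_age_years)
}

#' Cambial age by calendar year
#' @param series A [ring_width_series].
#' @param stump_age_years Passed to [estimate_pith_year()].
#' @return Integer vector of ages, one per measured year.
#' @export
tree_age <- function(series, stump_age_years = 10) {
  series_years(series) - estimate_pith_year(series, stump_age_years) + 1L
}

#' Reconstruct over-bark breast-height diameter from ring widths
#'
#' `D(t) = bark_factor * (2 * cumulative ring width up to t + 2 * pith
#' offset)` in mm. The default factor 1.096 converts the under-bark radial
#' reconstruction to over-bark diameter, compensating for bark thickness
#' and drying shrinkage; see [bark_factor_calibration()] for how such a
#' factor is estimated against field diameter tapes.
#'
#' @param series A [ring_width_series].
#' @param bark_factor Multiplicative over-bark correction.
#' @return Numeric vector of diameters (mm), one per measured year.
#' @export
reconstruct_diameter <- function(series, bark_factor = 1.096) {
  bark_factor * (2 * cumsum(series$widths) + 2 * series$pith_offset_mm)
}

#' Site-specific height model
#'
#' Height-diameter polynomials fitted separately per catchment, metres,
#' with the 1.3 m breast-height intercept:
#' Certovo (cubic): `1.3 + 0.08661 d - 6.975e-5 d^2 + 2.137e-8 d^3`;
#' Plesne (quadratic): `1.3 + 0.05763 d - 2.596e-5 d^2`; d in mm.
#'
#' @param diameter_mm Diameter at breast height, mm.
#' @param site `"Certovo"` or `"Plesne"`.
#' @return Height in m.
#' @export
height_model <- function(diameter_mm, site) {
  d <- diameter_mm
  switch(as.character(site),
         Certovo = 1.3 + 0.08661 * d - 6.975e-5 * d^2 + 2.137e-8 * d^3,
         Plesne = 1.3 + 0.05763 * d - 2.596e-5 * d^2,
         stop("unknown site: ", site, " (expected Certovo or Plesne)"))
}

#' Crown-length model
#'
#' Single power law for both catchments: `0.0894 * d^0.8022` m, d in mm.
#' Crown length has a comparatively minor influence on total biomass, so
#' one pooled model is used.
#'
#' @param diameter_mm Diameter at breast height, mm.
#' @return Crown length in m.
#' @export
crown_length_model <- function(diameter_mm) {
  stopifnot(all(diameter_mm >= 0))
  0.0894 * diameter_mm^0.8022
}

# the five log-linear biomass component models: each component is
# exp(cf * [b0 + terms]), cf a multiplicative correction applied to the
# whole linear predictor. ld = ln(diameter/10) i.e. diameter in cm,
# lh = ln(height m), la = ln(age yr), lc = ln(crown length m).
.biomass_models <- list(
  needles = function(ld, lh, la, lc)
    1.07410095 * (-1.18863 + 3.33792 * ld - 0.24482 * ld^2 - 3.31885 * lh +
                    0.49368 * lh^2 - 0.13463 * la + 0.85797 * lc),
  branches = function(ld, lh, la, lc)
    1.20383259 * (0.61063 + 2.40589 * ld - 3.65994 * lh + 0.4398 * lh^2 +
                    0.91027 * lc),
  dry_branches = function(ld, lh, la, lc)
    1.22896995 * (-3.09062 + 2.04823 * ld - 1.286761 * lh + 0.62836 * la),
  stem = function(ld, lh, la, lc)
    1.0097234 * (-2.83958 + 2.55203 * ld - 0.14991 * ld^2 - 0.19172 * lh +
                   0.25739 * lh^2 - 0.08278 * la),
  roots = function(ld, lh, la, lc)
    1.0526828 * (-8.15491 + 4.08262 * ld - 0.28378 * ld^2 + 0.34963 * la +
                   0.2452 * lc))

#' Biomass components from tree geometry
#'
#' Evaluates the five allometric component models (needles, branches, dry
#' branches, stem, roots; kg dry mass) from diameter (mm; the models use
#' diameter/10, i.e. cm, internally), height (m), cambial age (yr) and
#' crown length (m). Total biomass is the sum of the five components.
#'
#' @param diameter_mm,height_m,age_years,crown_length_m Numeric vectors
#'   (recycled to common length); all log arguments must be positive and
#'   `height_m > 1.3`.
#' @param tree_id Optional id used in error messages.
#' @return `data.frame` with the five components and `total_kg`.
#' @export
biomass_components <- function(diameter_mm, height_m, age_years,
                               crown_length_m, tree_id = NULL) {
  n <- max(length(diameter_mm), length(height_m), length(age_years),
           length(crown_length_m))
  d <- rep_len(diameter_mm, n); h <- rep_len(height_m, n)
  a <- rep_len(age_years, n); cl <- rep_len(crown_length_m, n)
  bad <- d <= 0 | h <= 1.3 | a < 1 | cl <= 0
  if (any(bad))
    stop("non-positive log argument in biomass model",
         if (!is.null(tree_id)) paste0(" (tree ", tree_id, ")"),
         " at position(s) ", paste(which(bad), collapse = ","))
  ld <- log(d / 10); lh <- log(h); la <- log(a); lc <- log(cl)
  comp <- lapply(.biomass_models, function(f) exp(f(ld, lh, la, lc)))
  out <- data.frame(needles_kg = comp$needles,
                    branches_kg = comp$branches,
                    dry_branches_kg = comp$dry_branches,
                    stem_kg = comp$stem,
                    roots_kg = comp$roots)
  out$total_kg <- rowSums(out)
  out
}

#' Annual biomass increment from a total-biomass series
#'
#' First differences of total biomass over consecutive years; the first
#' year carries no increment. Negative increments (possible where the age
#' terms of the component models dominate) are kept and reported with a
#' message, never dropped.
#'
#' @param total_kg Numeric vector of total biomass.
#' @param years Matching calendar years (must be consecutive).
#' @return `data.frame` with `year` and `increment_kg` (length
#'   `length(years) - 1`).
#' @export
biomass_increment <- function(total_kg, years) {
  stopifnot(length(total_kg) == length(years), length(years) >= 2L)
  if (any(diff(years) != 1))
    stop("years must be consecutive; gap after ",
         paste(years[which(diff(years) != 1)], collapse = ","))
  inc <- diff(total_kg)
  if (any(inc < 0))
    message(sum(inc < 0), " negative biomass increment(s) retained")
  data.frame(year = years[-1], increment_kg = inc)
}

#' Calibrate an over-bark correction factor
#'
#' Zero-intercept least squares of measured over-bark diameters on
#' reconstructed under-bark diameters: the fitted slope is the
#' multiplicative correction applied by [reconstruct_diameter()].
#'
#' @param reconstructed Reconstructed final-year diameters (under bark).
#' @param measured Field-measured diameters, same trees, same order.
#' @return The estimated factor (scalar).
#' @export
bark_factor_calibration <- function(reconstructed, measured) {
  stopifnot(length(reconstructed) == length(measured))
  if (length(reconstructed) < 3L) stop("need >= 3 diameter pairs")
  if (any(reconstructed <= 0) || any(measured <= 0))
    stop("diameters must be positive")
  sum(measured * reconstructed) / sum(reconstructed^2)
}

#' Full per-tree biomass reconstruction
#'
#' Chains the geometric and allometric steps for one ring-width series:
#' diameter reconstruction, per-year height, crown length and cambial age
#' (geometry re-derived from each year's reconstructed diameter), the five
#' biomass components, total biomass and its annual increment. Deterministic:
#' identical inputs give identical outputs.
#'
#' @param series A [ring_width_series].
#' @param bark_factor Over-bark correction for [reconstruct_diameter()].
#' @param stump_age_years Passed to [estimate_pith_year()].
#' @return `data.frame` with columns `tree_id,year,diameter_mm,height_m,
#'   crown_length_m,age,needles_kg,branches_kg,dry_branches_kg,stem_kg,
#'   roots_kg,total_kg,increment_kg` (`NA` increment in the first year).
#' @export
biomass_series <- function(series, bark_factor = 1.096, stump_age_years = 10) {
  yrs <- series_years(series)
  d <- reconstruct_diameter(series, bark_factor)
  h <- height_model(d, series$site)
  cl <- crown_length_model(d)
  age <- tree_age(series, stump_age_years)
  bm <- biomass_components(d, h, age, cl, tree_id = series$tree_id)
  inc <- biomass_increment(bm$total_kg, yrs)
  data.frame(tree_id = series$tree_id, year = yrs,
             diameter_mm = d, height_m = h, crown_length_m = cl, age = age,
             bm,
             increment_kg = c(NA_real_, inc$increment_kg))
}

#' Biomass reconstruction for a collection of series
#' @param series_list List of [ring_width_series].
#' @inheritParams biomass_series
#' @return Row-bound `data.frame` of [biomass_series()] outputs.
#' @export
biomass_series_all <- function(series_list, bark_factor = 1.096,
                               stump_age_years = 10) {
  do.call(rbind, lapply(series_list, biomass_series,
                        bark_factor = bark_factor,
                        stump_age_years = stump_age_years))
}
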