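#' Carbon isotope fractionation constants
#'
#' The two discrimination endpoints of the simple Farquhar model and the
#' CO2/H2O diffusivity ratio: `a` = 4.4 permil (fractionation during
#' diffusion through the stomata), `b` = 27 permil (fractionation during
#' carboxylation by Rubisco), `diffusivity_ratio` = 0.625 (converts a CO2
#' gradient into water terms under A = (Ca - Ci) * g_c and g_w = 1.6 g_c).
#'
#' @param a Stomatal diffusion fractionation, permil.
#' @param b Carboxylation fractionation, permil.
#' @param diffusivity_ratio Ratio of CO2 to H2O diffusivity.
#' @return List of class `fractionation_constants`.
#' @export
fractionation_constants <- function(a = 4.4, b = 27, diffusivity_ratio = 0.625) {
  stopifnot(b > a, a > 0, diffusivity_ratio > 0)
  structure(list(a = a, b = b, diffusivity_ratio = diffusivity_ratio),
            class = "fractionation_constants")
}

#' Convert wood delta-13C to foliage delta-13C
#'
#' Bulk wood is isotopically offset from the foliage where the sugars were
#' fixed; the empirical linear relation
#' `d13C_foliage = 1.0523 * d13C_wood - 0.205` maps one to the other.
#'
#' @param d13c_wood Wood delta-13C, permil VPDB.
#' @return Foliage delta-13C, permil VPDB.
#' @seealso [foliage_to_wood()] for the exact inverse.
#' @export
wood_to_foliage <- function(d13c_wood) {
  stopifnot(all(is.finite(d13c_wood)))
  1.0523 * d13c_wood - 0.205
}

#' Invert the wood-to-foliage delta-13C relation
#' @param d13c_foliage Foliage delta-13C, permil VPDB.
#' @return Wood delta-13C, permil VPDB.
#' @export
foliage_to_wood <- function(d13c_foliage) (d13c_foliage + 0.205) / 1.0523

#' Carbon isotope discrimination
#'
#' Discrimination of the plant against 13C relative to the atmosphere,
#' `Delta = (d13C_air - d13C_foliage) / (1 + d13C_foliage/1000)`, in permil.
#' Accounts for the anthropogenic decline of atmospheric d13C (the Suess
#' effect) by referencing each sample to the air composition of its years.
#'
#' @param d13c_air Atmospheric delta-13C, permil VPDB.
#' @param d13c_foliage Foliage delta-13C, permil VPDB.
#' @return Discrimination Delta-13C, permil.
#' @export
discrimination <- function(d13c_air, d13c_foliage) {
  stopifnot(all(is.finite(d13c_air)), all(is.finite(d13c_foliage)))
  denom <- 1 + d13c_foliage / 1000
  if (any(denom <= 0))
    stop("non-positive denominator: d13c_foliage must exceed -1000 permil")
  (d13c_air - d13c_foliage) / denom
}

#' Invert discrimination back to foliage delta-13C
#' @param delta13c Discrimination, permil.
#' @param d13c_air Atmospheric delta-13C, permil VPDB.
#' @return Foliage delta-13C, permil VPDB.
#' @export
discrimination_to_foliage <- function(delta13c, d13c_air) {
  (d13c_air - delta13c) / (1 + delta13c / 1000)
}

#' Intercellular CO2 concentration
#'
#' `Ci = Ca * (Delta - a) / (b - a)`, micromol CO2 per mol air. At
#' `Delta = a` the leaf interior is CO2-free (Ci = 0); at `Delta = b` it
#' equilibrates with the atmosphere (Ci = Ca). Values of `Delta` outside
#' `[a, b]` produce Ci outside `[0, Ca]` with a warning rather than an
#' error: they can arise from measurement noise near the boundaries.
#'
#' @param delta13c Discrimination, permil.
#' @param ca_ppm Atmospheric CO2, ppm (> 0).
#' @param consts A [fractionation_constants] object.
#' @return Ci in ppm.
#' @export
intercellular_co2 <- function(delta13c, ca_ppm,
                              consts = fractionation_constants()) {
  stopifnot(all(ca_ppm > 0))
  out <- which(delta13c < consts$a | delta13c > consts$b)
  if (length(out))
    warning(length(out), " discrimination value(s) outside [a, b]; ",
            "Ci falls outside [0, Ca]")
  ca_ppm * (delta13c - consts$a) / (consts$b - consts$a)
}

#' Intrinsic water-use efficiency
#'
#' `iWUE = (Ca - Ci) * 0.625`, micromol CO2 per mol H2O: the assimilation
#' rate per unit stomatal conductance to water vapour, assuming
#' `A = (Ca - Ci) * g_c` and the fixed CO2/H2O diffusivity ratio.
#'
#' @param ca_ppm Atmospheric CO2, ppm.
#' @param ci_ppm Intercellular CO2, ppm.
#' @param consts A [fractionation_constants] object.
#' @return iWUE in micromol CO2 per mol H2O.
#' @export
intrinsic_wue <- function(ca_ppm, ci_ppm, consts = fractionation_constants()) {
  stopifnot(all(is.finite(ca_ppm)), all(is.finite(ci_ppm)))
  (ca_ppm - ci_ppm) * consts$diffusivity_ratio
}

#' Physiological series from wood-isotope segments
#'
#' Composes the wood-to-foliage conversion, discrimination, Ci and iWUE for
#' every segment of a wood delta-13C table. For a multi-year segment the
#' atmospheric d13C and Ca are evaluated at the arithmetic midpoint year of
#' the segment via [interpolate_atmosphere()] (`atmosphere_at = "midpoint"`,
#' the default) or as the mean of the annual values over the segment
#' (`"mean"`); the two differ negligibly for segments of at most five years
#' on a near-linear record.
#'
#' @param segments `data.frame` with `tree_id,start_year,end_year,d13c_wood`
#'   (see [read_isotope_csv()]).
#' @param atmosphere `data.frame` with `year,d13c_air,ca_ppm`.
#' @param consts A [fractionation_constants] object.
#' @param atmosphere_at `"midpoint"` or `"mean"`.
#' @return `data.frame` with columns `tree_id,start_year,end_year,
#'   d13c_wood,d13c_foliage,delta13C,ci_ppm,iwue`.
#' @export
physiology_series <- function(segments, atmosphere,
                              consts = fractionation_constants(),
                              atmosphere_at = c("midpoint", "mean")) {
  atmosphere_at <- match.arg(atmosphere_at)
  segments <- validate_isotope_segments(segments)
  rng <- range(atmosphere$year)
  uncovered <- segments$start_year < rng[1] | segments$end_year > rng[2]
  if (any(uncovered))
    stop("atmospheric record does not cover segment(s): ",
         paste(sprintf("%s %d-%d", segments$tree_id[uncovered],
                       segments$start_year[uncovered],
                       segments$end_year[uncovered]), collapse = "; "))
  if (atmosphere_at == "midpoint") {
    mid <- (segments$start_year + segments$end_year) / 2
    atm <- interpolate_atmosphere(atmosphere, mid)
  } else {
    atm <- do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
      a <- interpolate_atmosphere(atmosphere,
                                  segments$start_year[i]:segments$end_year[i])
      data.frame(year = NA, d13c_air = mean(a$d13c_air),
                 ca_ppm = mean(a$ca_ppm))
    }))
  }
  fol <- wood_to_foliage(segments$d13c_wood)
  delta <- discrimination(atm$d13c_air, fol)
  ci <- intercellular_co2(delta, atm$ca_ppm, consts)
  data.frame(tree_id = segments$tree_id,
             start_year = segments$start_year,
             end_year = segments$end_year,
             d13c_wood = segments$d13c_wood,
             d13c_foliage = fol,
             delta13C = delta,
             ci_ppm = ci,
             iwue = intrinsic_wue(atm$ca_ppm, ci, consts))
}
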