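#' Run the full retrospective analysis on a synthetic dataset
#'
#' One-shot orchestration of every stage: simulate the atmosphere, climate,
#' ring widths and wood-isotope segments; reconstruct physiology
#' (discrimination, Ci, iWUE) and biomass increment; estimate the
#' variance-stabilizing power and spline-detrend the increment and
#' seasonal climate series; screen single months and correlate by period;
#' average into periods and fit the period mixed models; and assemble the
#' percent-change report. All randomness flows from `config$seed`;
#' re-running with the same config reproduces every output exactly.
#'
#' Trees whose increment series contain non-positive values fall back to
#' `p = 1` for the power transform (the transform is undefined there);
#' climate series are never power transformed.
#'
#' @param config A [sim_config].
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as CSV/JSON together with a `manifest.json` recording the package
#'   version, seed and configuration.
#' @param screen_window Year window for the preliminary month screen.
#' @return Named list bundle with elements `atmosphere`, `climate`,
#'   `physiology`, `biomass`, `power_p`, `detrended`, `chronology`,
#'   `screen`, `correlations`, `period_fits`, `increment_vs_delta`,
#'   `report`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         screen_window = c(1901, 2007)) {
  atmosphere <- simulate_atmosphere(config)
  climate <- simulate_climate(config)
  rings <- simulate_ring_widths(config, climate)
  iso <- simulate_isotopes(config, atmosphere)
  iso_rings <- simulate_ring_widths(config, climate,
                                    n_trees = config$n_isotope_trees,
                                    id_prefix = c(Certovo = "CI",
                                                  Plesne = "PI"))
  sites <- c(vapply(rings, `[[`, "", "site"),
             vapply(iso_rings, `[[`, "", "site"))

  # physiology from isotope segments
  physio <- physiology_series(iso$segments, atmosphere)
  physio$site <- iso$segments$site[match(physio$tree_id,
                                         iso$segments$tree_id)]

  # biomass reconstruction for increment and isotope trees
  biomass <- biomass_series_all(c(rings, iso_rings))
  inc <- biomass[!is.na(biomass$increment_kg),
                 c("tree_id", "year", "increment_kg")]

  # adaptive power from the pooled increment series
  inc_series <- split(inc$increment_kg, inc$tree_id)
  positive <- vapply(inc_series, function(x) all(x > 0), logical(1))
  p <- optimal_power(inc_series[positive])

  # residual detrending of each tree's increment series
  det <- lapply(names(inc_series), function(id) {
    d <- inc[inc$tree_id == id, ]
    pt <- if (all(d$increment_kg > 0)) as.numeric(p) else 1
    r <- detrend_series(d$increment_kg, d$year, p = pt)
    data.frame(tree_id = id, r)
  })
  detrended <- do.call(rbind, det)
  chron <- stats::aggregate(residual ~ year, detrended, mean)
  names(chron) <- c("year", "value")

  # month screen and seasonal correlations by period
  screen <- screen_months(chron, climate, window = screen_window)
  seasons <- default_seasons()
  residx <- detrended[, c("tree_id", "year", "residual")]
  names(residx)[3] <- "value"
  correlations <- do.call(rbind, lapply(names(seasons), function(v) {
    s <- aggregate_season(climate, seasons[[v]])
    s <- s[!is.na(s$value), ]
    sd <- detrend_series(s$value, s$year, p = 1)
    spearman_by_period(residx, data.frame(year = sd$year,
                                          value = sd$residual),
                       config$periods, variable = v)
  }))

  # period means and mixed models
  periods <- config$periods
  pm_delta <- period_means(data.frame(tree_id = physio$tree_id,
                                      start_year = physio$start_year,
                                      end_year = physio$end_year,
                                      value = physio$delta13C), periods)
  pm_ci <- period_means(data.frame(tree_id = physio$tree_id,
                                   start_year = physio$start_year,
                                   end_year = physio$end_year,
                                   value = physio$ci_ppm), periods)
  pm_iwue <- period_means(data.frame(tree_id = physio$tree_id,
                                     start_year = physio$start_year,
                                     end_year = physio$end_year,
                                     value = physio$iwue), periods)
  pm_inc <- period_means(stats::setNames(inc, c("tree_id", "year", "value")),
                         periods)
  sens <- do.call(rbind, lapply(names(inc_series), function(id) {
    d <- inc[inc$tree_id == id, ]
    num <- 2 * abs(diff(d$increment_kg))
    den <- d$increment_kg[-1] + d$increment_kg[-nrow(d)]
    keep <- den != 0
    data.frame(tree_id = id, year = d$year[-1][keep],
               value = (num / den)[keep])
  }))
  pm_var <- period_means(sens, periods)

  add_site <- function(pm) {
    pm$catchment <- sites[as.character(pm$tree_id)]
    pm
  }
  period_fits <- list(
    d13c = fit_period_model(add_site(pm_delta), response = "d13c"),
    ci = fit_period_model(add_site(pm_ci), response = "ci"),
    iwue = fit_period_model(add_site(pm_iwue), response = "iwue"),
    biomass_increment = fit_period_model(add_site(pm_inc),
                                         response = "biomass_increment"),
    interannual_variability =
      fit_period_model(add_site(pm_var),
                       response = "interannual_variability"))

  # increment-discrimination coupling on the isotope trees
  joint <- merge(stats::setNames(pm_delta[, 1:3],
                                 c("tree_id", "period", "delta13C")),
                 stats::setNames(pm_inc[, 1:3],
                                 c("tree_id", "period", "increment")))
  increment_vs_delta <- if (nrow(joint) >= 10L)
    fit_increment_vs_discrimination(joint) else NULL

  bundle <- list(atmosphere = atmosphere, climate = climate,
                 physiology = physio, biomass = biomass,
                 power_p = p, detrended = detrended, chronology = chron,
                 screen = screen, correlations = correlations,
                 period_fits = period_fits,
                 increment_vs_delta = increment_vs_delta,
                 report = headline_report())

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(physio, file.path(out_dir, "physiology.csv"),
                     row.names = FALSE)
    utils::write.csv(biomass, file.path(out_dir, "biomass.csv"),
                     row.names = FALSE)
    utils::write.csv(detrended, file.path(out_dir, "detrended.csv"),
                     row.names = FALSE)
    utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    write_coefficient_table(period_fits,
                            file.path(out_dir, "period_models.csv"))
    jsonlite::write_json(bundle$report,
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(package = "ringphys",
           version = as.character(utils::packageVersion("ringphys")),
           seed = config$seed,
           config = config[setdiff(names(config), "periods")],
           periods = config$periods),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  bundle
}
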