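# shared fixture builders; everything is generated in code, nothing on disk

# linear toy atmosphere covering 1850-2011
toy_atmosphere <- function(years = 1850:2011, ca0 = 290, ca1 = 390,
                           d0 = -6.4, d1 = -8.3) {
  f <- (years - years[1]) / (years[length(years)] - years[1])
  data.frame(year = years, d13c_air = d0 + (d1 - d0) * f,
             ca_ppm = ca0 + (ca1 - ca0) * f)
}

# random ring-width series for round-trip tests
random_series <- function(id, n = NULL, first_year = NULL) {
  if (is.null(n)) n <- sample(5:60, 1)
  if (is.null(first_year)) first_year <- sample(1600:1990, 1)
  # stay below 9.99 mm: the Tucson stop marker occupies that code point
  ring_width_series(id, "Certovo", first_year,
                    round(stats::runif(n, 0, 9.9), 2),
                    pith_offset_mm = round(stats::runif(1, 0, 10), 2))
}

# tree-period data with known variance components for mixed-model tests
sim_period_data <- function(n_trees, effects = c(pre = 0, pollution = -1.876,
                                                 post1 = -0.696,
                                                 post2 = -0.480),
                            intercept = 19.635, tree_sd = 0.57,
                            resid_sd = 0.345) {
  periods <- names(effects)
  d <- expand.grid(tree_id = sprintf("T%03d", seq_len(n_trees)),
                   period = factor(periods, levels = periods))
  tre <- stats::rnorm(n_trees, 0, tree_sd)
  d$value <- intercept + effects[as.character(d$period)] +
    tre[match(d$tree_id, unique(d$tree_id))] +
    stats::rnorm(nrow(d), 0, resid_sd)
  d
}
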