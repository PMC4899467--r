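test_that("synthetic atmosphere is monotone and hits the period anchors", {
  atm <- simulate_atmosphere(sim_config(seed = 1))
  expect_true(all(diff(atm$ca_ppm) > 0))
  expect_true(all(diff(atm$d13c_air) < 0))
  expect_equal(mean(atm$ca_ppm[atm$year %in% 1971:1989]), 339,
               tolerance = 3 / 339)
  expect_equal(mean(atm$ca_ppm[atm$year %in% 2006:2011]), 381,
               tolerance = 3 / 381)
  expect_identical(atm, simulate_atmosphere(sim_config(seed = 99)))
})

test_that("synthetic climate matches the site climatology", {
  cfg <- sim_config(seed = 2)
  cl <- simulate_climate(cfg)
  tm <- cl[cl$variable == "temperature", ]
  annual <- tapply(tm$value, tm$year, mean)
  expect_equal(mean(annual), 4, tolerance = 0.3 / 4)
  pr <- cl[cl$variable == "precipitation", ]
  expect_gte(mean(tapply(pr$value, pr$year, sum)), 1200)
  expect_true(all(pr$value >= 0))
  cc <- cl[cl$variable == "cloud_cover", ]
  expect_true(all(cc$value >= 0 & cc$value <= 100))
  # cloud is negatively coupled to temperature anomalies
  tj <- tm$value[tm$month == 7]
  cj <- cc$value[cc$month == 7]
  expect_lt(cor(tj, cj), 0)
  expect_identical(cl, simulate_climate(sim_config(seed = 2)))
})

test_that("synthetic ring widths are reproducible, positive, age-trended", {
  cfg <- sim_config(seed = 3, n_increment_trees = c(Certovo = 8, Plesne = 8))
  cl <- simulate_climate(cfg)
  rw <- simulate_ring_widths(cfg, cl)
  expect_length(rw, 16L)
  expect_true(all(vapply(rw, function(s) all(s$widths >= 0), logical(1))))
  expect_identical(rw, simulate_ring_widths(cfg, cl))
  # early rings are wider on average than late rings (negative exponential)
  early <- mean(vapply(rw, function(s) mean(s$widths[1:30]), numeric(1)))
  late <- mean(vapply(rw, function(s) mean(rev(s$widths)[1:30]), numeric(1)))
  expect_gt(early, late)
})

test_that("without a climate effect the month screen finds nothing special", {
  cfg <- sim_config(seed = 4, climate_beta = 0,
                    n_increment_trees = c(Certovo = 20, Plesne = 0))
  cl <- simulate_climate(cfg)
  rw <- simulate_ring_widths(cfg, cl)
  inc <- biomass_series_all(rw)
  inc <- inc[!is.na(inc$increment_kg), ]
  det <- do.call(rbind, lapply(split(inc, inc$tree_id), function(d) {
    r <- detrend_series(d$increment_kg, d$year,
                        p = if (all(d$increment_kg > 0)) 0.2 else 1)
    data.frame(year = r$year, value = r$residual)
  }))
  chron <- aggregate(value ~ year, det, mean)
  sc <- screen_months(chron, cl)
  expect_lt(mean(sc$p < 0.05), 0.2)
})

test_that("noiseless isotope simulation is identifiable through physiology", {
  cfg <- sim_config(seed = 5, tree_sd_delta = 0, noise_sd_delta = 0,
                    n_isotope_trees = c(Certovo = 3, Plesne = 2))
  atm <- simulate_atmosphere(cfg)
  iso <- simulate_isotopes(cfg, atm)
  phys <- physiology_series(iso$segments, atm)
  # exact chain check: each segment's reconstructed discrimination equals
  # the mean of the generated annual truth over its years
  truth <- iso$true_delta
  for (i in seq_len(nrow(phys))) {
    tv <- truth$delta13C[truth$tree_id == phys$tree_id[i] &
                           truth$year >= phys$start_year[i] &
                           truth$year <= phys$end_year[i]]
    expect_equal(phys$delta13C[i], mean(tv), tolerance = 1e-9)
  }
  # period means recover the configured effects up to boundary-straddling
  # segments (a segment overlapping a period edge mixes two period levels)
  pm <- period_means(data.frame(tree_id = phys$tree_id,
                                start_year = phys$start_year,
                                end_year = phys$end_year,
                                value = phys$delta13C),
                     cfg$periods)
  agg <- tapply(pm$value, pm$period, mean)
  expect_equal(unname(agg["pre"]), 19.635, tolerance = 0.2 / 19.6)
  expect_equal(unname(agg["pollution"]), 19.635 - 1.876,
               tolerance = 0.3 / 17.8)
  expect_equal(unname(agg["post1"]), 19.635 - 0.696, tolerance = 0.3 / 18.9)
  expect_equal(unname(agg["post2"]), 19.635 - 0.480, tolerance = 0.3 / 19.2)
})

test_that("discrimination inverts through wood delta-13C to 1e-9", {
  atm <- toy_atmosphere()
  delta <- seq(14, 24, by = 0.5)
  a <- interpolate_atmosphere(atm, rep(1975, length(delta)))
  wood <- foliage_to_wood(discrimination_to_foliage(delta, a$d13c_air))
  back <- discrimination(a$d13c_air, wood_to_foliage(wood))
  expect_equal(back, delta, tolerance = 1e-9)
})

test_that("simulate_dataset emits files that read back consistently", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 6, n_increment_trees = c(Certovo = 4, Plesne = 3),
                    n_isotope_trees = c(Certovo = 3, Plesne = 2))
  paths <- simulate_dataset(cfg, dir)
  expect_true(all(file.exists(paths)))
  rw <- read_rwl(paths[["rwl"]], site = "Certovo")
  expect_length(rw, 7L)
  iso <- read_isotope_csv(paths[["isotopes"]])
  expect_true(all(iso$end_year - iso$start_year + 1 <= 5))
  atm <- read_atmosphere_csv(paths[["atmosphere"]])
  cl <- read_climate_csv(paths[["climate"]])
  expect_setequal(unique(cl$variable),
                  c("temperature", "cloud_cover", "precipitation", "pdsi"))
  # the emitted widths match the in-memory generator to 0.01 mm
  rw_mem <- simulate_ring_widths(cfg, simulate_climate(cfg))
  expect_equal(rw[["C001"]]$widths, rw_mem[["C001"]]$widths)
})
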