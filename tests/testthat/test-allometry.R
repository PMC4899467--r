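test_that("pith year combines missing-ring and stump-age corrections", {
  s <- ring_width_series("A", "Certovo", 1850,
                         c(1.6, 1.4, 1.5, 1.5, 1.5, rep(1, 20)), 6)
  expect_equal(estimate_pith_year(s), 1836) # 1850 - round(6/1.5) - 10
  s0 <- ring_width_series("B", "Certovo", 1850, rep(1.5, 10), 0)
  expect_equal(estimate_pith_year(s0), 1840) # core through pith
  age <- tree_age(s)
  expect_equal(diff(age), rep(1L, length(age) - 1L))
  expect_error(estimate_pith_year(ring_width_series("C", "Certovo", 1850,
                                                    rep(1, 4))),
               ">= 5 rings")
  expect_error(estimate_pith_year(ring_width_series("D", "Certovo", 1850,
                                                    c(0, 0, 0, 0, 0, 1))),
               "zero mean")
})

test_that("diameter reconstruction applies the over-bark factor", {
  w <- rep(2, 50) # cumulative 100 mm in the final year
  s <- ring_width_series("A", "Certovo", 1900, w, 5)
  d <- reconstruct_diameter(s)
  expect_equal(d[50], 1.096 * (2 * 100 + 2 * 5)) # 230.16
  expect_true(all(diff(d) >= 0))
  # the factor is purely multiplicative
  expect_equal(reconstruct_diameter(s, bark_factor = 1), d / 1.096)
  z <- ring_width_series("B", "Certovo", 1900, rep(0, 10), 0)
  expect_equal(reconstruct_diameter(z), rep(0, 10))
})

test_that("height models evaluate the printed site polynomials", {
  expect_equal(height_model(300, "Certovo"), 21.58249, tolerance = 1e-6)
  expect_equal(height_model(300, "Plesne"), 16.2526, tolerance = 1e-6)
  expect_equal(height_model(0, "Certovo"), 1.3)
  expect_equal(height_model(0, "Plesne"), 1.3)
  expect_error(height_model(300, "Elsewhere"), "unknown site")
})

test_that("crown length is a concave power law through the origin", {
  expect_equal(crown_length_model(0), 0)
  expect_equal(crown_length_model(300), 8.67929, tolerance = 1e-5)
  d <- seq(10, 600, by = 10)
  cl <- crown_length_model(d)
  expect_true(all(diff(cl) > 0))
  expect_true(all(diff(diff(cl)) < 0))
})

test_that("biomass components match an independent evaluation", {
  # spreadsheet-style re-evaluation of the printed component models,
  # written out term by term, independent of the package implementation
  d <- c(150, 300, 450); h <- c(14, 20, 26); a <- c(80, 150, 220)
  cl <- c(5, 9, 12)
  ld <- log(d / 10); lh <- log(h); la <- log(a); lcl <- log(cl)
  needles <- exp(1.07410095 * (-1.18863 + 3.33792 * ld - 0.24482 * ld^2 -
                                 3.31885 * lh + 0.49368 * lh^2 -
                                 0.13463 * la + 0.85797 * lcl))
  branches <- exp(1.20383259 * (0.61063 + 2.40589 * ld - 3.65994 * lh +
                                  0.4398 * lh^2 + 0.91027 * lcl))
  dry <- exp(1.22896995 * (-3.09062 + 2.04823 * ld - 1.286761 * lh +
                             0.62836 * la))
  stem <- exp(1.0097234 * (-2.83958 + 2.55203 * ld - 0.14991 * ld^2 -
                             0.19172 * lh + 0.25739 * lh^2 - 0.08278 * la))
  roots <- exp(1.0526828 * (-8.15491 + 4.08262 * ld - 0.28378 * ld^2 +
                              0.34963 * la + 0.2452 * lcl))
  out <- biomass_components(d, h, a, cl)
  expect_equal(out$needles_kg, needles)
  expect_equal(out$branches_kg, branches)
  expect_equal(out$dry_branches_kg, dry)
  expect_equal(out$stem_kg, stem)
  expect_equal(out$roots_kg, roots)
  expect_equal(out$total_kg, needles + branches + dry + stem + roots)
  # frozen spot value for the mature-tree geometry
  m <- biomass_components(300, 20, 150, 9)
  expect_equal(m$stem_kg, 239.791, tolerance = 1e-4)
  expect_equal(m$needles_kg, 25.93111, tolerance = 1e-4)
  expect_gt(m$stem_kg, m$needles_kg)
  expect_true(all(unlist(m) > 0))
})

test_that("biomass models reject non-positive log arguments", {
  expect_error(biomass_components(0, 20, 150, 9, tree_id = "T9"), "T9")
  expect_error(biomass_components(300, 1.3, 150, 9), "position")
})

test_that("biomass increment is the telescoping first difference", {
  inc <- biomass_increment(c(100, 110, 125), 2000:2002)
  expect_equal(inc$increment_kg, c(10, 15))
  expect_equal(inc$year, 2001:2002)
  expect_equal(biomass_increment(rep(50, 5), 2000:2004)$increment_kg,
               rep(0, 4))
  x <- cumsum(runif(20, 0, 5)) + 100
  expect_equal(sum(biomass_increment(x, 2000:2019)$increment_kg),
               x[20] - x[1])
  expect_error(biomass_increment(c(1, 2, 3), c(2000, 2001, 2003)), "gap")
})

test_that("bark factor calibration recovers the generating ratio", {
  set.seed(77)
  r <- runif(129, 100, 600)
  expect_equal(bark_factor_calibration(r, 1.096 * r), 1.096)
  expect_equal(bark_factor_calibration(r, r), 1)
  noisy <- 1.096 * r * (1 + rnorm(129, 0, 0.05))
  expect_equal(bark_factor_calibration(r, noisy), 1.096, tolerance = 0.01)
  expect_error(bark_factor_calibration(r[1:2], r[1:2]), ">= 3")
})

test_that("the widths-to-increment chain is deterministic", {
  set.seed(3)
  s <- ring_width_series("A", "Plesne", 1900, runif(80, 0.3, 3), 4)
  b1 <- biomass_series(s)
  b2 <- biomass_series(s)
  expect_identical(b1, b2)
  expect_equal(b1$total_kg,
               rowSums(b1[, c("needles_kg", "branches_kg",
                              "dry_branches_kg", "stem_kg", "roots_kg")]))
  expect_true(all(diff(b1$diameter_mm) >= 0))
})
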