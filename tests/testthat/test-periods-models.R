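test_that("default periods match the pollution chronology", {
  p <- default_periods()
  expect_equal(p$label, c("pre", "pollution", "post1", "post2"))
  expect_equal(p$start_year, c(1900, 1971, 1998, 2006))
  expect_equal(p$end_year, c(1935, 1989, 2005, 2011))
  expect_error(period_definition(c("a", "b"), c(1900, 1930), c(1940, 1950)),
               "overlap")
})

test_that("period means weight segments by year overlap", {
  periods <- default_periods()
  seg <- data.frame(tree_id = "A", start_year = 1969, end_year = 1973,
                    value = 20)
  pm <- period_means(seg, periods)
  expect_equal(pm$n[pm$period == "pollution"], 3) # 1971-1973 of 5 years
  # two segments with overlap weights 2 and 5
  seg2 <- data.frame(tree_id = "A",
                     start_year = c(1969, 1974), end_year = c(1972, 1978),
                     value = c(18, 20))
  pm2 <- period_means(seg2, periods)
  expect_equal(pm2$value[pm2$period == "pollution"], (2 * 18 + 5 * 20) / 7,
               tolerance = 1e-9)
  # annual series fully inside a period reduces to the plain mean
  ann <- data.frame(tree_id = "B", year = 1998:2005, value = 1:8)
  pma <- period_means(ann, periods)
  expect_equal(pma$value[pma$period == "post1"], mean(1:8))
  expect_equal(pma$n[pma$period == "post1"], 8)
})

test_that("balanced noiseless data degenerate to group-mean differences", {
  d <- expand.grid(tree_id = sprintf("T%02d", 1:10),
                   period = factor(c("pre", "pollution"),
                                   levels = c("pre", "pollution")))
  d$value <- ifelse(d$period == "pre", 10, 12)
  suppressWarnings(ct <- fit_period_model(d))
  expect_equal(ct$terms$estimate[ct$terms$term == "intercept"], 10,
               tolerance = 1e-6)
  expect_equal(ct$terms$estimate[ct$terms$term == "pollution"], 2,
               tolerance = 1e-6)
})

test_that("AIC selection drops the period structure under a true null", {
  set.seed(61)
  prefers_null <- replicate(20, {
    d <- sim_period_data(15, effects = c(pre = 0, pollution = 0,
                                         post1 = 0, post2 = 0),
                         tree_sd = 1, resid_sd = 1)
    ct <- suppressWarnings(fit_period_model(d))
    ct$aic_table$fixed[which.min(ct$aic_table$aic)] == "1"
  })
  expect_gt(mean(prefers_null), 0.5)
})

test_that("AIC selection keeps real period effects", {
  set.seed(62)
  d <- sim_period_data(31)
  ct <- fit_period_model(d, response = "d13c")
  expect_equal(ct$aic_table$fixed[which.min(ct$aic_table$aic)], "period")
  est <- ct$terms$estimate
  names(est) <- ct$terms$term
  expect_equal(unname(est["pollution"]), -1.876, tolerance = 0.35)
  expect_equal(unname(est["post1"]), -0.696, tolerance = 0.35)
})

test_that("model predictions are invariant to the reference level", {
  set.seed(63)
  d <- sim_period_data(20)
  ct1 <- fit_period_model(d)
  d2 <- d
  d2$period <- factor(as.character(d2$period),
                      levels = c("pollution", "pre", "post1", "post2"))
  ct2 <- fit_period_model(d2)
  em1 <- tukey_contrasts(ct1$fit)$emmeans
  em2 <- tukey_contrasts(ct2$fit)$emmeans
  expect_equal(em1$emmean[order(as.character(em1$period))],
               em2$emmean[order(as.character(em2$period))],
               tolerance = 1e-6)
})

test_that("Tukey comparisons separate distant groups and merge equal ones", {
  set.seed(64)
  # two indistinguishable, one far-away period
  d <- sim_period_data(20, effects = c(pre = 0, pollution = 0.01,
                                       post1 = 10),
                       tree_sd = 0.5, resid_sd = 1)
  tc <- tukey_contrasts(fit_period_model(d)$fit)
  ltr <- tc$letters
  expect_true(grepl("[a-z]", ltr[["pre"]]))
  expect_equal(ltr[["pre"]], ltr[["pollution"]])
  expect_false(any(strsplit(ltr[["post1"]], "")[[1]] %in%
                     strsplit(ltr[["pre"]], "")[[1]]))
  pp <- tc$contrasts$p.value[grepl("pre - pollution", tc$contrasts$contrast)]
  expect_gt(pp, 0.9)
})

test_that("compact letters are consistent with any p-value matrix", {
  set.seed(65)
  for (rep in 1:25) {
    k <- sample(3:6, 1)
    p <- matrix(1, k, k, dimnames = list(letters[1:k], letters[1:k]))
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      p[i, j] <- p[j, i] <- runif(1)
    ltr <- compact_letters(p, alpha = 0.3)
    share <- function(a, b)
      length(intersect(strsplit(ltr[[a]], "")[[1]],
                       strsplit(ltr[[b]], "")[[1]])) > 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (p[i, j] < 0.3) {
        expect_false(share(letters[i], letters[j]))
      } else {
        expect_true(share(letters[i], letters[j]))
      }
    }
  }
})

test_that("pseudo-R2 recovers known variance components", {
  set.seed(66)
  n_tree <- 400
  d <- expand.grid(tree_id = seq_len(n_tree), obs = 1:4)
  d$x <- rnorm(nrow(d)) # fixed-effect variance ~ 1 with slope 1
  tre <- rnorm(n_tree, 0, sqrt(2))
  d$value <- d$x + tre[d$tree_id] + rnorm(nrow(d), 0, 1)
  fit <- lme4::lmer(value ~ x + (1 | tree_id), data = d, REML = TRUE)
  r2 <- pseudo_r2(fit)
  expect_lt(abs(r2[["r2m"]] - 0.25), 0.03)
  expect_lt(abs(r2[["r2c"]] - 0.75), 0.03)
})

test_that("pseudo-R2 limiting cases: no fixed effects, strong clustering", {
  set.seed(67)
  n_tree <- 200
  d <- expand.grid(tree_id = seq_len(n_tree), obs = 1:4)
  tre <- rnorm(n_tree, 0, 2)
  d$value <- tre[d$tree_id] + rnorm(nrow(d), 0, 1)
  fit <- lme4::lmer(value ~ 1 + (1 | tree_id), data = d, REML = TRUE)
  r2 <- pseudo_r2(fit)
  expect_equal(unname(r2["r2m"]), 0, tolerance = 1e-8)
  expect_equal(unname(r2["r2c"]), 4 / 5, tolerance = 0.05) # the ICC
})

test_that("increment-discrimination model recovers period-specific slopes", {
  set.seed(68)
  n_tree <- 40
  d <- expand.grid(tree_id = sprintf("T%02d", 1:n_tree),
                   period = factor(c("pre", "pollution", "post1"),
                                   levels = c("pre", "pollution", "post1")))
  d$delta13C <- rnorm(nrow(d), 19, 1)
  slope <- c(pre = -5.3, pollution = 0.2, post1 = -6.2)
  tre <- rnorm(n_tree, 0, 3)
  d$increment <- 120 + slope[as.character(d$period)] * d$delta13C +
    tre[match(d$tree_id, unique(d$tree_id))] + rnorm(nrow(d), 0, 2)
  ct <- fit_increment_vs_discrimination(d)
  expect_lt(ct$slopes[["pre"]], -3)
  expect_lt(ct$slopes[["post1"]], -3)
  expect_lt(abs(ct$slopes[["pollution"]]), 1.5)
  # single period degenerates to a random-intercept regression
  ct1 <- fit_increment_vs_discrimination(d[d$period == "pre", ])
  expect_equal(unname(ct1$slopes["pre"]), -5.3, tolerance = 0.5)
})

test_that("null increment-discrimination interactions stay mostly silent", {
  set.seed(69)
  sig <- replicate(30, {
    n_tree <- 25
    d <- expand.grid(tree_id = sprintf("T%02d", 1:n_tree),
                     period = factor(c("pre", "pollution"),
                                     levels = c("pre", "pollution")))
    d$delta13C <- rnorm(nrow(d), 19, 1)
    tre <- rnorm(n_tree, 0, 1)
    d$increment <- 10 + tre[match(d$tree_id, unique(d$tree_id))] +
      rnorm(nrow(d), 0, 1)
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(increment ~ delta13C * period + (1 | tree_id), data = d)))
    tv <- stats::coef(summary(fit))["delta13C:periodpollution", "t value"]
    abs(tv) > 1.96
  })
  expect_lt(mean(sig), 0.2)
})
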