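# The simulated panels use NO2-magnitude truth: category levels around
# 33.5-35.7 ppb in the first year with annual slopes near -1.

nash_int <- c(A = 33.5, B = 35.1, C = 35.3, D = 35.7)
nash_slp <- c(A = -1.01, B = -0.93, C = -0.91, D = -0.90)

test_that("noise-free panels recover intercepts and slopes to 1e-6", {
  sim <- simulate_panel(20, 2000:2016, nash_int[c("A", "D")],
                        nash_slp[c("A", "D")], sigma_u = 0, sigma_e = 0,
                        seed = 1)
  fit <- fit_trend(sim$panel, sim$scores)
  expect_equal(unname(fit$beta["intercept"]), 33.5, tolerance = 1e-6)
  expect_equal(unname(fit$beta["intercept"] + fit$beta["cat_D"]), 35.7,
               tolerance = 1e-6)
  expect_equal(unname(fit$beta["year"]), -1.01, tolerance = 1e-6)
  expect_equal(unname(category_slope(fit, "D")["estimate"]), -0.90,
               tolerance = 1e-6)
  expect_lt(fit$sigma2_u, 1e-10)
})

test_that("balanced-design fixed effects equal the OLS oracle", {
  sim <- simulate_panel(30, 2000:2016, nash_int, nash_slp,
                        sigma_u = 0.5, sigma_e = 0.3, seed = 5)
  fit <- fit_trend(sim$panel, sim$scores)
  d <- merge(sim$panel, sim$scores, by = "tract_id")
  d$category <- factor(d$category, levels = c("A", "B", "C", "D"))
  d$year_c <- d$year - 2000
  ols <- lm(mean ~ category * year_c, data = d)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
  # with sigma2_u > 0, mixed-model SEs dominate the naive OLS SEs for
  # between-tract (level) contrasts
  expect_gt(fit$sigma2_u, 0)
  se_mm <- sqrt(diag(fit$vcov))
  se_ols <- sqrt(diag(vcov(ols)))
  expect_gt(se_mm["intercept"], se_ols["(Intercept)"])
  expect_gt(se_mm["cat_D"], se_ols["categoryD"])
})

test_that("zero between-tract variance is typically estimated at the boundary", {
  # the REML estimate of a zero variance component lands exactly on the
  # boundary whenever the between-tract mean square does not exceed the
  # within-tract one, i.e. on about half of datasets; check the typical
  # behaviour over replicates rather than one draw
  ratios <- vapply(1:20, function(s) {
    sim <- simulate_panel(30, 2000:2008, nash_int, nash_slp,
                          sigma_u = 0, sigma_e = 0.3, seed = 800 + s)
    fit <- fit_trend(sim$panel, sim$scores)
    fit$sigma2_u / fit$sigma2_e
  }, 0)
  expect_gte(sum(ratios < 1e-6), 6)   # a clear boundary cluster
  expect_lt(median(ratios), 5e-3)
  expect_lt(max(ratios), 0.05)        # never materially away from zero
})

test_that("predicted levels and slopes are exact linear combinations", {
  sim <- simulate_panel(10, 2000:2016, nash_int, nash_slp,
                        sigma_u = 0.3, sigma_e = 0.3, seed = 3)
  fit <- fit_trend(sim$panel, sim$scores)

  p0 <- predicted_level(fit, "A", 2000)
  expect_equal(unname(p0["estimate"]), unname(fit$beta["intercept"]))
  expect_equal(unname(p0["se"]), sqrt(fit$vcov["intercept", "intercept"]))

  manual <- fit$beta["intercept"] + fit$beta["cat_D"] +
    (fit$beta["year"] + fit$beta["cat_D:year"]) * 16
  expect_equal(unname(predicted_level(fit, "D", 2016)["estimate"]),
               unname(manual))

  for (cc in c("A", "B", "C", "D")) {
    expect_equal(unname(category_slope(fit, cc)["estimate"]),
                 unname(predicted_level(fit, cc, 2001)["estimate"] -
                        predicted_level(fit, cc, 2000)["estimate"]),
                 tolerance = 1e-10)
  }
  expect_error(predicted_level(fit, "ungraded", 2000), "unknown category")
})

test_that("a synthetic trend table reproduces published-style arithmetic", {
  # coefficients mirror a large-city NO2 fit: D starts 3 ppb above A and
  # declines slightly faster
  sim <- simulate_panel(15, 2000:2016, c(A = 35.0, D = 38.0),
                        c(A = -0.84, D = -0.86), sigma_u = 0, sigma_e = 0,
                        seed = 2)
  fit <- fit_trend(sim$panel, sim$scores)
  expect_equal(unname(predicted_level(fit, "D", 2016)["estimate"]),
               35.0 + 3.0 + (-0.86) * 16, tolerance = 1e-8) # = 24.24
})

test_that("changing the year origin leaves levels and slopes unchanged", {
  sim <- simulate_panel(20, 2000:2016, nash_int, nash_slp,
                        sigma_u = 0.5, sigma_e = 0.3, seed = 11)
  f0 <- fit_trend(sim$panel, sim$scores, year_origin = 2000)
  f8 <- fit_trend(sim$panel, sim$scores, year_origin = 2008)
  expect_false(isTRUE(all.equal(f0$beta["intercept"], f8$beta["intercept"])))
  for (cc in c("A", "C", "D")) {
    expect_equal(predicted_level(f0, cc, 2013), predicted_level(f8, cc, 2013),
                 tolerance = 1e-8)
    expect_equal(category_slope(f0, cc), category_slope(f8, cc),
                 tolerance = 1e-8)
  }
})

test_that("overall tests have power against large separations and reduce at y0", {
  sim <- simulate_panel(50, 2000:2016, nash_int, nash_slp,
                        sigma_u = 0.1, sigma_e = 0.1, seed = 13)
  fit <- fit_trend(sim$panel, sim$scores)
  expect_lt(overall_level_test(fit, 2000)["p"], 1e-6)
  expect_lt(overall_slope_test(fit)["p"], 1e-6)

  # at the origin year the interaction coefficients multiply zero: the test
  # must equal a joint test of the main category effects alone
  idx <- paste0("cat_", c("B", "C", "D"))
  L <- matrix(0, 3, length(fit$beta), dimnames = list(NULL, names(fit$beta)))
  L[cbind(1:3, match(idx, names(fit$beta)))] <- 1
  est <- drop(L %*% fit$beta)
  stat <- drop(t(est) %*% solve(L %*% fit$vcov %*% t(L)) %*% est)
  expect_equal(unname(overall_level_test(fit, 2000)["statistic"]), stat,
               tolerance = 1e-10)
})

test_that("contrast count and Bonferroni divisor track the categories present", {
  sim3 <- simulate_panel(15, 2000:2016, nash_int, nash_slp,
                         sigma_u = 0.3, sigma_e = 0.3, seed = 17)
  fit3 <- fit_trend(sim3$panel, sim3$scores)
  ct3 <- pairwise_contrasts(fit3, "level", year = 2000, gate = FALSE)
  expect_equal(nrow(ct3), 3)
  expect_equal(ct3$bonferroni_alpha, rep(0.05 / 3, 3))

  int5 <- c(nash_int, ungraded = 31.7)
  slp5 <- c(nash_slp, ungraded = -0.82)
  sim5 <- simulate_panel(15, 2000:2016, int5, slp5,
                         sigma_u = 0.3, sigma_e = 0.3, seed = 18)
  fit5 <- fit_trend(sim5$panel, sim5$scores)
  ct5 <- pairwise_contrasts(fit5, "slope", gate = FALSE)
  expect_equal(nrow(ct5), 4)
  expect_equal(ct5$bonferroni_alpha, rep(0.05 / 4, 4))
})

test_that("pairwise contrasts are gated on the overall test", {
  # null panel: no category differences at all
  null_int <- c(A = 35, B = 35, C = 35, D = 35)
  null_slp <- c(A = -0.9, B = -0.9, C = -0.9, D = -0.9)
  sim <- simulate_panel(25, 2000:2016, null_int, null_slp,
                        sigma_u = 0.5, sigma_e = 0.3, seed = 1203)
  fit <- fit_trend(sim$panel, sim$scores)
  ov <- overall_slope_test(fit)
  if (ov["p"] >= 0.05) {
    ct <- pairwise_contrasts(fit, "slope", gate = TRUE)
    expect_true(all(!ct$evaluated))
    expect_true(all(is.na(ct$significant)))
  }
  ct_ungated <- pairwise_contrasts(fit, "slope", gate = FALSE)
  expect_true(all(ct_ungated$evaluated))
})

test_that("the trend table is consistent with the operations it summarises", {
  int5 <- c(nash_int, ungraded = 31.7)
  slp5 <- c(nash_slp, ungraded = -0.82)
  sim <- simulate_panel(20, 2000:2016, int5, slp5,
                        sigma_u = 0.4, sigma_e = 0.3, seed = 23)
  tt <- build_trend_table(sim$panel, sim$scores, years = c(2000, 2008, 2016))
  expect_equal(tt$levels$category, c("D", "C", "B", "ungraded", "A"))
  for (i in seq_len(nrow(tt$levels))) {
    cc <- tt$levels$category[i]
    for (y in c(2000, 2008, 2016)) {
      expect_equal(tt$levels[[paste0("level_", y)]][i],
                   unname(predicted_level(tt$fit, cc, y)["estimate"]))
    }
    expect_equal(tt$levels$slope[i],
                 unname(category_slope(tt$fit, cc)["estimate"]))
  }
  expect_equal(unname(tt$overall_p["slope"]),
               unname(overall_slope_test(tt$fit)["p"]))
  expect_error(build_trend_table(sim$panel, sim$scores, years = 1990),
               "within the panel span")

  # noise-free: every table cell equals the generator truth
  sim0 <- simulate_panel(10, 2000:2016, int5, slp5, sigma_u = 0,
                         sigma_e = 0, seed = 2)
  tt0 <- build_trend_table(sim0$panel, sim0$scores)
  for (i in seq_len(nrow(tt0$levels))) {
    cc <- tt0$levels$category[i]
    for (y in c(2000, 2008, 2016)) {
      expect_equal(tt0$levels[[paste0("level_", y)]][i],
                   unname(int5[cc] + slp5[cc] * (y - 2000)), tolerance = 1e-6)
    }
    expect_equal(tt0$levels$slope[i], unname(slp5[cc]), tolerance = 1e-6)
  }
})

test_that("degenerate designs are rejected with informative errors", {
  sim <- simulate_panel(5, 2000:2005, nash_int[c("A", "D")],
                        nash_slp[c("A", "D")], seed = 4)
  expect_error(fit_trend(sim$panel, sim$scores, reference = "C"),
               "reference")
  one_year <- sim$panel[sim$panel$year == 2000, ]
  expect_error(fit_trend(one_year, sim$scores), "2 distinct years")
  orphan <- sim$panel
  orphan$tract_id[1] <- "nope"
  expect_error(fit_trend(orphan, sim$scores), "category")
})
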