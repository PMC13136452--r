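test_that("tract lattice tiles the extent with exact areas and disjoint cells", {
  t4 <- generate_tracts(2, 2, 1000)
  expect_equal(nrow(t4), 4)
  expect_true(all(t4$land_area == 1e6))
  expect_equal(sum(vapply(t4$geometry, poly_area, 0)), 4e6)

  t1 <- generate_tracts(1, 1, 500)
  expect_equal(poly_as_rect(t1$geometry[[1]]), c(0, 0, 500, 500))

  t3 <- generate_tracts(3, 1, 1000)
  expect_equal(sum(vapply(t3$geometry, poly_area, 0)), 3e6)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(intersection_area(t3$geometry[[i]], t3$geometry[[j]]), 0)
  }
  expect_equal(anyDuplicated(t3$id), 0)
  expect_error(generate_tracts(0, 1, 1000), "nx")
  expect_error(generate_tracts(2, 2, -5), "cell_m")
})

test_that("HOLC map generator hits target coverage and stays non-overlapping", {
  tracts <- generate_tracts(8, 8, 1000)
  total <- 64e6

  full <- generate_holc_map(tracts, list(A = 0.25, B = 0.25, C = 0.25,
                                         D = 0.25, margin = 0), seed = 1)
  expect_equal(sum(vapply(full$geometry, poly_area, 0)) / total, 1,
               tolerance = 1e-6)

  donly <- generate_holc_map(tracts, list(D = 0.5, margin = 0.5), seed = 2)
  expect_true(all(donly$grade == "D"))
  realized <- sum(vapply(donly$geometry, poly_area, 0)) / total
  expect_lt(abs(realized - 0.5), 0.05)

  layout <- list(A = 0.10, B = 0.20, C = 0.25, D = 0.20, margin = 0.25)
  h <- generate_holc_map(tracts, layout, seed = 3)
  areas <- vapply(h$geometry, poly_area, 0)
  for (g in c("A", "B", "C", "D")) {
    expect_lt(abs(sum(areas[h$grade == g]) / total - layout[[g]]), 0.05)
  }
  # pairwise non-overlap (bbox-prefiltered exact intersection)
  rects <- lapply(h$geometry, poly_as_rect)
  for (i in seq_len(nrow(h) - 1)) for (j in (i + 1):nrow(h)) {
    expect_lt(rect_overlap_area(rects[[i]], rects[[j]]), 1e-6)
  }
  expect_error(generate_holc_map(tracts, list(A = 0.6, B = 0.6, margin = 0)),
               "sum")
})

test_that("generators are deterministic under a fixed seed", {
  tracts <- generate_tracts(5, 5, 1000)
  h1 <- generate_holc_map(tracts, seed = 11)
  h2 <- generate_holc_map(tracts, seed = 11)
  expect_identical(h1, h2)
  expect_false(identical(h1, generate_holc_map(tracts, seed = 12)))

  s <- score_city(tracts, h1)
  tr <- synthetic_truth("no2")
  g1 <- generate_pollution_grid(tracts, s, tr, 2000, seed = 5)
  g2 <- generate_pollution_grid(tracts, s, tr, 2000, seed = 5)
  expect_identical(g1, g2)
  expect_false(identical(g1$values$value,
                         generate_pollution_grid(tracts, s, tr, 2000,
                                                 seed = 6)$values$value))
})

test_that("some tracts straddle two grades under the default layout", {
  tracts <- generate_tracts(8, 8, 1000)
  h <- generate_holc_map(tracts, seed = 3)
  s <- score_city(tracts, h)
  n_grades <- rowSums(as.matrix(s[, c("frac_A", "frac_B", "frac_C", "frac_D")]) > 0)
  expect_gt(sum(n_grades >= 2), 0)
})

test_that("pollution surface follows the deterministic trend exactly when noise-free", {
  tracts <- generate_tracts(2, 2, 1000)
  h <- generate_holc_map(tracts, list(D = 1, margin = 0), seed = 1)
  s <- score_city(tracts, h)
  tr <- truth_flat(35.0, -0.84)
  g <- generate_pollution_grid(tracts, s, tr, 2000:2002, seed = 1)
  yr <- as.integer(format(g$values$date, "%Y"))
  expect_equal(g$values$value, 35.0 - 0.84 * (yr - 2000), tolerance = 1e-12)
  expect_error(generate_pollution_grid(tracts, s, tr, integer(0)), "non-empty")
})

test_that("a full year of pure seasonality averages out", {
  tracts <- generate_tracts(1, 1, 1000)
  h <- generate_holc_map(tracts, list(A = 1, margin = 0), seed = 1)
  s <- score_city(tracts, h)
  tr <- synthetic_truth("no2",
                        category_intercepts = c(A = 35, B = 35, C = 35,
                                                D = 35, ungraded = 35),
                        category_slopes = c(A = 0, B = 0, C = 0, D = 0,
                                            ungraded = 0),
                        seasonal_amplitude = 3, noise_sd = 0, tract_re_sd = 0)
  g <- generate_pollution_grid(tracts, s, tr, 2001, seed = 1) # 365-day year
  # independent oracle: numeric mean of the sinusoid over the 365 days
  oracle <- 35 + mean(3 * sin(2 * pi * (1:365) / 365))
  expect_equal(mean(g$values$value), oracle, tolerance = 1e-12)
  expect_lt(abs(mean(g$values$value) - 35), 0.02)
})

test_that("aberrant injection shifts the city mean by delta times cell fraction", {
  tracts <- generate_tracts(4, 4, 1000)
  h <- generate_holc_map(tracts, list(C = 1, margin = 0), seed = 1)
  s <- score_city(tracts, h)
  g <- generate_pollution_grid(tracts, s, truth_flat(30, 0), 2000:2003, seed = 1)
  win <- as.Date(c("2002-01-01", "2003-12-31"))
  gi <- inject_aberrant_values(g, win, delta = -15, frac_cells = 0.5, seed = 9)

  in_win <- g$values$date >= win[1] & g$values$date <= win[2]
  drop_obs <- mean(g$values$value[in_win]) - mean(gi$values$value[in_win])
  expect_equal(drop_obs, 7.5, tolerance = 1e-9) # exactly delta * frac on a flat field
  expect_equal(nrow(gi$injected), sum(in_win) / 2)

  g0 <- inject_aberrant_values(g, win, delta = 0, frac_cells = 0.5, seed = 9)
  expect_equal(g0$values$value, g$values$value)
  expect_error(inject_aberrant_values(g, as.Date(c("2010-01-01", "2010-12-31")),
                                      -15, 0.5), "outside")
})

test_that("census generator honours truth distributions, clamps SVI, and injects missingness", {
  scores <- data.frame(tract_id = sprintf("t%03d", 1:500),
                       category = rep(c("A", "B", "C", "D", "ungraded"), 100))
  tr <- synthetic_truth("no2")

  tr0 <- tr
  tr0$census_effects$sd <- 0
  tr0$svi_effects$sd <- 0
  tab0 <- generate_census_tables(scores, tr0, seed = 4)
  m <- merge(tab0$census,
             tr0$census_effects[, c("variable", "period", "category", "mean")],
             by.x = c("variable", "period"), by.y = c("variable", "period"))
  m <- m[m$category == scores$category[match(m$tract_id, scores$tract_id)], ]
  expect_equal(m$value, m$mean, tolerance = 1e-12)

  tab <- generate_census_tables(scores, tr, seed = 4)
  expect_true(all(tab$svi$svi >= 0 & tab$svi$svi <= 1))

  tabm <- generate_census_tables(scores, tr, seed = 4, missing_rate = 0.10)
  realized <- mean(is.na(tabm$census$value))
  expect_lt(abs(realized - 0.10), 0.03)
})
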