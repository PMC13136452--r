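# Fixtures built in code: small cities and analytic oracles.

# Noise-free truth: deterministic pollution surface.
truth_noise_free <- function(pollutant = "no2", intercepts = NULL,
                             slopes = NULL) {
  synthetic_truth(pollutant,
                  category_intercepts = intercepts,
                  category_slopes = slopes,
                  seasonal_amplitude = 0, noise_sd = 0, tract_re_sd = 0)
}

# Flat truth: every category shares one intercept/slope (useful for exact
# aggregation identities regardless of which tract dominates a cell).
truth_flat <- function(intercept = 35.0, slope = -0.84) {
  lv <- c(A = intercept, B = intercept, C = intercept, D = intercept,
          ungraded = intercept)
  sl <- c(A = slope, B = slope, C = slope, D = slope, ungraded = slope)
  truth_noise_free(intercepts = lv, slopes = sl)
}

# A 1 x n row lattice whose graded rectangles cover both ends and leave
# exactly n_ungraded tracts uncovered in the middle; the hull of the graded
# areas still spans every tract, so all n tracts are selected.
row_city_with_ungraded <- function(n, n_ungraded, cell_m = 1000) {
  stopifnot(n_ungraded < n - 1)
  tracts <- generate_tracts(n, 1, cell_m)
  n_left <- ceiling((n - n_ungraded) / 2)
  n_right <- (n - n_ungraded) - n_left
  graded <- data.frame(id = c("A_001", "D_001"), grade = c("A", "D"),
                       numeric_grade = c(1L, 4L))
  graded$geometry <- list(
    rect_poly(0, 0, n_left * cell_m, cell_m),
    rect_poly((n - n_right) * cell_m, 0, n * cell_m, cell_m))
  class(graded) <- c("graded_area_set", "data.frame")
  list(tracts = tracts, graded = graded)
}

# Independent oracle: intersection area of two axis-aligned rectangles given
# as c(x0, y0, x1, y1).
rect_overlap_area <- function(a, b) {
  max(0, min(a[3], b[3]) - max(a[1], b[1])) *
    max(0, min(a[4], b[4]) - max(a[2], b[2]))
}

poly_as_rect <- function(p) {
  c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))
}
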