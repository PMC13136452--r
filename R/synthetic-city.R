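# Synthetic-city generator: a tract lattice, non-overlapping HOLC-graded
# rectangles, a daily pollution grid with category-linked levels and trends,
# and census/SVI tables whose variables co-vary with the redlining category.
# Every generator is deterministic given (inputs, seed); a master seed derives
# independent per-component substreams.

GRADES <- c("A", "B", "C", "D")
CATEGORIES <- c("A", "B", "C", "D", "ungraded")

# Deterministic substream seed from a master seed and a component label.
# Polynomial rolling hash so that similar labels ("rep1", "rep2", ...) map to
# well-separated substreams.
derive_seed <- function(seed, component) {
  h <- 0
  for (c in utf8ToInt(component)) h <- (h * 131 + c) %% 1000003
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h * 2654435761) %%
               2147483647)
}

#' Ground-truth parameters for a synthetic city
#'
#' Bundles every parameter the generators draw from: pollutant levels at the
#' first study year and their annual trends per redlining category, within-year
#' seasonality, daily noise, the tract-level random-intercept SD, the spatial
#' grade layout, and the census/SVI distributions per category and period.
#' Defaults are sized to a large US city: NO2 around 32-38 ppb in 2000
#' declining roughly 1 ppb/yr, PM2.5 around 16 ug/m3 declining 0.5 ug/m3/yr,
#' with steeper redlining gradients in NO2 than PM2.5.
#'
#' @param pollutant "no2" (ppb) or "pm25" (ug/m3); selects default levels.
#' @param category_intercepts Named vector (A, B, C, D, ungraded): pollutant
#'   level at the first study year.
#' @param category_slopes Named vector: annual change, units/yr.
#' @param seasonal_amplitude Amplitude of the annual sinusoid (pollutant units).
#' @param noise_sd Daily residual SD (pollutant units); must be >= 0.
#' @param tract_re_sd SD of the tract-level random intercept; must be >= 0.
#' @param grade_layout Named list of target area fractions for grades A-D plus
#'   `margin`, the deliberately ungraded fraction; fractions must sum to 1.
#' @param census_effects Data frame (variable, period, category, mean, sd)
#'   giving the per-category census distributions; see
#'   [default_census_effects()].
#' @param svi_effects Data frame (period, category, mean, sd) for the Social
#'   Vulnerability Index, on the 0-1 scale.
#' @return An object of class `synthetic_truth` (a list of the above).
#' @export
synthetic_truth <- function(pollutant = c("no2", "pm25"),
                            category_intercepts = NULL,
                            category_slopes = NULL,
                            seasonal_amplitude = NULL,
                            noise_sd = 1.5,
                            tract_re_sd = 0.5,
                            grade_layout = NULL,
                            census_effects = NULL,
                            svi_effects = NULL) {
  pollutant <- match.arg(pollutant)
  if (is.null(category_intercepts)) {
    category_intercepts <- switch(pollutant,
      no2  = c(A = 33.5, B = 35.1, C = 35.3, D = 35.7, ungraded = 31.7),
      pm25 = c(A = 15.7, B = 15.6, C = 15.8, D = 16.2, ungraded = 15.8))
  }
  if (is.null(category_slopes)) {
    category_slopes <- switch(pollutant,
      no2  = c(A = -1.01, B = -0.93, C = -0.91, D = -0.90, ungraded = -0.82),
      pm25 = c(A = -0.48, B = -0.47, C = -0.49, D = -0.50, ungraded = -0.48))
  }
  if (is.null(seasonal_amplitude)) {
    seasonal_amplitude <- switch(pollutant, no2 = 3, pm25 = 2)
  }
  if (is.null(grade_layout)) {
    grade_layout <- list(A = 0.10, B = 0.20, C = 0.25, D = 0.20, margin = 0.25)
  }
  if (is.null(census_effects)) census_effects <- default_census_effects()
  if (is.null(svi_effects)) svi_effects <- default_svi_effects()
  stopifnot(noise_sd >= 0, tract_re_sd >= 0, seasonal_amplitude >= 0)
  stopifnot(all(CATEGORIES %in% names(category_intercepts)),
            all(CATEGORIES %in% names(category_slopes)))
  fr <- vapply(GRADES, function(g) grade_layout[[g]] %||% 0, 0)
  if (any(is.na(fr)) || any(fr < 0) || any(fr > 1)) {
    stop("grade_layout fractions must lie in [0, 1] for all of A, B, C, D")
  }
  if (sum(fr) > 1 + 1e-9) stop("grade coverage fractions must sum to <= 1")
  structure(
    list(pollutant = pollutant,
         category_intercepts = category_intercepts[CATEGORIES],
         category_slopes = category_slopes[CATEGORIES],
         seasonal_amplitude = seasonal_amplitude,
         noise_sd = noise_sd,
         tract_re_sd = tract_re_sd,
         grade_layout = grade_layout,
         census_effects = census_effects,
         svi_effects = svi_effects),
    class = "synthetic_truth")
}

#' Default per-category census distributions for the generator
#'
#' Means per redlining category and period (early = decennial census, late =
#' a five-year survey window ~16 years on) for the ten tract variables the
#' demographic summary covers, with SDs set to a fixed fraction of each mean.
#' Magnitudes follow the familiar redlining gradients of large US cities:
#' income, home value and college attainment highest in A tracts and lowest in
#' D tracts, with the reverse gradient for poverty and percent Black.
#'
#' @param sd_frac SD of each tract draw as a fraction of the category mean.
#' @return Data frame with columns variable, period, category, mean, sd.
#' @export
default_census_effects <- function(sd_frac = 0.15) {
  m <- function(ung, A, B, C, D) c(A = A, B = B, C = C, D = D, ungraded = ung)
  early <- list(
    total_population  = m(4848, 4458, 4290, 4636, 4176),
    pop_density       = m(4608, 4674, 9113, 15893, 27436),
    pct_white         = m(86.6, 85.0, 81.5, 70.1, 55.3),
    pct_black         = m(3.7, 3.9, 5.6, 15.4, 22.1),
    pct_hispanic      = m(3.9, 4.8, 6.1, 8.2, 17.0),
    median_income     = m(82775, 94054, 85507, 69640, 52459),
    pct_poverty       = m(6.1, 5.2, 6.6, 8.6, 16.1),
    median_home_value = m(334085, 419508, 431935, 342542, 296578),
    median_gross_rent = m(1296, 1338, 1300, 1239, 1050),
    pct_bachelors     = m(22.6, 24.6, 23.0, 22.2, 17.4))
  late <- list(
    total_population  = m(4776, 4540, 4448, 4523, 4240),
    pop_density       = m(4641, 6613, 11012, 20042, 30622),
    pct_white         = m(79.8, 74.5, 71.5, 63.4, 54.6),
    pct_black         = m(4.6, 6.7, 8.0, 16.3, 21.6),
    pct_hispanic      = m(8.0, 9.1, 12.0, 13.9, 22.0),
    median_income     = m(87525, 104553, 94626, 78482, 62484),
    pct_poverty       = m(10.0, 11.3, 9.5, 11.9, 17.1),
    median_home_value = m(447206, 599081, 605976, 516863, 490727),
    median_gross_rent = m(1608, 1661, 1536, 1550, 1340),
    pct_bachelors     = m(29.6, 29.2, 26.8, 26.9, 25.2))
  rows <- lapply(names(early), function(v) {
    rbind(
      data.frame(variable = v, period = "early", category = CATEGORIES,
                 mean = unname(early[[v]][CATEGORIES]),
                 sd = unname(early[[v]][CATEGORIES]) * sd_frac),
      data.frame(variable = v, period = "late", category = CATEGORIES,
                 mean = unname(late[[v]][CATEGORIES]),
                 sd = unname(late[[v]][CATEGORIES]) * sd_frac))
  })
  do.call(rbind, rows)
}

#' Default per-category SVI distributions for the generator
#'
#' Social Vulnerability Index means/SDs by category and period on the 0-1
#' percentile scale, with D-category vulnerability roughly twice that of A.
#'
#' @return Data frame with columns period, category, mean, sd.
#' @export
default_svi_effects <- function() {
  rbind(
    data.frame(period = "early", category = CATEGORIES,
               mean = c(0.332, 0.357, 0.481, 0.664, 0.328),
               sd = c(0.234, 0.254, 0.273, 0.249, 0.232)),
    data.frame(period = "late", category = CATEGORIES,
               mean = c(0.348, 0.355, 0.445, 0.598, 0.314),
               sd = c(0.219, 0.268, 0.268, 0.286, 0.174)))
}

#' Generate a square-lattice tract set
#'
#' Tiles the rectangle `[0, nx * cell_m] x [0, ny * cell_m]` with `nx * ny`
#' square census tracts of side `cell_m`; `land_area` equals the polygon area
#' (the synthetic city has no water).
#'
#' @param nx,ny Number of tracts along x and y (>= 1).
#' @param cell_m Tract side length in metres (> 0).
#' @param seed Unused (generation is deterministic); kept so every generator
#'   shares the same signature.
#' @return A `tract_set`: data frame with columns id, land_area and a
#'   list-column geometry of polygon matrices.
#' @export
generate_tracts <- function(nx, ny, cell_m = 1000, seed = 1L) {
  if (nx < 1 || ny < 1 || cell_m <= 0) {
    stop("nx and ny must be >= 1 and cell_m > 0")
  }
  ij <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  geom <- lapply(seq_len(nrow(ij)), function(k) {
    rect_poly(ij$ix[k] * cell_m, ij$iy[k] * cell_m,
              (ij$ix[k] + 1) * cell_m, (ij$iy[k] + 1) * cell_m)
  })
  out <- data.frame(id = sprintf("tract_%04d", seq_len(nrow(ij))),
                    land_area = rep(cell_m^2, nrow(ij)))
  out$geometry <- geom
  class(out) <- c("tract_set", "data.frame")
  out
}

#' @export
print.tract_set <- function(x, ...) {
  cat(sprintf("<tract_set> %d tracts, total land area %.4g km2\n",
              nrow(x), sum(x$land_area) / 1e6))
  invisible(x)
}

#' Generate a non-overlapping HOLC grade map over a tract lattice
#'
#' Works on a half-tract lattice so that graded rectangles can split tracts.
#' A seeded random subset of half-cells is left ungraded (the `margin`), and
#' the remaining half-cells are assigned to grades A-D in contiguous serpentine
#' runs sized to the target fractions; runs are merged into axis-aligned
#' rectangles, one polygon per run. Realized per-grade area fractions equal the
#' targets up to half-cell rounding.
#'
#' @param tracts A `tract_set` from [generate_tracts()] (must be a full
#'   lattice).
#' @param layout Named list of target fractions for A, B, C, D and `margin`
#'   (must sum to 1; grades alone must not exceed 1).
#' @param seed Integer master seed.
#' @return A `graded_area_set`: data frame with id, grade, numeric_grade and a
#'   geometry list-column of rectangles.
#' @export
generate_holc_map <- function(tracts, layout = list(A = 0.10, B = 0.20,
                                                    C = 0.25, D = 0.20,
                                                    margin = 0.25),
                              seed = 1L) {
  fr <- vapply(GRADES, function(g) layout[[g]] %||% 0, 0)
  if (any(fr < 0)) stop("grade fractions must be non-negative")
  if (sum(fr) > 1 + 1e-9) stop("requested grade coverage fractions sum to > 1")
  margin <- if (is.null(layout$margin)) 1 - sum(fr) else layout$margin
  if (abs(sum(fr) + margin - 1) > 1e-6) {
    stop("grade fractions plus margin must sum to 1")
  }
  bb <- poly_bbox(do.call(rbind, tracts$geometry))
  cell_m <- sqrt(tracts$land_area[1])
  half <- cell_m / 2
  hx <- round((bb["xmax"] - bb["xmin"]) / half)
  hy <- round((bb["ymax"] - bb["ymin"]) / half)
  total <- hx * hy
  counts <- round(fr * total)
  # rounding may oversubscribe; trim the largest grades first
  while (sum(counts) > total) counts[which.max(counts)] <- counts[which.max(counts)] - 1L

  cells <- expand.grid(ix = seq_len(hx) - 1L, iy = seq_len(hy) - 1L)
  n_margin <- total - sum(counts)
  rng <- local({
    set.seed(derive_seed(seed, "holc_margin"))
    sample.int(total, n_margin)
  })
  graded_idx <- setdiff(seq_len(total), rng)
  # serpentine order keeps each grade spatially contiguous, as on HOLC maps
  ord <- order(cells$iy, ifelse(cells$iy %% 2 == 0, cells$ix, -cells$ix))
  ord <- ord[ord %in% graded_idx]
  grade_of <- rep(NA_character_, total)
  pos <- 0L
  for (g in GRADES) {
    if (counts[g] > 0) {
      grade_of[ord[(pos + 1):(pos + counts[g])]] <- g
      pos <- pos + counts[g]
    }
  }
  # merge consecutive same-grade half-cells within each row into rectangles
  feats <- list()
  for (g in GRADES) {
    sel <- which(grade_of == g)
    if (!length(sel)) next
    gc <- cells[sel, ]
    for (iy in sort(unique(gc$iy))) {
      xs <- sort(gc$ix[gc$iy == iy])
      runs <- split(xs, cumsum(c(1, diff(xs) != 1)))
      for (r in runs) {
        feats[[length(feats) + 1L]] <- list(
          grade = g,
          poly = rect_poly(bb["xmin"] + min(r) * half, bb["ymin"] + iy * half,
                           bb["xmin"] + (max(r) + 1) * half,
                           bb["ymin"] + (iy + 1) * half))
      }
    }
  }
  if (!length(feats)) stop("layout produced no graded area")
  grade <- vapply(feats, `[[`, "", "grade")
  out <- data.frame(
    id = sprintf("%s_%03d", grade, stats::ave(seq_along(grade), grade,
                                              FUN = seq_along)),
    grade = grade,
    numeric_grade = match(grade, GRADES))
  out$geometry <- lapply(feats, `[[`, "poly")
  class(out) <- c("graded_area_set", "data.frame")
  out
}

#' @export
print.graded_area_set <- function(x, ...) {
  a <- vapply(x$geometry, poly_area, 0)
  cat(sprintf("<graded_area_set> %d polygons; area by grade (km2): %s\n",
              nrow(x),
              paste(sprintf("%s=%.3g", GRADES,
                            vapply(GRADES, function(g) sum(a[x$grade == g]) / 1e6, 0)),
                    collapse = " ")))
  invisible(x)
}

#' Generate a daily pollution grid over a synthetic city
#'
#' Each grid cell inherits the redlining category of its dominant tract (the
#' tract with the largest overlap). The daily value for a cell on day t of
#' year y is
#' `intercept(category) + slope(category) * (y - y0) +
#'  seasonal_amplitude * sin(2 * pi * doy / 365) + u(tract) + N(0, noise_sd)`,
#' with y0 the first requested year and u a tract-level random intercept.
#'
#' @param tracts A `tract_set`.
#' @param scores A score table (or any data frame with tract_id and category).
#' @param truth A [synthetic_truth()] object.
#' @param years Integer vector of calendar years (non-empty).
#' @param cell_m Grid cell side in metres (nominally 1000).
#' @param extent Optional c(xmin, ymin, xmax, ymax); defaults to the tract
#'   bounding box. A smaller extent creates deliberate coverage shortfall.
#' @param seed Integer master seed.
#' @return A `pollution_grid`: list with `cells` (cell_id, x0, y0, size_m,
#'   dominant_tract, category), `values` (cell_id, date, value), `pollutant`,
#'   and `span`.
#' @export
generate_pollution_grid <- function(tracts, scores, truth, years,
                                    cell_m = 1000, extent = NULL, seed = 1L) {
  if (length(years) == 0) stop("year range must be non-empty")
  years <- sort(unique(as.integer(years)))
  if (is.null(extent)) {
    bb <- poly_bbox(do.call(rbind, tracts$geometry))
    extent <- c(bb["xmin"], bb["ymin"], bb["xmax"], bb["ymax"])
  }
  nxc <- max(1L, ceiling((extent[3] - extent[1]) / cell_m - 1e-9))
  nyc <- max(1L, ceiling((extent[4] - extent[2]) / cell_m - 1e-9))
  ij <- expand.grid(ix = seq_len(nxc) - 1L, iy = seq_len(nyc) - 1L)
  cells <- data.frame(cell_id = sprintf("g%04d", seq_len(nrow(ij))),
                      x0 = extent[1] + ij$ix * cell_m,
                      y0 = extent[2] + ij$iy * cell_m,
                      size_m = cell_m)
  tract_bb <- lapply(tracts$geometry, poly_bbox)
  cat_of <- stats::setNames(as.character(scores$category), scores$tract_id)
  dom <- character(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    cp <- rect_poly(cells$x0[k], cells$y0[k],
                    cells$x0[k] + cell_m, cells$y0[k] + cell_m)
    cb <- poly_bbox(cp)
    best <- NA_character_; best_a <- 0
    for (t in seq_len(nrow(tracts))) {
      if (bbox_disjoint(cb, tract_bb[[t]])) next
      a <- intersection_area(cp, tracts$geometry[[t]])
      if (a > best_a) { best_a <- a; best <- tracts$id[t] }
    }
    dom[k] <- best
  }
  cells$dominant_tract <- dom
  cells$category <- ifelse(is.na(dom), "ungraded", unname(cat_of[dom]))
  cells$category[is.na(cells$category)] <- "ungraded"

  set.seed(derive_seed(seed, "tract_re"))
  re <- stats::setNames(stats::rnorm(nrow(tracts), 0, truth$tract_re_sd),
                        tracts$id)
  cell_re <- ifelse(is.na(cells$dominant_tract), 0, re[cells$dominant_tract])

  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  dates <- dates[as.integer(format(dates, "%Y")) %in% years]
  yr <- as.integer(format(dates, "%Y"))
  doy <- as.integer(format(dates, "%j"))
  y0 <- min(years)
  season <- truth$seasonal_amplitude * sin(2 * pi * doy / 365)

  nc <- nrow(cells); nd <- length(dates)
  ic <- truth$category_intercepts[cells$category]
  sl <- truth$category_slopes[cells$category]
  # cell-major blocks: all dates for cell 1, then cell 2, ...
  base <- rep(ic + cell_re, each = nd) + rep(sl, each = nd) * rep(yr - y0, nc) +
    rep(season, nc)
  set.seed(derive_seed(seed, "daily_noise"))
  noise <- if (truth$noise_sd > 0) stats::rnorm(nc * nd, 0, truth$noise_sd) else 0
  values <- data.frame(cell_id = rep(cells$cell_id, each = nd),
                       date = rep(dates, nc),
                       value = base + noise)
  structure(list(cells = cells, values = values,
                 pollutant = truth$pollutant, span = range(dates)),
            class = "pollution_grid")
}

#' @export
print.pollution_grid <- function(x, ...) {
  cat(sprintf("<pollution_grid> %s: %d cells x %d days (%s to %s)\n",
              x$pollutant, nrow(x$cells),
              length(unique(x$values$date)), x$span[1], x$span[2]))
  invisible(x)
}

#' Inject a sustained aberrant offset into a pollution grid
#'
#' Adds `delta` to the daily values of a seeded random subset of cells within a
#' date window, emulating the sustained clusters of implausibly low values that
#' real exposure surfaces can carry. The injected cell-day mask is recorded in
#' the `injected` element so screening recovery can be verified.
#'
#' @param grid A `pollution_grid`.
#' @param window Length-2 Date vector (start, end), within the grid span.
#' @param delta Offset added to affected values (negative for a dip).
#' @param frac_cells Fraction of cells affected, in (0, 1].
#' @param seed Integer seed for the cell subset.
#' @return A modified copy of `grid` with an `injected` data frame
#'   (cell_id, date).
#' @export
inject_aberrant_values <- function(grid, window, delta, frac_cells = 0.5,
                                   seed = 1L) {
  window <- as.Date(window)
  if (length(window) != 2 || is.na(window[1]) || window[2] < window[1]) {
    stop("window must be a non-empty (start, end) date range")
  }
  if (window[1] > grid$span[2] || window[2] < grid$span[1]) {
    stop("window lies outside the grid's date span")
  }
  if (frac_cells <= 0 || frac_cells > 1) stop("frac_cells must be in (0, 1]")
  set.seed(derive_seed(seed, "aberrant_cells"))
  n_aff <- max(1L, round(frac_cells * nrow(grid$cells)))
  aff <- sort(sample(grid$cells$cell_id, n_aff))
  hit <- grid$values$cell_id %in% aff &
    grid$values$date >= window[1] & grid$values$date <= window[2]
  grid$values$value[hit] <- grid$values$value[hit] + delta
  grid$injected <- grid$values[hit, c("cell_id", "date")]
  rownames(grid$injected) <- NULL
  grid
}

#' Generate census and SVI tables tied to redlining categories
#'
#' Draws each tract's value for every census variable and period from the
#' category-specific normal distribution in `truth$census_effects`, clamping
#' percentages to \code{[0, 100]} and monetary/population values to be
#' positive; SVI draws are clamped to \code{[0, 1]}. Optionally blanks a
#' random fraction of census values to emulate survey missingness.
#'
#' @param scores Score table (or data frame with tract_id, category).
#' @param truth A [synthetic_truth()] object.
#' @param seed Integer master seed.
#' @param missing_rate Fraction of census values set missing, in \code{[0, 1)}.
#' @return List with `census` (tract_id, period, variable, value) and `svi`
#'   (tract_id, period, svi).
#' @export
generate_census_tables <- function(scores, truth, seed = 1L,
                                   missing_rate = 0) {
  if (nrow(scores) == 0) stop("scores must be non-empty")
  stopifnot(missing_rate >= 0, missing_rate < 1)
  eff <- truth$census_effects
  cat_of <- as.character(scores$category)
  grid <- expand.grid(tract_i = seq_len(nrow(scores)),
                      period = c("early", "late"),
                      variable = unique(eff$variable),
                      stringsAsFactors = FALSE)
  key <- paste(eff$variable, eff$period, eff$category)
  mu <- stats::setNames(eff$mean, key)
  sg <- stats::setNames(eff$sd, key)
  gkey <- paste(grid$variable, grid$period, cat_of[grid$tract_i])
  set.seed(derive_seed(seed, "census_draw"))
  val <- stats::rnorm(nrow(grid), mu[gkey], sg[gkey])
  pctvar <- startsWith(grid$variable, "pct_")
  val[pctvar] <- pmin(pmax(val[pctvar], 0), 100)
  val[!pctvar] <- pmax(val[!pctvar], 1)
  if (missing_rate > 0) {
    set.seed(derive_seed(seed, "census_missing"))
    val[stats::runif(length(val)) < missing_rate] <- NA_real_
  }
  census <- data.frame(tract_id = scores$tract_id[grid$tract_i],
                       period = grid$period, variable = grid$variable,
                       value = val)

  sv <- truth$svi_effects
  sgrid <- expand.grid(tract_i = seq_len(nrow(scores)),
                       period = c("early", "late"), stringsAsFactors = FALSE)
  skey <- paste(sv$period, sv$category)
  smu <- stats::setNames(sv$mean, skey)
  ssg <- stats::setNames(sv$sd, skey)
  sk <- paste(sgrid$period, cat_of[sgrid$tract_i])
  set.seed(derive_seed(seed, "svi_draw"))
  svi_val <- pmin(pmax(stats::rnorm(nrow(sgrid), smu[sk], ssg[sk]), 0), 1)
  svi <- data.frame(tract_id = scores$tract_id[sgrid$tract_i],
                    period = sgrid$period, svi = svi_val)
  list(census = census, svi = svi)
}

#' Simulate a complete synthetic city
#'
#' Chains every generator: tract lattice, HOLC map, redlining scores, daily
#' pollution grid, and census/SVI tables, all under one master seed.
#'
#' @param nx,ny Tract lattice dimensions.
#' @param cell_m Tract side in metres.
#' @param grid_cell_m Pollution grid cell side in metres.
#' @param years Calendar years of daily pollution.
#' @param pollutant "no2" or "pm25".
#' @param truth A [synthetic_truth()]; defaults to the pollutant's defaults.
#' @param layout Grade layout; defaults to `truth$grade_layout`.
#' @param seed Integer master seed.
#' @param missing_rate Census missingness rate.
#' @return A `synthetic_city` list: tracts, graded_areas, scores, pollution,
#'   census, svi, truth, seed.
#' @export
simulate_city <- function(nx = 10, ny = 10, cell_m = 1000,
                          grid_cell_m = 1000, years = 2000:2016,
                          pollutant = c("no2", "pm25"), truth = NULL,
                          layout = NULL, seed = 1L, missing_rate = 0) {
  pollutant <- match.arg(pollutant)
  if (is.null(truth)) truth <- synthetic_truth(pollutant)
  if (is.null(layout)) layout <- truth$grade_layout
  tracts <- generate_tracts(nx, ny, cell_m, seed)
  graded <- generate_holc_map(tracts, layout, seed)
  scores <- score_city(tracts, graded)
  grid <- generate_pollution_grid(tracts, scores, truth, years,
                                  cell_m = grid_cell_m, seed = seed)
  tabs <- generate_census_tables(scores, truth, seed, missing_rate)
  structure(list(tracts = tracts, graded_areas = graded, scores = scores,
                 pollution = grid, census = tabs$census, svi = tabs$svi,
                 truth = truth, seed = seed),
            class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat(sprintf("<synthetic_city> %d tracts, %d graded polygons, %s grid (%d cells), seed %d\n",
              nrow(x$tracts), nrow(x$graded_areas), x$pollution$pollutant,
              nrow(x$pollution$cells), x$seed))
  print(attr(x$scores, "summary"))
  invisible(x)
}

#' Simulate an annual exposure panel directly (no geometry)
#'
#' Draws tract-year annual means straight from the trend model the package
#' fits: `mean = intercept(category) + slope(category) * (year - min(year)) +
#' u(tract) + N(0, sigma_e)`. This is the workhorse for the simulation studies
#' of the mixed model (parameter recovery, CI coverage, type-I error), where
#' daily-scale simulation would add nothing but runtime.
#'
#' @param n_per_category Tracts per category.
#' @param years Calendar years.
#' @param intercepts,slopes Named vectors over the categories to simulate.
#' @param sigma_u Tract random-intercept SD.
#' @param sigma_e Annual residual SD.
#' @param pollutant Label stored in the panel.
#' @param seed Integer seed.
#' @return List with `panel` (exposure_panel), `scores` (tract_id, category).
#' @export
simulate_panel <- function(n_per_category = 100, years = 2000:2016,
                           intercepts = c(A = 33.5, B = 35.1, C = 35.3,
                                          D = 35.7),
                           slopes = c(A = -1.01, B = -0.93, C = -0.91,
                                      D = -0.90),
                           sigma_u = 0.5, sigma_e = 0.3,
                           pollutant = "no2", seed = 1L) {
  stopifnot(identical(sort(names(intercepts)), sort(names(slopes))),
            sigma_u >= 0, sigma_e >= 0)
  cats <- names(intercepts)
  n_tr <- n_per_category * length(cats)
  scores <- data.frame(
    tract_id = sprintf("tract_%04d", seq_len(n_tr)),
    category = rep(cats, each = n_per_category))
  set.seed(derive_seed(seed, "panel"))
  u <- stats::rnorm(n_tr, 0, sigma_u)
  panel <- expand.grid(tract_i = seq_len(n_tr), year = sort(years))
  mean_val <- intercepts[scores$category[panel$tract_i]] +
    slopes[scores$category[panel$tract_i]] * (panel$year - min(years)) +
    u[panel$tract_i] +
    if (sigma_e > 0) stats::rnorm(nrow(panel), 0, sigma_e) else 0
  panel <- data.frame(tract_id = scores$tract_id[panel$tract_i],
                      year = panel$year, pollutant = pollutant,
                      mean = unname(mean_val),
                      n_days = ifelse(panel$year %% 4 == 0, 366L, 365L))
  class(panel) <- c("exposure_panel", "data.frame")
  list(panel = panel, scores = scores)
}
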