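# Grid-to-tract exposure aggregation: area-proportional weights, aberrant-
# value screening, daily tract values, and tract-year annual means.

cell_polygon <- function(cells, k) {
  rect_poly(cells$x0[k], cells$y0[k],
            cells$x0[k] + cells$size_m[k], cells$y0[k] + cells$size_m[k])
}

#' Area-proportional weights of grid cells over a tract
#'
#' For every grid cell overlapping the tract, the weight is the intersection
#' area divided by the tract area (geometry area by default, mirroring the
#' exposure-weighting convention; land area is used for redlining fractions).
#' The raw weights sum to the covered fraction of the tract; when coverage is
#' below 1 they are optionally renormalized to sum to 1.
#'
#' @param tract One-row `tract_set`.
#' @param grid A `pollution_grid`.
#' @param renormalize Renormalize weights to sum to 1 when coverage < 1.
#' @param min_coverage Minimum covered fraction below which the tract is
#'   flagged (its daily values will be treated as missing downstream).
#' @param denominator "geometry" (polygon area) or "land_area".
#' @return List with tract_id, `entries` (named weights), `coverage`, and
#'   `low_coverage` flag.
#' @export
compute_area_weights <- function(tract, grid, renormalize = TRUE,
                                 min_coverage = 0.8,
                                 denominator = c("geometry", "land_area")) {
  denominator <- match.arg(denominator)
  geom <- if (is.list(tract$geometry) && !is.matrix(tract$geometry)) {
    tract$geometry[[1]]
  } else {
    tract$geometry
  }
  denom <- if (denominator == "land_area") tract$land_area[1] else poly_area(geom)
  if (!is.finite(denom) || denom <= 0) stop("tract has zero area")
  tb <- poly_bbox(geom)
  cells <- grid$cells
  w <- numeric(0)
  for (k in seq_len(nrow(cells))) {
    cp <- cell_polygon(cells, k)
    if (bbox_disjoint(tb, poly_bbox(cp))) next
    a <- intersection_area(geom, cp)
    if (a > 0) w[cells$cell_id[k]] <- a / denom
  }
  coverage <- sum(w)
  low <- coverage < min_coverage
  if (low) {
    warning(sprintf("tract %s: grid coverage %.3f below %.2f",
                    tract$id[1], coverage, min_coverage))
  }
  if (renormalize && length(w) && coverage > 0) w <- w / coverage
  list(tract_id = tract$id[1], entries = w, coverage = coverage,
       low_coverage = low)
}

#' Weighted daily tract value from cell values
#'
#' Weighted average over the overlapped cells with data that day,
#' renormalizing over the non-missing cells.
#'
#' @param weights Output of [compute_area_weights()].
#' @param day_values Named numeric vector, cell_id -> value (NA = missing).
#' @return Scalar value, or NA when every overlapped cell is missing.
#' @export
tract_daily_value <- function(weights, day_values) {
  w <- weights$entries
  v <- day_values[names(w)]
  ok <- !is.na(v)
  if (!any(ok)) return(NA_real_)
  sum(w[ok] * v[ok]) / sum(w[ok])
}

#' Annual average of a daily series
#'
#' Arithmetic mean of the non-missing daily values in the calendar year;
#' the result is missing when fewer than `min_day_frac` of the year's days
#' are available. Leap days are included.
#'
#' @param daily Data frame with columns date, value.
#' @param year Calendar year.
#' @param min_day_frac Minimum available-day fraction in (0, 1].
#' @return One-row data frame: year, mean, n_days.
#' @export
annual_average <- function(daily, year, min_day_frac = 0.75) {
  stopifnot(min_day_frac > 0, min_day_frac <= 1)
  yr <- as.integer(format(as.Date(daily$date), "%Y"))
  v <- daily$value[yr == year]
  v <- v[!is.na(v)]
  diy <- if (year %% 4 == 0 && (year %% 100 != 0 || year %% 400 == 0)) 366 else 365
  m <- if (length(v) / diy < min_day_frac) NA_real_ else mean(v)
  data.frame(year = year, mean = m, n_days = length(v))
}

#' Screen aberrant pollution values
#'
#' Two methods. `robust_z` flags cell-days whose value deviates from the same
#' cell's same-calendar-month median (across all years) by more than
#' `threshold` robust SDs (scaled MAD), where the deviation is sustained for
#' at least `min_run_days` consecutive days; flagged records are removed.
#' `manual_list` removes exactly the configured (cell_id, start, end) tuples,
#' expressing an inspection-based exclusion (cell_id NA means all cells).
#'
#' @param grid A `pollution_grid` (screening acts on its `values`).
#' @param method "robust_z" or "manual_list".
#' @param threshold Robust-z threshold (> 0).
#' @param min_run_days Minimum run of consecutive flagged days.
#' @param exclusions For `manual_list`: data frame with columns cell_id
#'   (NA = all cells), start, end (Dates).
#' @return List: `grid` (cleaned copy), `report` (removals by year), and
#'   `flags` (cell_id, date removed).
#' @export
screen_aberrant <- function(grid, method = c("robust_z", "manual_list"),
                            threshold = 5, min_run_days = 14,
                            exclusions = NULL) {
  method <- tryCatch(match.arg(method),
                     error = function(e) stop("unknown screening method"))
  dt <- data.table::as.data.table(grid$values)
  if (method == "robust_z") {
    stopifnot(threshold > 0)
    dt[, month := data.table::month(date)]
    dt[, yr := data.table::year(date)]
    # reference: the cell's same-calendar-month median across all years;
    # robust SD: the typical within-month day-to-day scale (median across
    # years of each year's scaled MAD), so a slow annual trend widens the
    # deviations only mildly without inflating the scale
    dt[, med := stats::median(value), by = .(cell_id, month)]
    dt[, madv := stats::mad(value), by = .(cell_id, month, yr)]
    dt[, madv := stats::median(madv), by = .(cell_id, month)]
    dt[, flag := madv > 0 & abs(value - med) > threshold * madv]
    # keep only flags sustained for >= min_run_days consecutive calendar days
    # per cell (gaps in the date series break a run)
    dt <- dt[order(cell_id, date)]
    dt[, day_gap := c(1L, diff(as.integer(date))), by = cell_id]
    dt[, seg := cumsum(!flag | day_gap != 1L), by = cell_id]
    dt[, run := flag & sum(flag) >= min_run_days, by = .(cell_id, seg)]
    flags <- dt[run == TRUE, .(cell_id, date)]
  } else {
    if (is.null(exclusions) || nrow(exclusions) == 0) {
      flags <- dt[0, .(cell_id, date)]
    } else {
      hit <- rep(FALSE, nrow(dt))
      for (i in seq_len(nrow(exclusions))) {
        in_win <- dt$date >= as.Date(exclusions$start[i]) &
          dt$date <= as.Date(exclusions$end[i])
        if (!is.na(exclusions$cell_id[i])) {
          in_win <- in_win & dt$cell_id == exclusions$cell_id[i]
        }
        hit <- hit | in_win
      }
      flags <- dt[hit, .(cell_id, date)]
    }
  }
  flagged_key <- paste(flags$cell_id, flags$date)
  keep <- !(paste(grid$values$cell_id, grid$values$date) %in% flagged_key)
  cleaned <- grid
  cleaned$values <- grid$values[keep, , drop = FALSE]
  rownames(cleaned$values) <- NULL
  report <- if (nrow(flags)) {
    rep_dt <- flags[, .(n_removed = .N),
                    by = .(year = as.integer(format(date, "%Y")))]
    as.data.frame(rep_dt[order(year)])
  } else {
    data.frame(year = integer(0), n_removed = integer(0))
  }
  list(grid = cleaned, report = report, flags = as.data.frame(flags))
}

#' Aggregate a city's pollution grid to a tract-year panel
#'
#' Full aggregation chain: area weights per tract, optional screening, daily
#' weighted tract values, annual means. Deterministic given its inputs.
#'
#' @param tracts A `tract_set`.
#' @param grid A `pollution_grid`.
#' @param screen NULL for no screening, or a list of arguments for
#'   [screen_aberrant()] (e.g. `list(method = "robust_z", threshold = 5)`).
#' @param min_coverage,renormalize Passed to [compute_area_weights()].
#' @param min_day_frac Passed to the annual mean rule.
#' @return An `exposure_panel` data frame (tract_id, year, pollutant, mean,
#'   n_days) with attributes `coverage` (per tract) and `screen_report`.
#' @export
aggregate_city <- function(tracts, grid, screen = NULL, min_coverage = 0.8,
                           renormalize = TRUE, min_day_frac = 0.75) {
  screen_report <- NULL
  if (!is.null(screen)) {
    sc <- do.call(screen_aberrant, c(list(grid = grid), screen))
    grid <- sc$grid
    screen_report <- sc$report
  }
  wl <- lapply(seq_len(nrow(tracts)), function(i) {
    suppressWarnings(compute_area_weights(tracts[i, ], grid,
                                          renormalize = renormalize,
                                          min_coverage = min_coverage))
  })
  coverage <- data.frame(tract_id = tracts$id,
                         coverage = vapply(wl, `[[`, 0, "coverage"),
                         low_coverage = vapply(wl, `[[`, TRUE, "low_coverage"))
  wtab <- data.table::rbindlist(lapply(wl, function(w) {
    if (!length(w$entries) || w$low_coverage) return(NULL)
    data.table::data.table(tract_id = w$tract_id,
                           cell_id = names(w$entries), w = unname(w$entries))
  }))
  if (is.null(wtab) || nrow(wtab) == 0) {
    stop("no tract has sufficient grid coverage")
  }
  vals <- data.table::as.data.table(grid$values)
  merged <- merge(wtab, vals, by = "cell_id", allow.cartesian = TRUE)
  daily <- merged[!is.na(value),
                  .(value = sum(w * value) / sum(w)),
                  by = .(tract_id, date)]
  daily[, year := as.integer(format(date, "%Y"))]
  ann <- daily[, .(mean = mean(value), n_days = .N), by = .(tract_id, year)]
  yrs <- sort(unique(as.integer(format(grid$values$date, "%Y"))))
  diy <- ifelse(yrs %% 4 == 0 & (yrs %% 100 != 0 | yrs %% 400 == 0), 366L, 365L)
  names(diy) <- yrs
  ann[, mean := ifelse(n_days / diy[as.character(year)] < min_day_frac,
                       NA_real_, mean)]
  panel <- as.data.frame(ann[order(tract_id, year)])
  panel$pollutant <- grid$pollutant
  panel <- panel[, c("tract_id", "year", "pollutant", "mean", "n_days")]
  attr(panel, "coverage") <- coverage
  attr(panel, "screen_report") <- screen_report
  class(panel) <- c("exposure_panel", "data.frame")
  panel
}

#' @export
print.exposure_panel <- function(x, ...) {
  cat(sprintf("<exposure_panel> %s: %d tracts x years %d-%d (%d rows)\n",
              x$pollutant[1], length(unique(x$tract_id)),
              min(x$year), max(x$year), nrow(x)))
  invisible(x)
}
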