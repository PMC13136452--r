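# End-to-end pipeline: simulate or ingest -> score -> aggregate ->
# demographics -> trends, with every output written as diff-able text and a
# log of every parameter in effect. All randomness flows from config$seed, so
# a fixed configuration reproduces its outputs byte for byte.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full redlining/pollution report pipeline
#'
#' Chains every stage and writes all outputs into `out_dir`: tract and graded
#' geometry (GeoJSON), the score table and category summary, the tract-year
#' exposure panel and any screening exclusions, the category-level census/SVI
#' summary, the trend table with fit coefficients, a per-category annual-mean
#' series for plotting, and a run log. With no input files configured, a
#' synthetic city is simulated under `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every in-memory stage product.
#' @export
run_report <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  simulate <- is.null(config$tracts_file)

  if (simulate) {
    city <- stage("simulate", simulate_city(
      nx = config$nx, ny = config$ny, cell_m = config$cell_m,
      grid_cell_m = config$grid_cell_m, years = config$years,
      pollutant = config$pollutant, seed = config$seed,
      missing_rate = config$missing_rate))
    tracts <- city$tracts; graded <- city$graded_areas
    grid <- city$pollution; census <- city$census; svi <- city$svi
  } else {
    tracts <- stage("ingest", read_polygons(
      config$tracts_file, "tracts", config$id_field, config$area_field))
    graded <- stage("ingest", read_polygons(
      config$holc_file, "graded", config$id_field,
      grade_field = config$grade_field))
    grid <- stage("ingest", read_grid_csv(
      config$grid_values_file, config$grid_cells_file, config$pollutant))
    census <- stage("ingest", utils::read.csv(config$census_file))
    svi <- stage("ingest", utils::read.csv(config$svi_file))
  }

  scores <- stage("score", score_city(tracts, graded, config$sliver_m2))
  screen <- if (!is.null(config$screen_method)) {
    if (config$screen_method == "robust_z") {
      list(method = "robust_z", threshold = config$screen_threshold,
           min_run_days = config$screen_min_run_days)
    } else {
      list(method = "manual_list", exclusions = config$manual_exclusions)
    }
  }
  panel <- stage("aggregate", aggregate_city(
    tracts[tracts$id %in% scores$tract_id, ], grid, screen = screen,
    min_coverage = config$min_coverage, renormalize = config$renormalize,
    min_day_frac = config$min_day_frac))
  demo <- stage("demographics", build_summary(census, svi, scores))
  trends <- stage("trends", build_trend_table(
    panel, scores, years = config$report_years, reference = config$reference,
    alpha = config$alpha, gate = config$gate))
  series <- stage("trends", category_year_means(panel, scores))

  # ---- outputs ------------------------------------------------------------
  write_geojson(tracts, file.path(out_dir, "tracts.geojson"),
                config$id_field, config$area_field)
  write_geojson(graded, file.path(out_dir, "graded_areas.geojson"),
                config$id_field, grade_field = config$grade_field)
  write_scores_csv(scores, file.path(out_dir, "scores.csv"))
  utils::write.csv(as.data.frame(panel), file.path(out_dir, "panel.csv"),
                   row.names = FALSE)
  sr <- attr(panel, "screen_report")
  if (!is.null(sr)) {
    utils::write.csv(sr, file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  }
  fmt <- format_summary(demo)
  utils::write.csv(fmt$census, file.path(out_dir, "census_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(fmt$svi, file.path(out_dir, "svi_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(trends$levels, file.path(out_dir, "trend_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(beta = as.list(trends$fit$beta),
         vcov = trends$fit$vcov,
         sigma2_u = trends$fit$sigma2_u, sigma2_e = trends$fit$sigma2_e,
         method = trends$fit$method, overall_p = as.list(trends$overall_p)),
    file.path(out_dir, "trend_fit.json"), digits = NA, auto_unbox = TRUE)
  utils::write.csv(series, file.path(out_dir, "category_year_means.csv"),
                   row.names = FALSE)

  dropped <- nrow(tracts) - nrow(scores)
  log_lines <- c(
    sprintf("redlinair report"),
    sprintf("seed: %d", config$seed),
    sprintf("mode: %s", if (simulate) "synthetic" else "ingest"),
    sprintf("pollutant: %s", config$pollutant),
    sprintf("sliver_m2: %g | min_coverage: %g | renormalize: %s | min_day_frac: %g",
            config$sliver_m2, config$min_coverage, config$renormalize,
            config$min_day_frac),
    sprintf("screen: %s", config$screen_method %||% "none"),
    if (!is.null(sr)) sprintf("screening removed %d cell-days", sum(sr$n_removed)),
    sprintf("model: reference=%s alpha=%g gate=%s method=%s",
            config$reference, config$alpha, config$gate, trends$fit$method),
    sprintf("tracts in: %d | selected (scored): %d | dropped outside boundary: %d",
            nrow(tracts), nrow(scores), dropped),
    sprintf("panel rows: %d | tracts in panel: %d",
            nrow(panel), length(unique(panel$tract_id))))
  writeLines(log_lines, file.path(out_dir, "report_log.txt"))

  invisible(list(tracts = tracts, graded_areas = graded, scores = scores,
                 panel = panel, demographics = demo, trends = trends,
                 series = series, out_dir = out_dir))
}

#' Per-category annual mean pollution series
#'
#' Averages the tract-year annual means within each redlining category, the
#' series behind the longitudinal trend figure.
#'
#' @param panel An `exposure_panel`.
#' @param scores Score table.
#' @return Data frame: category, year, mean, n_tracts.
#' @export
category_year_means <- function(panel, scores) {
  cat_of <- stats::setNames(as.character(scores$category), scores$tract_id)
  d <- data.frame(category = unname(cat_of[panel$tract_id]),
                  year = panel$year, mean = panel$mean)
  d <- d[!is.na(d$mean), ]
  agg <- stats::aggregate(mean ~ category + year, d, mean)
  n <- stats::aggregate(mean ~ category + year, d, length)
  agg$n_tracts <- n$mean
  agg <- agg[order(match(agg$category, CATEGORIES), agg$year), ]
  rownames(agg) <- NULL
  agg
}

#' Plot per-category annual pollution trends
#'
#' Line plot of the category-averaged annual means over time (requires
#' ggplot2).
#'
#' @param panel An `exposure_panel`.
#' @param scores Score table.
#' @return A ggplot object.
#' @export
plot_category_trends <- function(panel, scores) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  s <- category_year_means(panel, scores)
  unit <- if (identical(panel$pollutant[1], "no2")) "NO2 (ppb)" else "PM2.5 (ug/m3)"
  ggplot2::ggplot(s, ggplot2::aes(x = .data$year, y = .data$mean,
                                  colour = .data$category)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Year", y = paste("Annual mean", unit),
                  colour = "Redlining\ncategory") +
    ggplot2::theme_minimal()
}
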