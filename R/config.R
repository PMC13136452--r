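# Pipeline configuration: one validated list of every tunable the pipeline
# honours, with the package defaults spelled out in a single place.

config_defaults <- function() {
  list(
    # synthetic-city inputs (used when no files are given)
    nx = 10L, ny = 10L, cell_m = 1000, grid_cell_m = 1000,
    years = 2000:2016, pollutant = "no2", missing_rate = 0,
    # real-data inputs (GeoJSON / CSV); all-or-none for the geometry pair
    tracts_file = NULL, holc_file = NULL,
    grid_values_file = NULL, grid_cells_file = NULL,
    census_file = NULL, svi_file = NULL,
    id_field = "GEOID", area_field = "ALAND", grade_field = "holc_grade",
    # scoring
    sliver_m2 = 1,
    # aggregation
    min_coverage = 0.8, renormalize = TRUE, min_day_frac = 0.75,
    # screening: NULL disables; "robust_z" or "manual_list"
    screen_method = NULL, screen_threshold = 5, screen_min_run_days = 14,
    manual_exclusions = NULL,
    # trend model
    reference = "A", report_years = c(2000, 2008, 2016),
    alpha = 0.05, gate = TRUE,
    seed = 1L)
}

#' Build a validated pipeline configuration
#'
#' All arguments default to the package's documented defaults; unknown keys
#' are rejected.
#'
#' @param ... Named overrides of the defaults (see [config_defaults] source
#'   for the full key list).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  defs <- config_defaults()
  unknown <- setdiff(names(over), names(defs))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defs, over, keep.null = TRUE)
  stopifnot(cfg$sliver_m2 >= 0,
            cfg$min_coverage >= 0, cfg$min_coverage <= 1,
            cfg$min_day_frac > 0, cfg$min_day_frac <= 1,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$screen_threshold > 0, cfg$screen_min_run_days >= 1,
            cfg$pollutant %in% c("no2", "pm25"))
  if (!is.null(cfg$screen_method) &&
      !cfg$screen_method %in% c("robust_z", "manual_list")) {
    stop("screen_method must be NULL, 'robust_z' or 'manual_list'")
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$years)) y$years <- as.integer(y$years)
  if (!is.null(y$manual_exclusions)) {
    y$manual_exclusions <- do.call(rbind, lapply(y$manual_exclusions, function(e) {
      data.frame(cell_id = e$cell_id %||% NA_character_,
                 start = as.Date(e$start), end = as.Date(e$end))
    }))
  }
  do.call(pipeline_config, y)
}
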