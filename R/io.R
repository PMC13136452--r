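# GeoJSON and CSV interchange. GeoJSON is the canonical geometry format
# (single file, text, diff-able); coordinates must already be in a projected
# planar frame in metres — no reprojection is performed.

poly_to_ring <- function(poly) {
  rbind(unname(poly), unname(poly)[1, , drop = FALSE])
}

#' Write tracts or graded areas as GeoJSON
#'
#' @param x A `tract_set` or `graded_area_set`.
#' @param path Output file.
#' @param id_field,area_field,grade_field Property names to write (census
#'   dialect defaults).
#' @return `path`, invisibly.
#' @export
write_geojson <- function(x, path, id_field = "GEOID", area_field = "ALAND",
                          grade_field = "holc_grade") {
  feats <- lapply(seq_len(nrow(x)), function(i) {
    props <- stats::setNames(list(x$id[i]), id_field)
    if ("land_area" %in% names(x)) props[[area_field]] <- x$land_area[i]
    if ("grade" %in% names(x)) props[[grade_field]] <- x$grade[i]
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(poly_to_ring(x$geometry[[i]]))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read tract or HOLC polygons from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of Polygon features in a planar frame.
#' For `layer = "tracts"`, land area is taken from `area_field` when present
#' and from the polygon area otherwise. For `layer = "graded"`, features with
#' a grade outside A-D are rejected with a row-level message (or skipped).
#'
#' @param path GeoJSON file.
#' @param layer "tracts" or "graded".
#' @param id_field,area_field,grade_field Property names (census dialect
#'   defaults: GEOID, ALAND in m2, holc_grade).
#' @param on_bad_grade "error" (default) or "skip".
#' @return A `tract_set` or `graded_area_set`.
#' @export
read_polygons <- function(path, layer = c("tracts", "graded"),
                          id_field = "GEOID", area_field = "ALAND",
                          grade_field = "holc_grade",
                          on_bad_grade = c("error", "skip")) {
  layer <- match.arg(layer)
  on_bad_grade <- match.arg(on_bad_grade)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  if (is.null(feats) || !length(feats)) stop("no features in GeoJSON")
  parse_one <- function(f, i) {
    if (!identical(f$geometry$type, "Polygon")) {
      stop(sprintf("feature %d: only Polygon geometries are supported", i))
    }
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) >= 2 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    props <- f$properties
    if (is.null(props[[id_field]])) {
      stop(sprintf("feature %d: missing id field '%s' (available: %s)",
                   i, id_field, paste(names(props), collapse = ", ")))
    }
    list(id = as.character(props[[id_field]]), geometry = m, props = props)
  }
  parsed <- lapply(seq_along(feats), function(i) parse_one(feats[[i]], i))
  if (layer == "tracts") {
    land <- vapply(seq_along(parsed), function(i) {
      a <- parsed[[i]]$props[[area_field]]
      if (is.null(a)) poly_area(parsed[[i]]$geometry) else as.numeric(a)
    }, 0)
    out <- data.frame(id = vapply(parsed, `[[`, "", "id"), land_area = land)
    out$geometry <- lapply(parsed, `[[`, "geometry")
    class(out) <- c("tract_set", "data.frame")
    out
  } else {
    grade <- vapply(seq_along(parsed), function(i) {
      g <- parsed[[i]]$props[[grade_field]]
      if (is.null(g)) NA_character_ else as.character(g)
    }, "")
    bad <- which(!grade %in% GRADES)
    if (length(bad)) {
      msg <- sprintf("invalid HOLC grade in feature(s) %s: %s (expected A-D)",
                     paste(bad, collapse = ", "),
                     paste(unique(grade[bad]), collapse = ", "))
      if (on_bad_grade == "error") stop(msg)
      warning(paste(msg, "- skipped"))
      parsed <- parsed[-bad]
      grade <- grade[-bad]
    }
    out <- data.frame(id = vapply(parsed, `[[`, "", "id"), grade = grade,
                      numeric_grade = match(grade, GRADES))
    out$geometry <- lapply(parsed, `[[`, "geometry")
    class(out) <- c("graded_area_set", "data.frame")
    out
  }
}

#' Write a score table to CSV (plus a JSON category summary)
#'
#' @param scores A `score_table`.
#' @param path CSV path; the summary is written next to it as `<path>.summary.json`.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE)
  s <- attr(scores, "summary")
  if (!is.null(s)) {
    jsonlite::write_json(s, paste0(path, ".summary.json"), digits = NA)
  }
  invisible(path)
}

#' Read a pollution grid from CSV values plus a lattice spec
#'
#' @param values_path CSV with columns cell_id, date (ISO-8601), value.
#' @param cells A data frame (cell_id, x0, y0, size_m) or a CSV path to one.
#' @param pollutant "no2" or "pm25".
#' @return A `pollution_grid`.
#' @export
read_grid_csv <- function(values_path, cells, pollutant = c("no2", "pm25")) {
  pollutant <- match.arg(pollutant)
  vals <- utils::read.csv(values_path, stringsAsFactors = FALSE)
  req <- c("cell_id", "date", "value")
  if (!all(req %in% names(vals))) {
    stop(sprintf("grid CSV must have columns %s", paste(req, collapse = ", ")))
  }
  vals$date <- as.Date(vals$date)
  if (is.character(cells)) cells <- utils::read.csv(cells, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "x0", "y0", "size_m") %in% names(cells)))
  structure(list(cells = cells, values = vals, pollutant = pollutant,
                 span = range(vals$date)),
            class = "pollution_grid")
}

#' Write a pollution grid's values (and cells) to CSV
#'
#' @param grid A `pollution_grid`.
#' @param values_path Values CSV path.
#' @param cells_path Optional lattice-spec CSV path.
#' @return `values_path`, invisibly.
#' @export
write_grid_csv <- function(grid, values_path, cells_path = NULL) {
  v <- grid$values
  v$date <- format(v$date, "%Y-%m-%d")
  utils::write.csv(v, values_path, row.names = FALSE)
  if (!is.null(cells_path)) {
    utils::write.csv(grid$cells[, c("cell_id", "x0", "y0", "size_m")],
                     cells_path, row.names = FALSE)
  }
  invisible(values_path)
}
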