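# Tract-level historical-redlining scoring: study boundary, tract selection,
# grade fractions by areal overlay, continuous weighted score, and category.
#
# The score is the area-fraction-weighted average of the numeric HOLC grades
# covering a tract (A = 1, B = 2, C = 3, D = 4), a continuous index in [0, 4];
# tracts with no graded area score 0 and are "ungraded".

#' Study boundary: convex hull of the graded areas
#'
#' The analysis boundary is the smallest convex polygon enclosing all HOLC
#' graded polygons (the convex hull of their vertices).
#'
#' @param graded_areas A `graded_area_set`.
#' @return A counter-clockwise convex polygon matrix.
#' @export
compute_boundary <- function(graded_areas) {
  if (is.null(graded_areas) || nrow(graded_areas) == 0) {
    stop("at least one graded polygon is required to form a boundary")
  }
  pts <- do.call(rbind, graded_areas$geometry)
  convex_hull_points(pts)
}

#' Select tracts within or intersecting the study boundary
#'
#' A tract is retained when its intersection with the boundary has positive
#' area (above a sliver tolerance); tracts that only touch the boundary along
#' an edge are excluded. Input order is preserved.
#'
#' @param tracts A `tract_set`.
#' @param boundary Convex polygon matrix (from [compute_boundary()]).
#' @param sliver_m2 Minimum intersection area in square metres counted as a
#'   real overlap (default 1).
#' @return The retained subset of `tracts`.
#' @export
select_tracts <- function(tracts, boundary, sliver_m2 = 1) {
  keep <- vapply(tracts$geometry, function(g) {
    intersection_area(g, boundary) > sliver_m2
  }, logical(1))
  out <- tracts[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tract_set", "data.frame")
  out
}

#' Fraction of a tract's land area under each HOLC grade
#'
#' Intersects the tract with every graded polygon and divides the per-grade
#' overlap area by the tract's land area. Per-polygon overlaps below the
#' sliver tolerance are dropped (digitization slivers). If overlapping graded
#' polygons of different grades push the fraction total above 1, the fractions
#' are rescaled to sum to 1 with a data-quality warning.
#'
#' @param tract One-row `tract_set` (or list with id, land_area, geometry).
#' @param graded_areas A `graded_area_set`.
#' @param sliver_m2 Sliver tolerance in square metres.
#' @return Named numeric vector of fractions over grades A-D (only grades with
#'   positive overlap appear); empty when the tract is untouched.
#' @export
grade_fractions <- function(tract, graded_areas, sliver_m2 = 1) {
  geom <- if (is.list(tract$geometry) && !is.matrix(tract$geometry)) {
    tract$geometry[[1]]
  } else {
    tract$geometry
  }
  land <- tract$land_area[1]
  if (!is.finite(land) || land <= 0) stop("tract land_area must be positive")
  tb <- poly_bbox(geom)
  acc <- c(A = 0, B = 0, C = 0, D = 0)
  for (k in seq_len(nrow(graded_areas))) {
    gp <- graded_areas$geometry[[k]]
    if (bbox_disjoint(tb, poly_bbox(gp))) next
    a <- tryCatch(intersection_area(geom, gp), error = function(e) {
      stop(sprintf("invalid geometry while overlaying graded area '%s': %s",
                   graded_areas$id[k], conditionMessage(e)))
    })
    if (a >= sliver_m2) acc[graded_areas$grade[k]] <- acc[graded_areas$grade[k]] + a
  }
  fr <- acc / land
  fr <- fr[fr > 0]
  if (length(fr) && sum(fr) > 1 + 1e-9) {
    warning(sprintf(
      "tract %s: grade fractions sum to %.6f > 1 (overlapping graded polygons); rescaled",
      tract$id[1], sum(fr)))
    fr <- fr / sum(fr)
  }
  fr
}

#' Continuous weighted redlining score
#'
#' Multiplies each grade's area fraction by its numeric grade (A = 1, B = 2,
#' C = 3, D = 4) and sums. An empty fraction map scores 0.
#'
#' @param fractions Named numeric vector over grades (subset of A-D).
#' @return Score in \code{[0, 4]}.
#' @export
weighted_score <- function(fractions) {
  if (length(fractions) == 0) return(0)
  stopifnot(all(names(fractions) %in% GRADES))
  sum(fractions * match(names(fractions), GRADES))
}

#' Categorize a redlining score
#'
#' Left-open, right-closed bins: 0 is "ungraded", (0, 1] is A, (1, 2] is B,
#' (2, 3] is C, (3, 4] is D.
#'
#' @param score Numeric vector of scores in \code{[0, 4]}.
#' @return Character vector of categories.
#' @export
categorize_score <- function(score) {
  if (any(score < -1e-9 | score > 4 + 1e-9)) {
    stop("score must lie in [0, 4]")
  }
  out <- character(length(score))
  zero <- score <= 1e-12
  out[zero] <- "ungraded"
  out[!zero] <- GRADES[pmin(ceiling(score[!zero] - 1e-12), 4L)]
  out
}

#' Score every tract in a city
#'
#' Full scoring chain: boundary from the graded areas, selection of tracts
#' within or intersecting it, grade fractions, weighted score, and category
#' for each selected tract. Category counts and percentage shares are attached
#' as the `summary` attribute.
#'
#' @param tracts A `tract_set`.
#' @param graded_areas A `graded_area_set`.
#' @param sliver_m2 Sliver tolerance in square metres.
#' @return A `score_table`: data frame with tract_id, frac_A..frac_D, score,
#'   category, plus a `summary` attribute (category, n, share_pct).
#' @export
score_city <- function(tracts, graded_areas, sliver_m2 = 1) {
  if (nrow(tracts) == 0 || nrow(graded_areas) == 0) {
    stop("tracts and graded_areas must be non-empty")
  }
  boundary <- compute_boundary(graded_areas)
  sel <- select_tracts(tracts, boundary, sliver_m2)
  n <- nrow(sel)
  fr_mat <- matrix(0, n, 4, dimnames = list(NULL, GRADES))
  score <- numeric(n)
  for (i in seq_len(n)) {
    fr <- grade_fractions(sel[i, ], graded_areas, sliver_m2)
    fr_mat[i, names(fr)] <- fr
    score[i] <- weighted_score(fr)
  }
  out <- data.frame(tract_id = sel$id,
                    frac_A = fr_mat[, "A"], frac_B = fr_mat[, "B"],
                    frac_C = fr_mat[, "C"], frac_D = fr_mat[, "D"],
                    score = score,
                    category = categorize_score(score))
  rownames(out) <- NULL
  counts <- table(factor(out$category, levels = CATEGORIES))
  summary <- data.frame(category = names(counts),
                        n = as.integer(counts),
                        share_pct = round(100 * as.integer(counts) / n, 1))
  attr(out, "summary") <- summary
  attr(out, "boundary") <- boundary
  class(out) <- c("score_table", "data.frame")
  out
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d tracts\n", nrow(x)))
  print(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}
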