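# Category-level demographic summaries: census/ACS variable means by
# redlining category and period, percent change between periods, and SVI
# means/SDs. Means are unweighted tract averages with missing values omitted;
# all arithmetic is full precision, display rounding happens only at
# serialization.

category_factor <- function(x) factor(as.character(x), levels = CATEGORIES)

#' Mean of a census variable by redlining category
#'
#' Unweighted arithmetic mean over the tracts in each category for one
#' variable and period; missing tract values are omitted and the number of
#' contributing tracts reported.
#'
#' @param table Census table (tract_id, period, variable, value) or SVI table
#'   (tract_id, period, svi).
#' @param scores Score table (or data frame with tract_id, category).
#' @param variable Variable name (ignored for an SVI table).
#' @param period "early" or "late".
#' @return Data frame: category, mean, n.
#' @export
category_means <- function(table, scores, variable = NULL,
                           period = c("early", "late")) {
  period_ <- match.arg(period)
  if ("svi" %in% names(table)) {
    sub <- table[table$period == period_, ]
    sub$value <- sub$svi
  } else {
    if (is.null(variable) || !variable %in% table$variable) {
      stop(sprintf("unknown variable '%s'", variable %||% "<null>"))
    }
    sub <- table[table$period == period_ & table$variable == variable, ]
  }
  cat_of <- stats::setNames(as.character(scores$category), scores$tract_id)
  if (any(!sub$tract_id %in% names(cat_of))) {
    stop("every tract in the table must appear in scores")
  }
  sub$category <- category_factor(cat_of[sub$tract_id])
  agg <- lapply(split(sub$value, sub$category), function(v) {
    v <- v[!is.na(v)]
    c(mean = if (length(v)) mean(v) else NA_real_, n = length(v))
  })
  out <- data.frame(category = names(agg),
                    mean = vapply(agg, `[[`, 0, "mean"),
                    n = as.integer(vapply(agg, `[[`, 0, "n")))
  rownames(out) <- NULL
  out[out$n > 0 | out$category %in% as.character(unique(sub$category)), ,
      drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percent change between two period means
#'
#' `100 * (late - early) / early`, full precision (round to one decimal for
#' display). Undefined (NA) when the early mean is zero or either mean is
#' missing.
#'
#' @param early_mean,late_mean Numeric vectors (recycled).
#' @return Percent change, NA where undefined.
#' @export
percent_change <- function(early_mean, late_mean) {
  out <- 100 * (late_mean - early_mean) / early_mean
  out[is.na(early_mean) | is.na(late_mean) | early_mean == 0] <- NA_real_
  out
}

#' SVI mean and SD by redlining category
#'
#' Per-category mean and sample SD (n - 1 denominator) of tract SVI values for
#' one period; missing values omitted, SD reported missing for singleton
#' categories.
#'
#' @param svi SVI table (tract_id, period, svi).
#' @param scores Score table.
#' @param period "early" or "late".
#' @return Data frame: category, mean, sd, n.
#' @export
svi_summary <- function(svi, scores, period = c("early", "late")) {
  period_ <- match.arg(period)
  cm <- category_means(svi, scores, period = period_)
  cat_of <- stats::setNames(as.character(scores$category), scores$tract_id)
  sub <- svi[svi$period == period_, ]
  sub$category <- category_factor(cat_of[sub$tract_id])
  sds <- vapply(split(sub$svi, sub$category), function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2) stats::sd(v) else NA_real_
  }, 0)
  cm$sd <- unname(sds[as.character(cm$category)])
  cm[, c("category", "mean", "sd", "n")]
}

#' Full category-level demographic summary
#'
#' Assembles the complete summary: for every census variable and category, the
#' early and late period means (with n) and the percent change of the category
#' means; plus SVI mean/SD per category and period.
#'
#' @param census Census table (tract_id, period, variable, value).
#' @param svi SVI table (tract_id, period, svi).
#' @param scores Score table.
#' @return A `category_summary` list with `census` and `svi` data frames.
#' @export
build_summary <- function(census, svi, scores) {
  vars <- sort(unique(census$variable))
  rows <- lapply(vars, function(v) {
    e <- category_means(census, scores, v, "early")
    l <- category_means(census, scores, v, "late")
    m <- merge(e, l, by = "category", suffixes = c("_early", "_late"))
    m$variable <- v
    m$pct_change <- percent_change(m$mean_early, m$mean_late)
    m
  })
  cen <- do.call(rbind, rows)
  cen$category <- category_factor(cen$category)
  cen <- cen[order(match(cen$variable, vars), cen$category),
             c("variable", "category", "mean_early", "n_early",
               "mean_late", "n_late", "pct_change")]
  rownames(cen) <- NULL
  sv <- rbind(cbind(period = "early", svi_summary(svi, scores, "early")),
              cbind(period = "late", svi_summary(svi, scores, "late")))
  rownames(sv) <- NULL
  structure(list(census = cen, svi = sv), class = "category_summary")
}

#' @export
print.category_summary <- function(x, ...) {
  cat(sprintf("<category_summary> %d variables x %d categories; SVI by period\n",
              length(unique(x$census$variable)),
              length(unique(x$census$category))))
  invisible(x)
}

#' Serialize a category summary for display
#'
#' Applies the display conventions: monetary/population/density means as
#' integers, percentage-type means to one decimal, percent change to one
#' decimal, SVI to three decimals.
#'
#' @param summary A `category_summary`.
#' @return List of two data frames with rounded columns.
#' @export
format_summary <- function(summary) {
  cen <- summary$census
  pct <- startsWith(cen$variable, "pct_")
  cen$mean_early <- ifelse(pct, round(cen$mean_early, 1), round(cen$mean_early))
  cen$mean_late <- ifelse(pct, round(cen$mean_late, 1), round(cen$mean_late))
  cen$pct_change <- round(cen$pct_change, 1)
  sv <- summary$svi
  sv$mean <- round(sv$mean, 3)
  sv$sd <- round(sv$sd, 3)
  list(census = cen, svi = sv)
}
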