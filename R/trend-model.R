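# Linear mixed-effects trend model of annual pollution on redlining category,
# calendar year, and their interaction, with tract random intercepts:
#
#   mean_{it} = b0 + b_c[cat(i)] + (b_t + b_ct[cat(i)]) * (year - y0)
#               + u_i + e_{it},   u_i ~ N(0, s2_u),  e_{it} ~ N(0, s2_e)
#
# Estimation is REML (lme4) with an ML fallback on non-convergence. Predicted
# levels, per-category slopes, overall Wald chi-square tests, and
# Bonferroni-adjusted pairwise contrasts against the reference category are
# derived from the fixed-effect estimates and covariance.

#' Fit the category-by-year mixed-effects trend model
#'
#' @param panel An `exposure_panel` (tract_id, year, mean; one pollutant).
#' @param scores Score table (or data frame with tract_id, category).
#' @param reference Reference category (default "A").
#' @param year_origin Year at which the intercept is anchored; defaults to the
#'   first panel year so the intercept is the reference-category level then.
#' @param reml Use REML (default) or ML.
#' @return A `trend_fit`: coefficients (named intercept, cat_<c>, year,
#'   cat_<c>:year), fixed-effect covariance, variance components `sigma2_u`
#'   and `sigma2_e`, categories, year origin and fit metadata.
#' @export
fit_trend <- function(panel, scores, reference = "A", year_origin = NULL,
                      reml = TRUE) {
  if (length(unique(panel$pollutant)) > 1) {
    stop("fit one pollutant at a time")
  }
  cat_of <- stats::setNames(as.character(scores$category), scores$tract_id)
  if (any(!panel$tract_id %in% names(cat_of))) {
    stop("every panel tract must have a redlining category")
  }
  d <- data.frame(tract_id = panel$tract_id,
                  year = panel$year,
                  y = panel$mean,
                  category = unname(cat_of[panel$tract_id]))
  d <- d[!is.na(d$y), ]
  cats_present <- intersect(CATEGORIES, unique(d$category))
  if (!reference %in% cats_present) {
    stop(sprintf("reference category '%s' not present in the panel", reference))
  }
  if (length(cats_present) < 2) stop("need at least 2 categories")
  if (length(unique(d$year)) < 2) stop("need at least 2 distinct years")
  tab <- table(d$category)
  if (any(tab < 2)) {
    stop(sprintf("singular design: category %s has fewer than 2 tract-years",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  if (is.null(year_origin)) year_origin <- min(d$year)
  d$year_c <- d$year - year_origin
  d$category <- factor(d$category,
                       levels = c(reference, setdiff(cats_present, reference)))
  d$tract_id <- factor(d$tract_id)
  non_ref <- levels(d$category)[-1]

  canonical <- function(nm) {
    nm <- sub("^\\(Intercept\\)$", "intercept", nm)
    nm <- sub("^category", "cat_", nm)
    nm <- sub("^year_c$", "year", nm)
    nm <- sub("^cat_(.*):year_c$", "cat_\\1:year", nm)
    nm
  }

  ols <- stats::lm(y ~ category * year_c, data = d)
  resid_scale <- stats::sigma(ols)
  y_scale <- max(stats::sd(d$y), 1e-8)
  if (resid_scale < 1e-8 * y_scale) {
    # noise-free panel: the mixed-model likelihood is degenerate, and the
    # exact least-squares solution with zero variance components is the MLE
    beta <- stats::coef(ols)
    V <- suppressWarnings(stats::vcov(ols)) # "essentially perfect fit"
    names(beta) <- canonical(names(beta))
    dimnames(V) <- list(names(beta), names(beta))
    return(structure(
      list(beta = beta, vcov = V, sigma2_u = 0, sigma2_e = resid_scale^2,
           reference = reference, categories = levels(d$category),
           year_origin = year_origin, method = "degenerate-ols",
           converged = TRUE, n_tracts = nlevels(d$tract_id), n_obs = nrow(d)),
      class = "trend_fit"))
  }

  fit_once <- function(use_reml) {
    warned <- FALSE
    m <- withCallingHandlers(
      lme4::lmer(y ~ category * year_c + (1 | tract_id), data = d,
                 REML = use_reml),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    list(model = m, clean = !warned)
  }
  r <- tryCatch(fit_once(reml), error = function(e) NULL)
  method <- if (reml) "REML" else "ML"
  if (is.null(r) || !r$clean) {
    r2 <- tryCatch(fit_once(FALSE), error = function(e) NULL)
    if (!is.null(r2) && r2$clean) {
      r <- r2
      method <- "ML (REML fallback)"
    }
  }
  if (is.null(r)) stop("mixed-model fit failed to converge (REML and ML)")
  m <- r$model
  beta <- lme4::fixef(m)
  V <- as.matrix(stats::vcov(m))
  names(beta) <- canonical(names(beta))
  dimnames(V) <- list(names(beta), names(beta))
  vc <- as.data.frame(lme4::VarCorr(m))
  structure(
    list(beta = beta, vcov = V,
         sigma2_u = vc$vcov[vc$grp == "tract_id"],
         sigma2_e = vc$vcov[vc$grp == "Residual"],
         reference = reference, categories = levels(d$category),
         year_origin = year_origin, method = method, converged = r$clean,
         n_tracts = nlevels(d$tract_id), n_obs = nrow(d),
         n_tracts_by_category = table(cat_of[levels(d$tract_id)])),
    class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> ref=%s, y0=%d, %s; %d tracts, %d obs\n  sigma_u=%.4g, sigma_e=%.4g\n",
    x$reference, x$year_origin, x$method, x$n_tracts, x$n_obs,
    sqrt(x$sigma2_u), sqrt(x$sigma2_e)))
  print(round(x$beta, 4))
  invisible(x)
}

# Linear-combination vector over the fixed effects for a category level at a
# given year (level = TRUE) or its slope (level = FALSE).
contrast_vector <- function(fit, category, year = NULL, level = TRUE) {
  if (!category %in% fit$categories) {
    stop(sprintf("unknown category '%s'", category))
  }
  L <- stats::setNames(numeric(length(fit$beta)), names(fit$beta))
  if (level) {
    t <- year - fit$year_origin
    L["intercept"] <- 1
    L["year"] <- t
    if (category != fit$reference) {
      L[paste0("cat_", category)] <- 1
      L[paste0("cat_", category, ":year")] <- t
    }
  } else {
    L["year"] <- 1
    if (category != fit$reference) {
      L[paste0("cat_", category, ":year")] <- 1
    }
  }
  L
}

#' Model-predicted pollution level for a category and year
#'
#' `b0 + b_c + (b_t + b_ct) * (year - y0)`, with the SE from the
#' linear-combination variance of the fixed-effect covariance.
#'
#' @param fit A `trend_fit`.
#' @param category Category label present in the fit.
#' @param year Calendar year.
#' @return Named vector: estimate, se.
#' @export
predicted_level <- function(fit, category, year) {
  L <- contrast_vector(fit, category, year, level = TRUE)
  c(estimate = sum(L * fit$beta),
    se = sqrt(drop(L %*% fit$vcov %*% L)))
}

#' Annual slope for a category
#'
#' `b_t` for the reference, `b_t + b_ct` otherwise, with combined SE.
#'
#' @inheritParams predicted_level
#' @return Named vector: estimate, se.
#' @export
category_slope <- function(fit, category) {
  L <- contrast_vector(fit, category, level = FALSE)
  c(estimate = sum(L * fit$beta),
    se = sqrt(drop(L %*% fit$vcov %*% L)))
}

wald_chisq <- function(fit, Lmat) {
  est <- drop(Lmat %*% fit$beta)
  V <- Lmat %*% fit$vcov %*% t(Lmat)
  Vi <- tryCatch(solve(V), error = function(e) {
    stop("singular contrast covariance; overall test unavailable")
  })
  stat <- drop(t(est) %*% Vi %*% est)
  df <- nrow(Lmat)
  c(statistic = stat, df = df,
    p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Overall test of category level differences at a year
#'
#' Joint Wald chi-square test that all non-reference category level offsets at
#' the given year, `b_c + b_ct * (year - y0)`, are simultaneously zero;
#' degrees of freedom = number of non-reference categories.
#'
#' @param fit A `trend_fit`.
#' @param year Calendar year.
#' @return Named vector: statistic, df, p.
#' @export
overall_level_test <- function(fit, year) {
  non_ref <- setdiff(fit$categories, fit$reference)
  t <- year - fit$year_origin
  Lmat <- t(vapply(non_ref, function(cc) {
    L <- stats::setNames(numeric(length(fit$beta)), names(fit$beta))
    L[paste0("cat_", cc)] <- 1
    L[paste0("cat_", cc, ":year")] <- t
    L
  }, numeric(length(fit$beta))))
  wald_chisq(fit, Lmat)
}

#' Overall test of slope differences across categories
#'
#' Joint Wald chi-square test that all category-by-year interaction
#' coefficients are simultaneously zero.
#'
#' @param fit A `trend_fit`.
#' @return Named vector: statistic, df, p.
#' @export
overall_slope_test <- function(fit) {
  non_ref <- setdiff(fit$categories, fit$reference)
  Lmat <- t(vapply(non_ref, function(cc) {
    L <- stats::setNames(numeric(length(fit$beta)), names(fit$beta))
    L[paste0("cat_", cc, ":year")] <- 1
    L
  }, numeric(length(fit$beta))))
  wald_chisq(fit, Lmat)
}

#' Pairwise contrasts against the reference category
#'
#' One contrast per non-reference category versus the reference, for levels at
#' a year or for slopes, with a Bonferroni threshold alpha / m (m = number of
#' non-reference categories present). When gating is on (the default), the
#' pairwise contrasts are only evaluated if the corresponding overall test is
#' significant at alpha; otherwise they are marked not evaluated.
#'
#' @param fit A `trend_fit`.
#' @param mode "level" or "slope".
#' @param year Calendar year (required for mode = "level").
#' @param alpha Family-wise significance level.
#' @param gate Gate the contrasts on the overall test.
#' @return Data frame: comparison, estimate, se, statistic, p, bonferroni
#'   threshold, significant (NA when gated out), evaluated.
#' @export
pairwise_contrasts <- function(fit, mode = c("level", "slope"), year = NULL,
                               alpha = 0.05, gate = TRUE) {
  mode <- match.arg(mode)
  if (mode == "level" && is.null(year)) stop("year is required for level contrasts")
  non_ref <- setdiff(fit$categories, fit$reference)
  m <- length(non_ref)
  overall <- if (mode == "level") overall_level_test(fit, year) else overall_slope_test(fit)
  pass_gate <- !gate || overall["p"] < alpha
  rows <- lapply(non_ref, function(cc) {
    Lc <- contrast_vector(fit, cc, year, level = mode == "level") -
      contrast_vector(fit, fit$reference, year, level = mode == "level")
    est <- sum(Lc * fit$beta)
    se <- sqrt(drop(Lc %*% fit$vcov %*% Lc))
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(comparison = sprintf("%s vs %s", cc, fit$reference),
               estimate = est, se = se, statistic = z, p = p,
               bonferroni_alpha = alpha / m,
               significant = if (pass_gate) p < alpha / m else NA,
               evaluated = pass_gate)
  })
  out <- do.call(rbind, rows)
  attr(out, "overall") <- overall
  attr(out, "m") <- m
  out
}

#' Full trend table: levels, slopes, tests, and contrast flags
#'
#' Assembles the complete trend summary for one pollutant: per-category
#' model-predicted levels at the requested years and slopes, overall Wald test
#' p-values per year and for the slopes, and Bonferroni-starred pairwise
#' significance flags. Categories are ordered D, C, B, ungraded, reference.
#'
#' @param panel An `exposure_panel`.
#' @param scores Score table.
#' @param years Years at which to report predicted levels.
#' @param reference Reference category.
#' @param alpha Family-wise significance level.
#' @param gate Gate pairwise contrasts on the overall test.
#' @return A `trend_table` list: `levels` (wide data frame), `overall_p`,
#'   `contrasts`, and the underlying `fit`.
#' @export
build_trend_table <- function(panel, scores, years = c(2000, 2008, 2016),
                              reference = "A", alpha = 0.05, gate = TRUE) {
  fit <- fit_trend(panel, scores, reference)
  pr <- range(panel$year)
  if (any(years < pr[1] | years > pr[2])) {
    stop("requested years must lie within the panel span")
  }
  non_ref <- setdiff(fit$categories, fit$reference)
  ord <- c(intersect(c("D", "C", "B", "ungraded"), non_ref), fit$reference)
  lev_contr <- lapply(stats::setNames(years, years), function(y) {
    pairwise_contrasts(fit, "level", year = y, alpha = alpha, gate = gate)
  })
  slope_contr <- pairwise_contrasts(fit, "slope", alpha = alpha, gate = gate)
  star <- function(contr, cc) {
    if (cc == fit$reference) return(FALSE)
    s <- contr$significant[contr$comparison == sprintf("%s vs %s", cc, fit$reference)]
    isTRUE(s)
  }
  rows <- lapply(ord, function(cc) {
    lv <- vapply(years, function(y) predicted_level(fit, cc, y)["estimate"], 0)
    st <- vapply(years, function(y) star(lev_contr[[as.character(y)]], cc),
                 logical(1))
    sl <- category_slope(fit, cc)
    row <- data.frame(category = cc,
                      n_tracts = if (!is.null(fit$n_tracts_by_category)) {
                        as.integer(fit$n_tracts_by_category[cc])
                      } else NA_integer_)
    for (k in seq_along(years)) {
      row[[paste0("level_", years[k])]] <- lv[k]
      row[[paste0("sig_", years[k])]] <- st[k]
    }
    row$slope <- sl["estimate"]
    row$slope_se <- sl["se"]
    row$slope_sig <- star(slope_contr, cc)
    row
  })
  levels_df <- do.call(rbind, rows)
  overall_p <- c(stats::setNames(
    vapply(years, function(y) overall_level_test(fit, y)["p"], 0),
    paste0("level_", years)),
    slope = unname(overall_slope_test(fit)["p"]))
  structure(list(levels = levels_df, overall_p = overall_p,
                 contrasts = c(lev_contr, list(slope = slope_contr)),
                 years = years, alpha = alpha, fit = fit),
            class = "trend_table")
}

#' @export
print.trend_table <- function(x, ...) {
  cat(sprintf("<trend_table> ref=%s; overall p: %s\n", x$fit$reference,
              paste(sprintf("%s=%.4g", names(x$overall_p), x$overall_p),
                    collapse = ", ")))
  df <- x$levels
  for (cl in grep("^level_|^slope$|^slope_se$", names(df), value = TRUE)) {
    df[[cl]] <- round(df[[cl]], 2)
  }
  print(df, row.names = FALSE)
  cat(sprintf("  '*' (sig_*) marks Bonferroni-significant contrasts vs %s at alpha/%d\n",
              x$fit$reference, attr(x$contrasts$slope, "m")))
  invisible(x)
}
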