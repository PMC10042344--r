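# Posterior mortality surfaces, regional/national rate tables, trend
# summaries and map export.

#' Predict the posterior mortality surface
#'
#' For each posterior draw and grid cell computes
#' `p = inv_logit(alpha_survey + x_cell' beta + zeta_cell)` — covariates
#' standardized with the training record stored in the fit — and summarizes
#' cell-wise into posterior mean and equal-tailed 95% bounds. Cells with any
#' NODATA covariate are masked.
#'
#' @param fit a [fit_mortality()] result.
#' @param rasters a [raster_stack()] covering at least the fitted covariates,
#'   on the fitted grid (any grid for non-spatial fits).
#' @param survey survey year to predict (default: the last fitted survey).
#' @param level credible level for the bounds.
#' @return object of class `geomort_surface`: `mean`, `lower`, `upper` as
#'   [grid_raster()]s of probabilities, `rate_*` accessors in per-1000 units
#'   via [surface_rate()], plus `survey`.
#' @export
predict_surface <- function(fit, rasters, survey = NULL, level = 0.95) {
  stopifnot(inherits(fit, "geomort_fit"), inherits(rasters, "geomort_stack"))
  survey <- survey %||% fit$survey_years[length(fit$survey_years)]
  if (!survey %in% fit$survey_years) {
    stop("survey ", survey, " was not fitted (have: ",
         paste(fit$survey_years, collapse = ", "), ")")
  }
  grid <- stack_grid(rasters)
  covs <- fit$design_record$covariates
  if (!all(covs %in% names(rasters))) {
    stop("rasters missing fitted covariates: ",
         paste(setdiff(covs, names(rasters)), collapse = ", "))
  }
  ncells <- length(grid$values)
  if (fit$spatial && ncells != ncol(fit$draws$zeta)) {
    stop("raster grid does not match the fitted lattice")
  }

  Xc <- if (length(covs)) {
    matrix(vapply(covs, function(nm) as.vector(rasters[[nm]]$values),
                  numeric(ncells)),
           nrow = ncells, ncol = length(covs), dimnames = list(NULL, covs))
  } else matrix(0, ncells, 0)
  valid <- if (ncol(Xc)) rowSums(is.na(Xc)) == 0 else rep(TRUE, ncells)
  if (ncol(Xc)) {
    Xc <- standardize_design(Xc[valid, , drop = FALSE],
                             center = fit$design_record$center,
                             scale = fit$design_record$scale)
  } else Xc <- Xc[valid, , drop = FALSE]

  a <- fit$draws$alpha[, as.character(survey)]
  S <- length(a)
  eta <- matrix(a, S, sum(valid))
  if (ncol(Xc)) eta <- eta + fit$draws$beta %*% t(Xc)
  if (fit$spatial) eta <- eta + fit$draws$zeta[, valid, drop = FALSE]
  p <- inv_logit(eta)

  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  put <- function(v) {
    full <- rep(NA_real_, ncells); full[valid] <- v
    grid_raster(matrix(full, nrow(grid$values), ncol(grid$values)),
                xll = grid$xll, yll = grid$yll, cellsize = grid$cellsize)
  }
  structure(list(
    mean = put(colMeans(p)),
    lower = put(apply(p, 2, stats::quantile, probs = qs[1])),
    upper = put(apply(p, 2, stats::quantile, probs = qs[2])),
    survey = survey, level = level
  ), class = "geomort_surface")
}

#' @export
print.geomort_surface <- function(x, ...) {
  v <- x$mean$values
  cat(sprintf(
    "<geomort_surface> survey %s, %d x %d cells; mean rate %.1f per 1000 (range %.1f-%.1f)\n",
    x$survey, nrow(v), ncol(v), 1000 * mean(v, na.rm = TRUE),
    1000 * min(v, na.rm = TRUE), 1000 * max(v, na.rm = TRUE)))
  invisible(x)
}

#' Surface in deaths per 1000 live births
#'
#' @param surface a [predict_surface()] result.
#' @param which one of `"mean"`, `"lower"`, `"upper"`.
#' @return a [grid_raster()] scaled to per-1000 units.
#' @export
surface_rate <- function(surface, which = "mean") {
  r <- surface[[match.arg(which, c("mean", "lower", "upper"))]]
  grid_raster(1000 * r$values, r$xll, r$yll, r$cellsize, r$nodata)
}

#' Aggregate a mortality surface over regions
#'
#' Assigns grid cells to regions by cell center, then averages the posterior
#' mean probability (weighted by a population raster when given, else
#' uniformly) into a per-1000 rate per region, plus the national rate over
#' all assigned cells. Cells assigned to no region are counted, reported via
#' an attribute, and excluded.
#'
#' @param surfaces a single [predict_surface()] result or a list of them
#'   (one column per surface, named by survey).
#' @param regions a `geomort_regions` object.
#' @param weights optional population [grid_raster()] on the same grid.
#' @return data.frame: one row per region plus `"National"`, one column per
#'   survey, entries deaths per 1000 live births; attribute
#'   `"n_unassigned"` counts cells outside all regions.
#' @export
aggregate_regions <- function(surfaces, regions, weights = NULL) {
  if (inherits(surfaces, "geomort_surface")) surfaces <- list(surfaces)
  stopifnot(length(surfaces) >= 1, inherits(regions, "geomort_regions"))
  grid <- surfaces[[1]]$mean
  assignment <- assign_cells(grid, regions)
  wvec <- if (is.null(weights)) rep(1, length(assignment)) else {
    if (!identical(dim(weights$values), dim(grid$values))) {
      stop("population weights are not on the surface grid")
    }
    as.vector(weights$values)
  }

  cols <- lapply(surfaces, function(s) {
    p <- as.vector(s$mean$values)
    ok <- !is.na(p) & !is.na(wvec)
    reg <- vapply(seq_along(regions), function(k) {
      use <- ok & !is.na(assignment) & assignment == k
      if (!any(use)) return(NA_real_)
      1000 * stats::weighted.mean(p[use], wvec[use])
    }, 0)
    nat <- 1000 * stats::weighted.mean(p[ok & !is.na(assignment)],
                                       wvec[ok & !is.na(assignment)])
    c(reg, nat)
  })
  out <- data.frame(region = c(vapply(regions, `[[`, "", "name"), "National"))
  years <- vapply(surfaces, function(s) as.character(s$survey), "")
  for (j in seq_along(cols)) out[[years[j]]] <- cols[[j]]
  attr(out, "n_unassigned") <- sum(is.na(assignment))
  out
}

#' National and regional rate table across surveys
#'
#' Predicts a surface per fitted survey and aggregates it over regions:
#' the per-1000 analogue of a national/regional mortality table.
#'
#' @inheritParams predict_surface
#' @param regions a `geomort_regions` object.
#' @param weights optional population [grid_raster()].
#' @return data.frame as in [aggregate_regions()], one column per survey.
#' @export
rate_table <- function(fit, rasters, regions, weights = NULL) {
  surfaces <- lapply(fit$survey_years, function(yr) {
    predict_surface(fit, rasters, survey = yr)
  })
  aggregate_regions(surfaces, regions, weights)
}

#' Trend summary of a rate table
#'
#' Absolute and percent change between consecutive surveys and first-to-last
#' per row, a monotone-decline flag, and a stagnation flag raised when the
#' change between the last two surveys is below 5% of the earlier value.
#'
#' @param rates data.frame from [aggregate_regions()]/[rate_table()]: a
#'   `region` column plus one numeric column per survey (in time order).
#' @param stagnation_tol relative-change threshold for stagnation (0.05).
#' @return list with `summary` (per-region first-to-last change, percent
#'   change, `monotone_decreasing`, `stagnant_last`) and `steps`
#'   (per-region consecutive changes).
#' @export
trend_table <- function(rates, stagnation_tol = 0.05) {
  stopifnot(is.data.frame(rates), "region" %in% names(rates))
  ycols <- setdiff(names(rates), "region")
  if (length(ycols) < 2) stop("trend needs at least 2 surveys")
  M <- as.matrix(rates[ycols])
  steps <- do.call(rbind, lapply(seq_len(nrow(M)), function(i) {
    data.frame(
      region = rates$region[i],
      from = ycols[-length(ycols)], to = ycols[-1],
      change = diff(M[i, ]),
      pct_change = 100 * diff(M[i, ]) / M[i, -length(ycols)],
      row.names = NULL
    )
  }))
  last_rel <- abs(M[, length(ycols)] - M[, length(ycols) - 1]) /
    M[, length(ycols) - 1]
  summary <- data.frame(
    region = rates$region,
    first = M[, 1], last = M[, length(ycols)],
    change = M[, length(ycols)] - M[, 1],
    pct_change = 100 * (M[, length(ycols)] - M[, 1]) / M[, 1],
    monotone_decreasing = apply(M, 1, function(r) all(diff(r) <= 0)),
    stagnant_last = last_rel < stagnation_tol,
    row.names = NULL
  )
  list(summary = summary, steps = steps)
}

#' Export a mortality surface as rasters and a map image
#'
#' Writes the posterior mean and interval bounds as ESRI ASCII grids in
#' per-1000 units, plus a PNG map with a continuous color scale (per-1000
#' legend). NODATA cells are transparent and excluded from the color
#' scaling.
#'
#' @param surface a [predict_surface()] result.
#' @param out_prefix path prefix; files `<prefix>_mean.asc`, `_lower.asc`,
#'   `_upper.asc` and `<prefix>.png` are written.
#' @param width,height PNG size in pixels.
#' @return named character vector of file paths, invisibly.
#' @export
render_maps <- function(surface, out_prefix, width = 900, height = 800) {
  stopifnot(inherits(surface, "geomort_surface"))
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  files <- c(
    mean = paste0(out_prefix, "_mean.asc"),
    lower = paste0(out_prefix, "_lower.asc"),
    upper = paste0(out_prefix, "_upper.asc"),
    png = paste0(out_prefix, ".png")
  )
  for (band in c("mean", "lower", "upper")) {
    write_ascii_grid(surface_rate(surface, band), files[[band]])
  }

  r <- surface_rate(surface, "mean")
  cc <- cell_centers(r)
  cc$rate <- as.vector(r$values)
  lim <- range(cc$rate, na.rm = TRUE)
  gp <- ggplot2::ggplot(cc, ggplot2::aes(x = .data$lon, y = .data$lat,
                                         fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = "Deaths per 1000\nlive births", limits = lim,
      na.value = "transparent"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Predicted under-five mortality, survey %s", surface$survey),
      x = "Longitude", y = "Latitude"
    ) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(files[["png"]], gp, width = width / 100, height = height / 100,
                  dpi = 100, bg = "white")
  invisible(files)
}

#' Histogram of PIT values
#'
#' Visual calibration check: mid-PIT values of a well-calibrated model are
#' approximately Uniform(0, 1).
#'
#' @param pit numeric vector from [compute_pit()].
#' @param path output PNG path.
#' @param bins histogram bins.
#' @return `path`, invisibly.
#' @export
plot_pit <- function(pit, path, bins = 20) {
  df <- data.frame(pit = pit)
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pit)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, length.out = bins + 1),
                            fill = "steelblue", color = "white") +
    ggplot2::geom_hline(yintercept = length(pit) / bins, linetype = 2) +
    ggplot2::labs(x = "PIT", y = "Count",
                  title = "Leave-one-out mid-PIT calibration") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, gp, width = 6, height = 4, dpi = 100, bg = "white")
  invisible(path)
}
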