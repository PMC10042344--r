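# Covariate extraction at cluster locations, the collinearity screen, and
# design-matrix standardization.

check_clusters <- function(clusters) {
  needed <- c("survey_year", "cluster_id", "lon", "lat", "births", "deaths")
  missing <- setdiff(needed, names(clusters))
  if (length(missing)) stop("cluster table lacks columns: ", paste(missing, collapse = ", "))
  if (any(clusters$births < 1)) stop("every modeled cluster needs births >= 1")
  if (any(clusters$deaths < 0 | clusters$deaths > clusters$births)) {
    stop("deaths must satisfy 0 <= deaths <= births")
  }
  invisible(clusters)
}

#' Extract raster covariate values at cluster locations
#'
#' Reads the nearest-cell value of every covariate at each cluster's
#' coordinates (no interpolation; points on a cell boundary resolve to the
#' lower row/column index). Clusters outside the raster extent, or landing on
#' NODATA cells, raise errors naming the offending `cluster_id`s.
#'
#' @param clusters cluster table (`survey_year`, `cluster_id`, `lon`, `lat`,
#'   `births`, `deaths`).
#' @param rasters a [raster_stack()] of covariates.
#' @return numeric matrix (clusters x covariates) with the cluster-to-cell
#'   map in attribute `"cell"` and the grid in attribute `"grid"`.
#' @export
extract_covariates <- function(clusters, rasters) {
  check_clusters(clusters)
  stopifnot(inherits(rasters, "geomort_stack"))
  grid <- stack_grid(rasters)
  idx <- cell_index(grid, clusters$lon, clusters$lat)
  if (any(!idx$inside)) {
    stop("clusters outside the raster extent: ",
         paste(clusters$cluster_id[!idx$inside], collapse = ", "))
  }
  X <- vapply(rasters, function(r) r$values[cbind(idx$row, idx$col)],
              numeric(nrow(clusters)))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(rasters)))
  for (nm in colnames(X)) {
    if (all(is.na(rasters[[nm]]$values))) {
      stop("covariate '", nm, "' is NODATA everywhere")
    }
    bad <- is.na(X[, nm])
    if (any(bad)) {
      stop("covariate '", nm, "' is NODATA at clusters: ",
           paste(clusters$cluster_id[bad], collapse = ", "))
    }
  }
  attr(X, "cell") <- idx$cell
  attr(X, "grid") <- grid
  X
}

#' Pairwise-correlation screen for collinear covariates
#'
#' Computes the full Pearson correlation matrix and walks the covariates in
#' declared order: a covariate is excluded when its absolute correlation with
#' any already-retained covariate reaches `threshold` (so of a collinear
#' pair, the later-ordered member is dropped). Zero-variance columns are
#' excluded first with their own reason. The screen is idempotent: screening
#' the retained set again excludes nothing.
#'
#' @param design numeric matrix of covariate values (clusters x covariates).
#' @param threshold absolute-correlation cutoff, default 0.8.
#' @param order character vector giving the declared covariate order; default
#'   the column order of `design`.
#' @return object of class `geomort_screen`: `retained` (character),
#'   `correlation` (full matrix), `exclusions` (data.frame with columns
#'   `covariate`, `reason`, `paired_with`, `r`).
#' @export
correlation_screen <- function(design, threshold = 0.8, order = colnames(design)) {
  stopifnot(is.matrix(design), ncol(design) >= 1, threshold > 0)
  if (ncol(design) >= 2 && nrow(design) < 3) {
    stop("need at least 3 rows to estimate correlations")
  }
  if (!setequal(order, colnames(design))) {
    stop("`order` must be a permutation of the design's column names")
  }
  sds <- apply(design, 2, stats::sd)
  C <- suppressWarnings(stats::cor(design))
  exclusions <- data.frame(covariate = character(), reason = character(),
                           paired_with = character(), r = numeric())
  retained <- character()
  for (v in order) {
    if (!is.finite(sds[v]) || sds[v] == 0) {
      exclusions <- rbind(exclusions, data.frame(
        covariate = v, reason = "zero variance", paired_with = NA_character_,
        r = NA_real_))
      next
    }
    hit <- retained[abs(C[v, retained]) >= threshold]
    if (length(hit)) {
      worst <- hit[which.max(abs(C[v, hit]))]
      exclusions <- rbind(exclusions, data.frame(
        covariate = v, reason = "collinear", paired_with = worst,
        r = C[v, worst]))
    } else {
      retained <- c(retained, v)
    }
  }
  structure(list(retained = retained, correlation = C, exclusions = exclusions,
                 threshold = threshold),
            class = "geomort_screen")
}

#' @export
print.geomort_screen <- function(x, ...) {
  cat(sprintf("<geomort_screen> |r| >= %g: %d retained, %d excluded\n",
              x$threshold, length(x$retained), nrow(x$exclusions)))
  if (nrow(x$exclusions)) {
    for (i in seq_len(nrow(x$exclusions))) {
      e <- x$exclusions[i, ]
      if (e$reason == "collinear") {
        cat(sprintf("  - %s excluded: r = %.5f with %s\n", e$covariate, e$r,
                    e$paired_with))
      } else {
        cat(sprintf("  - %s excluded: %s\n", e$covariate, e$reason))
      }
    }
  }
  invisible(x)
}

#' Write the correlation matrix and exclusion report
#'
#' @param screen a [correlation_screen()] result.
#' @param cor_csv path for the correlation-matrix CSV.
#' @param report_txt optional path for a plain-text exclusion report.
#' @return `screen`, invisibly.
#' @export
write_screen_report <- function(screen, cor_csv, report_txt = NULL) {
  utils::write.csv(screen$correlation, cor_csv)
  if (!is.null(report_txt)) {
    con <- file(report_txt, "w")
    on.exit(close(con))
    writeLines(utils::capture.output(print(screen)), con)
  }
  invisible(screen)
}

#' Standardize a design matrix
#'
#' Centers and scales each column by its own mean and standard deviation and
#' stores the record (attributes `"center"`, `"scale"`) for prediction-time
#' reuse and back-transformation. Coefficients fitted on the result are
#' per-SD effects.
#'
#' @param design numeric matrix (clusters x retained covariates).
#' @param center,scale optional stored records (reuse the training record at
#'   prediction time); computed from `design` when `NULL`.
#' @return standardized matrix with attributes `"center"` and `"scale"`
#'   (cluster-to-cell and grid attributes are carried through).
#' @export
standardize_design <- function(design, center = NULL, scale = NULL) {
  stopifnot(is.matrix(design))
  if (is.null(center)) center <- colMeans(design)
  if (is.null(scale)) scale <- apply(design, 2, stats::sd)
  if (any(!is.finite(scale) | scale == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(design)[!is.finite(scale) | scale == 0], collapse = ", "),
         "; exclude them before standardizing")
  }
  Xs <- sweep(sweep(design, 2, center), 2, scale, "/")
  attr(Xs, "center") <- center
  attr(Xs, "scale") <- scale
  attr(Xs, "cell") <- attr(design, "cell")
  attr(Xs, "grid") <- attr(design, "grid")
  Xs
}

#' Back-transform a standardized design matrix
#'
#' @param design a matrix produced by [standardize_design()].
#' @return the matrix on its original scale.
#' @export
unstandardize_design <- function(design) {
  center <- attr(design, "center"); scale <- attr(design, "scale")
  if (is.null(center) || is.null(scale)) stop("no standardization record found")
  out <- sweep(sweep(design, 2, scale, "*"), 2, center, "+")
  attr(out, "center") <- NULL
  attr(out, "scale") <- NULL
  out
}
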