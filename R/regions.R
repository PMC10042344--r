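# Region polygons: GeoJSON FeatureCollection I/O and cell assignment.

#' Build rectangular regions partitioning a grid
#'
#' Splits the raster extent into an `nx` by `ny` grid of rectangular regions,
#' a stand-in for administrative polygons in synthetic studies.
#'
#' @param raster a [grid_raster()] defining the extent.
#' @param nx,ny number of region columns/rows.
#' @param names optional character vector of `nx * ny` region names.
#' @return object of class `geomort_regions`: a list of regions, each with
#'   `name` and closed ring coordinates `x`, `y`.
#' @export
make_regions <- function(raster, nx = 2, ny = 2, names = NULL) {
  ext <- raster_extent(raster)
  xs <- seq(ext["xmin"], ext["xmax"], length.out = nx + 1)
  ys <- seq(ext["ymin"], ext["ymax"], length.out = ny + 1)
  k <- 0
  regions <- list()
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      k <- k + 1
      nm <- if (is.null(names)) sprintf("Region %d", k) else names[k]
      regions[[k]] <- list(
        name = nm,
        x = c(xs[i], xs[i + 1], xs[i + 1], xs[i], xs[i]),
        y = c(ys[j], ys[j], ys[j + 1], ys[j + 1], ys[j])
      )
    }
  }
  structure(regions, class = "geomort_regions")
}

#' @export
print.geomort_regions <- function(x, ...) {
  cat(sprintf("<geomort_regions> %d regions: %s\n", length(x),
              paste(vapply(x, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

#' Write regions as a GeoJSON FeatureCollection
#'
#' @param regions a [make_regions()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions_geojson <- function(regions, path) {
  features <- lapply(regions, function(r) {
    ring <- lapply(seq_along(r$x), function(i) c(r$x[i], r$y[i]))
    list(
      type = "Feature",
      properties = list(region_name = r$name),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a GeoJSON FeatureCollection of region polygons
#'
#' Only Polygon geometries are supported; the first (outer) ring is used and
#' the `region_name` property names each region.
#'
#' @param path GeoJSON file.
#' @return a `geomort_regions` object.
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) stop("expected a FeatureCollection")
  regions <- lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    if (!identical(f$geometry$type, "Polygon")) {
      stop("feature ", i, ": only Polygon geometries are supported")
    }
    ring <- f$geometry$coordinates[[1]]
    list(
      name = f$properties$region_name %||% sprintf("Region %d", i),
      x = vapply(ring, function(p) as.numeric(p[[1]]), 0),
      y = vapply(ring, function(p) as.numeric(p[[2]]), 0)
    )
  })
  structure(regions, class = "geomort_regions")
}

# even-odd rule point-in-polygon, vectorized over points; boundary points
# count as inside on the lower/left edges (consistent with partitions)
point_in_polygon <- function(px, py, poly_x, poly_y) {
  inside <- logical(length(px))
  n <- length(poly_x)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]
    xj <- poly_x[j]; yj <- poly_y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# assign cell centers to regions; first matching region wins
assign_cells <- function(raster, regions) {
  cc <- cell_centers(raster)
  assignment <- rep(NA_integer_, nrow(cc))
  for (k in seq_along(regions)) {
    todo <- is.na(assignment)
    if (!any(todo)) break
    hit <- point_in_polygon(cc$lon[todo], cc$lat[todo],
                            regions[[k]]$x, regions[[k]]$y)
    assignment[which(todo)[hit]] <- k
  }
  assignment
}
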