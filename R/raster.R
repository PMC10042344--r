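# Minimal single-band raster container on a regular lon/lat grid, plus
# ESRI ASCII grid I/O. Values are stored as a matrix whose first row is the
# NORTHERNMOST row (the ESRI ASCII convention); cells are addressed either by
# (row, col) or by a column-major vector index (`as.vector` of the matrix).

#' Create a grid raster
#'
#' A lightweight single-band raster: a numeric matrix (row 1 = northernmost
#' row) plus the grid geometry of an ESRI ASCII header. `NA` encodes NODATA.
#'
#' @param values numeric matrix, row 1 = top (north).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize cell edge length (degrees or km; any consistent unit).
#' @param nodata value used for NODATA on disk (in memory always `NA`).
#' @return an object of class `geomort_raster`.
#' @export
grid_raster <- function(values, xll = 0, yll = 0, cellsize = 1, nodata = -9999) {
  values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) < 1) stop("raster must have positive dimensions")
  stopifnot(is.numeric(cellsize), cellsize > 0)
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize, nodata = nodata),
    class = "geomort_raster"
  )
}

#' @export
print.geomort_raster <- function(x, ...) {
  cat(sprintf(
    "<geomort_raster> %d x %d cells, cellsize %g, origin (%g, %g), %d NODATA\n",
    nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll, sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.geomort_raster <- function(x) dim(x$values)

raster_extent <- function(r) {
  c(
    xmin = r$xll, xmax = r$xll + ncol(r$values) * r$cellsize,
    ymin = r$yll, ymax = r$yll + nrow(r$values) * r$cellsize
  )
}

#' Locate grid cells for point coordinates
#'
#' Maps lon/lat points to (row, col) indices of their nearest cell.
#' Points on a cell boundary are assigned by rounding the fractional index
#' half-down, i.e. the lower of the two candidate indices wins.
#'
#' @param raster a [grid_raster()].
#' @param lon,lat point coordinates.
#' @return list with integer vectors `row`, `col`, `cell` (column-major index)
#'   and logical `inside`.
#' @export
cell_index <- function(raster, lon, lat) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  fx <- (lon - raster$xll) / raster$cellsize
  fy <- (raster$yll + nr * raster$cellsize - lat) / raster$cellsize
  inside <- fx >= 0 & fx <= nc & fy >= 0 & fy <= nr
  col <- pmax(1L, as.integer(ceiling(fx)))
  row <- pmax(1L, as.integer(ceiling(fy)))
  col[!inside] <- NA_integer_
  row[!inside] <- NA_integer_
  list(row = row, col = col, cell = (col - 1L) * nr + row, inside = inside)
}

#' Coordinates of cell centers
#'
#' @param raster a [grid_raster()].
#' @return data.frame with `cell`, `row`, `col`, `lon`, `lat` in column-major
#'   cell order (matching `as.vector(raster$values)`).
#' @export
cell_centers <- function(raster) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  data.frame(
    cell = seq_len(nr * nc), row = row, col = col,
    lon = raster$xll + (col - 0.5) * raster$cellsize,
    lat = raster$yll + (nr - row + 0.5) * raster$cellsize
  )
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param raster a [grid_raster()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  v <- raster$values
  v[is.na(v)] <- raster$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.12g", raster$xll),
    sprintf("yllcorner %.12g", raster$yll),
    sprintf("cellsize %.12g", raster$cellsize),
    sprintf("NODATA_value %.12g", raster$nodata)
  ), con)
  utils::write.table(
    format(v, digits = 17, scientific = TRUE, trim = TRUE),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return a [grid_raster()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[key]])) stop("missing ESRI ASCII header field: ", key)
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ESRI ASCII grid: expected ", hdr$ncols * hdr$nrows, " values, got ", length(vals))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  grid_raster(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cellsize = hdr$cellsize, nodata = nodata)
}

#' Bundle aligned rasters into a covariate stack
#'
#' @param ... named [grid_raster()] objects (or a single named list) sharing
#'   the same grid geometry.
#' @return an object of class `geomort_stack` (a named list of rasters).
#' @export
raster_stack <- function(...) {
  rasters <- list(...)
  if (length(rasters) == 1 && !inherits(rasters[[1]], "geomort_raster")) {
    rasters <- rasters[[1]]
  }
  if (is.null(names(rasters)) || any(names(rasters) == "")) {
    stop("all rasters in a stack must be named")
  }
  ref <- rasters[[1]]
  for (nm in names(rasters)) {
    r <- rasters[[nm]]
    if (!inherits(r, "geomort_raster")) stop("'", nm, "' is not a grid_raster")
    if (!identical(dim(r$values), dim(ref$values)) ||
        !isTRUE(all.equal(c(r$xll, r$yll, r$cellsize), c(ref$xll, ref$yll, ref$cellsize)))) {
      stop("raster '", nm, "' does not share the stack geometry")
    }
  }
  structure(rasters, class = "geomort_stack")
}

#' @export
print.geomort_stack <- function(x, ...) {
  cat(sprintf("<geomort_stack> %d covariates on a %d x %d grid: %s\n",
              length(x), nrow(x[[1]]$values), ncol(x[[1]]$values),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Grid geometry of a covariate stack
#'
#' @param stack a [raster_stack()].
#' @return the first raster, defining the shared grid.
#' @export
stack_grid <- function(stack) stack[[1]]
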