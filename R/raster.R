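## Minimal single-band geographic raster container on a regular lon/lat
## grid (EPSG:4326), stored row 1 = northernmost row, plus plain-text
## ESRI ASCII grid (.asc) input/output.

#' Construct a grid raster
#'
#' @param values numeric matrix; row 1 is the northernmost (top) row.
#' @param xmin,ymin lower-left corner of the grid (degrees).
#' @param res square cell size in degrees.
#' @param name covariate name.
#' @param units unit string (e.g. `"degC"`, `"mm"`).
#' @return object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin, ymin, res, name = "layer", units = "") {
  stopifnot(is.matrix(values), res > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, res = res,
         nrow = nrow(values), ncol = ncol(values),
         name = name, units = units),
    class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %s [%s]: %d x %d cells, res %g deg, origin (%g, %g)\n",
              x$name, x$units, x$nrow, x$ncol, x$res, x$xmin, x$ymin))
  invisible(x)
}

raster_xmax <- function(r) r$xmin + r$ncol * r$res
raster_ymax <- function(r) r$ymin + r$nrow * r$res

#' Cell-centre coordinates of a raster
#'
#' @param r a `grid_raster`.
#' @return list with vectors `lon` (length ncol, west to east) and `lat`
#'   (length nrow, north to south, matching the row order of `r$values`).
#' @export
raster_coords <- function(r) {
  list(lon = r$xmin + (seq_len(r$ncol) - 0.5) * r$res,
       lat = raster_ymax(r) - (seq_len(r$nrow) - 0.5) * r$res)
}

# Row/col of the cells containing lon/lat points; NA outside the extent.
raster_cell <- function(r, lonlat) {
  if (is.null(dim(lonlat))) lonlat <- matrix(lonlat, ncol = 2)
  col <- floor((lonlat[, 1] - r$xmin) / r$res) + 1
  row <- floor((raster_ymax(r) - lonlat[, 2]) / r$res) + 1
  bad <- col < 1 | col > r$ncol | row < 1 | row > r$nrow
  col[bad] <- NA; row[bad] <- NA
  cbind(row = row, col = col)
}

#' Raster value at point locations (containing cell)
#'
#' @param r a `grid_raster`.
#' @param lonlat n x 2 matrix of lon/lat.
#' @return numeric vector; NA outside the extent.
#' @export
raster_value_at <- function(r, lonlat) {
  rc <- raster_cell(r, lonlat)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc[, 1])
  out[ok] <- r$values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Build a raster by evaluating a function of (lon, lat)
#'
#' @param bbox c(xmin, xmax, ymin, ymax) in degrees.
#' @param res cell size in degrees; guarded against absurdly fine grids.
#' @param f vectorised function `f(lon, lat)`.
#' @inheritParams grid_raster
#' @export
raster_from_function <- function(bbox, res, f, name = "layer", units = "") {
  width <- bbox[2] - bbox[1]; height <- bbox[4] - bbox[3]
  if (width <= 0 || height <= 0) stop("degenerate bbox: zero area")
  if (res < width / 10000 || res < height / 10000)
    stop("resolution finer than 1/10000 of the bbox; refusing (resource guard)")
  ncol <- max(1L, as.integer(ceiling(width / res)))
  nrow <- max(1L, as.integer(ceiling(height / res)))
  lon <- bbox[1] + (seq_len(ncol) - 0.5) * res
  lat <- (bbox[3] + nrow * res) - (seq_len(nrow) - 0.5) * res
  vals <- outer(lat, lon, function(la, lo) f(lo, la))
  grid_raster(vals, bbox[1], bbox[3], res, name = name, units = units)
}

#' Write a raster as an ESRI ASCII grid (.asc)
#'
#' Plain-text interchange format readable by standard GIS tooling.
#'
#' @param r a `grid_raster`.
#' @param path output path.
#' @param nodata value standing in for NA cells.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", r$ncol),
    sprintf("nrows %d", r$nrow),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$res),
    sprintf("NODATA_value %g", nodata)), con)
  v <- r$values
  v[is.na(v)] <- nodata
  for (i in seq_len(nrow(v)))
    writeLines(paste(formatC(v[i, ], format = "g", digits = 10), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid (.asc)
#'
#' @param path file path.
#' @param name,units metadata attached to the result.
#' @return a `grid_raster` with nodata cells as NA.
#' @export
read_asc <- function(path, name = NULL, units = "") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  stopifnot(nrow(vals) == hdr$nrows, ncol(vals) == hdr$ncols)
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  grid_raster(vals, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
              name = name %||% sub("\\.asc$", "", basename(path)), units = units)
}
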