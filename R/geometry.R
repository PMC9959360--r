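## Planar polygon utilities used by the admin-map generator, pixel masking
## and admin aggregation. Polygons are plain n x 2 matrices of (lon, lat)
## vertices, open rings (first vertex not repeated), oriented either way.

#' Signed/absolute polygon area (shoelace formula)
#'
#' @param poly n x 2 matrix of vertices (open ring).
#' @param signed return the signed area (positive for counter-clockwise)?
#' @return area in squared coordinate units.
#' @export
polygon_area <- function(poly, signed = FALSE) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- sum(x * yn - xn * y) / 2
  if (signed) a else abs(a)
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-14) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Clip polygon against half-plane {a x + b y <= c} (Sutherland-Hodgman step).
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  f <- a * poly[, 1] + b * poly[, 2] - c    # <= 0 means keep
  out <- matrix(0, n + 4, 2)
  k <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    fi <- f[i]; fj <- f[j]
    if (fi <= 0) { k <- k + 1; out[k, ] <- poly[i, ] }
    if ((fi < 0 && fj > 0) || (fi > 0 && fj < 0)) {
      t <- fi / (fi - fj)
      k <- k + 1
      out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

# Voronoi cell of seeds[i, ] within convex region poly, by bisector clipping.
voronoi_cell <- function(i, seeds, region) {
  p <- seeds[i, ]
  cell <- region
  for (j in seq_len(nrow(seeds))) {
    if (j == i || nrow(cell) == 0) next
    q <- seeds[j, ]
    d <- q - p
    # keep points x with |x-p| <= |x-q|  <=>  2 d.x <= |q|^2 - |p|^2
    cell <- clip_halfplane(cell, 2 * d[1], 2 * d[2],
                           sum(q^2) - sum(p^2))
  }
  cell
}

#' Test points against a polygon (even-odd ray casting)
#'
#' Vectorised over points; boundary points count as inside (within a small
#' tolerance handled by the crossing rule).
#'
#' @param pts n x 2 matrix (or length-2 vector) of lon/lat points.
#' @param poly polygon as an n x 2 matrix, open ring.
#' @return logical vector.
#' @export
point_in_polygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  px <- pts[, 1]; py <- pts[, 2]
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

#' Rectangle polygon from a bounding box
#'
#' @param bbox c(xmin, xmax, ymin, ymax).
#' @return 4 x 2 vertex matrix (open ring).
#' @export
bbox_polygon <- function(bbox) {
  cbind(c(bbox[1], bbox[2], bbox[2], bbox[1]),
        c(bbox[3], bbox[3], bbox[4], bbox[4]))
}

# Uniform points inside a polygon by rejection from its bounding box.
runif_in_polygon <- function(n, poly) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(NA_real_, n, 2)
  got <- 0
  guard <- 0
  while (got < n) {
    guard <- guard + 1
    if (guard > 10000) stop("rejection sampling failed: degenerate polygon?")
    m <- max(2 * (n - got), 16)
    cand <- cbind(runif(m, xr[1], xr[2]), runif(m, yr[1], yr[2]))
    ok <- point_in_polygon(cand, poly)
    take <- min(sum(ok), n - got)
    if (take > 0) {
      out[(got + 1):(got + take), ] <- cand[which(ok)[seq_len(take)], , drop = FALSE]
      got <- got + take
    }
  }
  out
}

## ---- GeoJSON ----------------------------------------------------------

#' Write polygons to a GeoJSON FeatureCollection
#'
#' @param polys list of n x 2 matrices (open rings).
#' @param properties data.frame with one row per polygon.
#' @param path output file.
#' @export
write_geojson <- function(polys, properties, path) {
  feats <- lapply(seq_along(polys), function(i) {
    ring <- polys[[i]]
    ring <- rbind(ring, ring[1, ])  # close the ring per GeoJSON spec
    list(
      type = "Feature",
      properties = as.list(properties[i, , drop = FALSE]),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(k)
          as.numeric(ring[k, ])))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' @param path GeoJSON file with Polygon features.
#' @return list with `polys` (list of matrices, outer rings, unclosed) and
#'   `properties` (data.frame).
#' @export
read_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  stopifnot(identical(fc$type, "FeatureCollection"))
  polys <- lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  })
  props <- do.call(rbind, lapply(fc$features, function(f)
    as.data.frame(f$properties, stringsAsFactors = FALSE)))
  list(polys = polys, properties = props)
}
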