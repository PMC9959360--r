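#' Generate a nested two-level administrative map
#'
#' Partitions the configured bounding box into `n_admin1` first-level
#' polygons, each subdivided into `n_admin2_per_admin1` second-level
#' polygons, by Voronoi tessellation of uniformly drawn seed points
#' (clipped by half-plane intersection). With 37 first-level units of
#' ~21 subdivisions each the structure mirrors a country of 37 states
#' and 774 local government areas. All polygons are convex, valid,
#' mutually non-overlapping and jointly cover the bbox.
#'
#' @param config a [sim_config()].
#' @return an `admin_map`: list with `bbox`, `admin1` (ids + polygons)
#'   and `admin2` (ids, admin1 ids + polygons).
#' @export
generate_admin_map <- function(config) {
  bb <- config$domain_bbox
  if (bb[2] <= bb[1] || bb[4] <= bb[3]) stop("invalid-domain: degenerate bbox")
  region <- bbox_polygon(bb)
  with_seed(config$seed, {
    n1 <- config$n_admin1
    n2 <- config$n_admin2_per_admin1
    if (n1 == 1L) {
      polys1 <- list(region)
    } else {
      seeds1 <- cbind(runif(n1, bb[1], bb[2]), runif(n1, bb[3], bb[4]))
      polys1 <- lapply(seq_len(n1), voronoi_cell, seeds = seeds1, region = region)
    }
    ids1 <- sprintf("A%02d", seq_len(n1))
    polys2 <- list(); ids2 <- character(); parent2 <- character()
    for (i in seq_len(n1)) {
      cell <- polys1[[i]]
      if (n2 == 1L) {
        sub <- list(cell)
      } else {
        seeds2 <- runif_in_polygon(n2, cell)
        sub <- lapply(seq_len(n2), voronoi_cell, seeds = seeds2, region = cell)
      }
      polys2 <- c(polys2, sub)
      ids2 <- c(ids2, sprintf("%s-L%02d", ids1[i], seq_len(n2)))
      parent2 <- c(parent2, rep(ids1[i], n2))
    }
  })
  structure(list(
    bbox = bb,
    admin1 = list(ids = ids1, polys = polys1),
    admin2 = list(ids = ids2, admin1_ids = parent2, polys = polys2)
  ), class = "admin_map")
}

#' @export
print.admin_map <- function(x, ...) {
  cat(sprintf("<admin_map> %d level-1 / %d level-2 units over bbox [%g, %g] x [%g, %g]\n",
              length(x$admin1$ids), length(x$admin2$ids),
              x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4]))
  invisible(x)
}

#' Write one level of an admin map to GeoJSON
#'
#' @param map an `admin_map`.
#' @param path output file.
#' @param level 1 or 2.
#' @export
write_admin_geojson <- function(map, path, level = 2) {
  if (level == 1) {
    write_geojson(map$admin1$polys,
                  data.frame(id = map$admin1$ids, stringsAsFactors = FALSE),
                  path)
  } else {
    write_geojson(map$admin2$polys,
                  data.frame(id = map$admin2$ids,
                             admin1_id = map$admin2$admin1_ids,
                             stringsAsFactors = FALSE),
                  path)
  }
}

# Locate points in admin units; returns character ids (NA when outside).
locate_admin <- function(map, lonlat, level = 2) {
  if (is.null(dim(lonlat))) lonlat <- matrix(lonlat, ncol = 2)
  polys <- if (level == 1) map$admin1$polys else map$admin2$polys
  ids <- if (level == 1) map$admin1$ids else map$admin2$ids
  out <- rep(NA_character_, nrow(lonlat))
  todo <- rep(TRUE, nrow(lonlat))
  for (k in seq_along(polys)) {
    if (!any(todo)) break
    p <- polys[[k]]
    xr <- range(p[, 1]); yr <- range(p[, 2])
    cand <- todo & lonlat[, 1] >= xr[1] - 1e-12 & lonlat[, 1] <= xr[2] + 1e-12 &
      lonlat[, 2] >= yr[1] - 1e-12 & lonlat[, 2] <= yr[2] + 1e-12
    if (!any(cand)) next
    hit <- point_in_polygon(lonlat[cand, , drop = FALSE], p)
    idx <- which(cand)[hit]
    out[idx] <- ids[k]
    todo[idx] <- FALSE
  }
  out
}
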