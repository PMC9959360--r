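## Linkage of climate/urbanisation raster covariates to survey clusters:
## circular-buffer extraction at displaced coordinates (2 km urban /
## 10 km rural, compensating the geo-masking displacement), join by
## cluster id, and the published categorisation schemes.

#' Mean raster value within a circular buffer around a point
#'
#' Averages the cells whose centres fall within a great-circle (haversine)
#' buffer of the point: radius 2 km for urban and 10 km for rural
#' clusters, or an explicit `radius_km`. Nodata (NA) cells are excluded;
#' if the buffer is smaller than one cell the containing cell's value is
#' returned; a buffer that is entirely nodata yields NA.
#'
#' @param raster a `grid_raster`.
#' @param point c(lon, lat).
#' @param urban logical; selects the 2 km (TRUE) / 10 km (FALSE) radius.
#' @param radius_km optional explicit radius overriding `urban`.
#' @return scalar buffer mean (NA if nothing valid in the buffer).
#' @export
extract_buffer_mean <- function(raster, point, urban = FALSE, radius_km = NULL) {
  r_km <- radius_km %||% (if (isTRUE(urban)) 2 else 10)
  xy <- raster_coords(raster)
  lat0 <- point[2]
  dlat <- r_km / 110.574
  dlon <- r_km / (111.320 * max(cos(lat0 * pi / 180), 1e-6))
  ci <- which(xy$lon >= point[1] - dlon - raster$res &
                xy$lon <= point[1] + dlon + raster$res)
  ri <- which(xy$lat >= lat0 - dlat - raster$res &
                xy$lat <= lat0 + dlat + raster$res)
  if (!length(ci) || !length(ri)) return(NA_real_)
  grid <- expand.grid(row = ri, col = ci)
  d <- geosphere::distHaversine(point,
                                cbind(xy$lon[grid$col], xy$lat[grid$row]))
  sel <- d <= r_km * 1000
  if (!any(sel)) {
    # buffer smaller than a cell: take the containing cell
    v <- raster_value_at(raster, matrix(point, ncol = 2))
    return(v)
  }
  vals <- raster$values[cbind(grid$row[sel], grid$col[sel])]
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Link raster covariates to a cluster table
#'
#' Adds one numeric column per raster, computed by [extract_buffer_mean()]
#' at each cluster's displaced coordinates with the urban/rural buffer
#' radius. The augmented table joins onto the child table by `cluster_id`
#' alone. Duplicate cluster ids are a hard error; clusters outside every
#' raster keep their row with NA covariates and a warning.
#'
#' @param clusters cluster table with `cluster_id`, `disp_lon`,
#'   `disp_lat`, `urban` columns (falls back to `lon`/`lat` if no
#'   displaced coordinates are present).
#' @param rasters named list of `grid_raster`s (possibly empty).
#' @param point_value raster names sampled at the cluster point itself
#'   instead of buffer-averaged — appropriate for categorical class
#'   rasters, whose codes must not be averaged (default: the
#'   urbanisation settlement classification).
#' @return `clusters` with the new covariate columns.
#' @export
link_geocovariates <- function(clusters, rasters,
                               point_value = "urbanization") {
  if (anyDuplicated(clusters$cluster_id))
    stop("duplicate cluster id(s): ",
         paste(unique(clusters$cluster_id[duplicated(clusters$cluster_id)]),
               collapse = ", "))
  if (!length(rasters)) return(clusters)
  lon <- clusters$disp_lon %||% clusters$lon
  lat <- clusters$disp_lat %||% clusters$lat
  any_missing <- FALSE
  for (nm in names(rasters)) {
    vals <- if (nm %in% point_value)
      raster_value_at(rasters[[nm]], cbind(lon, lat))
    else
      vapply(seq_len(nrow(clusters)), function(i)
        extract_buffer_mean(rasters[[nm]], c(lon[i], lat[i]),
                            urban = clusters$urban[i]), numeric(1))
    if (anyNA(vals)) any_missing <- TRUE
    clusters[[nm]] <- vals
  }
  if (any_missing)
    warning("some clusters fall outside the raster extent; covariates set to NA")
  clusters
}

#' Categorise continuous climate covariates
#'
#' Applies the published banding: DLST <30 / [30, 35) / >=35 degC;
#' rainfall <142 / [142, 1200) / >=1200 mm; aridity index <17.5 /
#' [17.5, 32.5] / >32.5 (domain [0, 300]); urbanisation class codes
#' 1/2/3 to urban centres / urban clusters / rural villages. Interval
#' ends are half-open as stated, so the bands partition each covariate's
#' domain without gaps.
#'
#' @param values numeric vector (or integer class codes for
#'   `urbanization`).
#' @param scheme one of "dlst", "rainfall", "aridity", "urbanization".
#' @return factor with the catalogue's levels for that covariate.
#' @export
categorize_climate <- function(values, scheme = c("dlst", "rainfall",
                                                  "aridity", "urbanization")) {
  scheme <- match.arg(scheme)
  lv <- covariate_catalog()[[scheme]]$levels
  out <- switch(scheme,
    dlst = {
      if (any(values[!is.na(values)] < -90 | values[!is.na(values)] > 90))
        stop("validation error: DLST outside plausible degC domain")
      cut(values, c(-Inf, 30, 35, Inf), labels = lv, right = FALSE)
    },
    rainfall = {
      if (any(values[!is.na(values)] < 0))
        stop("validation error: negative rainfall")
      cut(values, c(-Inf, 142, 1200, Inf), labels = lv, right = FALSE)
    },
    aridity = {
      if (any(values[!is.na(values)] < 0 | values[!is.na(values)] > 300))
        stop("validation error: aridity index outside [0, 300]")
      # wet > 32.5; semi-arid [17.5, 32.5]; arid < 17.5
      f <- ifelse(values > 32.5, "wet",
                  ifelse(values >= 17.5, "semi_arid", "arid"))
      factor(f, levels = lv)
    },
    urbanization = {
      codes <- as.integer(round(values))
      if (any(!codes[!is.na(codes)] %in% 1:3))
        stop("validation error: urbanization class must be 1, 2 or 3")
      factor(c("urban_centres", "urban_clusters", "rural_villages")[codes],
             levels = lv)
    })
  out
}

#' Attach categorised climate covariates to a linked cluster table
#'
#' Convenience wrapper running [categorize_climate()] on every climate
#' column produced by [link_geocovariates()].
#'
#' @param clusters linked cluster table with numeric `dlst`, `rainfall`,
#'   `aridity`, `urbanization` columns (any subset).
#' @return table with the numeric columns replaced by category factors.
#' @export
categorize_cluster_climate <- function(clusters) {
  for (v in intersect(c("dlst", "rainfall", "aridity", "urbanization"),
                      names(clusters)))
    clusters[[v]] <- categorize_climate(clusters[[v]], v)
  clusters
}
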