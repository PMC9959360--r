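#' Sample survey clusters under a two-stage stratified design
#'
#' Strata are admin-1 units crossed with urban/rural residence. Stratum
#' sizes are simulated as admin-1 polygon area times the urban (or rural)
#' population share, and clusters are allocated to strata proportionally
#' (largest-remainder rounding), emulating selection of enumeration areas
#' with probability proportional to size. Cluster locations are uniform
#' within the stratum polygon; each cluster carries a design weight
#' (stratum share over sampled share, normalised to mean 1) and a child
#' count (Poisson around `children_per_cluster`).
#'
#' @param admin_map an `admin_map` from [generate_admin_map()].
#' @param config a [sim_config()].
#' @return data.frame of cluster sites: `cluster_id`, `admin1_id`,
#'   `admin2_id`, `stratum_id`, `urban`, `lon`, `lat` (true location),
#'   `n_children`, `weight`.
#' @export
sample_clusters <- function(admin_map, config) {
  uf <- config$urban_fraction
  if (config$urban_strata && uf == 0)
    stop("empty-stratum: urban strata requested but urban_fraction = 0")
  n1 <- length(admin_map$admin1$ids)
  areas <- vapply(admin_map$admin1$polys, polygon_area, numeric(1))
  if (config$urban_strata) {
    strata <- data.frame(
      admin1 = rep(admin_map$admin1$ids, each = 2),
      urban = rep(c(TRUE, FALSE), n1),
      size = as.vector(rbind(areas * uf, areas * (1 - uf))),
      stringsAsFactors = FALSE)
    strata <- strata[strata$size > 0, , drop = FALSE]
  } else {
    strata <- data.frame(admin1 = admin_map$admin1$ids, urban = FALSE,
                         size = areas, stringsAsFactors = FALSE)
  }
  if (config$n_clusters < nrow(strata))
    stop("n_clusters (", config$n_clusters, ") below the number of strata (",
         nrow(strata), ")")
  strata$share <- strata$size / sum(strata$size)
  n_alloc <- largest_remainder(config$n_clusters * strata$share)
  # guarantee at least one cluster per stratum
  while (any(n_alloc == 0)) {
    i <- which.max(n_alloc); j <- which(n_alloc == 0)[1]
    n_alloc[i] <- n_alloc[i] - 1L; n_alloc[j] <- 1L
  }

  with_seed(config$seed + 1L, {
    rows <- vector("list", nrow(strata))
    for (s in seq_len(nrow(strata))) {
      k <- n_alloc[s]
      poly <- admin_map$admin1$polys[[match(strata$admin1[s], admin_map$admin1$ids)]]
      pts <- runif_in_polygon(k, poly)
      nch <- if (config$children_jitter)
        pmax(1L, rpois(k, config$children_per_cluster))
      else rep(as.integer(round(config$children_per_cluster)), k)
      rows[[s]] <- data.frame(
        admin1_id = strata$admin1[s],
        stratum_id = paste0(strata$admin1[s], if (config$urban_strata)
          ifelse(strata$urban[s], ":urban", ":rural") else ""),
        urban = strata$urban[s],
        lon = pts[, 1], lat = pts[, 2],
        n_children = nch,
        weight = strata$share[s] / (k / config$n_clusters),
        stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, rows)
  })
  sites$weight <- sites$weight / mean(rep(sites$weight, sites$n_children))
  sites$cluster_id <- sprintf("c%04d", seq_len(nrow(sites)))
  sites$admin2_id <- locate_admin(admin_map, cbind(sites$lon, sites$lat), level = 2)
  rownames(sites) <- NULL
  sites[, c("cluster_id", "admin1_id", "admin2_id", "stratum_id", "urban",
            "lon", "lat", "n_children", "weight")]
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- as.integer(round(sum(x))) - as.integer(sum(fl))
  add <- integer(length(x))
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    add[ord[seq_len(rem)]] <- 1L
  }
  as.integer(fl + add)
}

#' Geo-mask cluster coordinates by random displacement
#'
#' Mirrors DHS confidentiality masking: each cluster is displaced along a
#' uniform random bearing by a distance uniform on [0, cap] with a 2 km
#' cap for urban and 10 km for rural clusters (great-circle distances on
#' WGS84). Points falling outside the country boundary are redrawn. True
#' coordinates are retained (columns `lon`/`lat`) for validation only;
#' analysis uses `disp_lon`/`disp_lat`.
#'
#' @param sites cluster table from [sample_clusters()].
#' @param seed integer seed.
#' @param max_km named caps c(urban, rural) in km; 0 disables displacement.
#' @param boundary polygon the displaced points must stay inside (defaults
#'   to the sites' bounding region if omitted).
#' @return `sites` with `disp_lon`, `disp_lat`, `disp_km` columns added.
#' @export
displace_coordinates <- function(sites, seed = 1L,
                                 max_km = c(urban = 2, rural = 10),
                                 boundary = NULL) {
  if (is.null(boundary)) {
    pad <- 0.2
    boundary <- bbox_polygon(c(min(sites$lon) - pad, max(sites$lon) + pad,
                               min(sites$lat) - pad, max(sites$lat) + pad))
  }
  caps <- ifelse(sites$urban, max_km[["urban"]], max_km[["rural"]])
  with_seed(seed, {
    n <- nrow(sites)
    dlon <- sites$lon; dlat <- sites$lat; dkm <- numeric(n)
    for (i in seq_len(n)) {
      if (caps[i] == 0) next
      repeat {
        brg <- runif(1, 0, 360)
        dist <- runif(1, 0, caps[i]) * 1000  # metres
        p <- geosphere::destPoint(c(sites$lon[i], sites$lat[i]), brg, dist,
                                  f = 0)  # spherical model, consistent with haversine caps
        if (point_in_polygon(p, boundary)) break
      }
      dlon[i] <- p[1]; dlat[i] <- p[2]; dkm[i] <- dist / 1000
    }
  })
  sites$disp_lon <- dlon; sites$disp_lat <- dlat; sites$disp_km <- dkm
  sites
}
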