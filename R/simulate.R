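## Child-level outcome simulation and synthetic covariate rasters; the
## simulate_survey() orchestrator runs the full generator: admin map ->
## cluster sampling -> geo-masking -> rasters -> buffer linkage ->
## mesh + latent Matern field -> child records.

#' Simulate child records for a set of cluster sites
#'
#' Child covariates are drawn from the catalogue marginals; cluster-level
#' climate covariates are taken from matching columns of `sites` when
#' present (e.g. after raster linkage) and drawn from their marginals
#' otherwise. Stunting follows
#' `Bernoulli(plogis(intercept + sum beta x + S(site)))` with the latent
#' field value of the child's cluster; HAZ is back-filled from a normal
#' distribution truncated consistently with stunting status (stunted
#' iff HAZ < -2).
#'
#' @param sites cluster table ([sample_clusters()] output, possibly
#'   augmented with climate category columns).
#' @param field numeric vector of latent field values, one per site
#'   (already projected to the site locations); `NULL` means no field.
#' @param config a [sim_config()].
#' @return child-level data.frame (one row per child).
#' @export
simulate_children <- function(sites, field = NULL, config = sim_config()) {
  cat <- covariate_catalog()
  covs <- config$covariates
  unknown <- setdiff(covs, names(cat))
  if (length(unknown))
    stop("schema error: unknown covariate(s): ", paste(unknown, collapse = ", "))
  if (is.null(field)) field <- rep(0, nrow(sites))
  stopifnot(length(field) == nrow(sites))
  betas <- config$betas

  with_seed(config$seed + 2L, {
    idx <- rep(seq_len(nrow(sites)), sites$n_children)
    n <- length(idx)
    children <- data.frame(
      child_id = sprintf("k%06d", seq_len(n)),
      cluster_id = sites$cluster_id[idx],
      stratum_id = sites$stratum_id[idx],
      admin1_id = sites$admin1_id[idx],
      admin2_id = sites$admin2_id[idx],
      weight = sites$weight[idx],
      stringsAsFactors = FALSE)
    eta <- rep(config$intercept, n) + field[idx]
    for (v in covs) {
      entry <- cat[[v]]
      if (entry$kind == "cluster" && v %in% names(sites)) {
        val <- factor(as.character(sites[[v]])[idx], levels = entry$levels)
      } else if (entry$kind == "cluster") {
        site_val <- sample(entry$levels, nrow(sites), replace = TRUE,
                           prob = entry$probs)
        val <- factor(site_val[idx], levels = entry$levels)
      } else {
        val <- factor(sample(entry$levels, n, replace = TRUE,
                             prob = entry$probs), levels = entry$levels)
      }
      children[[v]] <- val
      for (k in seq_along(entry$levels[-1])) {
        lev <- entry$levels[-1][k]
        b <- betas[paste0(v, ":", lev)]
        if (!is.na(b)) eta <- eta + ifelse(val == lev, b, 0)
      }
    }
    p <- plogis(eta)
    children$stunted <- rbinom(n, 1, p)
    # HAZ consistent with status: truncated normal around haz_mean
    mu <- config$haz_mean; sdv <- config$haz_sd
    u <- runif(n)
    pc <- pnorm(-2, mu, sdv)
    children$haz <- ifelse(
      children$stunted == 1,
      qnorm(u * pc, mu, sdv),
      qnorm(pc + u * (1 - pc), mu, sdv))
    children$true_p <- p
  })
  children
}

#' Generate smooth synthetic covariate rasters
#'
#' Builds DLST (degC), rainfall (mm), aridity-index and urbanisation-class
#' rasters over the configured bbox. Surfaces follow a north-south
#' climate gradient (hotter/more arid north) with smooth sinusoidal
#' texture so every published category band is populated; urbanisation
#' marks a few seeded city centres (class 1) with surrounding towns
#' (class 2) in a rural matrix (class 3). `constants` forces named
#' rasters to a constant value (useful for degenerate checks).
#'
#' @param admin_map an `admin_map` (supplies the bbox).
#' @param config a [sim_config()].
#' @param res cell size in degrees (default 0.1, ~10 km).
#' @param constants optional named list, e.g. `list(dlst = 31)`.
#' @return named list of `grid_raster`s.
#' @export
rasterize_covariates <- function(admin_map, config, res = 0.1,
                                 constants = NULL) {
  bb <- admin_map$bbox
  latmin <- bb[3]; latspan <- bb[4] - bb[3]
  lonmid <- (bb[1] + bb[2]) / 2
  with_seed(config$seed + 3L, {
    ncity <- max(3L, config$n_admin1)
    cities <- cbind(runif(ncity, bb[1], bb[2]), runif(ncity, bb[3], bb[4]))
  })
  north <- function(lat) (lat - latmin) / latspan     # 0 south -> 1 north
  fns <- list(
    dlst = function(lon, lat)
      26 + 12 * north(lat) + 1.5 * sin(2 * pi * (lon - lonmid) / 4),
    rainfall = function(lon, lat)
      pmax(30, 2100 - 2100 * north(lat) +
             150 * sin(2 * pi * (lon - lonmid) / 5)),
    aridity = function(lon, lat)
      pmin(300, pmax(0, 60 - 55 * north(lat) +
                       6 * cos(2 * pi * (lon - lonmid) / 3))),
    urbanization = function(lon, lat) {
      d2 <- Reduce(pmin, lapply(seq_len(nrow(cities)), function(k)
        (lon - cities[k, 1])^2 + (lat - cities[k, 2])^2))
      ifelse(d2 < 0.08^2, 1, ifelse(d2 < 0.3^2, 2, 3))
    })
  units <- c(dlst = "degC", rainfall = "mm", aridity = "index",
             urbanization = "class")
  out <- list()
  for (nm in names(fns)) {
    f <- if (!is.null(constants[[nm]])) {
      const <- constants[[nm]]
      function(lon, lat) rep(const, length(lon))
    } else fns[[nm]]
    out[[nm]] <- raster_from_function(bb, res, f, name = nm,
                                      units = units[[nm]])
  }
  out
}

#' Run the full synthetic survey generator
#'
#' Orchestrates the pipeline end to end: admin map, stratified cluster
#' sampling, geo-masking displacement, covariate rasters, circular-buffer
#' linkage and categorisation, mesh construction, one latent Matern field
#' draw, and child records. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param rasters simulate and link covariate rasters? (climate
#'   covariates fall back to marginal draws when FALSE).
#' @param raster_res raster cell size in degrees.
#' @param mesh_args list of arguments passed to [build_mesh()].
#' @return list with `children`, `clusters`, `admin_map`, `rasters`,
#'   `mesh`, `field` (mesh-vertex draw), `field_at_sites` and `config`.
#' @export
simulate_survey <- function(config = sim_config(), rasters = TRUE,
                            raster_res = 0.1,
                            mesh_args = list(max_edge = c(1, 2),
                                             cutoff = 0.15)) {
  map <- generate_admin_map(config)
  sites <- sample_clusters(map, config)
  sites <- displace_coordinates(sites, seed = config$seed + 4L,
                                max_km = config$displacement_km,
                                boundary = bbox_polygon(map$bbox))
  rst <- list()
  if (isTRUE(rasters)) {
    rst <- rasterize_covariates(map, config, res = raster_res)
    keep <- intersect(names(rst), config$covariates)
    if (length(keep)) {
      sites <- link_geocovariates(sites, rst[keep])
      sites <- categorize_cluster_climate(sites)
    }
  }
  mesh <- do.call(build_mesh,
                  c(list(points = cbind(sites$disp_lon, sites$disp_lat)),
                    mesh_args))
  field <- simulate_spatial_field(mesh, config$field_kappa, config$field_tau,
                                  n = 1, seed = config$seed + 5L)[, 1]
  A <- projector(mesh, cbind(sites$disp_lon, sites$disp_lat))
  f_sites <- as.numeric(A %*% field)
  children <- simulate_children(sites, f_sites, config)
  # carry analysis coordinates onto the child table for model fitting
  m <- match(children$cluster_id, sites$cluster_id)
  children$lon <- sites$disp_lon[m]
  children$lat <- sites$disp_lat[m]
  list(children = children, clusters = sites, admin_map = map,
       rasters = rst, mesh = mesh, field = field,
       field_at_sites = f_sites, config = config)
}
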