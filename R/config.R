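#' Configuration for the synthetic DHS-like survey generator
#'
#' Defaults emulate the design of a national DHS: two-stage stratified
#' cluster sampling with urban/rural strata inside each first-level admin
#' unit, 30 households per cluster, geo-masking displacement of cluster
#' GPS coordinates (2 km urban / 10 km rural), a Matern (nu = 1) latent
#' risk field with marginal variance 0.24 and scale kappa = 7.33 per
#' degree, and the covariate effect structure of [covariate_catalog()].
#' The default domain is a Nigeria-scale lon/lat rectangle.
#'
#' @param seed integer seed driving every random choice of the generator.
#' @param n_admin1 number of first-level admin units (states).
#' @param n_admin2_per_admin1 second-level units (LGAs) per state.
#' @param n_clusters number of survey clusters (enumeration areas).
#' @param urban_fraction proportion of the population that is urban.
#' @param households_per_cluster households selected per cluster.
#' @param children_per_cluster mean analysed children per cluster
#'   (Poisson; DHS-scale default 12,627 / 1,377 ~ 9.2).
#' @param children_jitter Poisson-jitter the per-cluster child count?
#' @param field_kappa Matern scale parameter (per degree).
#' @param field_variance marginal variance of the latent field.
#' @param betas named log-odds vector, names `covariate:level`
#'   (see [catalog_betas()]).
#' @param intercept baseline log-odds of stunting at reference levels.
#' @param covariates catalogue covariates simulated for each child/cluster.
#' @param domain_bbox c(xmin, xmax, ymin, ymax) in degrees.
#' @param urban_strata stratify clusters by urban/rural within admin-1?
#' @param displacement_km c(urban, rural) geo-masking caps in km.
#' @param haz_mean,haz_sd centre/spread of the HAZ distribution used to
#'   back-fill continuous z-scores consistent with stunting status.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_admin1 = 6L,
                       n_admin2_per_admin1 = 4L,
                       n_clusters = 120L,
                       urban_fraction = 0.4,
                       households_per_cluster = 30L,
                       children_per_cluster = 9.2,
                       children_jitter = TRUE,
                       field_kappa = 7.33,
                       field_variance = 0.24,
                       betas = catalog_betas(covariates),
                       intercept = -0.6,
                       covariates = names(covariate_catalog()),
                       domain_bbox = c(3, 14, 4, 14),
                       urban_strata = TRUE,
                       displacement_km = c(urban = 2, rural = 10),
                       haz_mean = -1.3,
                       haz_sd = 1.1) {
  cfg <- list(seed = as.integer(seed), n_admin1 = as.integer(n_admin1),
              n_admin2_per_admin1 = as.integer(n_admin2_per_admin1),
              n_clusters = as.integer(n_clusters),
              urban_fraction = urban_fraction,
              households_per_cluster = as.integer(households_per_cluster),
              children_per_cluster = children_per_cluster,
              children_jitter = isTRUE(children_jitter),
              field_kappa = field_kappa, field_variance = field_variance,
              field_tau = matern_tau(field_kappa, field_variance),
              betas = betas, intercept = intercept,
              covariates = covariates,
              domain_bbox = as.numeric(domain_bbox),
              urban_strata = isTRUE(urban_strata),
              displacement_km = displacement_km,
              haz_mean = haz_mean, haz_sd = haz_sd)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_admin1 >= 1, cfg$n_admin2_per_admin1 >= 1,
            cfg$n_clusters >= 1, cfg$households_per_cluster >= 1)
  if (cfg$urban_fraction < 0 || cfg$urban_fraction > 1)
    stop("urban_fraction must lie in [0, 1]")
  if (cfg$field_kappa <= 0) stop("field_kappa must be positive")
  if (cfg$field_tau <= 0) stop("field_tau must be positive")
  bb <- cfg$domain_bbox
  if (length(bb) != 4 || bb[2] <= bb[1] || bb[4] <= bb[3])
    stop("invalid-domain: domain_bbox must be c(xmin, xmax, ymin, ymax) with positive area")
  known <- catalog_betas(cfg$covariates)
  unknown <- setdiff(names(cfg$betas), names(known))
  if (length(unknown))
    stop("betas reference unknown covariate levels: ",
         paste(unknown, collapse = ", "))
  invisible(cfg)
}
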