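test_that("trivial admin partition is the bbox itself", {
  cfg <- sim_config(n_admin1 = 1, n_admin2_per_admin1 = 1,
                    domain_bbox = c(0, 2, 0, 3))
  map <- generate_admin_map(cfg)
  expect_length(map$admin1$polys, 1)
  expect_length(map$admin2$polys, 1)
  expect_equal(polygon_area(map$admin2$polys[[1]]), 6)
})

test_that("level-2 polygons tile the bbox (shoelace area oracle)", {
  for (cfg in list(sim_config(seed = 3, n_admin1 = 5, n_admin2_per_admin1 = 4),
                   sim_config(seed = 9, n_admin1 = 2, n_admin2_per_admin1 = 7,
                              domain_bbox = c(-1, 1, -2, 0)))) {
    map <- generate_admin_map(cfg)
    bb <- cfg$domain_bbox
    bbox_area <- (bb[2] - bb[1]) * (bb[4] - bb[3])
    a2 <- sum(vapply(map$admin2$polys, polygon_area, numeric(1)))
    expect_equal(a2, bbox_area, tolerance = 1e-6)
    a1 <- sum(vapply(map$admin1$polys, polygon_area, numeric(1)))
    expect_equal(a1, bbox_area, tolerance = 1e-6)
  }
})

test_that("a 37 x 21 map mirrors a 37-state / 777-LGA structure", {
  cfg <- sim_config(seed = 5, n_admin1 = 37, n_admin2_per_admin1 = 21)
  map <- generate_admin_map(cfg)
  expect_length(map$admin1$polys, 37)
  expect_length(map$admin2$polys, 37 * 21)
  expect_equal(sum(vapply(map$admin2$polys, polygon_area, numeric(1))),
               (14 - 3) * (14 - 4), tolerance = 1e-6)
})

test_that("degenerate bbox is rejected", {
  expect_error(sim_config(domain_bbox = c(0, 0, 0, 1)), "invalid-domain")
})

test_that("cluster sampling honours counts, strata and determinism", {
  cfg <- sim_config(seed = 2, n_clusters = 1377, n_admin1 = 6,
                    n_admin2_per_admin1 = 2)
  map <- generate_admin_map(cfg)
  sites <- sample_clusters(map, cfg)
  expect_equal(nrow(sites), 1377)
  expect_false(anyDuplicated(sites$cluster_id) > 0)
  expect_true(all(table(sites$stratum_id) >= 1))
  # same seed twice: byte-identical site table
  expect_identical(sites, sample_clusters(map, cfg))
  # all-urban configuration
  cfg_u <- sim_config(seed = 2, n_clusters = 40, n_admin1 = 3,
                      urban_fraction = 1)
  sites_u <- sample_clusters(generate_admin_map(cfg_u), cfg_u)
  expect_true(all(sites_u$urban))
  # urban strata requested with no urban population
  cfg_0 <- sim_config(seed = 2, n_clusters = 40, n_admin1 = 3,
                      urban_fraction = 0, urban_strata = TRUE)
  expect_error(sample_clusters(generate_admin_map(cfg_0), cfg_0),
               "empty-stratum")
})

test_that("geo-masking displacement respects the urban/rural caps", {
  cfg <- sim_config(seed = 8, n_clusters = 400, n_admin1 = 2,
                    urban_fraction = 0.5)
  map <- generate_admin_map(cfg)
  sites <- sample_clusters(map, cfg)
  disp <- displace_coordinates(sites, seed = 4,
                               boundary = bbox_polygon(map$bbox))
  d_km <- geosphere::distHaversine(cbind(disp$lon, disp$lat),
                                   cbind(disp$disp_lon, disp$disp_lat)) / 1000
  expect_true(all(d_km[disp$urban] <= 2 + 1e-6))
  expect_true(all(d_km[!disp$urban] <= 10 + 1e-6))
  # distances are stochastic, not degenerate
  expect_gt(sd(d_km[!disp$urban]), 0)
  # displaced points stay inside the boundary
  expect_true(all(point_in_polygon(cbind(disp$disp_lon, disp$disp_lat),
                                   bbox_polygon(map$bbox))))
  # zero cap leaves coordinates untouched
  same <- displace_coordinates(sites, seed = 4,
                               max_km = c(urban = 0, rural = 0))
  expect_equal(same$disp_lon, sites$lon)
  expect_equal(same$disp_lat, sites$lat)
})

test_that("displacement distance cap holds over many rural draws", {
  # large-sample displacement check: uniform-on-[0, cap] distances
  n <- 10000
  sites <- data.frame(cluster_id = sprintf("c%05d", 1:n),
                      urban = FALSE, lon = runif(n, 5, 9),
                      lat = runif(n, 6, 10))
  disp <- displace_coordinates(sites, seed = 99,
                               boundary = bbox_polygon(c(4, 10, 5, 11)))
  d_km <- geosphere::distHaversine(cbind(disp$lon, disp$lat),
                                   cbind(disp$disp_lon, disp$disp_lat)) / 1000
  expect_lte(max(d_km), 10 + 1e-6)
  expect_gt(sd(d_km), 1)
  expect_gt(max(d_km), 9)  # the cap is actually approached
})

test_that("latent field draws match the closed-form marginal variance", {
  g <- as.matrix(expand.grid(seq(0, 1, length.out = 29),
                             seq(0, 1, length.out = 29)))
  mesh <- build_mesh(g, cutoff = 0, boundary_extension = 0.45,
                     max_edge = c(0.05, 0.1))
  kappa <- sqrt(8) / 0.35
  sigma2 <- 0.24
  tau <- matern_tau(kappa, sigma2)
  x <- simulate_spatial_field(mesh, kappa, tau, n = 500, seed = 42)
  interior <- mesh$loc[, 1] >= 0.25 & mesh$loc[, 1] <= 0.75 &
    mesh$loc[, 2] >= 0.25 & mesh$loc[, 2] <= 0.75
  emp <- mean(apply(x[interior, ], 1, var))
  expect_equal(emp, sigma2, tolerance = 0.1)
  # reproducible under the same seed
  x2 <- simulate_spatial_field(mesh, kappa, tau, n = 2, seed = 7)
  x3 <- simulate_spatial_field(mesh, kappa, tau, n = 2, seed = 7)
  expect_identical(x2, x3)
  # infinite tau collapses the field
  x0 <- simulate_spatial_field(mesh, kappa, 1e8, n = 1, seed = 1)
  expect_lt(max(abs(x0)), 1e-6)
})

test_that("null generator gives 50% prevalence and exact haz consistency", {
  cfg <- sim_config(seed = 31, n_clusters = 120, n_admin1 = 3,
                    n_admin2_per_admin1 = 2, children_per_cluster = 12,
                    covariates = "diarrhoea",
                    betas = c("diarrhoea:yes" = 0), intercept = 0)
  map <- generate_admin_map(cfg)
  sites <- sample_clusters(map, cfg)
  kids <- simulate_children(sites, field = NULL, config = cfg)
  p <- mean(kids$stunted)
  expect_equal(p, 0.5, tolerance = 3 * sqrt(0.25 / nrow(kids)) / 0.5)
  expect_true(all((kids$haz < -2) == (kids$stunted == 1)))
  # byte-identical regeneration under the same config
  expect_identical(kids, simulate_children(sites, NULL, cfg))
  # unknown beta name is a schema error
  expect_error(sim_config(betas = c("nosuch:yes" = 1)), "unknown covariate")
})

test_that("default national-scale config yields ~12,627 analysed children", {
  cfg <- sim_config(seed = 1, n_clusters = 1377)
  map <- generate_admin_map(cfg)
  sites <- sample_clusters(map, cfg)
  n <- sum(sites$n_children)
  # Poisson total around 1377 * 9.2 = 12668 (the published analysed size
  # is 12,627); allow 4 sd
  expect_lt(abs(n - 12627), 4 * sqrt(12668) + 41)
})

test_that("intercept is recovered by a plain logistic fit on null-field data", {
  cfg <- sim_config(seed = 13, n_clusters = 200, n_admin1 = 2,
                    n_admin2_per_admin1 = 2, children_per_cluster = 25,
                    covariates = "diarrhoea",
                    betas = c("diarrhoea:yes" = 0), intercept = -0.6)
  map <- generate_admin_map(cfg)
  sites <- sample_clusters(map, cfg)
  kids <- simulate_children(sites, NULL, cfg)
  fit <- glm(stunted ~ 1, family = binomial(), data = kids)
  se <- sqrt(vcov(fit)[1, 1])
  expect_lt(abs(coef(fit)[1] - (-0.6)), 3 * se)
})

test_that("synthetic rasters populate every published climate band", {
  cfg <- sim_config(seed = 4, n_admin1 = 3)
  map <- generate_admin_map(cfg)
  rst <- rasterize_covariates(map, cfg, res = 0.2)
  expect_setequal(names(rst), c("dlst", "rainfall", "aridity", "urbanization"))
  expect_true(all(is.finite(rst$dlst$values)))
  expect_lt(min(rst$dlst$values), 30)
  expect_gt(max(rst$dlst$values), 35)
  bands <- table(categorize_climate(as.vector(rst$dlst$values), "dlst"))
  expect_true(all(bands > 0))
  rain_bands <- table(categorize_climate(as.vector(rst$rainfall$values), "rainfall"))
  expect_true(all(rain_bands > 0))
  # constant override
  rstc <- rasterize_covariates(map, cfg, res = 0.2, constants = list(dlst = 31))
  expect_true(all(rstc$dlst$values == 31))
  # resolution guard
  expect_error(rasterize_covariates(map, cfg, res = 1e-5), "resource")
})

test_that("the survey writer emits a readable artifact set", {
  cfg <- sim_config(seed = 21, n_clusters = 30, n_admin1 = 2,
                    n_admin2_per_admin1 = 2, children_per_cluster = 6,
                    covariates = c("diarrhoea", "dlst"))
  sim <- simulate_survey(cfg, raster_res = 0.25,
                         mesh_args = list(max_edge = c(2, 4), cutoff = 0.5))
  dir <- tempfile()
  write_survey(sim, dir)
  expect_true(file.exists(file.path(dir, "children.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_child_table(file.path(dir, "children.csv"))
  expect_equal(nrow(back), nrow(sim$children))
  expect_equal(back$stunted, sim$children$stunted)
  a2 <- read_geojson(file.path(dir, "admin2.geojson"))
  expect_equal(nrow(a2$properties), 4)
})
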