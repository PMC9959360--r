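test_that("buffer means behave on constant rasters and sub-cell radii", {
  const <- raster_from_function(c(5, 7, 8, 10), 0.05,
                                function(lon, lat) rep(4.2, length(lon)))
  expect_equal(extract_buffer_mean(const, c(6, 9), radius_km = 2), 4.2)
  expect_equal(extract_buffer_mean(const, c(6, 9), radius_km = 50), 4.2)
  # radius smaller than one cell returns the containing cell's value
  grad <- raster_from_function(c(5, 7, 8, 10), 0.5,
                               function(lon, lat) lon * 100 + lat)
  v <- extract_buffer_mean(grad, c(5.3, 8.2), radius_km = 0.05)
  expect_equal(v, raster_value_at(grad, cbind(5.3, 8.2)))
})

test_that("buffer mean matches a dense-lattice brute-force oracle", {
  r <- raster_from_function(c(5, 7, 8, 10), 0.02,
                            function(lon, lat) 3 * lon - 2 * lat + 40)
  pt <- c(6.1, 9.05)
  got <- extract_buffer_mean(r, pt, radius_km = 10)
  # brute force over a 0.001-degree lattice inside the buffer
  lon <- seq(pt[1] - 0.15, pt[1] + 0.15, by = 0.001)
  lat <- seq(pt[2] - 0.15, pt[2] + 0.15, by = 0.001)
  gg <- expand.grid(lon = lon, lat = lat)
  d <- geosphere::distHaversine(pt, as.matrix(gg))
  want <- mean(3 * gg$lon[d <= 10000] - 2 * gg$lat[d <= 10000] + 40)
  expect_equal(got, want, tolerance = 0.005 * abs(want) / abs(want) + 0.005)
})

test_that("buffer mean is invariant to splitting the raster into tiles", {
  r <- raster_from_function(c(5, 7, 8, 10), 0.04,
                            function(lon, lat) sin(lon) + cos(lat) * 2)
  pt <- c(6, 9)
  full <- extract_buffer_mean(r, pt, radius_km = 10)
  # split into a north and a south tile and recombine with cell counts
  nr <- r$nrow; half <- nr %/% 2
  north <- grid_raster(r$values[1:half, , drop = FALSE],
                       r$xmin, r$ymin + (nr - half) * r$res, r$res)
  south <- grid_raster(r$values[(half + 1):nr, , drop = FALSE],
                       r$xmin, r$ymin, r$res)
  count_in <- function(tile) {
    xy <- raster_coords(tile)
    gg <- expand.grid(lat = xy$lat, lon = xy$lon)
    sum(geosphere::distHaversine(pt, cbind(gg$lon, gg$lat)) <= 10000)
  }
  n1 <- count_in(north); n2 <- count_in(south)
  m1 <- extract_buffer_mean(north, pt, radius_km = 10)
  m2 <- extract_buffer_mean(south, pt, radius_km = 10)
  expect_equal((m1 * n1 + m2 * n2) / (n1 + n2), full, tolerance = 1e-12)
})

test_that("linkage joins one column per raster onto 1377 clusters", {
  cfg <- sim_config(seed = 2, n_clusters = 1377, n_admin1 = 4,
                    n_admin2_per_admin1 = 2)
  map <- generate_admin_map(cfg)
  sites <- sample_clusters(map, cfg)
  sites <- displace_coordinates(sites, seed = 3,
                                boundary = bbox_polygon(map$bbox))
  rst <- rasterize_covariates(map, cfg, res = 0.2)
  linked <- link_geocovariates(sites, rst)
  expect_equal(nrow(linked), 1377)
  expect_true(all(c("dlst", "rainfall", "aridity", "urbanization") %in%
                    names(linked)))
  expect_false(anyNA(linked$dlst))
  # empty raster list leaves the table unchanged
  expect_identical(link_geocovariates(sites, list()), sites)
  # duplicate ids are a hard error
  dup <- rbind(sites[1:2, ], sites[1, ])
  expect_error(link_geocovariates(dup, rst), "duplicate")
})

test_that("clusters outside the rasters keep their rows with NA", {
  r <- raster_from_function(c(0, 1, 0, 1), 0.1,
                            function(lon, lat) rep(1, length(lon)))
  sites <- data.frame(cluster_id = c("a", "b"), urban = FALSE,
                      lon = c(0.5, 30), lat = c(0.5, 30))
  expect_warning(out <- link_geocovariates(sites, list(x = r)), "outside")
  expect_equal(nrow(out), 2)
  expect_true(is.na(out$x[2]) && !is.na(out$x[1]))
})

test_that("published climate bands are honoured at their boundaries", {
  expect_equal(as.character(categorize_climate(34.95, "dlst")), "30to34.9")
  expect_equal(as.character(categorize_climate(c(29.99, 35.0), "dlst")),
               c("lt30", "ge35"))
  expect_equal(as.character(categorize_climate(142, "rainfall")), "medium")
  expect_equal(as.character(categorize_climate(c(141.9, 1200), "rainfall")),
               c("low", "high"))
  expect_equal(as.character(categorize_climate(17.5, "aridity")), "semi_arid")
  expect_equal(as.character(categorize_climate(c(17.4, 32.5, 32.6), "aridity")),
               c("arid", "semi_arid", "wet"))
  expect_equal(as.character(categorize_climate(1:3, "urbanization")),
               c("urban_centres", "urban_clusters", "rural_villages"))
  expect_error(categorize_climate(-1, "aridity"), "validation error")
  expect_error(categorize_climate(400, "aridity"), "validation error")
})

test_that("categorisation is exhaustive and mutually exclusive", {
  set.seed(3)
  for (scheme in c("dlst", "rainfall", "aridity")) {
    vals <- switch(scheme,
                   dlst = runif(500, 10, 50),
                   rainfall = runif(500, 0, 3000),
                   aridity = runif(500, 0, 300))
    f <- categorize_climate(vals, scheme)
    expect_false(anyNA(f))
    expect_true(all(levels(f) == covariate_catalog()[[scheme]]$levels))
  }
})
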