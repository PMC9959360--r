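test_that("four corner points with no extension give two triangles", {
  m <- build_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                  cutoff = 0, boundary_extension = 0)
  expect_equal(nrow(m$loc), 4)
  expect_equal(nrow(m$tri), 2)
  expect_true(all(m$boundary))
})

test_that("collinear points are rejected and a huge cutoff degenerates", {
  expect_error(build_mesh(cbind(1:5, 2 * (1:5)), cutoff = 0,
                          boundary_extension = 0), "collinear")
  expect_error(build_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                          cutoff = 10, boundary_extension = 0),
               "fewer than 3")
})

test_that("unit right triangle reproduces the textbook element matrices", {
  fem <- fem_matrices(rbind(c(0, 0), c(1, 0), c(0, 1)), matrix(1:3, 1))
  expect_equal(as.matrix(fem$G),
               rbind(c(1, -0.5, -0.5), c(-0.5, 0.5, 0), c(-0.5, 0, 0.5)),
               ignore_attr = TRUE)
  expect_equal(Matrix::diag(fem$C), rep(1 / 6, 3))
})

test_that("triangulation is Delaunay and FEM matrices satisfy invariants", {
  set.seed(10)
  pts <- cbind(runif(80), runif(80))
  dt <- delaunay_triangulate(pts)
  # empty-circumcircle property at every triangle
  worst <- 0
  for (t in seq_len(nrow(dt$tri))) {
    v <- dt$tri[t, ]
    cc <- stuntmap:::circumcircle(dt$loc[v[1], 1], dt$loc[v[1], 2],
                                  dt$loc[v[2], 1], dt$loc[v[2], 2],
                                  dt$loc[v[3], 1], dt$loc[v[3], 2])
    d2 <- (dt$loc[-v, 1] - cc[1])^2 + (dt$loc[-v, 2] - cc[2])^2
    worst <- max(worst, cc[3] - min(d2))
  }
  expect_lt(worst, 1e-9)
  m <- build_mesh(pts, cutoff = 0.03, boundary_extension = 0.2,
                  max_edge = c(0.2, 0.3))
  expect_true(all(Matrix::diag(m$C) > 0))
  expect_lt(max(abs(Matrix::rowSums(m$G))), 1e-9)
  expect_equal(max(abs(m$G - Matrix::t(m$G))), 0)
  # cutoff thinning: retained original points pairwise >= cutoff apart
  d <- as.matrix(dist(m$loc))
  diag(d) <- Inf
  expect_gte(min(d), 0.8 * 0.03)  # ring points may sit closer than cutoff
})

test_that("projector performs exact barycentric interpolation", {
  m <- unit_square_mesh(5)
  # at a vertex: single unit weight
  A <- projector(m, m$loc[7, , drop = FALSE])
  expect_equal(sum(A != 0), 1)
  expect_equal(sum(A), 1)
  # at a triangle centroid: three weights of 1/3
  tri1 <- m$tri[1, ]
  centroid <- colMeans(m$loc[tri1, ])
  Ac <- projector(m, matrix(centroid, 1))
  expect_equal(sort(as.numeric(Ac[1, tri1])), rep(1 / 3, 3), tolerance = 1e-9)
  # linear reproduction: A (a + b x + c y at vertices) == a + b x + c y
  set.seed(2)
  locs <- cbind(runif(40, 0.01, 0.99), runif(40, 0.01, 0.99))
  Ar <- projector(m, locs)
  expect_false(any(attr(Ar, "outside")))
  f <- 2 + 3 * m$loc[, 1] - 5 * m$loc[, 2]
  expect_equal(as.numeric(Ar %*% f), 2 + 3 * locs[, 1] - 5 * locs[, 2],
               tolerance = 1e-9)
  # rows sum to one inside, zero outside
  expect_equal(Matrix::rowSums(Ar), rep(1, 40), tolerance = 1e-10)
  Ao <- projector(m, rbind(c(2, 2)))
  expect_true(attr(Ao, "outside"))
  expect_equal(sum(Ao != 0), 0)
})

test_that("SPDE precision obeys its algebraic structure", {
  m <- unit_square_mesh(6)
  Q1 <- spde_precision(m, kappa = 3, tau = 1)
  expect_equal(max(abs(Q1 - Matrix::t(Q1))), 0)
  # doubling tau multiplies Q by 4 exactly
  Q2 <- spde_precision(m, kappa = 3, tau = 2)
  expect_equal(max(abs(Q2 - 4 * Q1)), 0, tolerance = 1e-12)
  # with G = 0 the precision is diagonal tau^2 kappa^4 C
  m0 <- m
  m0$G <- m$G * 0
  Q0 <- spde_precision(m0, kappa = 2, tau = 3)
  expect_equal(as.matrix(Q0), as.matrix(9 * 16 * m$C), tolerance = 1e-12)
  expect_error(spde_precision(m, -1, 1), "domain error")
})

test_that("kappa/tau map to range and variance and invert exactly", {
  expect_equal(matern_params_from(sqrt(8), 1)$range, 1)
  kappa <- 2.5
  tau <- 1 / (2 * sqrt(pi) * kappa)
  expect_equal(matern_params_from(kappa, tau)$variance, 1, tolerance = 1e-12)
  # published-scale inversion round trip: kappa 7.33, variance 0.24
  tau2 <- matern_tau(7.33, 0.24)
  expect_equal(matern_params_from(7.33, tau2)$variance, 0.24,
               tolerance = 1e-12)
  expect_error(matern_params_from(0, 1), "domain error")
})

test_that("mesh serialises to JSON and precision to MatrixMarket", {
  m <- unit_square_mesh(4)
  path <- tempfile(fileext = ".json")
  write_mesh_json(m, path)
  back <- read_mesh_json(path)
  expect_equal(back$loc, unname(as.matrix(m$loc)))
  expect_equal(as.matrix(back$G), as.matrix(m$G), tolerance = 1e-12)
  mtx <- tempfile(fileext = ".mtx")
  write_mtx(spde_precision(m, 2, 1), mtx)
  rt <- Matrix::readMM(mtx)
  expect_equal(as.matrix(rt), as.matrix(spde_precision(m, 2, 1)),
               tolerance = 1e-10)
})

test_that("simulated fields reproduce the Matern variogram shape", {
  g <- as.matrix(expand.grid(seq(0, 1, length.out = 31),
                             seq(0, 1, length.out = 31)))
  mesh <- build_mesh(g, cutoff = 0, boundary_extension = 0.5,
                     max_edge = c(0.05, 0.1))
  range_true <- 0.45
  kappa <- sqrt(8) / range_true
  tau <- matern_tau(kappa, 1)
  x <- simulate_spatial_field(mesh, kappa, tau, n = 500, seed = 77)
  interior <- which(mesh$loc[, 1] >= 0.2 & mesh$loc[, 1] <= 0.8 &
                      mesh$loc[, 2] >= 0.2 & mesh$loc[, 2] <= 0.8)
  # binned empirical semivariogram over interior pairs vs the closed form
  interior <- interior[seq(1, length(interior), by = 3)]
  pairs <- t(combn(interior, 2))
  d <- sqrt(rowSums((mesh$loc[pairs[, 1], ] - mesh$loc[pairs[, 2], ])^2))
  keep <- d >= 0.2 * range_true & d <= range_true
  pairs <- pairs[keep, , drop = FALSE]; d <- d[keep]
  gamma_pair <- 0.5 * rowMeans((x[pairs[, 1], ] - x[pairs[, 2], ])^2)
  bins <- cut(d, breaks = seq(0.2, 1, length.out = 6) * range_true)
  gamma_emp <- tapply(gamma_pair, bins, mean)
  gamma_theo <- tapply(1 - matern_correlation(d, kappa), bins, mean)
  expect_lt(max(abs(gamma_emp / gamma_theo - 1)), 0.1)
})
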