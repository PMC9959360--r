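test_that("PG draws match the closed-form Polya-Gamma moments", {
  set.seed(1)
  for (z in c(0, 2)) {
    x <- rpg(rep(z, 40000))
    m <- if (z == 0) 0.25 else tanh(z / 2) / (2 * z)
    v <- if (z == 0) 1 / 24 else (sinh(z) - z) / (4 * z^3) / cosh(z / 2)^2
    expect_equal(mean(x), m, tolerance = 4 * sqrt(v / 40000) / m)
    expect_equal(var(x), v, tolerance = 0.05)
  }
  set.seed(9); a <- rpg(rep(1, 5))
  set.seed(9); b <- rpg(rep(1, 5))
  expect_identical(a, b)
})

test_that("intercept-only posterior recovers an observed 30% rate", {
  df <- data.frame(stunted = c(rep(1L, 30), rep(0L, 70)))
  fit <- fit_nonspatial(df, model_spec(),
                        mcmc_control(n_iter = 3000, burnin = 500, thin = 1,
                                     chains = 2, seed = 3))
  p_post <- mean(plogis(fit$beta[, 1]))
  expect_equal(p_post, 0.30, tolerance = 0.02 / 0.30)
  expect_lte(max(fit$diagnostics$rhat), 1.05)
})

test_that("Gibbs posterior agrees with dense grid quadrature (n = 60)", {
  set.seed(21)
  x <- rep(0:1, each = 30)
  y <- rbinom(60, 1, plogis(-0.4 + 0.9 * x))
  df <- data.frame(stunted = y, grp = factor(ifelse(x == 1, "b", "a")))
  fit <- fit_nonspatial(df, model_spec(terms = "grp"),
                        mcmc_control(n_iter = 6000, burnin = 1000, thin = 1,
                                     chains = 2, seed = 5))
  post_mean <- colMeans(fit$beta)
  # trapezoid quadrature over the two-parameter posterior
  n0 <- sum(x == 0); y0 <- sum(y[x == 0])
  n1 <- sum(x == 1); y1 <- sum(y[x == 1])
  b0 <- seq(-4, 4, by = 0.02); b1 <- seq(-4, 4, by = 0.02)
  lp <- outer(b0, b1, function(a, b) {
    p0 <- plogis(a); p1 <- plogis(a + b)
    y0 * log(p0) + (n0 - y0) * log1p(-p0) +
      y1 * log(p1) + (n1 - y1) * log1p(-p1) +
      dnorm(a, 0, 10, log = TRUE) + dnorm(b, 0, 10, log = TRUE)
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  quad <- c(sum(rowSums(w) * b0), sum(colSums(w) * b1))
  expect_lt(max(abs(post_mean - quad)), 0.05)
})

test_that("odds-ratio summaries follow their definitions", {
  fit0 <- structure(list(
    beta = matrix(0, 500, 2, dimnames = list(NULL, c("(Intercept)", "gyes"))),
    chain = rep(1L, 500),
    map = data.frame(col = c("(Intercept)", "gyes"),
                     term = c("(Intercept)", "g"), level = c("", "yes")),
    spec = model_spec(terms = "g"), spatial = FALSE), class = "stunt_fit")
  o <- summarize_or(fit0)
  expect_equal(o$or, 1)
  expect_equal(o$cri_low, 1)
  expect_equal(o$cri_high, 1)
  expect_false(o$significant)
  # tight draws around log(1.35)
  set.seed(2)
  fit1 <- fit0
  fit1$beta[, 2] <- rnorm(500, log(1.35), 1e-4)
  o1 <- summarize_or(fit1)
  expect_equal(o1$or, 1.35, tolerance = 1e-3)
  # percentile matches a sorted-array brute-force computation exactly
  set.seed(4)
  d <- rnorm(1000)
  s <- sort(d)
  for (pr in c(0.025, 0.5, 0.975)) {
    h <- (1000 - 1) * pr + 1
    brute <- s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
    expect_identical(stuntmap:::percentile(d, pr), brute)
  }
  expect_error(summarize_or(structure(list(beta = matrix(0, 10, 1)),
                                      class = "stunt_fit")), "100")
})

test_that("exchanging the reference level inverts the odds ratio", {
  set.seed(12)
  n <- 800
  g <- sample(c("a", "b"), n, replace = TRUE)
  y <- rbinom(n, 1, plogis(-0.3 + 0.7 * (g == "b")))
  ctl <- mcmc_control(n_iter = 2500, burnin = 500, thin = 1, chains = 1,
                      seed = 6)
  df_ab <- data.frame(stunted = y, g = factor(g, levels = c("a", "b")))
  df_ba <- data.frame(stunted = y, g = factor(g, levels = c("b", "a")))
  or_ab <- summarize_or(fit_nonspatial(df_ab, model_spec(terms = "g"), ctl))$or
  or_ba <- summarize_or(fit_nonspatial(df_ba, model_spec(terms = "g"), ctl))$or
  expect_equal(or_ab, 1 / or_ba, tolerance = 0.1)
})

test_that("two seeds give posterior means within Monte-Carlo error", {
  set.seed(31)
  df <- data.frame(stunted = rbinom(400, 1, 0.35),
                   g = factor(sample(c("a", "b"), 400, TRUE)))
  f1 <- fit_nonspatial(df, model_spec(terms = "g"),
                       mcmc_control(n_iter = 3000, burnin = 500, thin = 1,
                                    chains = 1, seed = 1))
  f2 <- fit_nonspatial(df, model_spec(terms = "g"),
                       mcmc_control(n_iter = 3000, burnin = 500, thin = 1,
                                    chains = 1, seed = 999))
  for (j in 1:2) {
    mcse <- function(f) sd(f$beta[, j]) / sqrt(f$diagnostics$ess[j])
    tol <- 3 * sqrt(mcse(f1)^2 + mcse(f2)^2)
    expect_lt(abs(mean(f1$beta[, j]) - mean(f2$beta[, j])), tol)
  }
})

test_that("a collapsed spatial model matches the non-spatial fit", {
  cfg <- recovery_config(55, n_clusters = 80, children = 12)
  sim <- simulate_survey(cfg, rasters = FALSE,
                         mesh_args = list(max_edge = c(0.8, 1.6), cutoff = 0.3))
  ctl_ns <- mcmc_control(n_iter = 1500, burnin = 400, thin = 1, chains = 1,
                         seed = 8)
  f_ns <- fit_nonspatial(sim$children, model_spec(terms = "diarrhoea"), ctl_ns)
  # tau huge and fixed: field variance ~ 1/(4 pi kappa^2 tau^2) ~ 0
  ctl_sp <- mcmc_control(n_iter = 1500, burnin = 400, thin = 1, chains = 1,
                         seed = 8, fix_hyper = c(5, 1e4))
  f_sp <- fit_geospatial(sim$children,
                         model_spec(terms = "diarrhoea", spatial = TRUE),
                         sim$mesh, ctl_sp)
  expect_lt(max(abs(colMeans(f_sp$beta) - colMeans(f_ns$beta))), 0.08)
  expect_lt(max(abs(f_sp$S)), 1e-2)
})

test_that("separation and rank problems are reported", {
  df <- data.frame(stunted = c(1, 1, 1, 0, 0, 0),
                   g = factor(c("a", "a", "a", "b", "b", "b")))
  expect_warning(fit_nonspatial(df, model_spec(terms = "g"),
                                mcmc_control(n_iter = 200, burnin = 50,
                                             thin = 1, chains = 1, seed = 1)),
                 "separation")
  # a term with a single observed level is dropped with a warning
  df2 <- data.frame(stunted = rbinom(20, 1, 0.5),
                    g = factor(rep("a", 20), levels = c("a", "b")),
                    h = factor(rep(c("a", "b"), 10)))
  expect_warning(f2 <- fit_nonspatial(df2, model_spec(terms = c("g", "h")),
                                      mcmc_control(n_iter = 200, burnin = 50,
                                                   thin = 1, chains = 1,
                                                   seed = 1)),
                 "dropping term 'g'")
  expect_false("gb" %in% colnames(f2$beta))
  # perfectly collinear factors are a rank error
  df3 <- data.frame(stunted = rbinom(20, 1, 0.5),
                    g = factor(rep(c("a", "b"), 10)),
                    h = factor(rep(c("x", "y"), 10)))
  expect_error(fit_nonspatial(df3, model_spec(terms = c("g", "h")),
                              mcmc_control(n_iter = 200, burnin = 50,
                                           thin = 1, chains = 1, seed = 1)),
               "rank deficient")
})

test_that("locations outside the mesh are a hard error for spatial fits", {
  m <- unit_square_mesh(4)
  df <- data.frame(stunted = rbinom(10, 1, 0.5), lon = 5, lat = 5)
  expect_error(fit_geospatial(df, model_spec(spatial = TRUE), m,
                              mcmc_control(n_iter = 100, burnin = 10,
                                           thin = 1, chains = 1, seed = 1)),
               "mesh/location mismatch")
})
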