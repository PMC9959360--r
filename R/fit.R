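## Bayesian logistic regression for stunting: non-spatial and geospatial
## (SPDE latent field) variants. Fixed effects and the latent field are
## updated jointly as one exact Gaussian block under Polya-Gamma
## augmentation; the Matern hyperparameters (kappa, tau) move by adaptive
## random-walk Metropolis on the log scale under penalised-complexity
## priors.

#' Model specification
#'
#' @param terms character vector of covariate (factor) columns entering
#'   the fixed effects; reference levels follow [covariate_catalog()]
#'   (first catalogue level) or the factor's first level.
#' @param outcome binary outcome column.
#' @param spatial include the SPDE latent field?
#' @param beta_prior_sd normal prior sd on fixed effects (log-odds).
#' @param pc_range0 reference range of the PC-style prior,
#'   P(range < pc_range0) = 0.5; default: domain diameter / 5 (set at
#'   fit time from the data).
#' @param pc_sigma0,pc_sigma_prob PC-style prior on the field sd:
#'   P(sigma > pc_sigma0) = pc_sigma_prob.
#' @param summary posterior point summary for odds ratios: "median"
#'   (default, robust) or "mean".
#' @return a `model_spec` object.
#' @export
model_spec <- function(terms = character(), outcome = "stunted",
                       spatial = FALSE, beta_prior_sd = 10,
                       pc_range0 = NULL, pc_sigma0 = 1,
                       pc_sigma_prob = 0.1,
                       summary = c("median", "mean")) {
  structure(list(terms = terms, outcome = outcome, spatial = isTRUE(spatial),
                 beta_prior_sd = beta_prior_sd, pc_range0 = pc_range0,
                 pc_sigma0 = pc_sigma0, pc_sigma_prob = pc_sigma_prob,
                 summary = match.arg(summary)),
            class = "model_spec")
}

#' MCMC controls
#'
#' Defaults are sized for desk-scale synthetic analyses; raise
#' `n_iter`/`chains` for production runs.
#'
#' @param n_iter iterations per chain (including burn-in).
#' @param burnin discarded initial iterations per chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param chains independent chains (>= 2 enables split-Rhat).
#' @param seed integer seed (chain c uses `seed + c`).
#' @param step_hyper initial random-walk sd for (log kappa, log tau);
#'   adapted during burn-in towards 20-40% acceptance.
#' @param hyper_steps Metropolis sub-steps for (kappa, tau) per Gibbs
#'   scan (cheap relative to the Gaussian block; improves mixing).
#' @param fix_hyper optional c(kappa, tau): hold the spatial
#'   hyperparameters fixed (no Metropolis step); mainly for degenerate
#'   checks such as collapsing the field by a huge tau.
#' @export
mcmc_control <- function(n_iter = 2500, burnin = 800, thin = 2, chains = 2,
                         seed = 1L, step_hyper = 0.4, hyper_steps = 3L,
                         fix_hyper = NULL) {
  stopifnot(n_iter > burnin, thin >= 1, chains >= 1)
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), chains = as.integer(chains),
                 seed = as.integer(seed), step_hyper = step_hyper,
                 hyper_steps = as.integer(hyper_steps),
                 fix_hyper = fix_hyper),
            class = "mcmc_control")
}

# Design matrix with catalogue-consistent factor coding (reference level
# first). Returns X plus a column map (term/level per column).
build_design <- function(table, spec, drop_unused = TRUE) {
  cat <- covariate_catalog()
  if (!length(spec$terms)) {
    X <- matrix(1, nrow(table), 1, dimnames = list(NULL, "(Intercept)"))
    return(list(X = X,
                map = data.frame(col = "(Intercept)", term = "(Intercept)",
                                 level = "", stringsAsFactors = FALSE)))
  }
  dat <- table[, spec$terms, drop = FALSE]
  terms <- spec$terms
  for (v in spec$terms) {
    lv <- if (v %in% names(cat)) cat[[v]]$levels else
      (if (is.factor(dat[[v]])) levels(dat[[v]]) else sort(unique(dat[[v]])))
    dat[[v]] <- factor(dat[[v]], levels = lv)
    if (drop_unused) {
      dat[[v]] <- droplevels(dat[[v]])
      if (nlevels(dat[[v]]) < 2) {
        warning("dropping term '", v,
                "': only one observed level in the data")
        terms <- setdiff(terms, v)
      }
    }
  }
  if (!length(terms)) {
    X <- matrix(1, nrow(table), 1, dimnames = list(NULL, "(Intercept)"))
    return(list(X = X,
                map = data.frame(col = "(Intercept)", term = "(Intercept)",
                                 level = "", stringsAsFactors = FALSE)))
  }
  X <- model.matrix(as.formula(paste("~", paste(terms, collapse = "+"))),
                    data = dat)
  if (drop_unused && qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient after reference coding")
  map <- data.frame(col = colnames(X), term = "(Intercept)", level = "",
                    stringsAsFactors = FALSE)
  for (v in spec$terms) {
    hit <- startsWith(map$col, v) & map$col != "(Intercept)"
    map$term[hit] <- v
    map$level[hit] <- substring(map$col[hit], nchar(v) + 1)
  }
  list(X = X, map = map)
}

# Warn if any covariate level perfectly predicts the outcome.
check_separation <- function(table, spec, y) {
  for (v in spec$terms) {
    tb <- table(table[[v]], y)
    if (any(tb == 0 & rowSums(tb) > 0))
      warning("possible separation: a level of '", v,
              "' perfectly predicts the outcome; the prior will dominate")
  }
}

#' Fit the non-spatial Bayesian logistic model
#'
#' Polya-Gamma-augmented Gibbs sampling: omega_i ~ PG(1, x_i' beta), then
#' beta | omega ~ N((X' Omega X + B0^-1)^-1 X'(y - 1/2), .) exactly.
#' No tuning parameters; convergence is reported via split-Rhat and
#' effective sample size.
#'
#' @param table child-level data (factors per the covariate catalogue).
#' @param spec a [model_spec()].
#' @param control an [mcmc_control()].
#' @return a `stunt_fit` with stacked post-burn-in draws.
#' @export
fit_nonspatial <- function(table, spec, control = mcmc_control()) {
  des <- build_design(table, spec)
  X <- des$X
  y <- table[[spec$outcome]]
  keep <- !is.na(y) & complete.cases(X)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  check_separation(table[keep, , drop = FALSE], spec, y)
  p <- ncol(X)
  B0inv <- diag(1 / spec$beta_prior_sd^2, p)
  kap <- y - 0.5
  Xt_kap <- crossprod(X, kap)

  n_keep <- length(seq(control$burnin + 1L, control$n_iter, by = control$thin))
  beta_draws <- matrix(NA_real_, n_keep * control$chains, p,
                       dimnames = list(NULL, colnames(X)))
  chain_id <- integer(n_keep * control$chains)
  row <- 0L
  for (ch in seq_len(control$chains)) {
    with_seed(control$seed + ch, {
      beta <- rep(0, p)
      for (it in seq_len(control$n_iter)) {
        eta <- as.numeric(X %*% beta)
        om <- rpg(eta)
        V <- chol2inv(chol(crossprod(X, X * om) + B0inv))
        m <- V %*% Xt_kap
        beta <- as.numeric(m + t(chol(V)) %*% rnorm(p))
        if (it > control$burnin &&
            (it - control$burnin - 1L) %% control$thin == 0L) {
          row <- row + 1L
          beta_draws[row, ] <- beta
          chain_id[row] <- ch
        }
      }
    })
  }
  out <- structure(list(
    beta = beta_draws, chain = chain_id, map = des$map, spec = spec,
    control = control, X = X, y = y, spatial = FALSE), class = "stunt_fit")
  out$diagnostics <- fit_diagnostics(out)
  out
}

#' Fit the geospatial Bayesian logistic model
#'
#' Joint Gibbs/Metropolis-within-Gibbs sampler: Polya-Gamma draws for the
#' augmentation variables; (beta, S) updated as one exact Gaussian block
#' with sparse joint precision [[X'OX + B0^-1, X'OA], [A'OX, Q + A'OA]];
#' (kappa, tau) by log-scale random-walk Metropolis (adapted to 20-40%
#' acceptance during burn-in) under PC-style priors on range and sd.
#'
#' @param table child-level data with `lon`/`lat` columns (cluster
#'   analysis coordinates).
#' @param spec a [model_spec()] (spatial implied).
#' @param mesh a `stunt_mesh` covering all locations (hard error
#'   otherwise).
#' @param control an [mcmc_control()].
#' @param coords names of the location columns.
#' @return a `stunt_fit` with `beta`, `S`, and `hyper` (kappa, tau) draws.
#' @export
fit_geospatial <- function(table, spec, mesh, control = mcmc_control(),
                           coords = c("lon", "lat")) {
  des <- build_design(table, spec)
  X <- des$X
  y <- table[[spec$outcome]]
  loc <- as.matrix(table[, coords])
  keep <- !is.na(y) & complete.cases(X) & complete.cases(loc)
  X <- X[keep, , drop = FALSE]; y <- y[keep]; loc <- loc[keep, , drop = FALSE]
  check_separation(table[keep, , drop = FALSE], spec, y)
  A <- projector(mesh, loc)
  if (any(attr(A, "outside")))
    stop("mesh/location mismatch: ", sum(attr(A, "outside")),
         " observation location(s) fall outside the mesh")
  p <- ncol(X); nv <- nrow(mesh$loc)
  B0inv <- Matrix::Diagonal(p, 1 / spec$beta_prior_sd^2)
  kap <- y - 0.5
  b_vec <- c(as.numeric(crossprod(X, kap)), as.numeric(Matrix::crossprod(A, kap)))

  diam <- sqrt(sum(apply(loc, 2, function(v) diff(range(v)))^2))
  range0 <- spec$pc_range0 %||% (diam / 5)
  lam_rho <- range0 * log(2)                       # P(range < range0) = 0.5
  lam_sig <- -log(spec$pc_sigma_prob) / spec$pc_sigma0  # P(sd > sigma0) = prob

  log_prior <- function(lk, lt) {
    kappa <- exp(lk); tau <- exp(lt)
    rho <- sqrt(8) / kappa
    sig <- 1 / (sqrt(4 * pi) * kappa * tau)
    # PC densities in (rho, sigma) plus the Jacobian to (log kappa, log tau)
    (log(lam_rho) - 2 * log(rho) - lam_rho / rho) +
      (log(lam_sig) - lam_sig * sig) + log(rho) + log(sig)
  }
  # precomputed SPDE ingredients: Q = tau^2 (k^4 C + 2 k^2 G + G C^-1 G)
  Cm <- mesh$C; Gm <- mesh$G
  M2 <- Matrix::forceSymmetric(
    Gm %*% Matrix::Diagonal(nrow(Cm), 1 / Matrix::diag(Cm)) %*% Gm)
  Qfun <- function(kappa, tau)
    Matrix::forceSymmetric(tau^2 * (kappa^4 * Cm + 2 * kappa^2 * Gm + M2))

  n_keep <- length(seq(control$burnin + 1L, control$n_iter, by = control$thin))
  tot <- n_keep * control$chains
  beta_draws <- matrix(NA_real_, tot, p, dimnames = list(NULL, colnames(X)))
  S_draws <- matrix(NA_real_, tot, nv)
  hyper_draws <- matrix(NA_real_, tot, 2, dimnames = list(NULL, c("kappa", "tau")))
  chain_id <- integer(tot)
  accept_rate <- numeric(control$chains)
  row <- 0L

  for (chn in seq_len(control$chains)) {
    with_seed(control$seed + chn, {
      fixed <- !is.null(control$fix_hyper)
      if (fixed) {
        lk <- log(control$fix_hyper[[1]]); lt <- log(control$fix_hyper[[2]])
      } else {
        lk <- log(sqrt(8) / range0)          # start at the prior median range
        lt <- log(matern_tau(exp(lk), 0.25)) # moderate field sd to start
      }
      beta <- rep(0, p); S <- rep(0, nv)
      chQ0 <- chol_or_diagnose(Qfun(exp(lk), exp(lt)))  # symbolic pattern
      chP0 <- NULL
      # Gaussian evidence of (kappa, tau) with (beta, S) integrated out,
      # given the current Polya-Gamma weights: 0.5 log|Q| - 0.5 log|P|
      # + 0.5 b'm with P the joint precision and m its mean solve.
      evidence <- function(lk, lt, XtWX, XtWA, AtWA) {
        Q <- Qfun(exp(lk), exp(lt))
        chQ <- suppressWarnings(
          tryCatch(Matrix::update(chQ0, Q), error = function(e) NULL))
        if (is.null(chQ)) return(NULL)
        ldQ <- 2 * as.numeric(Matrix::determinant(chQ, logarithm = TRUE,
                                                  sqrt = TRUE)$modulus)
        P <- Matrix::forceSymmetric(rbind(
          cbind(XtWX + B0inv, XtWA),
          cbind(Matrix::t(XtWA), Q + AtWA)))
        chP <- if (is.null(chP0)) chol_or_diagnose(P) else
          suppressWarnings(
            tryCatch(Matrix::update(chP0, P), error = function(e) NULL))
        if (is.null(chP)) return(NULL)
        chP0 <<- chP
        ldP <- 2 * as.numeric(Matrix::determinant(chP, logarithm = TRUE,
                                                  sqrt = TRUE)$modulus)
        m <- Matrix::solve(chP, b_vec, system = "A")
        list(lp = 0.5 * ldQ - 0.5 * ldP +
               0.5 * sum(b_vec * as.numeric(m)) + log_prior(lk, lt),
             chP = chP, m = as.numeric(m))
      }
      step <- control$step_hyper
      n_acc <- 0L; n_prop <- 0L
      for (it in seq_len(control$n_iter)) {
        eta <- as.numeric(X %*% beta) + as.numeric(A %*% S)
        om <- rpg(eta)
        XtWX <- Matrix::Matrix(crossprod(X, X * om), sparse = TRUE)
        XtWA <- Matrix::crossprod(Matrix::Matrix(X * om, sparse = TRUE), A)
        AtWA <- Matrix::crossprod(A, A * om)
        cur <- evidence(lk, lt, XtWX, XtWA, AtWA)
        if (is.null(cur)) stop("joint precision factorization failed")
        # --- collapsed Metropolis for (log kappa, log tau) ---
        for (sub in seq_len(if (fixed) 0L else control$hyper_steps)) {
          # correlated proposal along the variance-preserving ridge
          dlk <- rnorm(1, 0, step)
          lk_p <- lk + dlk
          lt_p <- lt - dlk + rnorm(1, 0, 0.6 * step)
          prop <- evidence(lk_p, lt_p, XtWX, XtWA, AtWA)
          n_prop <- n_prop + 1L
          if (!is.null(prop) && is.finite(prop$lp) &&
              log(runif(1)) < prop$lp - cur$lp) {
            lk <- lk_p; lt <- lt_p; cur <- prop
            n_acc <- n_acc + 1L
          }
        }
        # --- exact Gaussian draw of (beta, S) given (kappa, tau, omega) ---
        z <- rnorm(p + nv)
        u <- Matrix::solve(cur$chP, Matrix::solve(cur$chP, z, system = "Lt"),
                           system = "Pt")
        theta <- cur$m + as.numeric(u)
        beta <- theta[seq_len(p)]
        S <- theta[-seq_len(p)]
        if (it <= control$burnin && it %% 25L == 0L) {
          rate <- n_acc / max(n_prop, 1L)
          step <- min(2, max(0.02, step * exp(rate - 0.3)))
          n_acc <- 0L; n_prop <- 0L
        }
        if (it > control$burnin &&
            (it - control$burnin - 1L) %% control$thin == 0L) {
          row <- row + 1L
          beta_draws[row, ] <- beta
          S_draws[row, ] <- S
          hyper_draws[row, ] <- c(exp(lk), exp(lt))
          chain_id[row] <- chn
        }
      }
      accept_rate[chn] <- if (n_prop > 0) n_acc / n_prop else NA_real_
    })
  }
  out <- structure(list(
    beta = beta_draws, S = S_draws, hyper = hyper_draws, chain = chain_id,
    map = des$map, spec = spec, control = control, X = X, y = y,
    A = A, mesh = mesh, accept_rate = accept_rate, spatial = TRUE),
    class = "stunt_fit")
  out$diagnostics <- fit_diagnostics(out)
  out
}

#' @export
print.stunt_fit <- function(x, ...) {
  cat(sprintf("<stunt_fit> %s logistic model: %d obs, %d fixed effects, %d draws (%d chain%s)\n",
              if (x$spatial) "geospatial" else "non-spatial",
              length(x$y), ncol(x$beta), nrow(x$beta),
              x$control$chains, if (x$control$chains > 1) "s" else ""))
  d <- x$diagnostics
  cat(sprintf("  max split-Rhat %.3f, min ESS %.0f%s\n",
              max(d$rhat, na.rm = TRUE), min(d$ess, na.rm = TRUE),
              if (isTRUE(d$converged)) "" else "  [convergence flagged]"))
  invisible(x)
}

## ---- convergence diagnostics -----------------------------------------

split_rhat <- function(draws, chain) {
  # split each chain in half -> 2C sequences; standard potential scale
  # reduction factor
  seqs <- list()
  for (ch in unique(chain)) {
    x <- draws[chain == ch]
    h <- floor(length(x) / 2)
    if (h < 2) return(NA_real_)
    seqs <- c(seqs, list(x[1:h]), list(x[(h + 1):(2 * h)]))
  }
  m <- length(seqs); n <- length(seqs[[1]])
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, var, numeric(1))
  B <- n * var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(draws, chain) {
  # initial positive-sequence estimator, summed across chains
  total <- 0
  for (ch in unique(chain)) {
    x <- draws[chain == ch]
    n <- length(x)
    if (n < 4 || var(x) == 0) { total <- total + n; next }
    rho <- acf(x, lag.max = min(n - 2, 200), plot = FALSE)$acf[-1]
    s <- 0
    for (k in seq_along(rho)) {
      if (rho[k] < 0.01) break
      s <- s + rho[k]
    }
    total <- total + n / (1 + 2 * s)
  }
  total
}

fit_diagnostics <- function(fit, rhat_limit = 1.05, ess_limit = 200) {
  p <- ncol(fit$beta)
  mats <- fit$beta
  if (fit$spatial) mats <- cbind(mats, log(fit$hyper))
  rhat <- apply(mats, 2, split_rhat, chain = fit$chain)
  ess <- apply(mats, 2, ess_basic, chain = fit$chain)
  conv <- all(is.na(rhat) | rhat <= rhat_limit) && all(ess >= min(ess_limit, nrow(mats) / 2))
  list(rhat = rhat, ess = ess, converged = conv)
}

## ---- posterior summaries ---------------------------------------------

# Percentile by sorted-array linear interpolation (matches type-7).
percentile <- function(x, prob) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * prob + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

#' Summarise fixed effects as odds ratios with credible intervals
#'
#' OR = exp(posterior median) (or mean, per the spec) of each
#' non-reference coefficient; 95% CrI from the 2.5/97.5 percentiles of
#' the exponentiated draws; a level is flagged significant when its CrI
#' excludes 1.
#'
#' @param fit a `stunt_fit` with at least 100 retained draws.
#' @return data.frame of OR rows (term, level, or, cri_low, cri_high,
#'   significant).
#' @export
summarize_or <- function(fit) {
  if (nrow(fit$beta) < 100)
    stop("need at least 100 retained draws to summarise")
  map <- fit$map
  rows <- lapply(which(map$term != "(Intercept)"), function(j) {
    d <- fit$beta[, map$col[j]]
    point <- if (fit$spec$summary == "median") median(d) else mean(d)
    lo <- exp(percentile(d, 0.025))
    hi <- exp(percentile(d, 0.975))
    data.frame(term = map$term[j], level = map$level[j],
               or = exp(point), cri_low = lo, cri_high = hi,
               significant = (lo > 1) | (hi < 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarise the spatial hyperparameters
#'
#' Posterior median and 95% CrI of kappa, the Matern marginal variance
#' and the range, in native coordinate units plus a km conversion at the
#' data's mean latitude (reported side by side; no unit agreement is
#' forced).
#'
#' @param fit a spatial `stunt_fit`.
#' @param lat reference latitude for the km conversion (default: mean of
#'   the fitted locations).
#' @export
summarize_hyper <- function(fit, lat = NULL) {
  stopifnot(fit$spatial)
  kappa <- fit$hyper[, "kappa"]; tau <- fit$hyper[, "tau"]
  mp <- matern_params_from(kappa, tau)
  if (is.null(lat)) lat <- mean(fit$mesh$loc[, 2])
  summ <- function(x) c(est = median(x), lo = percentile(x, 0.025),
                        hi = percentile(x, 0.975))
  out <- rbind(kappa = summ(kappa), variance = summ(mp$variance),
               range = summ(mp$range),
               range_km = summ(degrees_to_km(mp$range, lat)))
  as.data.frame(out)
}

#' Save posterior draws and OR table to a fit directory
#'
#' Plain-text archive: `beta.csv` (draws x coefficients), `hyper.csv` and
#' `S.csv` for spatial fits, `or_table.csv`, and `meta.json` (spec,
#' controls, diagnostics, seeds).
#'
#' @param fit a `stunt_fit`; `dir` output directory.
#' @param dir output directory.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(fit$beta), file.path(dir, "beta.csv"),
            row.names = FALSE)
  if (fit$spatial) {
    write.csv(as.data.frame(fit$hyper), file.path(dir, "hyper.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(fit$S), file.path(dir, "S.csv"), row.names = FALSE)
  }
  write.csv(summarize_or(fit), file.path(dir, "or_table.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(
    spatial = fit$spatial, terms = fit$spec$terms,
    control = unclass(fit$control),
    diagnostics = lapply(fit$diagnostics, unname)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
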