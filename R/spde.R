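## SPDE (alpha = 2) representation of the Matern (nu = 1) Gaussian field.
## The smoothness is fixed at nu = 1 (alpha = 2 in two dimensions), the
## standard choice for this class of prevalence-mapping models; it is a
## documented constant, not a tuning knob.

#' Matern range and marginal variance implied by (kappa, tau)
#'
#' For the alpha = 2 SPDE in two dimensions: range = sqrt(8)/kappa (the
#' distance at which correlation falls to ~0.1) and marginal variance
#' sigma^2 = 1 / (4 pi kappa^2 tau^2).
#'
#' @param kappa,tau positive SPDE parameters (kappa per coordinate unit).
#' @return list with `range` and `variance` (vectorised).
#' @export
matern_params_from <- function(kappa, tau) {
  if (any(kappa <= 0) || any(tau <= 0))
    stop("domain error: kappa and tau must be positive")
  list(range = sqrt(8) / kappa,
       variance = 1 / (4 * pi * kappa^2 * tau^2))
}

#' Tau achieving a target marginal variance at given kappa
#'
#' Inverts sigma^2 = 1/(4 pi kappa^2 tau^2).
#'
#' @param kappa SPDE scale parameter; `variance` target marginal variance.
#' @param variance target marginal variance.
#' @export
matern_tau <- function(kappa, variance) {
  if (any(kappa <= 0) || any(variance <= 0))
    stop("domain error: kappa and variance must be positive")
  1 / (kappa * sqrt(4 * pi * variance))
}

#' Matern (nu = 1) correlation function
#'
#' rho(r) = (kappa r) K_1(kappa r), with rho(0) = 1.
#'
#' @param r distances (same units as 1/kappa); `kappa` scale parameter.
#' @param kappa SPDE scale parameter.
#' @export
matern_correlation <- function(r, kappa) {
  out <- kappa * r * besselK(kappa * r, 1)
  out[r == 0] <- 1
  out
}

#' Convert a distance in degrees to kilometres at a reference latitude
#'
#' Reporting helper: one degree of latitude is ~110.57 km and one degree
#' of longitude ~111.32 cos(lat) km; the average of the two local scales
#' is used. Model fitting itself stays in raw degree units.
#'
#' @param deg distance in degrees; `lat` reference latitude in degrees.
#' @param lat reference latitude (degrees).
#' @export
degrees_to_km <- function(deg, lat) {
  deg * (110.574 + 111.320 * cos(lat * pi / 180)) / 2
}

#' SPDE (alpha = 2) precision matrix
#'
#' Q = tau^2 (kappa^4 C + 2 kappa^2 G + G C^-1 G) with lumped mass C and
#' stiffness G from the mesh; sparse, symmetric positive definite.
#'
#' @param mesh a `stunt_mesh`.
#' @param kappa,tau positive SPDE parameters.
#' @return sparse symmetric precision matrix (`dsCMatrix`).
#' @export
spde_precision <- function(mesh, kappa, tau) {
  if (kappa <= 0 || tau <= 0) stop("domain error: kappa, tau must be positive")
  C <- mesh$C; G <- mesh$G
  Cinv <- Matrix::Diagonal(nrow(C), 1 / Matrix::diag(C))
  Q <- tau^2 * (kappa^4 * C + 2 * kappa^2 * G + G %*% Cinv %*% G)
  Matrix::forceSymmetric((Q + Matrix::t(Q)) / 2)
}

# Sparse Cholesky of Q; reports the smallest-eigenvalue estimate when the
# factorisation fails (numerically non-SPD precision).
chol_or_diagnose <- function(Q) {
  tryCatch(
    Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE),
    error = function(e) {
      lam <- tryCatch(
        min(eigen(as.matrix(Q), symmetric = TRUE, only.values = TRUE)$values),
        error = function(e2) NA_real_)
      stop(sprintf(
        "precision factorization failed (%s); smallest eigenvalue estimate: %g",
        conditionMessage(e), lam), call. = FALSE)
    })
}

#' Simulate zero-mean Gaussian fields with SPDE precision
#'
#' Draws x ~ N(0, Q(kappa, tau)^-1) at the mesh vertices via the sparse
#' Cholesky factorisation Q = P' L L' P, x = P' L^-T z.
#'
#' @param mesh a `stunt_mesh`.
#' @param kappa,tau positive SPDE parameters (defaults: DHS-scale truth
#'   kappa = 7.33 with marginal variance 0.24).
#' @param n number of independent draws.
#' @param seed optional integer seed.
#' @return n_vertices x n matrix of field draws.
#' @export
simulate_spatial_field <- function(mesh, kappa = 7.33,
                                   tau = matern_tau(7.33, 0.24),
                                   n = 1, seed = NULL) {
  Q <- spde_precision(mesh, kappa, tau)
  ch <- chol_or_diagnose(Q)
  nv <- nrow(Q)
  with_seed(seed, {
    z <- matrix(rnorm(nv * n), nv, n)
    x <- Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"), system = "Pt")
  })
  as.matrix(x)
}

#' Write a sparse matrix in MatrixMarket format
#'
#' @param M sparse matrix; `path` output `.mtx` file.
#' @param path output path.
#' @export
write_mtx <- function(M, path) {
  Matrix::writeMM(as(M, "generalMatrix"), path)
  invisible(path)
}
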