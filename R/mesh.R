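## Triangulated mesh for the SPDE representation of the Matern field:
## Bowyer-Watson Delaunay triangulation, cutoff thinning, convex boundary
## extension ring, and linear finite-element matrices (lumped mass C,
## stiffness G).

# Circumcentre and squared circumradius of triangles (vectorised).
circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  r2[!is.finite(r2)] <- Inf
  cbind(ux, uy, r2)
}

#' Delaunay triangulation of planar points (Bowyer-Watson)
#'
#' Incremental insertion with a super-triangle; a deterministic
#' micro-jitter (relative magnitude 1e-9) breaks cocircular ties such as
#' regular grids, and the jittered coordinates are the ones returned so
#' the triangulation is exactly Delaunay for the coordinates used.
#'
#' @param pts n x 2 coordinate matrix, n >= 3, not all collinear.
#' @return list with `loc` (possibly jittered coordinates) and `tri`
#'   (m x 3 matrix of vertex indices, counter-clockwise).
#' @export
delaunay_triangulate <- function(pts) {
  n0 <- nrow(pts)
  if (n0 < 3) stop("mesh error: need at least 3 points")
  ctr <- colMeans(pts)
  scl <- max(apply(pts, 2, function(v) diff(range(v))), 1e-12)
  P <- sweep(sweep(pts, 2, ctr), 2, rep(scl, 2), "/")
  # deterministic tie-breaking jitter (order-dependent, seed-free)
  h1 <- ((seq_len(n0) * 2654435761) %% 1000003) / 1000003 - 0.5
  h2 <- ((seq_len(n0) * 40503 + 17) %% 999983) / 999983 - 0.5
  P <- P + 1e-9 * cbind(h1, h2)
  if (abs(polygon_area(P[grDevices::chull(P), , drop = FALSE])) < 1e-6)
    stop("mesh error: points are (nearly) collinear")
  # super-triangle well outside the unit-scale cloud
  sv <- rbind(c(0, 40), c(-40, -30), c(40, -30))
  P <- rbind(P, sv)
  s1 <- n0 + 1L; s2 <- n0 + 2L; s3 <- n0 + 3L

  cap <- max(64L, 8L * n0)
  tri <- matrix(0L, cap, 3)
  cc <- matrix(0, cap, 3)        # ux, uy, r2
  alive <- logical(cap)
  tri[1, ] <- c(s1, s2, s3)
  cc[1, ] <- circumcircle(P[s1, 1], P[s1, 2], P[s2, 1], P[s2, 2], P[s3, 1], P[s3, 2])
  alive[1] <- TRUE
  ntri <- 1L

  for (i in seq_len(n0)) {
    px <- P[i, 1]; py <- P[i, 2]
    idx <- which(alive[seq_len(ntri)])
    bad <- idx[(px - cc[idx, 1])^2 + (py - cc[idx, 2])^2 <= cc[idx, 3]]
    if (!length(bad)) stop("mesh error: point not inside any circumcircle")
    # cavity boundary = edges of bad triangles appearing exactly once
    e <- rbind(tri[bad, c(1, 2), drop = FALSE],
               tri[bad, c(2, 3), drop = FALSE],
               tri[bad, c(3, 1), drop = FALSE])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    tab <- table(key)
    bnd <- e[key %in% names(tab)[tab == 1L], , drop = FALSE]
    alive[bad] <- FALSE
    m <- nrow(bnd)
    if (ntri + m > cap) {  # grow storage
      extra <- max(m, cap)
      tri <- rbind(tri, matrix(0L, extra, 3))
      cc <- rbind(cc, matrix(0, extra, 3))
      alive <- c(alive, logical(extra))
      cap <- cap + extra
    }
    rows <- ntri + seq_len(m)
    tri[rows, ] <- cbind(bnd, i)
    cc[rows, ] <- circumcircle(P[bnd[, 1], 1], P[bnd[, 1], 2],
                               P[bnd[, 2], 1], P[bnd[, 2], 2], px, py)
    alive[rows] <- TRUE
    ntri <- ntri + m
  }

  keep <- which(alive[seq_len(ntri)])
  T <- tri[keep, , drop = FALSE]
  T <- T[T[, 1] <= n0 & T[, 2] <= n0 & T[, 3] <= n0, , drop = FALSE]
  loc <- sweep(P[seq_len(n0), , drop = FALSE] * scl, 2, -ctr)
  # enforce counter-clockwise orientation
  ar <- (loc[T[, 2], 1] - loc[T[, 1], 1]) * (loc[T[, 3], 2] - loc[T[, 1], 2]) -
    (loc[T[, 3], 1] - loc[T[, 1], 1]) * (loc[T[, 2], 2] - loc[T[, 1], 2])
  flip <- ar < 0
  T[flip, ] <- T[flip, c(1, 3, 2), drop = FALSE]
  T <- T[abs(ar) > 1e-14, , drop = FALSE]
  list(loc = loc, tri = T)
}

# Greedy thinning: keep points pairwise farther apart than cutoff.
thin_points <- function(pts, cutoff) {
  if (cutoff <= 0 || nrow(pts) < 2) return(pts)
  keep <- 1L
  for (i in 2:nrow(pts)) {
    d2 <- (pts[keep, 1] - pts[i, 1])^2 + (pts[keep, 2] - pts[i, 2])^2
    if (min(d2) >= cutoff^2) keep <- c(keep, i)
  }
  pts[keep, , drop = FALSE]
}

# Convex extension: concentric scaled-hull rings with graded spacing, so
# the annulus between the data and the artificial boundary is triangulated
# gradually rather than by one layer of stretched triangles.
extension_ring <- function(pts, offset, spacing) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  ctr <- colMeans(hull)
  dirs <- sweep(hull, 2, ctr)
  len <- sqrt(rowSums(dirs^2))
  one_ring <- function(off, sp) {
    ring <- sweep(dirs * (1 + off / pmax(len, 1e-12)), 2, ctr, "+")
    out <- NULL
    n <- nrow(ring)
    for (i in seq_len(n)) {
      a <- ring[i, ]; b <- ring[if (i == n) 1L else i + 1L, ]
      seg <- sqrt(sum((b - a)^2))
      k <- max(1L, ceiling(seg / sp))
      t <- (seq_len(k) - 1) / k
      out <- rbind(out, cbind(a[1] + t * (b[1] - a[1]),
                              a[2] + t * (b[2] - a[2])))
    }
    out
  }
  fracs <- c(1 / 3, 2 / 3, 1)
  do.call(rbind, lapply(seq_along(fracs), function(i)
    one_ring(offset * fracs[i], spacing * (0.6 + 0.4 * i))))
}

#' Build a finite-element mesh over observation locations
#'
#' Points are thinned so no two retained points lie closer than `cutoff`,
#' a convex extension ring is added around the cloud to push the
#' artificial Neumann boundary away from the data (mitigating boundary
#' variance inflation), and the union is Delaunay-triangulated. Lumped
#' mass (`C`, diagonal) and stiffness (`G`) matrices are assembled with
#' linear elements. Coordinates are raw lon/lat degrees.
#'
#' @param points n x 2 matrix of locations (degrees).
#' @param max_edge c(interior, extension) target edge lengths; the second
#'   entry sets the spacing of ring points.
#' @param cutoff minimum distance between retained points (degrees).
#' @param boundary_extension outward offset of the extension ring in
#'   degrees; 0 suppresses the ring. Default: 15% of the cloud diameter.
#' @param fill_spacing optional spacing of extra interior steiner points
#'   (NULL = none; supply e.g. `max_edge[1]` for a space-filling mesh).
#' @return object of class `stunt_mesh`: `loc`, `tri`, `boundary` flag,
#'   sparse `C` and `G`.
#' @export
build_mesh <- function(points, max_edge = c(0.5, 1), cutoff = 0.05,
                       boundary_extension = NULL, fill_spacing = NULL) {
  points <- as.matrix(points)
  if (length(max_edge) == 1) max_edge <- rep(max_edge, 2)
  diam <- sqrt(sum(apply(points, 2, function(v) diff(range(v)))^2))
  if (is.null(boundary_extension)) boundary_extension <- 0.15 * max(diam, 1e-6)
  kept <- thin_points(points, cutoff)
  if (nrow(kept) < 3)
    stop("mesh error: cutoff leaves fewer than 3 points")
  all_pts <- kept
  if (!is.null(fill_spacing)) {
    hull <- kept[grDevices::chull(kept), , drop = FALSE]
    gx <- seq(min(kept[, 1]), max(kept[, 1]), by = fill_spacing)
    gy <- seq(min(kept[, 2]), max(kept[, 2]), by = fill_spacing)
    grid <- as.matrix(expand.grid(gx, gy))
    inside <- point_in_polygon(grid, hull)
    grid <- grid[inside, , drop = FALSE]
    if (nrow(grid)) {
      dmin <- apply(grid, 1, function(g)
        sqrt(min((all_pts[, 1] - g[1])^2 + (all_pts[, 2] - g[2])^2)))
      all_pts <- rbind(all_pts, grid[dmin > 0.45 * fill_spacing, , drop = FALSE])
    }
  }
  if (boundary_extension > 0) {
    ring <- extension_ring(all_pts, boundary_extension, max_edge[2])
    all_pts <- rbind(all_pts, ring)
  }
  dt <- delaunay_triangulate(all_pts)
  fem <- fem_matrices(dt$loc, dt$tri)
  bnd <- boundary_vertices(dt$tri, nrow(dt$loc))
  structure(list(loc = dt$loc, tri = dt$tri, boundary = bnd,
                 C = fem$C, G = fem$G), class = "stunt_mesh")
}

#' @export
print.stunt_mesh <- function(x, ...) {
  cat(sprintf("<stunt_mesh> %d vertices, %d triangles (%d boundary vertices)\n",
              nrow(x$loc), nrow(x$tri), sum(x$boundary)))
  invisible(x)
}

# Vertices on the outer boundary: endpoints of edges used by one triangle.
boundary_vertices <- function(tri, nv) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  once <- e[key %in% names(tab)[tab == 1L], , drop = FALSE]
  flag <- logical(nv)
  flag[unique(as.vector(once))] <- TRUE
  flag
}

#' Linear finite-element matrices on a triangulation
#'
#' `C` is the lumped (diagonal) mass matrix, `C_ii = sum(area)/3` over
#' incident triangles; `G` the stiffness matrix with per-element entries
#' `(e_i . e_j) / (4 A)` for opposite-edge vectors `e_i`. `G` is
#' symmetric with zero row sums (constants lie in its kernel).
#'
#' @param loc vertex coordinates, `tri` triangle index matrix.
#' @param tri m x 3 integer matrix.
#' @return list with sparse `C` (diagonal) and `G` (symmetric).
#' @export
fem_matrices <- function(loc, tri) {
  nv <- nrow(loc)
  p1 <- loc[tri[, 1], , drop = FALSE]
  p2 <- loc[tri[, 2], , drop = FALSE]
  p3 <- loc[tri[, 3], , drop = FALSE]
  e1 <- p3 - p2; e2 <- p1 - p3; e3 <- p2 - p1   # edge opposite vertex k
  area <- 0.5 * abs(e3[, 1] * (-e2[, 2]) - e3[, 2] * (-e2[, 1]))
  if (any(area <= 0)) stop("mesh error: degenerate (zero-area) triangle")
  cdiag <- numeric(nv)
  for (k in 1:3) {
    idx <- tri[, k]
    cdiag <- cdiag + unname(tapply(area / 3, factor(idx, levels = seq_len(nv)),
                                   sum, default = 0))
  }
  E <- list(e1, e2, e3)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (a in 1:3) for (b in 1:3) {
    ii <- c(ii, tri[, a]); jj <- c(jj, tri[, b])
    xx <- c(xx, rowSums(E[[a]] * E[[b]]) / (4 * area))
  }
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nv, nv))
  G <- Matrix::forceSymmetric((G + Matrix::t(G)) / 2)
  list(C = Matrix::Diagonal(nv, cdiag), G = G)
}

#' Projector (barycentric interpolation) matrix
#'
#' Maps mesh-vertex field values to arbitrary locations: each row holds
#' the barycentric weights of the location within its containing
#' triangle (at most 3 nonzeros summing to 1). Locations outside the
#' mesh get an all-zero row and are flagged.
#'
#' @param mesh a `stunt_mesh`.
#' @param locations n x 2 matrix in mesh coordinates (degrees).
#' @return sparse `dgCMatrix` (n x n_vertices) with logical attribute
#'   `"outside"` marking rows with no containing triangle.
#' @export
projector <- function(mesh, locations) {
  if (is.null(dim(locations))) locations <- matrix(locations, ncol = 2)
  loc <- mesh$loc; tri <- mesh$tri
  nt <- nrow(tri)
  # triangle bounding boxes for candidate prefiltering
  tx1 <- pmin(loc[tri[, 1], 1], loc[tri[, 2], 1], loc[tri[, 3], 1])
  tx2 <- pmax(loc[tri[, 1], 1], loc[tri[, 2], 1], loc[tri[, 3], 1])
  ty1 <- pmin(loc[tri[, 1], 2], loc[tri[, 2], 2], loc[tri[, 3], 2])
  ty2 <- pmax(loc[tri[, 1], 2], loc[tri[, 2], 2], loc[tri[, 3], 2])
  n <- nrow(locations)
  ii <- jj <- integer(0); xx <- numeric(0)
  outside <- logical(n)
  tol <- 1e-9
  for (q in seq_len(n)) {
    px <- locations[q, 1]; py <- locations[q, 2]
    cand <- which(px >= tx1 - tol & px <= tx2 + tol &
                    py >= ty1 - tol & py <= ty2 + tol)
    hit <- FALSE
    for (t in cand) {
      a <- loc[tri[t, 1], ]; b <- loc[tri[t, 2], ]; c <- loc[tri[t, 3], ]
      det <- (b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])
      w2 <- ((px - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (py - a[2])) / det
      w3 <- ((b[1] - a[1]) * (py - a[2]) - (px - a[1]) * (b[2] - a[2])) / det
      w1 <- 1 - w2 - w3
      if (w1 >= -tol && w2 >= -tol && w3 >= -tol) {
        w <- pmax(c(w1, w2, w3), 0); w <- w / sum(w)
        ii <- c(ii, rep(q, 3)); jj <- c(jj, tri[t, ]); xx <- c(xx, w)
        hit <- TRUE
        break
      }
    }
    if (!hit) outside[q] <- TRUE
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n, nrow(loc)))
  attr(A, "outside") <- outside
  A
}

#' Serialise / restore a mesh as JSON
#'
#' Stores vertices, triangles and boundary flags; FEM matrices are
#' re-assembled on read.
#'
#' @param mesh a `stunt_mesh`; `path` file path.
#' @export
write_mesh_json <- function(mesh, path) {
  jsonlite::write_json(list(
    vertices = unname(as.matrix(mesh$loc)),
    triangles = unname(as.matrix(mesh$tri)),
    boundary = mesh$boundary), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mesh_json
#' @export
read_mesh_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fem <- fem_matrices(obj$vertices, obj$triangles)
  structure(list(loc = obj$vertices, tri = obj$triangles,
                 boundary = as.logical(obj$boundary),
                 C = fem$C, G = fem$G), class = "stunt_mesh")
}
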