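## Gridded posterior prevalence prediction and admin-level aggregation.
## Aggregation happens at the draw level so unit and national credible
## intervals are coherent (not aggregates of pixel-wise intervals).

#' Predict the posterior prevalence surface on a raster grid
#'
#' For each retained draw d and pixel g:
#' p_dg = plogis(x_g' beta_d + (A_grid S_d)_g), where x_g holds the
#' raster-backed covariate categories of the pixel (DLST, rainfall,
#' aridity, urbanisation bands) and every survey-only covariate sits at
#' its reference level. Pixels outside the country polygon, outside the
#' mesh, or with missing covariates are masked (count reported via
#' attribute `"n_masked"`).
#'
#' @param fit a spatial `stunt_fit`.
#' @param rasters named list of `grid_raster`s for raster-backed model
#'   terms (continuous; categorised internally). May be empty.
#' @param mesh the mesh used at fit time.
#' @param grid_spec either a `grid_raster` supplying the grid geometry or
#'   a cell size in degrees (default 0.05, ~5 km).
#' @param boundary country polygon for masking (default: bbox of the
#'   mesh's non-extension area is not known, so no mask unless given).
#' @param ndraws posterior draws used (evenly spaced subsample).
#' @return a `prevalence_surface`: grid geometry, per-pixel posterior
#'   mean and 2.5/97.5% bounds (`grid_raster`s), the draw-level pixel
#'   matrix, and the pixel index kept.
#' @export
predict_grid <- function(fit, rasters = list(), mesh = fit$mesh,
                         grid_spec = 0.05, boundary = NULL, ndraws = 200) {
  stopifnot(fit$spatial)
  if (inherits(grid_spec, "grid_raster")) {
    geom <- grid_spec
  } else {
    bb <- c(min(mesh$loc[, 1]), max(mesh$loc[, 1]),
            min(mesh$loc[, 2]), max(mesh$loc[, 2]))
    if (!is.null(boundary))
      bb <- c(min(boundary[, 1]), max(boundary[, 1]),
              min(boundary[, 2]), max(boundary[, 2]))
    geom <- raster_from_function(bb, grid_spec,
                                 function(lon, lat) rep(0, length(lon)))
  }
  xy <- raster_coords(geom)
  pix <- cbind(rep(xy$lon, each = geom$nrow), rep(xy$lat, times = geom$ncol))
  # column-major pixel order: (row, col) = (i, j) at index (j-1)*nrow + i
  ok <- rep(TRUE, nrow(pix))
  if (!is.null(boundary)) ok <- ok & point_in_polygon(pix, boundary)
  A_grid <- projector(mesh, pix)
  ok <- ok & !attr(A_grid, "outside")

  # raster-backed covariate categories per pixel
  cat <- covariate_catalog()
  terms <- fit$spec$terms
  newdata <- data.frame(row.names = seq_len(nrow(pix)))
  for (v in terms) {
    if (v %in% names(rasters)) {
      vals <- raster_value_at(rasters[[v]], pix)
      ok <- ok & !is.na(vals)
      vals[is.na(vals)] <- vals[which(!is.na(vals))[1]]
      newdata[[v]] <- if (v %in% c("dlst", "rainfall", "aridity",
                                   "urbanization"))
        categorize_climate(vals, v)
      else stop("raster supplied for non-climate term: ", v)
    } else {
      lv <- cat[[v]]$levels[1]
      newdata[[v]] <- factor(rep(lv, nrow(pix)), levels = cat[[v]]$levels)
    }
  }
  des <- build_design(cbind(newdata,
                            setNames(data.frame(rep(0, nrow(pix))),
                                     fit$spec$outcome)), fit$spec,
                      drop_unused = FALSE)
  Xg <- des$X[, colnames(fit$beta), drop = FALSE]

  idx <- round(seq(1, nrow(fit$beta), length.out = min(ndraws, nrow(fit$beta))))
  keep <- which(ok)
  eta <- Xg[keep, , drop = FALSE] %*% t(fit$beta[idx, , drop = FALSE]) +
    A_grid[keep, , drop = FALSE] %*% t(fit$S[idx, , drop = FALSE])
  p <- plogis(as.matrix(eta))              # n_pix_kept x ndraws

  fill <- function(v) {
    m <- matrix(NA_real_, geom$nrow, geom$ncol)
    m[keep] <- v
    m
  }
  means <- rowMeans(p)
  los <- apply(p, 1, percentile, prob = 0.025)
  his <- apply(p, 1, percentile, prob = 0.975)
  structure(list(
    geom = geom,
    mean = grid_raster(fill(means), geom$xmin, geom$ymin, geom$res,
                       name = "prevalence_mean"),
    lower = grid_raster(fill(los), geom$xmin, geom$ymin, geom$res,
                        name = "prevalence_q025"),
    upper = grid_raster(fill(his), geom$xmin, geom$ymin, geom$res,
                        name = "prevalence_q975"),
    p_draws = p, pixel_index = keep, pixel_lonlat = pix[keep, , drop = FALSE],
    n_masked = sum(!ok)), class = "prevalence_surface")
}

#' @export
print.prevalence_surface <- function(x, ...) {
  cat(sprintf("<prevalence_surface> %d x %d grid, %d valid pixels, %d draws\n",
              x$geom$nrow, x$geom$ncol, length(x$pixel_index), ncol(x$p_draws)))
  invisible(x)
}

#' Aggregate a prevalence surface to administrative units
#'
#' Per posterior draw, the unit prevalence is the (population-weighted)
#' mean of its pixels; posterior mean and 95% CrI are then taken over
#' draws, so unit intervals are coherent with the pixel-level posterior.
#' Units containing no valid pixel are reported with NA and flagged.
#'
#' @param surface a `prevalence_surface`.
#' @param admin_map an `admin_map`.
#' @param level admin level (1 or 2).
#' @param pop_raster optional population `grid_raster` for weighting
#'   (equal weights when NULL).
#' @return data.frame of admin estimates in percent: unit id, prevalence
#'   mean, `cri_low`, `cri_high`, `n_pixels`, `pop_weight`.
#' @export
aggregate_admin <- function(surface, admin_map, level = 2, pop_raster = NULL) {
  polys <- if (level == 1) admin_map$admin1$polys else admin_map$admin2$polys
  ids <- if (level == 1) admin_map$admin1$ids else admin_map$admin2$ids
  pts <- surface$pixel_lonlat
  w <- if (is.null(pop_raster)) rep(1, nrow(pts)) else
    raster_value_at(pop_raster, pts)
  w[is.na(w) | w < 0] <- 0
  rows <- lapply(seq_along(polys), function(k) {
    inside <- point_in_polygon(pts, polys[[k]])
    if (!any(inside) || sum(w[inside]) == 0)
      return(data.frame(level = level, id = ids[k], prevalence = NA_real_,
                        cri_low = NA_real_, cri_high = NA_real_,
                        n_pixels = 0L, pop_weight = 0,
                        stringsAsFactors = FALSE))
    wk <- w[inside] / sum(w[inside])
    unit_draws <- as.numeric(wk %*% surface$p_draws[inside, , drop = FALSE])
    data.frame(level = level, id = ids[k],
               prevalence = 100 * mean(unit_draws),
               cri_low = 100 * percentile(unit_draws, 0.025),
               cri_high = 100 * percentile(unit_draws, 0.975),
               n_pixels = sum(inside), pop_weight = sum(w[inside]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$n_pixels == 0))
    warning(sum(out$n_pixels == 0), " unit(s) contain no valid pixel")
  out
}

#' National prevalence summary
#'
#' Country-level estimate by the same draw-level aggregation over all
#' valid pixels.
#'
#' @inheritParams aggregate_admin
#' @return one-row data.frame (percent scale).
#' @export
national_summary <- function(surface, admin_map = NULL, pop_raster = NULL) {
  pts <- surface$pixel_lonlat
  w <- if (is.null(pop_raster)) rep(1, nrow(pts)) else
    raster_value_at(pop_raster, pts)
  w[is.na(w) | w < 0] <- 0
  wk <- w / sum(w)
  nat <- as.numeric(wk %*% surface$p_draws)
  data.frame(level = 0, id = "national",
             prevalence = 100 * mean(nat),
             cri_low = 100 * percentile(nat, 0.025),
             cri_high = 100 * percentile(nat, 0.975),
             n_pixels = nrow(pts), pop_weight = sum(w),
             stringsAsFactors = FALSE)
}

#' Render admin-level choropleth maps
#'
#' Continuous-scale choropleths of unit prevalence; units without an
#' estimate are hatched grey. Written as PNG (or any device ggsave
#' recognises from the file extension).
#'
#' @param estimates output of [aggregate_admin()].
#' @param admin_map the matching `admin_map`.
#' @param file output image path.
#' @param level admin level drawn.
#' @param limits optional c(min, max) colour-scale endpoints (defaults to
#'   the data range).
#' @return the ggplot object, invisibly (also written to `file`).
#' @export
render_maps <- function(estimates, admin_map, file, level = 2,
                        limits = NULL) {
  polys <- if (level == 1) admin_map$admin1$polys else admin_map$admin2$polys
  ids <- if (level == 1) admin_map$admin1$ids else admin_map$admin2$ids
  df <- do.call(rbind, lapply(seq_along(polys), function(k) {
    p <- polys[[k]]
    data.frame(lon = p[, 1], lat = p[, 2], id = ids[k],
               stringsAsFactors = FALSE)
  }))
  df$prevalence <- estimates$prevalence[match(df$id, estimates$id)]
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                         group = .data$id,
                                         fill = .data$prevalence)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = "Stunting (%)", limits = limits,
                                  na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file, gg, width = 6, height = 6, dpi = 150)
  invisible(gg)
}
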