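## Hold-out validation: split the survey by whole clusters (75/25 by
## default, stratified by admin-1 to preserve geographic spread), refit
## on the training clusters elsewhere, and score observed vs predicted
## cluster prevalence on the held-out clusters.

#' Split a child table into train/test sets by whole clusters
#'
#' Clusters are partitioned at the requested fraction with the test count
#' fixed at `floor((1 - train_fraction) * n_clusters)` (largest-remainder
#' allocation across admin-1 strata when stratified); children always
#' follow their cluster, so the child sets are disjoint and exhaustive.
#'
#' @param table child-level data.frame with `cluster_id` (and `admin1_id`
#'   when stratifying).
#' @param train_fraction proportion of clusters in the training set.
#' @param seed integer seed.
#' @param stratify_by_admin1 balance the split across admin-1 units?
#' @return list with `train` and `test` data.frames and the cluster id
#'   vectors used.
#' @export
split_clusters <- function(table, train_fraction = 0.75, seed = 1L,
                           stratify_by_admin1 = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  clusters <- unique(table$cluster_id)
  n <- length(clusters)
  if (n < 2) stop("need at least 2 clusters to split")
  n_test <- floor((1 - train_fraction) * n)
  if (n_test < 1 || n_test >= n)
    stop("fraction yields an empty train or test set")
  stratify_by_admin1 <- stratify_by_admin1 && "admin1_id" %in% names(table)
  with_seed(seed, {
    if (stratify_by_admin1) {
      adm <- table$admin1_id[match(clusters, table$cluster_id)]
      sizes <- table(adm)
      alloc <- largest_remainder(n_test * as.numeric(sizes) / n)
      test_ids <- character(0)
      for (k in seq_along(sizes)) {
        pool <- clusters[adm == names(sizes)[k]]
        take <- min(alloc[k], length(pool))
        if (take > 0)
          test_ids <- c(test_ids, sample(pool, take))
      }
      short <- n_test - length(test_ids)
      if (short > 0)
        test_ids <- c(test_ids, sample(setdiff(clusters, test_ids), short))
    } else {
      test_ids <- sample(clusters, n_test)
    }
  })
  in_test <- table$cluster_id %in% test_ids
  list(train = table[!in_test, , drop = FALSE],
       test = table[in_test, , drop = FALSE],
       train_clusters = setdiff(clusters, test_ids),
       test_clusters = test_ids)
}

#' Score a fitted model on held-out clusters
#'
#' Predicted prevalence of a test cluster is the posterior mean over
#' draws of the mean of `plogis(x' beta + A S)` over its children;
#' observed prevalence is the crude stunted fraction. Reports Pearson
#' and Spearman correlation, mean error, mean absolute error, and the
#' coverage of 95% posterior-predictive intervals (binomial sampling of
#' the cluster count folded in). Test clusters with no outcome data are
#' excluded.
#'
#' @param fit a `stunt_fit` trained on the training clusters.
#' @param test child-level test data (covariates + `lon`/`lat` for
#'   spatial fits).
#' @param ndraws posterior draws used.
#' @return a `validation_report` list: per-cluster table and metrics.
#' @export
evaluate_holdout <- function(fit, test, ndraws = 200) {
  des <- build_design(test, fit$spec, drop_unused = FALSE)
  X <- des$X[, colnames(fit$beta), drop = FALSE]
  y <- test[[fit$spec$outcome]]
  keep <- !is.na(y) & complete.cases(X)
  idx <- round(seq(1, nrow(fit$beta), length.out = min(ndraws, nrow(fit$beta))))
  eta <- X[keep, , drop = FALSE] %*% t(fit$beta[idx, , drop = FALSE])
  if (fit$spatial) {
    A <- projector(fit$mesh, as.matrix(test[keep, c("lon", "lat")]))
    if (any(attr(A, "outside")))
      stop("test location(s) outside the training mesh")
    eta <- eta + A %*% t(fit$S[idx, , drop = FALSE])
  }
  p <- plogis(as.matrix(eta))             # children x draws
  cl <- test$cluster_id[keep]
  yk <- y[keep]
  ids <- unique(cl)
  per <- lapply(ids, function(id) {
    rows <- which(cl == id)
    if (!length(rows)) return(NULL)
    pd <- colMeans(p[rows, , drop = FALSE])   # cluster prevalence per draw
    nch <- length(rows)
    ppd <- rbinom(length(pd), nch, pd) / nch  # posterior predictive
    obs <- mean(yk[rows])
    data.frame(cluster_id = id, n_children = nch, observed = obs,
               predicted = mean(pd),
               pi_low = percentile(ppd, 0.025),
               pi_high = percentile(ppd, 0.975),
               covered = obs >= percentile(ppd, 0.025) - 1e-12 &
                 obs <= percentile(ppd, 0.975) + 1e-12,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per)
  metrics <- list(
    pearson = cor(tab$observed, tab$predicted, method = "pearson"),
    spearman = cor(tab$observed, tab$predicted, method = "spearman"),
    mean_error = mean(tab$predicted - tab$observed),
    mae = mean(abs(tab$predicted - tab$observed)),
    coverage95 = mean(tab$covered),
    n_clusters = nrow(tab))
  structure(list(clusters = tab, metrics = metrics),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<validation_report> %d test clusters: Pearson r = %.3f, ",
                     "Spearman = %.3f, ME = %.4f, MAE = %.4f, 95%% PI coverage = %.2f\n"),
              m$n_clusters, m$pearson, m$spearman, m$mean_error, m$mae,
              m$coverage95))
  invisible(x)
}

#' Write a validation report (JSON + scatter plot)
#'
#' @param report a `validation_report`.
#' @param json_path output JSON path.
#' @param plot_path optional observed-vs-predicted scatter PNG.
#' @export
write_validation <- function(report, json_path, plot_path = NULL) {
  jsonlite::write_json(list(metrics = report$metrics,
                            clusters = report$clusters),
                       json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(plot_path)) {
    gg <- ggplot2::ggplot(report$clusters,
                          ggplot2::aes(x = .data$observed, y = .data$predicted)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
      ggplot2::labs(x = "Observed cluster prevalence",
                    y = "Predicted cluster prevalence") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(plot_path, gg, width = 5, height = 5, dpi = 150)
  }
  invisible(json_path)
}
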