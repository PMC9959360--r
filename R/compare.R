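## Model comparison: pointwise log-likelihood matrices, DIC
## (Spiegelhalter pD = Dbar - D(theta_bar)) and WAIC (variance penalty,
## pWAIC2). For spatial fits the pointwise likelihood conditions on the
## sampled latent field (conditional likelihood, the INLA-comparable
## choice).

#' Pointwise log-likelihood matrix of a fitted model
#'
#' Rows are posterior draws, columns observations:
#' `log dBern(y_i | plogis(x_i' beta_d + (A S_d)_i))`.
#'
#' @param fit a `stunt_fit`.
#' @param ndraws optional subsample of draws (evenly spaced) to bound
#'   memory; NULL uses all.
#' @return draws x n matrix, plus attribute `"theta_bar_loglik"`: the
#'   per-observation log-likelihood at the posterior-mean parameters.
#' @export
pointwise_loglik <- function(fit, ndraws = NULL) {
  idx <- seq_len(nrow(fit$beta))
  if (!is.null(ndraws) && ndraws < length(idx))
    idx <- round(seq(1, length(idx), length.out = ndraws))
  eta <- fit$beta[idx, , drop = FALSE] %*% t(fit$X)
  if (fit$spatial)
    eta <- eta + fit$S[idx, , drop = FALSE] %*% Matrix::t(fit$A)
  eta <- as.matrix(eta)
  y <- matrix(fit$y, nrow(eta), ncol(eta), byrow = TRUE)
  ll <- y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0)  # stable log plogis
  if (any(!is.finite(ll)))
    stop("non-finite log-likelihood at draw ",
         which(!is.finite(ll), arr.ind = TRUE)[1, 1], ", observation ",
         which(!is.finite(ll), arr.ind = TRUE)[1, 2])
  eta_bar <- as.numeric(colMeans(fit$beta[idx, , drop = FALSE]) %*% t(fit$X))
  if (fit$spatial)
    eta_bar <- eta_bar +
      as.numeric(fit$A %*% colMeans(fit$S[idx, , drop = FALSE]))
  llbar <- fit$y * eta_bar - log1p(exp(-abs(eta_bar))) - pmax(eta_bar, 0)
  attr(ll, "theta_bar_loglik") <- llbar
  ll
}

#' Deviance information criterion
#'
#' Dbar = mean over draws of -2 sum_i log p(y_i | theta);
#' pD = Dbar - D(theta_bar) (deviance at the posterior-mean parameters);
#' DIC = Dbar + pD.
#'
#' @param pointwise draws x n log-likelihood matrix.
#' @param theta_bar_loglik length-n log-likelihood at the posterior mean
#'   (defaults to the attribute attached by [pointwise_loglik()]).
#' @return list with `DIC`, `pD`, `Dbar`.
#' @export
compute_dic <- function(pointwise, theta_bar_loglik =
                          attr(pointwise, "theta_bar_loglik")) {
  if (nrow(pointwise) < 2) stop("need at least 2 draws")
  if (any(!is.finite(pointwise))) {
    bad <- which(!is.finite(pointwise), arr.ind = TRUE)[1, ]
    stop("non-finite log-likelihood (draw ", bad[1], ", observation ",
         bad[2], ")")
  }
  if (is.null(theta_bar_loglik))
    stop("theta_bar_loglik required (log-likelihood at posterior-mean parameters)")
  Dbar <- mean(-2 * rowSums(pointwise))
  Dhat <- -2 * sum(theta_bar_loglik)
  pD <- Dbar - Dhat
  list(DIC = Dbar + pD, pD = pD, Dbar = Dbar)
}

# Numerically stable log of column means of exp(ll).
log_col_means_exp <- function(ll) {
  mx <- apply(ll, 2, max)
  mx + log(colMeans(exp(sweep(ll, 2, mx))))
}

#' Watanabe-Akaike information criterion
#'
#' elpd_i = log mean_d exp(ll_di) - var_d(ll_di) (pWAIC2 penalty);
#' WAIC = -2 sum_i elpd_i. The log-mean-exp is max-shifted so the
#' computation cannot overflow. Observations with draw variance above
#' 0.4 trigger the customary reliability warning.
#'
#' @param pointwise draws x n log-likelihood matrix.
#' @return list with `WAIC`, `p_waic`, `elpd`, `lppd`.
#' @export
compute_waic <- function(pointwise) {
  if (nrow(pointwise) < 2) stop("need at least 2 draws")
  lppd_i <- log_col_means_exp(pointwise)
  p_i <- apply(pointwise, 2, var)
  if (any(p_i > 0.4))
    warning(sum(p_i > 0.4), " observation(s) with pointwise variance > 0.4; ",
            "WAIC may be unreliable for them")
  elpd <- sum(lppd_i - p_i)
  list(WAIC = -2 * elpd, p_waic = sum(p_i), elpd = elpd, lppd = sum(lppd_i))
}

#' Rank candidate models by DIC/WAIC
#'
#' Computes both criteria per candidate and sorts ascending by the chosen
#' one; exact ties break towards fewer parameters. Candidates must share
#' the observation set.
#'
#' @param candidates named list of `stunt_fit`s.
#' @param criterion "WAIC" (default) or "DIC".
#' @param ndraws draw subsample per candidate (see [pointwise_loglik()]).
#' @return data.frame (model, DIC, pD, WAIC, p_waic, n_params), sorted;
#'   a single candidate is reported without ranking.
#' @export
select_model <- function(candidates, criterion = c("WAIC", "DIC"),
                         ndraws = NULL) {
  criterion <- match.arg(criterion)
  if (!length(names(candidates)))
    names(candidates) <- paste0("model", seq_along(candidates))
  ns <- vapply(candidates, function(f) length(f$y), integer(1))
  if (length(unique(ns)) > 1)
    stop("refusing comparison: candidates have different observation counts (",
         paste(ns, collapse = ", "), ")")
  rows <- lapply(names(candidates), function(nm) {
    f <- candidates[[nm]]
    ll <- pointwise_loglik(f, ndraws = ndraws)
    dic <- compute_dic(ll)
    waic <- compute_waic(ll)
    data.frame(model = nm, DIC = dic$DIC, pD = dic$pD,
               WAIC = waic$WAIC, p_waic = waic$p_waic,
               n_params = ncol(f$beta) + if (f$spatial) nrow(f$mesh$loc) else 0L,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (nrow(tab) > 1)
    tab <- tab[order(tab[[criterion]], tab$n_params), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
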