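# Leave-one-out predictive checks (CPO, mid-PIT) and WAIC, all computed from
# the per-draw per-observation log-likelihood matrix.

#' Per-draw per-observation log-likelihood matrix
#'
#' Returns the S x n matrix `L` with `L[s, i]` the binomial log-pmf of
#' observation `i` under posterior draw `s`. Recomputed from the stored
#' linear-predictor draws (identical to the matrix accumulated during
#' sampling, and to per-observation calls of [log_likelihood()]).
#'
#' @param fit a [fit_mortality()] result with stored draws.
#' @param clusters optional cluster table; defaults to the fitted data.
#' @return numeric matrix, draws x observations.
#' @export
pointwise_loglik <- function(fit, clusters = fit$clusters) {
  stopifnot(inherits(fit, "geomort_fit"))
  if (is.null(fit$eta)) stop("fit was run with store_loglik = FALSE")
  if (ncol(fit$eta) != nrow(clusters)) stop("dimension mismatch")
  y <- clusters$deaths; n <- clusters$births
  lch <- lchoose(n, y)
  t(vapply(seq_len(nrow(fit$eta)), function(s) {
    binom_loglik(y, n, fit$eta[s, ], lch)
  }, numeric(nrow(clusters))))
}

#' Conditional predictive ordinates from posterior draws
#'
#' Leave-one-out predictive density of each observation by the harmonic-mean
#' importance identity, `CPO_i = 1 / mean_s exp(-L[s, i])`, evaluated in log
#' space. The importance weights are `exp(-L[s, i])`; an observation is
#' flagged unreliable when their effective sample size drops below
#' `0.1 * S`.
#'
#' @param L log-likelihood matrix (draws x observations), e.g. from
#'   [pointwise_loglik()] or `fit$loglik`.
#' @return list with `cpo` (vector), `ess` (effective sample sizes of the
#'   weights) and `unreliable` (logical vector).
#' @export
compute_cpo <- function(L) {
  L <- as.matrix(L)
  if (any(!is.finite(L))) stop("non-finite log-likelihood entries")
  S <- nrow(L)
  log_cpo <- -col_logmeanexp(-L)
  ess <- apply(L, 2, function(l) {
    lw <- -l - logsumexp(-l)      # normalized log weights
    exp(-logsumexp(2 * lw))
  })
  list(cpo = exp(log_cpo), ess = ess, unreliable = ess < 0.1 * S)
}

#' Leave-one-out mid-PIT for the binomial outcomes
#'
#' Probability integral transform with the discrete mid-correction:
#' `PIT_i = P(Y_rep < y_i) + 0.5 * P(Y_rep = y_i)`, with the replicate
#' distribution averaged over draws using the same leave-one-out importance
#' weights as the CPO. Approximately Uniform(0, 1) under a well-calibrated
#' model.
#'
#' @param fit a [fit_mortality()] result with stored draws.
#' @return numeric vector of PIT values in \[0, 1\].
#' @export
compute_pit <- function(fit) {
  stopifnot(inherits(fit, "geomort_fit"))
  if (is.null(fit$eta)) stop("fit was run with store_loglik = FALSE")
  y <- fit$clusters$deaths; n <- fit$clusters$births
  L <- fit$loglik
  vapply(seq_along(y), function(i) {
    p <- inv_logit(fit$eta[, i])
    lw <- -L[, i] - logsumexp(-L[, i])
    w <- exp(lw)
    sum(w * (stats::pbinom(y[i] - 1, n[i], p) +
               0.5 * stats::dbinom(y[i], n[i], p)))
  }, 0)
}

#' Widely applicable information criterion
#'
#' `lppd = sum_i log mean_s exp(L[s, i])` (log-sum-exp stable),
#' `p_waic = sum_i var_s L[s, i]` (denominator `S - 1`),
#' `waic = -2 (lppd - p_waic)`. Lower is better.
#'
#' @param L log-likelihood matrix (draws x observations), `S >= 2` draws.
#' @return list with `waic`, `p_waic`, `lppd`.
#' @export
compute_waic <- function(L) {
  L <- as.matrix(L)
  S <- nrow(L)
  if (S < 2) stop("WAIC needs at least 2 posterior draws")
  lppd <- sum(col_logmeanexp(L))
  cm <- colMeans(L)
  p_waic <- sum(colSums(sweep(L, 2, cm)^2) / (S - 1))
  list(waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd)
}

#' Model validation report
#'
#' Bundles CPO (with reliability flags), mid-PIT and WAIC for one fitted
#' model.
#'
#' @param fit a [fit_mortality()] result with stored draws.
#' @return object of class `geomort_validation`: `cpo`, `pit`,
#'   `n_unreliable_cpo`, `waic`, `p_waic`, `lppd`, `n_parameters`,
#'   `data_hash`.
#' @export
validation_report <- function(fit) {
  stopifnot(inherits(fit, "geomort_fit"))
  cpo <- compute_cpo(fit$loglik)
  w <- compute_waic(fit$loglik)
  structure(list(
    cpo = cpo$cpo, cpo_ess = cpo$ess, n_unreliable_cpo = sum(cpo$unreliable),
    pit = compute_pit(fit),
    waic = w$waic, p_waic = w$p_waic, lppd = w$lppd,
    n_parameters = n_parameters(fit), data_hash = fit$data_hash
  ), class = "geomort_validation")
}

#' @export
print.geomort_validation <- function(x, ...) {
  cat(sprintf(
    "<geomort_validation> WAIC %.1f (p_waic %.1f, lppd %.1f); %d/%d unreliable CPO; mean PIT %.3f\n",
    x$waic, x$p_waic, x$lppd, x$n_unreliable_cpo, length(x$cpo), mean(x$pit)))
  invisible(x)
}

n_parameters <- function(fit) {
  ncol(fit$draws$alpha) + ncol(fit$draws$beta) +
    if (fit$spatial) ncol(fit$draws$zeta) + 1L else 0L
}

#' Rank candidate models by WAIC
#'
#' Accepts fitted models and/or their [validation_report()]s (all on the same
#' data; verified by checksum), and ranks them ascending by WAIC. Ties
#' (difference below 1e-9) are broken in favor of fewer parameters.
#'
#' @param models named list of `geomort_fit` and/or `geomort_validation`
#'   objects.
#' @return data.frame sorted by rank with columns `model`, `waic`, `p_waic`,
#'   `lppd`, `delta_waic`, `n_parameters`, `best`.
#' @export
compare_models <- function(models) {
  stopifnot(is.list(models), length(models) >= 1)
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  reports <- lapply(models, function(m) {
    if (inherits(m, "geomort_fit")) validation_report(m)
    else if (inherits(m, "geomort_validation")) m
    else stop("models must be geomort_fit or geomort_validation objects")
  })
  hashes <- vapply(reports, `[[`, "", "data_hash")
  if (length(unique(hashes)) > 1) {
    stop("models were fitted to different data (checksum mismatch)")
  }
  tab <- data.frame(
    model = names(models),
    waic = vapply(reports, `[[`, 0, "waic"),
    p_waic = vapply(reports, `[[`, 0, "p_waic"),
    lppd = vapply(reports, `[[`, 0, "lppd"),
    n_parameters = vapply(reports, `[[`, 0L, "n_parameters"),
    row.names = NULL
  )
  # tie-break within 1e-9 by parameter count
  ord <- order(round(tab$waic / 1e-9) * 1e-9, tab$n_parameters)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_waic <- tab$waic - tab$waic[1]
  tab$best <- seq_len(nrow(tab)) == 1
  rownames(tab) <- NULL
  tab
}
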