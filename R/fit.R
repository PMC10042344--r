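# Posterior sampling by blocked adaptive Metropolis:
#   - (alpha, beta) jointly by random-walk Metropolis with a covariance
#     proposal adapted during burn-in,
#   - zeta by a chromatic (checkerboard) sweep of single-site Metropolis
#     updates — under the rook ICAR prior, same-color cells are conditionally
#     independent, so each color is proposed and accepted cell-wise in one
#     vectorized step,
#   - the sum-to-zero constraint by centering zeta after every sweep with the
#     mean transferred into the survey intercepts (likelihood-invariant),
#   - sigma_zeta by random-walk Metropolis on the log scale.
# Adaptation runs only during burn-in, so the retained chain is Markov.

#' MCMC configuration
#'
#' @param n_iter iterations per chain.
#' @param burn burn-in iterations (default half); adaptation happens only here.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param chains number of chains (>= 2 for convergence checks).
#' @param seed master seed; per-chain seeds are derived deterministically.
#' @return object of class `geomort_mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 4000, burn = floor(n_iter / 2), thin = 2,
                        chains = 2, seed = 1) {
  stopifnot(n_iter >= 10, burn >= 1, burn < n_iter, thin >= 1, chains >= 1)
  structure(list(n_iter = as.integer(n_iter), burn = as.integer(burn),
                 thin = as.integer(thin), chains = as.integer(chains),
                 seed = check_seed(seed)),
            class = "geomort_mcmc_config")
}

#' Fit the Bayesian binomial spatial regression
#'
#' Samples the posterior of the survey intercepts, per-SD covariate effects,
#' the lattice ICAR field and its scale, given a standardized design matrix
#' from [standardize_design()] (whose `"cell"` and `"grid"` attributes, set
#' by [extract_covariates()], map clusters to lattice cells).
#'
#' @param clusters cluster table (`survey_year`, `cluster_id`, `lon`, `lat`,
#'   `births`, `deaths`).
#' @param design standardized design matrix (may have zero columns for an
#'   intercept-only model).
#' @param spatial include the ICAR field? `FALSE` fits the pure binomial
#'   regression (the GLM limit).
#' @param config an [mcmc_config()].
#' @param priors passed to [model_spec()].
#' @param store_loglik keep the per-draw per-observation log-likelihood and
#'   linear-predictor matrices (needed for CPO/PIT/WAIC; disable to save
#'   memory on very large cluster tables).
#' @param rasters optional covariate [raster_stack()] (the one used in
#'   [extract_covariates()]). For spatial fits this enables an interweaving
#'   update that moves each coefficient jointly with the field along its
#'   covariate surface — exactly likelihood-invariant under nearest-cell
#'   extraction — which decorrelates the coefficients from the spatial field
#'   when covariates are themselves spatially smooth.
#' @return object of class `geomort_fit` with elements `draws` (matrices
#'   `alpha`, `beta`, `sigma_zeta`, `zeta` across all chains), `loglik` and
#'   `eta` (draws x clusters, when stored), `rhat`, `accept`, `converged`,
#'   plus the data, design record and spec needed downstream.
#' @export
fit_mortality <- function(clusters, design, spatial = TRUE,
                          config = mcmc_config(), priors = list(),
                          store_loglik = TRUE, rasters = NULL) {
  check_clusters(clusters)
  stopifnot(inherits(config, "geomort_mcmc_config"))
  X <- unclass(design)
  if (is.null(dim(X))) stop("`design` must be a matrix (possibly 0 columns)")
  K <- ncol(X)
  if (K > 0) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) stop("zero-variance design column(s): ",
                            paste(colnames(X)[sds == 0], collapse = ", "))
  }
  years <- sort(unique(clusters$survey_year))
  si <- match(clusters$survey_year, years)
  Tn <- length(years)

  grid <- attr(design, "grid")
  cell <- attr(design, "cell")
  if (spatial && (is.null(grid) || is.null(cell))) {
    stop("spatial fit needs the `grid`/`cell` attributes from extract_covariates()")
  }
  spec <- model_spec(
    grid = if (spatial) grid else grid_raster(matrix(0)),
    covariates = colnames(X) %||% character(), survey_years = years,
    spatial = spatial, priors = priors
  )

  y <- clusters$deaths; n <- clusters$births
  lch <- lchoose(n, y)
  fixed_sd <- spec$priors$fixed_sd
  sigma_sd <- spec$priors$sigma_sd

  if (spatial) {
    nr <- spec$nrows; nc <- spec$ncols
    ncells <- nr * nc
    Q0 <- spec$Q0
    W <- Matrix::Diagonal(ncells, Matrix::diag(Q0)) - Q0
    deg <- Matrix::diag(Q0)
    cellrow <- (seq_len(ncells) - 1L) %% nr + 1L
    cellcol <- (seq_len(ncells) - 1L) %/% nr + 1L
    color <- (cellrow + cellcol) %% 2L
    colorsets <- lapply(0:1, function(k) {
      cells_k <- which(color == k)
      pos <- integer(ncells); pos[cells_k] <- seq_along(cells_k)
      cl_k <- which(color[cell] == k)
      grp <- pos[cell[cl_k]]
      list(cells = cells_k, cl = cl_k, grp = grp, ug = sort(unique(grp)),
           deg = deg[cells_k])
    })

    # survey-level interweave: shifting alpha_t against the field on the
    # cells sampled by survey t (recentred) leaves every survey-t cluster's
    # linear predictor unchanged; only other surveys' clusters in shared
    # cells contribute a likelihood term
    svysets <- lapply(seq_len(Tn), function(t) {
      cells_t <- sort(unique(cell[si == t]))
      m_t <- length(cells_t) / ncells
      J <- numeric(ncells); J[cells_t] <- 1; J <- J - m_t
      QJ <- as.numeric(Q0 %*% J)
      inside <- cell %in% cells_t
      list(J = J, QJ = QJ, jqj = sum(J * QJ), m = m_t,
           is_t = si == t, inside = inside, aff = which(si != t & inside))
    })

    # interweaving setup: centered standardized covariate surfaces on the
    # lattice, valid only when they reproduce the cluster design exactly
    interweave <- NULL
    if (K > 0 && !is.null(rasters)) {
      rec_center <- attr(design, "center"); rec_scale <- attr(design, "scale")
      if (all(colnames(X) %in% names(rasters)) &&
          !is.null(rec_center) && !is.null(rec_scale)) {
        Zc <- vapply(colnames(X), function(nm) {
          (as.vector(rasters[[nm]]$values) - rec_center[nm]) / rec_scale[nm]
        }, numeric(ncells))
        if (!anyNA(Zc) && max(abs(Zc[cell, , drop = FALSE] - X)) < 1e-8) {
          mZ <- colMeans(Zc)
          Zcc <- sweep(Zc, 2, mZ)
          interweave <- list(
            Z = Zcc, mZ = mZ,
            QZ = as.matrix(Q0 %*% Zcc),
            zqz = colSums(Zcc * as.matrix(Q0 %*% Zcc))
          )
        }
      }
    }
  }

  d <- Tn + K
  nobs <- nrow(clusters)
  # initialize (alpha, beta) at the IRLS solution of the no-field binomial
  # regression, overdispersed per chain by a few standard errors; its Fisher
  # covariance seeds the block proposal (then adapted during burn-in)
  M <- matrix(0, nobs, Tn)
  M[cbind(seq_len(nobs), si)] <- 1
  if (K) M <- cbind(M, X)
  init <- tryCatch({
    gf <- suppressWarnings(stats::glm.fit(M, y / n, weights = n,
                                          family = stats::binomial()))
    co <- gf$coefficients
    w <- gf$weights
    V <- solve(crossprod(M, M * w))
    if (any(!is.finite(co)) || any(!is.finite(V))) stop("singular")
    list(theta = co, se = sqrt(diag(V)), propL = t(chol(V)))
  }, error = function(e) {
    a0 <- vapply(seq_len(Tn), function(t) {
      logit((sum(y[si == t]) + 0.5) / (sum(n[si == t]) + 1))
    }, 0)
    list(theta = c(a0, rep(0, K)), se = rep(0.1, d), propL = diag(0.05, d))
  })

  kept <- floor((config$n_iter - config$burn) / config$thin)

  run_chain <- function(chain) {
    set.seed(config$seed + 7919L * chain)
    theta <- init$theta + stats::rnorm(d, 0, 3 * init$se)
    zeta <- if (spatial) rep(0, ncells) else NULL
    sigma <- if (spatial) exp(stats::rnorm(1, log(0.3), 0.3)) else NULL

    eta_fix <- theta[si] + if (K) drop(X %*% theta[Tn + seq_len(K)]) else 0
    zeta_cl <- if (spatial) zeta[cell] else 0
    bll_cur <- binom_loglik(y, n, eta_fix + zeta_cl, lch)
    if (!all(is.finite(bll_cur))) stop("non-finite initial posterior")
    lprior_theta <- sum(stats::dnorm(theta, 0, fixed_sd, log = TRUE))

    log_s_t <- log(2.38 / sqrt(d)); propL <- init$propL
    log_s_z <- log(0.5); log_s_s <- log(0.3)
    log_s_iw <- rep(log(0.1), K)
    log_s_sv <- rep(log(0.1), Tn)
    log_s_c <- log(0.05)
    hist_theta <- matrix(NA_real_, config$burn, d)
    acc_t <- 0; acc_z_num <- 0; acc_z_den <- 0; acc_s <- 0

    out <- list(
      alpha = matrix(NA_real_, kept, Tn, dimnames = list(NULL, as.character(years))),
      beta = matrix(NA_real_, kept, K, dimnames = list(NULL, colnames(X))),
      sigma_zeta = if (spatial) numeric(kept),
      zeta = if (spatial) matrix(NA_real_, kept, ncells),
      loglik = if (store_loglik) matrix(NA_real_, kept, nobs),
      eta = if (store_loglik) matrix(NA_real_, kept, nobs)
    )
    s <- 0

    for (iter in seq_len(config$n_iter)) {
      ## --- (alpha, beta) block ---
      prop <- theta + exp(log_s_t) * drop(propL %*% stats::rnorm(d))
      eta_fix_p <- prop[si] + if (K) drop(X %*% prop[Tn + seq_len(K)]) else 0
      bll_p <- binom_loglik(y, n, eta_fix_p + zeta_cl, lch)
      lprior_p <- sum(stats::dnorm(prop, 0, fixed_sd, log = TRUE))
      logr <- sum(bll_p) - sum(bll_cur) + lprior_p - lprior_theta
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        theta <- prop; eta_fix <- eta_fix_p; bll_cur <- bll_p
        lprior_theta <- lprior_p
        if (iter > config$burn) acc_t <- acc_t + 1
      }

      if (spatial) {
        ## --- chromatic zeta sweep ---
        n_acc_sweep <- 0
        for (cs in colorsets) {
          cur <- zeta[cs$cells]
          s_nb <- as.numeric(W %*% zeta)[cs$cells]
          prop_z <- cur + exp(log_s_z) * stats::rnorm(length(cur))
          dprior <- -(0.5 / sigma^2) *
            (cs$deg * (prop_z^2 - cur^2) - 2 * (prop_z - cur) * s_nb)
          dll <- numeric(length(cur))
          if (length(cs$cl)) {
            e_new <- eta_fix[cs$cl] + prop_z[cs$grp]
            bll_new <- binom_loglik(y[cs$cl], n[cs$cl], e_new, lch[cs$cl])
            dj <- bll_new - bll_cur[cs$cl]
            dll[cs$ug] <- rowsum(dj, cs$grp)[, 1]
          }
          acc <- log(stats::runif(length(cur))) < dprior + dll
          if (any(acc)) {
            zeta[cs$cells[acc]] <- prop_z[acc]
            if (length(cs$cl)) {
              upd <- acc[cs$grp]
              bll_cur[cs$cl[upd]] <- bll_new[upd]
              zeta_cl[cs$cl] <- zeta[cell[cs$cl]]
            }
          }
          n_acc_sweep <- n_acc_sweep + sum(acc)
        }
        # sum-to-zero via centering; the mean moves into the intercepts,
        # leaving the likelihood untouched
        mu <- mean(zeta)
        zeta <- zeta - mu
        theta[seq_len(Tn)] <- theta[seq_len(Tn)] + mu
        eta_fix <- eta_fix + mu
        zeta_cl <- zeta_cl - mu
        lprior_theta <- sum(stats::dnorm(theta, 0, fixed_sd, log = TRUE))
        quad <- as.numeric(Matrix::crossprod(zeta, Q0 %*% zeta))
        if (iter > config$burn) {
          acc_z_num <- acc_z_num + n_acc_sweep; acc_z_den <- acc_z_den + ncells
        }

        ## --- sigma_zeta: slice sampler on the log scale ---
        # conditional log-density of u = log sigma given the field
        m <- ncells - 1
        sig_lpost <- function(u) {
          -m * u - quad / (2 * exp(2 * u)) +
            stats::dnorm(exp(u), 0, sigma_sd, log = TRUE) + u
        }
        u0 <- log(sigma)
        logy <- sig_lpost(u0) - stats::rexp(1)
        w <- 1
        lo <- u0 - w * stats::runif(1)
        hi <- lo + w
        while (sig_lpost(lo) > logy && u0 - lo < 20) lo <- lo - w
        while (sig_lpost(hi) > logy && hi - u0 < 20) hi <- hi + w
        repeat {
          u1 <- stats::runif(1, lo, hi)
          if (sig_lpost(u1) > logy) break
          if (u1 < u0) lo <- u1 else hi <- u1
          if (hi - lo < 1e-12) { u1 <- u0; break }
        }
        sigma <- exp(u1)
        acc_sig <- TRUE
        if (iter > config$burn) acc_s <- acc_s + 1

        ## --- joint rescaling of (zeta, sigma_zeta) ---
        # multiplicative move c on both; the GMRF quadratic form is invariant,
        # so the ratio is likelihood x c^{-(n-1)} x Half-Normal x Jacobian c^n
        cj <- exp(exp(log_s_c) * stats::rnorm(1))
        bll_c <- binom_loglik(y, n, eta_fix + cj * zeta_cl, lch)
        logr_c <- sum(bll_c) - sum(bll_cur) + log(cj) +
          stats::dnorm(cj * sigma, 0, sigma_sd, log = TRUE) -
          stats::dnorm(sigma, 0, sigma_sd, log = TRUE)
        apr_c <- if (is.finite(logr_c)) min(1, exp(min(0, logr_c))) else 0
        if (is.finite(logr_c) && log(stats::runif(1)) < logr_c) {
          zeta <- cj * zeta; zeta_cl <- cj * zeta_cl; sigma <- cj * sigma
          quad <- cj^2 * quad; bll_cur <- bll_c
        }

        ## --- interweaving: (alpha_t, zeta) on survey t's sampled cells ---
        sv_apr <- numeric(Tn)
        for (t in seq_len(Tn)) {
          sv <- svysets[[t]]
          delta <- exp(log_s_sv[t]) * stats::rnorm(1)
          dq <- -2 * delta * sum(sv$QJ * zeta) + delta^2 * sv$jqj
          th_p <- theta
          th_p[t] <- th_p[t] + delta * (1 - sv$m)
          th_p[setdiff(seq_len(Tn), t)] <- th_p[setdiff(seq_len(Tn), t)] -
            delta * sv$m
          lpr_p <- sum(stats::dnorm(th_p, 0, fixed_sd, log = TRUE))
          dll <- 0
          if (length(sv$aff)) {
            a <- sv$aff
            bll_a <- binom_loglik(y[a], n[a],
                                  eta_fix[a] + zeta_cl[a] - delta, lch[a])
            dll <- sum(bll_a) - sum(bll_cur[a])
          }
          logr_sv <- dll - dq / (2 * sigma^2) + lpr_p - lprior_theta
          sv_apr[t] <- if (is.finite(logr_sv)) min(1, exp(min(0, logr_sv))) else 0
          if (is.finite(logr_sv) && log(stats::runif(1)) < logr_sv) {
            theta <- th_p; lprior_theta <- lpr_p
            zeta <- zeta - delta * sv$J
            eta_fix <- eta_fix +
              delta * ifelse(sv$is_t, 1 - sv$m, -sv$m)
            zeta_cl <- zeta_cl - delta * (sv$inside - sv$m)
            quad <- quad + dq
            if (length(sv$aff)) bll_cur[sv$aff] <- bll_a
          }
        }

        ## --- interweaving: (beta_k, zeta) along the covariate surface ---
        # shear that leaves every cluster's linear predictor unchanged;
        # accepted on the field and coefficient priors alone
        if (!is.null(interweave)) {
          iw_apr <- numeric(K)
          for (k in seq_len(K)) {
            delta <- exp(log_s_iw[k]) * stats::rnorm(1)
            dq <- -2 * delta * sum(interweave$QZ[, k] * zeta) +
              delta^2 * interweave$zqz[k]
            th_p <- theta
            th_p[Tn + k] <- th_p[Tn + k] + delta
            th_p[seq_len(Tn)] <- th_p[seq_len(Tn)] - delta * interweave$mZ[k]
            lpr_p <- sum(stats::dnorm(th_p, 0, fixed_sd, log = TRUE))
            logr_iw <- -dq / (2 * sigma^2) + lpr_p - lprior_theta
            iw_apr[k] <- if (is.finite(logr_iw)) min(1, exp(min(0, logr_iw))) else 0
            if (is.finite(logr_iw) && log(stats::runif(1)) < logr_iw) {
              adj <- delta * (X[, k] - interweave$mZ[k])
              theta <- th_p; lprior_theta <- lpr_p
              zeta <- zeta - delta * interweave$Z[, k]
              eta_fix <- eta_fix + adj
              zeta_cl <- zeta_cl - adj
              quad <- quad + dq
            }
          }
        }
      }

      ## --- adaptation (burn-in only) ---
      if (iter <= config$burn) {
        gam <- min(0.1, 1 / sqrt(iter))
        apr <- if (is.finite(logr)) min(1, exp(min(0, logr))) else 0
        log_s_t <- log_s_t + gam * (apr - 0.234)
        hist_theta[iter, ] <- theta
        if (iter >= 200 && iter %% 100 == 0) {
          S_emp <- stats::cov(hist_theta[seq_len(iter), , drop = FALSE])
          propL <- tryCatch(t(chol(S_emp + diag(1e-8, d))), error = function(e) propL)
        }
        if (spatial) {
          log_s_z <- log_s_z + gam * (n_acc_sweep / ncells - 0.44)
          log_s_c <- log_s_c + gam * (apr_c - 0.44)
          log_s_sv <- log_s_sv + gam * (sv_apr - 0.44)
          if (!is.null(interweave)) {
            log_s_iw <- log_s_iw + gam * (iw_apr - 0.44)
          }
        }
      }

      ## --- storage ---
      if (iter > config$burn && (iter - config$burn) %% config$thin == 0) {
        s <- s + 1
        out$alpha[s, ] <- theta[seq_len(Tn)]
        if (K) out$beta[s, ] <- theta[Tn + seq_len(K)]
        if (spatial) { out$sigma_zeta[s] <- sigma; out$zeta[s, ] <- zeta }
        if (store_loglik) {
          out$loglik[s, ] <- bll_cur
          out$eta[s, ] <- eta_fix + zeta_cl
        }
      }
    }
    out$accept <- c(
      theta = acc_t / (config$n_iter - config$burn),
      zeta = if (spatial) acc_z_num / acc_z_den else NA_real_,
      sigma = if (spatial) acc_s / (config$n_iter - config$burn) else NA_real_
    )
    out
  }

  chains <- lapply(seq_len(config$chains), run_chain)

  bind <- function(name) do.call(rbind, lapply(chains, `[[`, name))
  draws <- list(
    alpha = bind("alpha"),
    beta = bind("beta"),
    sigma_zeta = if (spatial) unlist(lapply(chains, `[[`, "sigma_zeta")),
    zeta = if (spatial) bind("zeta")
  )

  # split R-hat over the monitored scalar parameters
  scalar_draws <- function(ch) {
    m <- cbind(ch$alpha, ch$beta)
    if (spatial) m <- cbind(m, sigma_zeta = ch$sigma_zeta)
    m
  }
  per_chain <- lapply(chains, scalar_draws)
  pnames <- c(paste0("alpha_", years),
              if (K) colnames(X),
              if (spatial) "sigma_zeta")
  rhat <- vapply(seq_len(ncol(per_chain[[1]])), function(j) {
    split_rhat(vapply(per_chain, function(m) m[, j], numeric(kept)))
  }, 0)
  names(rhat) <- pnames
  converged <- all(is.finite(rhat)) && all(rhat <= 1.05)
  if (!converged) {
    warning("split R-hat above 1.05 for: ",
            paste(pnames[!is.finite(rhat) | rhat > 1.05], collapse = ", "),
            "; treat results with caution", call. = FALSE)
  }

  structure(list(
    draws = draws,
    loglik = if (store_loglik) bind("loglik"),
    eta = if (store_loglik) bind("eta"),
    clusters = clusters,
    design_record = list(
      covariates = colnames(X) %||% character(),
      center = attr(design, "center"), scale = attr(design, "scale")
    ),
    cell = cell, spec = spec, survey_years = years, spatial = spatial,
    rhat = rhat, converged = converged,
    accept = do.call(rbind, lapply(chains, `[[`, "accept")),
    config = config,
    data_hash = rlang::hash(list(clusters$deaths, clusters$births))
  ), class = "geomort_fit")
}

#' Split R-hat for a single scalar parameter
#'
#' Each chain is split in half and the standard potential-scale-reduction
#' statistic is computed over the resulting sequences.
#'
#' @param draws matrix of draws, iterations x chains.
#' @return the split R-hat statistic (>= 1; near 1 indicates convergence).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  niter <- nrow(draws)
  half <- floor(niter / 2)
  seqs <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    cbind(draws[seq_len(half), j], draws[half + seq_len(half), j])
  }))
  m <- ncol(seqs); nn <- nrow(seqs)
  means <- colMeans(seqs)
  vars <- apply(seqs, 2, stats::var)
  B <- nn * stats::var(means)
  Wv <- mean(vars)
  if (Wv == 0) return(1)
  sqrt(((nn - 1) / nn * Wv + B / nn) / Wv)
}

#' @export
print.geomort_fit <- function(x, ...) {
  cat(sprintf(
    "<geomort_fit> %s model, %d clusters, %d surveys, %d draws (%d chains)\n",
    if (x$spatial) "spatial (ICAR)" else "non-spatial", nrow(x$clusters),
    length(x$survey_years), nrow(x$draws$alpha), x$config$chains))
  cat(sprintf("  max split R-hat: %.3f (%s)\n", max(x$rhat),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Summarize posterior coefficients with the credible-interval rule
#'
#' Posterior mean and equal-tailed credible interval per survey intercept,
#' per-SD covariate effect and (when present) the spatial field SD. An
#' effect is flagged significant when zero lies outside its credible
#' interval.
#'
#' @param fit a [fit_mortality()] result.
#' @param level credible level, default 0.95.
#' @return data.frame with columns `parameter`, `mean`, `lower`, `upper`,
#'   `significant`.
#' @export
summarize_coefficients <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "geomort_fit"), level > 0, level < 1)
  S <- nrow(fit$draws$alpha)
  if (S < 1) stop("empty posterior sample")
  if (S < 100) warning("fewer than 100 draws; interval estimates are unstable")
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  mats <- cbind(fit$draws$alpha, fit$draws$beta)
  colnames(mats) <- c(paste0("intercept_", colnames(fit$draws$alpha)),
                      colnames(fit$draws$beta))
  if (fit$spatial) mats <- cbind(mats, sigma_zeta = fit$draws$sigma_zeta)
  out <- data.frame(
    parameter = colnames(mats),
    mean = colMeans(mats),
    lower = apply(mats, 2, stats::quantile, probs = qs[1]),
    upper = apply(mats, 2, stats::quantile, probs = qs[2]),
    row.names = NULL
  )
  out$significant <- out$lower > 0 | out$upper < 0
  out$significant[out$parameter == "sigma_zeta"] <- NA
  out
}

#' @export
summary.geomort_fit <- function(object, ...) summarize_coefficients(object, ...)
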