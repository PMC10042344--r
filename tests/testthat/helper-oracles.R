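# Shared fixtures and independent oracles used across the suite.

# a tiny 3x3 raster with distinct values, unit cells anchored at the origin
toy_raster <- function() {
  grid_raster(matrix(1:9, 3, 3, byrow = TRUE), xll = 0, yll = 0, cellsize = 1)
}

toy_clusters <- function(lon, lat, births = 10, deaths = 2, year = 2000) {
  data.frame(
    survey_year = rep_len(year, length(lon)),
    cluster_id = sprintf("C%03d", seq_along(lon)),
    lon = lon, lat = lat,
    births = rep_len(births, length(lon)),
    deaths = rep_len(deaths, length(lon))
  )
}

# dense ICAR structure matrix by direct neighbor enumeration (independent of
# the sparse builder)
dense_icar_oracle <- function(nr, nc) {
  n <- nr * nc
  Q <- matrix(0, n, n)
  id <- function(r, c) (c - 1) * nr + r
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      i <- id(r, c)
      nbrs <- list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
      for (nb in nbrs) {
        if (nb[1] >= 1 && nb[1] <= nr && nb[2] >= 1 && nb[2] <= nc) {
          j <- id(nb[1], nb[2])
          Q[i, j] <- -1
          Q[i, i] <- Q[i, i] + 1
        }
      }
    }
  }
  Q
}

# brute-force WAIC from first principles (log() of plain means, loops)
waic_oracle <- function(L) {
  S <- nrow(L); n <- ncol(L)
  lppd <- 0; p_waic <- 0
  for (i in seq_len(n)) {
    lppd <- lppd + log(mean(exp(L[, i])))
    p_waic <- p_waic + var(L[, i])
  }
  list(waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd)
}

# minimal posterior-sample object for prediction/validation unit tests:
# draws are supplied directly instead of coming from MCMC
fake_fit <- function(clusters, eta = NULL, alpha, beta = NULL,
                     zeta = NULL, design_record = NULL, grid = NULL) {
  alpha <- as.matrix(alpha)
  S <- nrow(alpha)
  K <- if (is.null(beta)) 0 else ncol(beta)
  years <- as.integer(colnames(alpha))
  if (!is.null(eta)) {
    y <- clusters$deaths; n <- clusters$births
    L <- t(vapply(seq_len(S), function(s) {
      lchoose(n, y) + y * eta[s, ] - n * log(1 + exp(eta[s, ]))
    }, numeric(nrow(clusters))))
  } else L <- NULL
  structure(list(
    draws = list(alpha = alpha,
                 beta = if (is.null(beta)) matrix(0, S, 0) else beta,
                 sigma_zeta = if (!is.null(zeta)) rep(0.1, S),
                 zeta = zeta),
    loglik = L, eta = eta,
    clusters = clusters,
    design_record = design_record %||%
      list(covariates = character(), center = NULL, scale = NULL),
    spec = NULL, survey_years = years, spatial = !is.null(zeta),
    rhat = c(dummy = 1), converged = TRUE,
    config = mcmc_config(n_iter = 100, seed = 1),
    data_hash = rlang::hash(list(clusters$deaths, clusters$births))
  ), class = "geomort_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quick single-survey synthetic study with no spatial field (GLM limit)
glm_limit_sim <- function(n_clusters, seed, rate = 121,
                          beta = c(health_access = 0, population_density = -0.007,
                                   temperature = 0.13, precipitation = 0,
                                   altitude = 0, water_distance = 0),
                          grid = 25, births = c(20, 60)) {
  cfg <- sim_config(
    grid_nrows = grid, grid_ncols = grid, survey_years = 2000,
    clusters_per_survey = n_clusters, births_range = births,
    target_rates = rate, true_beta = beta, spatial_sd = 0, seed = seed
  )
  simulate_dataset(cfg)
}

# screen + standardize, keeping the cell/grid attributes for spatial fits
prepare_design <- function(clusters, rasters, threshold = 0.8) {
  X <- extract_covariates(clusters, rasters)
  sc <- correlation_screen(X, threshold = threshold)
  Xs <- standardize_design(X[, sc$retained, drop = FALSE])
  attr(Xs, "cell") <- attr(X, "cell")
  attr(Xs, "grid") <- attr(X, "grid")
  list(design = Xs, screen = sc)
}
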