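# Synthetic multi-survey cluster data with known ground truth.
#
# The generator draws spatially smooth covariate surfaces (Gaussian-kernel
# smoothed white noise), a zero-mean lattice GMRF, per-survey intercepts
# (either given directly or calibrated to target national rates per 1000),
# and binomial death counts at uniformly placed survey clusters — exactly the
# data-generating process assumed by the fitted model, so parameter-recovery
# checks are well-posed.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate a five-survey national study: a 50 x 50 lattice, six
#' correlated ecological covariates including a temperature/altitude
#' near-duplicate pair (target correlation -0.978), a smooth spatial field,
#' and national mortality declining from 121 to 59 per 1000 live births
#' across surveys.
#'
#' @param grid_nrows,grid_ncols lattice dimensions (positive integers).
#' @param cell_size cell edge length in degrees.
#' @param xll,yll lower-left corner of the grid.
#' @param survey_years integer vector of survey years.
#' @param clusters_per_survey clusters sampled per survey.
#' @param births_range integer range (min, max) for uniform live births per
#'   cluster; default 20–60, typical of DHS cluster birth counts.
#' @param true_alpha optional numeric vector (one logit-scale intercept per
#'   survey). When `NULL`, intercepts are calibrated so the grid-truth
#'   national rate equals `target_rates`.
#' @param target_rates per-survey national mortality per 1000 live births used
#'   to calibrate intercepts when `true_alpha` is `NULL`; defaults to the
#'   declining trajectory 121, 87, 73, 60, 59 recycled to the number of
#'   surveys.
#' @param true_beta named numeric vector of effects per standard deviation of
#'   each covariate surface.
#' @param spatial_sd realized (empirical) standard deviation of the latent
#'   spatial field; 0 disables it.
#' @param spatial_range correlation-length tempering of the lattice field in
#'   cells; `Inf` (default) gives the intrinsic CAR field used in fitting,
#'   finite values a proper CAR with shorter range.
#' @param covariate_smoothness Gaussian smoothing kernel SD in cells.
#' @param duplicate_pair_corr target Pearson correlation of the built-in
#'   temperature/altitude near-duplicate pair, in \[-1, 1\].
#' @param seed integer master seed; identical configs give identical output.
#' @return object of class `geomort_sim_config`.
#' @export
sim_config <- function(grid_nrows = 50, grid_ncols = 50, cell_size = 0.1,
                       xll = 33, yll = 3,
                       survey_years = c(2000, 2005, 2011, 2016, 2019),
                       clusters_per_survey = 150,
                       births_range = c(20, 60),
                       true_alpha = NULL,
                       target_rates = NULL,
                       true_beta = c(health_access = 0.03,
                                     population_density = -0.05,
                                     temperature = 0.13,
                                     precipitation = 0.04,
                                     altitude = 0,
                                     water_distance = 0.19),
                       spatial_sd = 0.3, spatial_range = Inf,
                       covariate_smoothness = 3,
                       duplicate_pair_corr = -0.978,
                       seed = 1) {
  stopifnot(
    grid_nrows >= 1, grid_ncols >= 1, cell_size > 0,
    length(survey_years) >= 1, clusters_per_survey >= 1,
    length(births_range) == 2, births_range[1] >= 1,
    births_range[2] >= births_range[1],
    spatial_sd >= 0, spatial_range > 0, covariate_smoothness > 0,
    abs(duplicate_pair_corr) <= 1
  )
  if (!is.null(true_alpha) && length(true_alpha) != length(survey_years)) {
    stop("`true_alpha` must have one value per survey year")
  }
  if (is.null(true_alpha)) {
    # canonical declining national trajectory, trimmed/recycled to the
    # number of surveys
    if (is.null(target_rates)) {
      target_rates <- rep_len(c(121, 87, 73, 60, 59), length(survey_years))
    }
    if (length(target_rates) != length(survey_years)) {
      stop("`target_rates` must have one value per survey year")
    }
    stopifnot(all(target_rates > 0), all(target_rates < 1000))
  }
  structure(list(
    grid_nrows = as.integer(grid_nrows), grid_ncols = as.integer(grid_ncols),
    cell_size = cell_size, xll = xll, yll = yll,
    survey_years = as.integer(survey_years),
    clusters_per_survey = as.integer(clusters_per_survey),
    births_range = as.integer(births_range),
    true_alpha = true_alpha, target_rates = target_rates,
    true_beta = true_beta,
    spatial_sd = spatial_sd, spatial_range = spatial_range,
    covariate_smoothness = covariate_smoothness,
    duplicate_pair_corr = duplicate_pair_corr,
    seed = check_seed(seed)
  ), class = "geomort_sim_config")
}

empty_grid <- function(config) {
  grid_raster(matrix(NA_real_, config$grid_nrows, config$grid_ncols),
              xll = config$xll, yll = config$yll, cellsize = config$cell_size)
}

# smooth white noise with a separable Gaussian kernel (SD `s` cells),
# edge-corrected by row-normalising the kernel matrices
smooth_field <- function(nr, nc, s) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (!is.finite(s)) return(matrix(mean(w), nr, nc))
  kmat <- function(m) {
    k <- exp(-outer(seq_len(m), seq_len(m), "-")^2 / (2 * s^2))
    k / rowSums(k)
  }
  kmat(nr) %*% w %*% t(kmat(nc))
}

standardize_field <- function(f) {
  s <- stats::sd(f)
  if (!is.finite(s) || s < 1e-12) return(f * 0)
  (f - mean(f)) / s
}

# residualize b against a (both unit-SD fields) and restandardize, so
# correlated combinations hit their target correlation exactly
orthogonalize <- function(b, a) {
  r <- b - mean(b) - stats::cov(as.vector(a), as.vector(b)) /
    stats::var(as.vector(a)) * (a - mean(a))
  standardize_field(r)
}

#' Generate smooth covariate rasters
#'
#' Produces six spatially smooth covariate surfaces in plausible units:
#' travel time to a health facility (hours), population density (persons per
#' km^2, log-normal), mean annual temperature (deg C), mean annual
#' precipitation (mm), altitude (m) and distance to the nearest water body
#' (km). Altitude is built as an affine transform of the temperature surface
#' plus orthogonalized smooth noise, so their empirical Pearson correlation
#' equals `duplicate_pair_corr` exactly; precipitation is moderately
#' negatively correlated with temperature.
#'
#' @param config a [sim_config()].
#' @return a [raster_stack()] of six covariates.
#' @export
generate_covariate_rasters <- function(config) {
  stopifnot(inherits(config, "geomort_sim_config"))
  set.seed(config$seed + 1L)
  nr <- config$grid_nrows; nc <- config$grid_ncols
  s <- config$covariate_smoothness
  f <- replicate(6, standardize_field(smooth_field(nr, nc, s)), simplify = FALSE)

  temp_f <- f[[1]]
  degenerate <- stats::sd(temp_f) < 1e-12  # smoothness -> Inf limit
  prec_f <- if (degenerate) f[[2]] else {
    rho_p <- -0.645
    rho_p * temp_f + sqrt(1 - rho_p^2) * orthogonalize(f[[2]], temp_f)
  }
  rho <- config$duplicate_pair_corr
  alt_f <- if (degenerate) f[[6]] else if (abs(rho) == 1) sign(rho) * temp_f else {
    rho * temp_f + sqrt(1 - rho^2) * orthogonalize(f[[6]], temp_f)
  }

  g <- function(values) grid_raster(values, xll = config$xll, yll = config$yll,
                                    cellsize = config$cell_size)
  raster_stack(list(
    health_access = g(2.5 + 1.5 * f[[3]]),
    population_density = g(exp(3 + f[[4]])),
    temperature = g(22 + 4 * temp_f),
    precipitation = g(900 + 350 * prec_f),
    altitude = g(1600 + 450 * alt_f),
    water_distance = g(15 + 10 * f[[5]])
  ))
}

# eigenvalues 2 - 2cos(pi k / m) and orthonormal cosine eigenvectors of the
# path-graph Laplacian on m nodes
path_laplacian_eigen <- function(m) {
  k <- 0:(m - 1)
  lambda <- 2 - 2 * cos(pi * k / m)
  V <- outer(seq_len(m), k, function(x, kk) cos(pi * kk * (x - 0.5) / m))
  V <- sweep(V, 2, c(sqrt(m), rep(sqrt(m / 2), m - 1)), "/")
  list(lambda = lambda, vectors = V)
}

#' Simulate a zero-mean lattice GMRF field
#'
#' Draws from the intrinsic first-order CAR field on the rectangular lattice
#' via its exact spectral factorization (the 2-D cosine eigenbasis of the
#' lattice graph Laplacian), dropping the constant (null) mode so the draw
#' sums to zero, then rescales so the realized standard deviation equals
#' `spatial_sd`. A finite `spatial_range` adds `1/range^2` to every spectral
#' precision, giving a proper CAR with shorter correlation length.
#'
#' @param config a [sim_config()].
#' @return numeric matrix (`grid_nrows` x `grid_ncols`), the field on the grid.
#' @export
simulate_gmrf_field <- function(config) {
  stopifnot(inherits(config, "geomort_sim_config"))
  set.seed(config$seed + 2L)
  nr <- config$grid_nrows; nc <- config$grid_ncols
  if (config$spatial_sd == 0 || nr * nc == 1) return(matrix(0, nr, nc))
  er <- path_laplacian_eigen(nr)
  ec <- path_laplacian_eigen(nc)
  prec <- outer(er$lambda, ec$lambda, "+") + ifelse(is.finite(config$spatial_range),
                                                   1 / config$spatial_range^2, 0)
  coef <- matrix(stats::rnorm(nr * nc), nr, nc)
  prec[1, 1] <- Inf  # remove the constant mode
  coef <- coef / sqrt(prec)
  field <- er$vectors %*% coef %*% t(ec$vectors)
  field <- field - mean(field)
  field / stats::sd(field) * config$spatial_sd
}

#' Compute the generator's ground truth
#'
#' Standardizes the covariate surfaces, draws the latent field, resolves the
#' per-survey intercepts (calibrated by root-finding to `target_rates` when
#' `true_alpha` is not given) and evaluates the true mortality probability
#' per cell and survey through the inverse-logit link.
#'
#' @param config a [sim_config()].
#' @param rasters covariate stack from [generate_covariate_rasters()].
#' @return object of class `geomort_truth`: `alpha` (named by survey year),
#'   `beta`, `zeta` (matrix), `p` (cells x surveys matrix of probabilities),
#'   and `national_rate` per 1000 per survey.
#' @export
ground_truth <- function(config, rasters) {
  stopifnot(inherits(config, "geomort_sim_config"), inherits(rasters, "geomort_stack"))
  if (!all(names(config$true_beta) %in% names(rasters))) {
    stop("`true_beta` names must match covariate raster names")
  }
  Xz <- vapply(names(config$true_beta), function(nm) {
    as.vector(standardize_field(rasters[[nm]]$values))
  }, numeric(config$grid_nrows * config$grid_ncols))
  zeta <- simulate_gmrf_field(config)
  eta0 <- drop(Xz %*% config$true_beta) + as.vector(zeta)

  years <- config$survey_years
  if (!is.null(config$true_alpha)) {
    alpha <- config$true_alpha
  } else {
    alpha <- vapply(config$target_rates / 1000, function(target) {
      stats::uniroot(function(a) mean(inv_logit(a + eta0)) - target,
                     lower = -20, upper = 20, tol = 1e-12)$root
    }, 0)
  }
  names(alpha) <- as.character(years)
  p <- vapply(alpha, function(a) inv_logit(a + eta0), numeric(length(eta0)))
  structure(list(
    alpha = alpha, beta = config$true_beta, zeta = zeta, p = p,
    national_rate = 1000 * colMeans(p)
  ), class = "geomort_truth")
}

#' Sample survey clusters with binomial death counts
#'
#' Each cluster is placed uniformly at random in a grid cell (coordinates
#' uniform within the cell), receives a uniform number of live births from
#' `births_range`, and a death count drawn Binomial(n, p) with p the true
#' probability of its cell and survey.
#'
#' @param config a [sim_config()].
#' @param rasters the covariate stack (defines the grid).
#' @param truth a [ground_truth()] object on the same grid.
#' @return data.frame with columns `survey_year`, `cluster_id`, `lon`, `lat`,
#'   `births`, `deaths`.
#' @export
sample_clusters <- function(config, rasters, truth) {
  stopifnot(inherits(config, "geomort_sim_config"), inherits(truth, "geomort_truth"))
  grid <- stack_grid(rasters)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  ncells <- nr * nc
  if (ncells < 1) stop("empty grid")
  if (nrow(truth$p) != ncells) stop("truth and rasters are on different grids")
  set.seed(config$seed + 3L)
  out <- vector("list", length(config$survey_years))
  for (t in seq_along(config$survey_years)) {
    m <- config$clusters_per_survey
    cells <- sample.int(ncells, m, replace = TRUE)
    row <- (cells - 1L) %% nr + 1L
    col <- (cells - 1L) %/% nr + 1L
    lon <- grid$xll + (col - 1 + stats::runif(m)) * grid$cellsize
    lat <- grid$yll + (nr - row + stats::runif(m)) * grid$cellsize
    births <- sample(seq(config$births_range[1], config$births_range[2]), m, replace = TRUE)
    deaths <- stats::rbinom(m, births, truth$p[cells, t])
    out[[t]] <- data.frame(
      survey_year = config$survey_years[t],
      cluster_id = sprintf("S%d_C%04d", config$survey_years[t], seq_len(m)),
      lon = lon, lat = lat, births = births, deaths = deaths
    )
  }
  do.call(rbind, out)
}

#' Simulate a complete synthetic study
#'
#' Runs the full generative pipeline: covariate rasters, ground truth (latent
#' field and intercepts) and cluster table, plus rectangular regions
#' partitioning the grid.
#'
#' @param config a [sim_config()].
#' @param region_nx,region_ny regions along x and y.
#' @return list with `config`, `rasters`, `truth`, `clusters`, `regions`.
#' @export
simulate_dataset <- function(config = sim_config(), region_nx = 2, region_ny = 2) {
  rasters <- generate_covariate_rasters(config)
  truth <- ground_truth(config, rasters)
  clusters <- sample_clusters(config, rasters, truth)
  regions <- make_regions(stack_grid(rasters), nx = region_nx, ny = region_ny)
  list(config = config, rasters = rasters, truth = truth,
       clusters = clusters, regions = regions)
}

#' Write a simulated study to disk in the pipeline's file formats
#'
#' Writes `clusters.csv`, one `cov_<name>.asc` ESRI ASCII grid per covariate,
#' `regions.geojson`, and (when ground truth is present) `truth_zeta.asc` and
#' `truth_parameters.csv`. Everything round-trips losslessly through the
#' package readers.
#'
#' @param sim output of [simulate_dataset()], or a list with at least
#'   `clusters`, `rasters`, `regions`.
#' @param dir output directory (created if missing).
#' @return character vector of files written, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  path <- function(f) file.path(dir, f)
  utils::write.csv(sim$clusters, path("clusters.csv"), row.names = FALSE)
  files <- c(files, path("clusters.csv"))
  # the file index keeps the declared covariate order (the screen's tie-break
  # order) stable across round-trips
  for (i in seq_along(sim$rasters)) {
    f <- path(sprintf("cov_%02d_%s.asc", i, names(sim$rasters)[i]))
    write_ascii_grid(sim$rasters[[i]], f)
    files <- c(files, f)
  }
  write_regions_geojson(sim$regions, path("regions.geojson"))
  files <- c(files, path("regions.geojson"))
  if (!is.null(sim$truth)) {
    g <- stack_grid(sim$rasters)
    write_ascii_grid(grid_raster(sim$truth$zeta, g$xll, g$yll, g$cellsize),
                     path("truth_zeta.asc"))
    pars <- data.frame(
      parameter = c(paste0("alpha_", names(sim$truth$alpha)),
                    paste0("beta_", names(sim$truth$beta))),
      value = c(unname(sim$truth$alpha), unname(sim$truth$beta))
    )
    utils::write.csv(pars, path("truth_parameters.csv"), row.names = FALSE)
    files <- c(files, path("truth_zeta.asc"), path("truth_parameters.csv"))
  }
  invisible(files)
}

#' Read a study fixture written by [write_fixture()]
#'
#' @param dir directory containing the fixture files.
#' @return list with `clusters`, `rasters`, `regions`.
#' @export
read_fixture <- function(dir) {
  clusters <- utils::read.csv(file.path(dir, "clusters.csv"),
                              stringsAsFactors = FALSE)
  cov_files <- sort(list.files(dir, pattern = "^cov_[0-9]+_.*\\.asc$",
                               full.names = TRUE))
  rasters <- lapply(cov_files, read_ascii_grid)
  names(rasters) <- sub("^cov_[0-9]+_(.*)\\.asc$", "\\1", basename(cov_files))
  list(
    clusters = clusters,
    rasters = raster_stack(rasters),
    regions = read_regions_geojson(file.path(dir, "regions.geojson"))
  )
}
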