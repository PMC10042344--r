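test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(grid_nrows = 15, grid_ncols = 12, clusters_per_survey = 20,
                    seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$rasters, b$rasters)
  expect_identical(a$truth, b$truth)
  expect_identical(a$clusters, b$clusters)
})

test_that("infinite smoothness collapses every covariate raster to a constant", {
  cfg <- sim_config(grid_nrows = 10, grid_ncols = 10,
                    covariate_smoothness = Inf, seed = 3)
  st <- generate_covariate_rasters(cfg)
  for (nm in names(st)) {
    expect_lt(diff(range(st[[nm]]$values)), 1e-12)
  }
})

test_that("the near-duplicate covariate pair hits its target correlation", {
  cfg <- sim_config(grid_nrows = 100, grid_ncols = 100,
                    duplicate_pair_corr = -0.98, seed = 5)
  st <- generate_covariate_rasters(cfg)
  r <- cor(as.vector(st$temperature$values), as.vector(st$altitude$values))
  expect_lt(abs(r - (-0.98)), 0.03)

  # empirical correlation matrix mirrors the structure of a worked
  # correlation table: symmetric with unit diagonal
  M <- sapply(st, function(x) as.vector(x$values))
  C <- cor(M)
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, ncol(M)))
  expect_true(all(abs(C) <= 1 + 1e-12))
})

test_that("the simulated lattice field is centered, scaled and spatially coherent", {
  cfg0 <- sim_config(grid_nrows = 20, grid_ncols = 20, spatial_sd = 0, seed = 1)
  expect_equal(simulate_gmrf_field(cfg0), matrix(0, 20, 20))

  cfg <- sim_config(grid_nrows = 40, grid_ncols = 40, spatial_sd = 0.5, seed = 2)
  z <- simulate_gmrf_field(cfg)
  expect_lt(abs(mean(z)), 3 * 0.5 / sqrt(length(z)))
  expect_equal(sd(z), 0.5, tolerance = 1e-12)

  # empirical correlogram: neighbors at lag 1 are more alike than cells 10
  # apart, averaged over 20 seeds
  lag_cor <- function(z, k) {
    nr <- nrow(z)
    cor(as.vector(z[seq_len(nr - k), ]), as.vector(z[k + seq_len(nr - k), ]))
  }
  cors <- sapply(1:20, function(s) {
    zi <- simulate_gmrf_field(sim_config(grid_nrows = 40, grid_ncols = 40,
                                         spatial_sd = 1, seed = 100 + s))
    c(lag1 = lag_cor(zi, 1), lag10 = lag_cor(zi, 10))
  })
  expect_gt(mean(cors["lag1", ]), mean(cors["lag10", ]))
})

test_that("cluster sampling respects degenerate probabilities and the binomial law", {
  cfg <- sim_config(grid_nrows = 5, grid_ncols = 5, survey_years = 2000,
                    clusters_per_survey = 200, spatial_sd = 0, seed = 7)
  st <- generate_covariate_rasters(cfg)
  mk_truth <- function(p) {
    structure(list(alpha = c("2000" = logit(max(min(p, 1 - 1e-12), 1e-12))),
                   beta = cfg$true_beta * 0,
                   zeta = matrix(0, 5, 5),
                   p = matrix(p, 25, 1),
                   national_rate = 1000 * p),
              class = "geomort_truth")
  }
  all0 <- sample_clusters(cfg, st, mk_truth(0))
  expect_true(all(all0$deaths == 0))
  all1 <- sample_clusters(cfg, st, mk_truth(1))
  expect_true(all(all1$deaths == all1$births))

  cfg_big <- sim_config(grid_nrows = 5, grid_ncols = 5, survey_years = 2000,
                        clusters_per_survey = 10000, spatial_sd = 0, seed = 8)
  cl <- sample_clusters(cfg_big, st, mk_truth(0.121))
  expect_lt(abs(mean(cl$deaths / cl$births) - 0.121), 0.01)
  expect_true(all(cl$deaths <= cl$births))
  expect_equal(nrow(cl), 10000)
})

test_that("ground-truth probabilities follow the inverse-logit identity", {
  cfg <- sim_config(grid_nrows = 12, grid_ncols = 12, seed = 21)
  st <- generate_covariate_rasters(cfg)
  truth <- ground_truth(cfg, st)
  expect_true(all(truth$p > 0 & truth$p < 1))
  # recompute p for one survey from alpha + X beta + zeta directly
  Xz <- sapply(names(truth$beta), function(nm) {
    v <- st[[nm]]$values
    as.vector((v - mean(v)) / sd(v))
  })
  eta <- truth$alpha[2] + drop(Xz %*% truth$beta) + as.vector(truth$zeta)
  expect_equal(unname(truth$p[, 2]), unname(inv_logit(eta)), tolerance = 1e-12)
  # intercept calibration: grid-truth national rates match the targets
  expect_equal(unname(truth$national_rate), cfg$target_rates, tolerance = 1e-6)
})

test_that("fixtures round-trip through the pipeline readers", {
  cfg <- sim_config(grid_nrows = 8, grid_ncols = 9, clusters_per_survey = 15,
                    seed = 13)
  sim <- simulate_dataset(cfg, region_nx = 2, region_ny = 2)
  dir <- withr::local_tempdir()
  write_fixture(sim, dir)
  back <- read_fixture(dir)

  expect_equal(back$clusters$deaths, sim$clusters$deaths)
  expect_equal(back$clusters$lon, sim$clusters$lon, tolerance = 1e-12)
  expect_true(all(back$clusters$deaths <= back$clusters$births))
  expect_identical(names(back$rasters), names(sim$rasters))
  for (nm in names(sim$rasters)) {
    expect_equal(back$rasters[[nm]]$values, unname(sim$rasters[[nm]]$values),
                 tolerance = 1e-12)
  }

  # regions partition the grid: polygon areas (rectangles) sum to grid area
  area <- function(r) abs(sum(diff(r$x[1:2])) * diff(r$y[2:3]))
  ext <- c(8 * 9 * cfg$cell_size^2)
  expect_equal(sum(sapply(back$regions, area)), ext, tolerance = 1e-10)
  # and every cell center is assigned to exactly one region
  asg <- geomort:::assign_cells(stack_grid(back$rasters), back$regions)
  expect_false(anyNA(asg))
})
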