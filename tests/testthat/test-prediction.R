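surface_from_p <- function(p_matrix, xll = 0, yll = 0, cs = 1, survey = 2000) {
  r <- grid_raster(p_matrix, xll = xll, yll = yll, cellsize = cs)
  structure(list(mean = r, lower = r, upper = r, survey = survey, level = 0.95),
            class = "geomort_surface")
}

test_that("prediction reproduces degenerate posteriors exactly", {
  # 2x2 grid, one covariate whose value everywhere equals the training mean
  grid <- grid_raster(matrix(0.7, 2, 2), cellsize = 1)
  st <- raster_stack(list(a = grid))
  S <- 10
  fit <- fake_fit(
    toy_clusters(0.5, 0.5),
    alpha = matrix(rep(-1.5, S), dimnames = list(NULL, "2000")),
    beta = matrix(rnorm(S), S, 1, dimnames = list(NULL, "a")),
    design_record = list(covariates = "a", center = c(a = 0.7), scale = c(a = 2))
  )
  surf <- predict_surface(fit, st, survey = 2000)
  # standardized covariate is 0, so p = inv_logit(alpha) in every cell/draw
  expect_equal(unname(surf$mean$values), matrix(inv_logit(-1.5), 2, 2),
               tolerance = 1e-12)
  expect_equal(surf$lower$values, surf$upper$values, tolerance = 1e-12)

  # one-cell grid, two draws with eta = 0 and eta = ln 3: mean p = 0.625
  g1 <- raster_stack(list(a = grid_raster(matrix(0.7))))
  fit2 <- fake_fit(
    toy_clusters(0.5, 0.5),
    alpha = matrix(c(0, log(3)), dimnames = list(NULL, "2000")),
    beta = matrix(0, 2, 1, dimnames = list(NULL, "a")),
    design_record = list(covariates = "a", center = c(a = 0.7), scale = c(a = 1))
  )
  surf2 <- predict_surface(fit2, g1, survey = 2000)
  expect_equal(drop(surf2$mean$values), (0.5 + 0.75) / 2, tolerance = 1e-12)

  # quantile ordering holds cell-wise
  expect_true(all(surf2$lower$values <= surf2$mean$values + 1e-12))
  expect_true(all(surf2$mean$values <= surf2$upper$values + 1e-12))
})

test_that("regional aggregation averages surfaces into per-1000 rates", {
  # uniform p = 0.121: every region and the nation at 121 per 1000
  u <- surface_from_p(matrix(0.121, 10, 10))
  regions <- make_regions(u$mean, nx = 2, ny = 2)
  rt <- aggregate_regions(u, regions)
  expect_equal(rt[["2000"]], rep(121, 5), tolerance = 1e-9)

  # single region covering the grid: region rate equals national rate
  whole <- make_regions(u$mean, nx = 1, ny = 1)
  rt1 <- aggregate_regions(u, whole)
  expect_equal(rt1[["2000"]][1], rt1[["2000"]][2], tolerance = 1e-12)

  # two equal-area regions at p = 0.02 and 0.10: national = 60 per 1000
  half <- matrix(c(rep(0.02, 50), rep(0.10, 50)), 10, 10)
  s2 <- surface_from_p(half)
  two <- make_regions(s2$mean, nx = 2, ny = 1)
  rt2 <- aggregate_regions(s2, two)
  expect_equal(rt2[["2000"]], c(20, 100, 60), tolerance = 1e-9)

  # conservation: national equals the weighted mean of regional rates
  set.seed(5)
  rnd <- surface_from_p(matrix(runif(100, 0.01, 0.2), 10, 10))
  w <- grid_raster(matrix(runif(100, 0.5, 5), 10, 10))
  rtw <- aggregate_regions(rnd, make_regions(rnd$mean, 2, 2), weights = w)
  wreg <- sapply(1:4, function(k) {
    asg <- geomort:::assign_cells(rnd$mean, make_regions(rnd$mean, 2, 2))
    sum(as.vector(w$values)[asg == k])
  })
  expect_equal(rtw[["2000"]][5],
               weighted.mean(rtw[["2000"]][1:4], wreg), tolerance = 1e-9)
  expect_equal(attr(rtw, "n_unassigned"), 0)
})

test_that("trend summaries flag decline, reversal and stagnation", {
  rates <- data.frame(region = "National",
                      `2000` = 121, `2005` = 87, `2011` = 73,
                      `2016` = 60, `2019` = 59, check.names = FALSE)
  tr <- trend_table(rates)
  expect_equal(tr$summary$change, -62)
  expect_true(tr$summary$monotone_decreasing)
  expect_true(tr$summary$stagnant_last)   # |59 - 60| / 60 < 5%
  expect_equal(nrow(tr$steps), 4)
  expect_equal(tr$steps$change[1], -34)

  flat <- data.frame(region = "R", a = 50, b = 50, c = 50)
  trf <- trend_table(flat)
  expect_equal(trf$summary$change, 0)
  expect_true(trf$summary$stagnant_last)

  up <- data.frame(region = "R", a = 40, b = 80)
  tru <- trend_table(up)
  expect_equal(tru$summary$pct_change, 100)
  expect_false(tru$summary$monotone_decreasing)
  expect_error(trend_table(data.frame(region = "R", a = 1)), "at least 2")
})

test_that("map export writes readable rasters and a non-empty image", {
  set.seed(2)
  p <- matrix(runif(100, 0.02, 0.15), 10, 10)
  p[1, 1] <- NA  # NODATA cell must survive export and stay out of the scale
  surf <- surface_from_p(p, xll = 33, yll = 3, cs = 0.1)
  prefix <- file.path(withr::local_tempdir(), "map")
  files <- render_maps(surf, prefix)

  back <- read_ascii_grid(files[["mean"]])
  expect_equal(back$values, unname(1000 * p), tolerance = 1e-10)
  expect_true(is.na(back$values[1, 1]))
  expect_gt(file.info(files[["png"]])$size, 1000)
})
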