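test_that("the ICAR structure matrix matches its definition on small lattices", {
  Q22 <- as.matrix(build_precision(2, 2))
  expect_equal(unname(diag(Q22)), rep(2, 4))
  expect_equal(unname(rowSums(Q22)), rep(0, 4))

  Q12 <- as.matrix(build_precision(1, 2))
  expect_equal(unname(Q12), matrix(c(1, -1, -1, 1), 2))

  Q43 <- as.matrix(build_precision(4, 3))
  expect_equal(unname(Q43), dense_icar_oracle(4, 3))
})

test_that("the ICAR structure matrix is symmetric PSD with null space = constants", {
  Q <- build_precision(5, 5)
  Qd <- as.matrix(Q)
  expect_equal(Qd, t(Qd))
  set.seed(31)
  for (i in 1:100) {
    x <- rnorm(25)
    expect_gte(drop(t(x) %*% Qd %*% x), -1e-10)
  }
  ev <- eigen(Qd, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(sum(ev < 1e-10), 1)  # one null mode: the constant vector
  # closed-form generalized log-determinant agrees with the dense spectrum
  expect_equal(geomort:::icar_logdet(5, 5), sum(log(ev[ev > 1e-10])),
               tolerance = 1e-10)
})

test_that("a masked lattice with disconnected components is rejected", {
  mask <- matrix(TRUE, 3, 3)
  mask[, 2] <- FALSE  # splits left and right columns
  expect_error(build_precision(3, 3, mask = mask), "disconnected")
  mask2 <- matrix(TRUE, 3, 3)
  mask2[1, 1] <- FALSE
  expect_s4_class(build_precision(3, 3, mask = mask2), "Matrix")
})

test_that("the binomial log-likelihood matches closed forms and stays stable", {
  cl <- toy_clusters(lon = c(0.5, 1.5, 2.5), lat = rep(0.5, 3),
                     births = c(10, 20, 15), deaths = c(2, 5, 0))
  X <- matrix(0, 3, 0)

  # symmetry point: all parameters zero gives p = 1/2 everywhere
  st0 <- list(alpha = 0, beta = numeric())
  expect_equal(log_likelihood(st0, cl, X),
               sum(lchoose(cl$births, cl$deaths) - cl$births * log(2)),
               tolerance = 1e-12)

  # single cluster, y = 0: closed form n * log(1 - p(eta))
  one <- toy_clusters(0.5, 0.5, births = 10, deaths = 0)
  for (eta in c(-3, 0, 1.7)) {
    expect_equal(log_likelihood(list(alpha = eta, beta = numeric()), one, X[1, , drop = FALSE]),
                 10 * log(1 - inv_logit(eta)), tolerance = 1e-12)
  }

  # brute-force pmf oracle with covariates
  set.seed(6)
  Xr <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("a", "b")))
  st <- list(alpha = -1.2, beta = c(a = 0.4, b = -0.8))
  eta <- -1.2 + drop(Xr %*% st$beta)
  expect_equal(log_likelihood(st, cl, Xr),
               sum(dbinom(cl$deaths, cl$births, inv_logit(eta), log = TRUE)),
               tolerance = 1e-12)

  # stability at extreme linear predictors
  for (a in c(-40, 40)) {
    v <- log_likelihood(list(alpha = a, beta = numeric()), cl, X)
    expect_true(is.finite(v))
  }
  bad <- cl; bad$deaths[1] <- bad$births[1] + 1
  expect_error(log_likelihood(st0, bad, X), "deaths")
})

test_that("the constrained field density matches a dense multivariate-normal oracle", {
  nr <- 3; nc <- 3
  Q0 <- build_precision(nr, nc)
  set.seed(12)
  zeta <- rnorm(9); zeta <- zeta - mean(zeta)
  sigma <- 0.7

  e <- eigen(as.matrix(Q0), symmetric = TRUE)
  keep <- e$values > 1e-10
  u <- drop(t(e$vectors[, keep]) %*% zeta)
  dens_oracle <- sum(dnorm(u, 0, sigma / sqrt(e$values[keep]), log = TRUE))

  expect_equal(gmrf_logdensity(zeta, sigma, Q0), dens_oracle, tolerance = 1e-10)
  expect_equal(gmrf_logdensity(zeta, sigma, Q0, logdet = geomort:::icar_logdet(3, 3)),
               dens_oracle, tolerance = 1e-10)
  expect_error(gmrf_logdensity(zeta + 1, sigma, Q0), "sum-to-zero")
})

test_that("model specifications round-trip through YAML", {
  spec <- model_spec(grid_raster(matrix(0, 4, 5), xll = 33, yll = 3,
                                 cellsize = 0.1),
                     covariates = c("temperature", "water_distance"),
                     survey_years = c(2000, 2005), spatial = TRUE,
                     priors = list(fixed_sd = 5, sigma_sd = 2))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(spec, f)
  back <- read_model_spec(f)
  expect_equal(back$covariates, spec$covariates)
  expect_equal(back$survey_years, spec$survey_years)
  expect_equal(back$priors, spec$priors)
  expect_true(back$spatial)
  expect_equal(as.matrix(back$Q0), as.matrix(spec$Q0))
})

test_that("the log-posterior decomposes into likelihood plus priors", {
  grid <- grid_raster(matrix(0, 3, 3))
  spec <- model_spec(grid, covariates = "a", survey_years = 2000, spatial = TRUE)
  set.seed(77)
  zeta <- rnorm(9); zeta <- zeta - mean(zeta)
  st <- list(alpha = c("2000" = -2), beta = c(a = 0.3), zeta = zeta,
             sigma_zeta = 0.5)

  # empty data: the joint prior
  empty <- toy_clusters(numeric(0), numeric(0))
  prior <- sum(dnorm(c(-2, 0.3), 0, 10, log = TRUE)) +
    gmrf_logdensity(zeta, 0.5, spec$Q0, spec$logdet) +
    log(2) + dnorm(0.5, 0, 1, log = TRUE)
  expect_equal(log_posterior(st, empty, matrix(0, 0, 1), spec), prior,
               tolerance = 1e-12)

  # scaling zeta by c changes the quadratic term by -(c^2-1)/(2 sigma^2) * quad
  quad <- drop(t(zeta) %*% as.matrix(spec$Q0) %*% zeta)
  for (cc in c(0.5, 2)) {
    st2 <- st; st2$zeta <- cc * zeta
    expect_equal(
      log_posterior(st2, empty, matrix(0, 0, 1), spec) -
        log_posterior(st, empty, matrix(0, 0, 1), spec),
      -(cc^2 - 1) / (2 * 0.5^2) * quad,
      tolerance = 1e-10
    )
  }

  # with data: posterior = likelihood + prior
  cl <- toy_clusters(0.5, 2.5, births = 30, deaths = 4)
  X <- matrix(0.8, 1, 1, dimnames = list(NULL, "a"))
  attr(X, "cell") <- 1L
  expect_equal(log_posterior(st, cl, X, spec),
               log_likelihood(st, cl, X) + prior, tolerance = 1e-12)
})
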