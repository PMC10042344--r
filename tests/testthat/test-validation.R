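test_that("CPO reduces correctly for degenerate posteriors", {
  cl <- toy_clusters(c(0.5, 1.5), c(0.5, 0.5), births = c(10, 8),
                     deaths = c(3, 2))
  eta1 <- matrix(c(-1.1, -0.6), 1, 2)
  f1 <- fake_fit(cl, eta = eta1, alpha = matrix(-1, dimnames = list(NULL, "2000")))
  res1 <- compute_cpo(f1$loglik)
  expect_equal(res1$cpo, exp(f1$loglik[1, ]), tolerance = 1e-12)

  # all draws identical: CPO equals the likelihood under that draw
  etaS <- matrix(rep(c(-1.1, -0.6), each = 40), 40, 2)
  fS <- fake_fit(cl, eta = etaS, alpha = matrix(rep(-1, 40), dimnames = list(NULL, "2000")))
  resS <- compute_cpo(fS$loglik)
  expect_equal(resS$cpo, exp(fS$loglik[1, ]), tolerance = 1e-12)
  expect_true(all(resS$cpo > 0 & resS$cpo <= 1))
  expect_false(any(resS$unreliable))  # equal weights: ESS = S
})

test_that("WAIC matches the brute-force definition and its limits", {
  set.seed(14)
  L <- matrix(rnorm(20, -3, 0.5), 5, 4)
  got <- compute_waic(L)
  want <- waic_oracle(L)
  expect_equal(got$waic, want$waic, tolerance = 1e-10)
  expect_equal(got$p_waic, want$p_waic, tolerance = 1e-10)
  expect_equal(got$lppd, want$lppd, tolerance = 1e-10)

  # constant over draws: zero effective parameters
  Lc <- matrix(rep(c(-2, -1, -4), each = 6), 6, 3)
  gotc <- compute_waic(Lc)
  expect_equal(gotc$p_waic, 0, tolerance = 1e-12)
  expect_equal(gotc$waic, -2 * sum(Lc[1, ]), tolerance = 1e-12)

  # duplicating every observation doubles all three quantities
  d2 <- compute_waic(cbind(L, L))
  expect_equal(d2$waic, 2 * got$waic, tolerance = 1e-10)
  expect_equal(d2$p_waic, 2 * got$p_waic, tolerance = 1e-10)
  expect_equal(d2$lppd, 2 * got$lppd, tolerance = 1e-10)

  # invariance to permuting draws and observations
  expect_equal(compute_waic(L[sample(5), ])$waic, got$waic, tolerance = 1e-12)
  expect_equal(compute_waic(L[, sample(4)])$waic, got$waic, tolerance = 1e-12)
  expect_error(compute_waic(L[1, , drop = FALSE]), "at least 2")
})

test_that("information inequalities hold on arbitrary posteriors", {
  set.seed(99)
  L <- matrix(rnorm(600, -2, 0.8), 50, 12)
  w <- compute_waic(L)
  expect_gte(w$lppd, sum(colMeans(L)))          # Jensen
  expect_gte(w$p_waic, 0)
  cpo <- compute_cpo(L)
  expect_lte(sum(log(cpo$cpo)), w$lppd + 1e-10) # importance-weighting penalty
})

test_that("mid-PIT respects the discrete boundary identities", {
  n <- 12
  # y = 0: PIT = 0.5 * P(Y = 0) <= 0.5 ; y = n: PIT >= 0.5
  cl <- toy_clusters(c(0.5, 1.5), c(0.5, 0.5), births = n,
                     deaths = c(0, n))
  set.seed(10)
  eta <- matrix(rnorm(100, -0.4, 0.3), 50, 2)
  fit <- fake_fit(cl, eta = eta,
                  alpha = matrix(rnorm(50), dimnames = list(NULL, "2000")))
  pit <- compute_pit(fit)
  expect_true(all(pit >= 0 & pit <= 1))
  expect_lte(pit[1], 0.5)
  expect_gte(pit[2], 0.5)

  # single draw, y = 0: exactly half the point mass at zero
  f1 <- fake_fit(cl[1, ], eta = matrix(-0.4),
                 alpha = matrix(-0.4, dimnames = list(NULL, "2000")))
  expect_equal(compute_pit(f1), 0.5 * dbinom(0, n, inv_logit(-0.4)),
               tolerance = 1e-12)
})

test_that("model comparison ranks by WAIC with a parameter-count tie-break", {
  sim <- glm_limit_sim(60, seed = 401, grid = 8)
  prep <- prepare_design(sim$clusters, sim$rasters)
  cfg <- mcmc_config(n_iter = 400, seed = 2)
  fit <- suppressWarnings(fit_mortality(sim$clusters, prep$design,
                                        spatial = FALSE, config = cfg))

  # single model: trivially best
  solo <- compare_models(list(m = fit))
  expect_true(solo$best[1])

  # identical models tie; equal parameter counts keep the first order stable
  two <- compare_models(list(a = fit, b = fit))
  expect_equal(two$delta_waic, c(0, 0), tolerance = 1e-12)

  # a genuinely different parameter count wins the tie
  rep_small <- validation_report(fit)
  rep_big <- rep_small
  rep_big$n_parameters <- rep_small$n_parameters + 5L
  tied <- compare_models(list(big = rep_big, small = rep_small))
  expect_equal(tied$model[1], "small")

  # different data are rejected by checksum
  other <- glm_limit_sim(60, seed = 402, grid = 8)
  oprep <- prepare_design(other$clusters, other$rasters)
  ofit <- suppressWarnings(fit_mortality(other$clusters, oprep$design,
                                         spatial = FALSE, config = cfg))
  expect_error(compare_models(list(a = fit, b = ofit)), "checksum")
})
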