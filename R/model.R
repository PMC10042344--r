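# The Bayesian binomial spatial regression, as pure functions of a parameter
# state:
#
#   deaths_j ~ Binomial(births_j, p_j)
#   logit(p_j) = alpha_{survey(j)} + x_j' beta + zeta_{cell(j)}
#
# with zeta a zero-mean intrinsic CAR (first-order rook ICAR) field on the
# raster lattice under a sum-to-zero constraint, weakly informative Normal
# priors on alpha and beta, and a Half-Normal prior on the field SD.

#' Build the ICAR structure matrix of a rectangular lattice
#'
#' First-order intrinsic CAR with rook neighborhood: the graph Laplacian
#' `Q0` with `Q0[i,i]` the number of neighbors and `Q0[i,k] = -1` for
#' neighboring cells. Cells are indexed column-major (`as.vector` of the
#' grid matrix). The full field precision is `Q0 / sigma^2` together with a
#' sum-to-zero constraint. With a `mask`, only `TRUE` cells enter the
#' lattice; a disconnected masked lattice is an error reporting the number
#' of components.
#'
#' @param nrows,ncols lattice dimensions.
#' @param mask optional logical matrix (`nrows` x `ncols`); `TRUE` = in model.
#' @return sparse symmetric matrix (class `dsCMatrix`) of dimension
#'   `ncells x ncells`.
#' @export
build_precision <- function(nrows, ncols, mask = NULL) {
  stopifnot(nrows >= 1, ncols >= 1)
  nr <- as.integer(nrows); nc <- as.integer(ncols)
  id <- matrix(seq_len(nr * nc), nr, nc)
  from <- c(if (nr > 1) id[-nr, ], if (nc > 1) id[, -nc])
  to <- c(if (nr > 1) id[-1, ], if (nc > 1) id[, -1])
  keep_cells <- seq_len(nr * nc)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), identical(dim(mask), c(nr, nc)))
    keep_cells <- which(as.vector(mask))
    if (!length(keep_cells)) stop("mask removes every cell")
    ok <- as.vector(mask)[from] & as.vector(mask)[to]
    from <- from[ok]; to <- to[ok]
    relabel <- match(seq_len(nr * nc), keep_cells)
    from <- relabel[from]; to <- relabel[to]
  }
  n <- length(keep_cells)
  if (length(from)) {
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    ncomp <- igraph::components(g)$no
  } else {
    ncomp <- n
  }
  if (ncomp > 1) {
    stop("lattice is disconnected (", ncomp, " components); ",
         "the intrinsic CAR field needs a connected lattice")
  }
  W <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(n, n), symmetric = TRUE)
  deg <- Matrix::rowSums(W)
  Matrix::Diagonal(n, deg) - W
}

# log generalized determinant (sum of log nonzero eigenvalues) of the full
# rectangular-lattice ICAR structure matrix, in closed form via the Kronecker
# sum of path-graph Laplacian spectra
icar_logdet <- function(nrows, ncols) {
  lr <- 2 - 2 * cos(pi * (0:(nrows - 1)) / nrows)
  lc <- 2 - 2 * cos(pi * (0:(ncols - 1)) / ncols)
  lambda <- outer(lr, lc, "+")
  sum(log(lambda[-1]))
}

#' Log-density of the constrained ICAR field
#'
#' Density of the zero-mean intrinsic CAR field with structure `Q0` and
#' conditional-scale parameter `sigma`, evaluated on the sum-to-zero subspace
#' (spectral normalization over the `n - 1` non-null eigenmodes).
#'
#' @param zeta numeric field vector (must sum to ~0).
#' @param sigma positive scale.
#' @param Q0 structure matrix from [build_precision()].
#' @param logdet log generalized determinant of `Q0`; computed by dense
#'   eigendecomposition when `NULL` (small lattices only).
#' @return log-density (a scalar).
#' @export
gmrf_logdensity <- function(zeta, sigma, Q0, logdet = NULL) {
  n <- length(zeta)
  stopifnot(nrow(Q0) == n, sigma > 0)
  if (abs(sum(zeta)) > 1e-6 * max(1, sqrt(n))) {
    stop("`zeta` must satisfy the sum-to-zero constraint")
  }
  if (is.null(logdet)) {
    ev <- eigen(as.matrix(Q0), symmetric = TRUE, only.values = TRUE)$values
    logdet <- sum(log(ev[ev > max(ev) * 1e-10]))
  }
  quad <- as.numeric(Matrix::crossprod(zeta, Q0 %*% zeta))
  m <- n - 1
  -0.5 * m * log(2 * pi) - m * log(sigma) + 0.5 * logdet - quad / (2 * sigma^2)
}

#' Model specification
#'
#' Bundles the lattice geometry, covariate names, survey years and priors.
#' Priors default to Normal(0, 10) on the intercepts and coefficients and
#' Half-Normal(1) on the spatial SD (weakly informative; per-SD covariate
#' scale makes these diffuse).
#'
#' @param grid a [grid_raster()] defining the lattice (values unused).
#' @param covariates character vector of (retained) covariate names.
#' @param survey_years integer vector of survey years with data.
#' @param spatial logical; include the ICAR field?
#' @param priors list with elements `fixed_sd` (Normal SD for alpha/beta) and
#'   `sigma_sd` (Half-Normal SD for the field scale).
#' @return object of class `geomort_spec` (includes the sparse `Q0` and its
#'   log generalized determinant when `spatial`).
#' @export
model_spec <- function(grid, covariates, survey_years,
                       spatial = TRUE,
                       priors = list()) {
  priors <- utils::modifyList(list(fixed_sd = 10, sigma_sd = 1), priors)
  stopifnot(priors$fixed_sd > 0, priors$sigma_sd > 0)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  spec <- list(
    grid = grid, nrows = nr, ncols = nc,
    covariates = covariates,
    survey_years = sort(unique(as.integer(survey_years))),
    spatial = isTRUE(spatial), priors = priors
  )
  if (spec$spatial) {
    spec$Q0 <- build_precision(nr, nc)
    spec$logdet <- icar_logdet(nr, nc)
  }
  structure(spec, class = "geomort_spec")
}

#' Serialize / read a model specification as YAML
#'
#' Records the priors, GMRF family tag, covariates, survey years and grid
#' geometry (the sparse structure matrix is rebuilt on read).
#'
#' @param spec a [model_spec()].
#' @param path YAML file path.
#' @return `write_model_spec()` returns `path` invisibly;
#'   `read_model_spec()` returns a `geomort_spec`.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "geomort_spec"))
  yaml::write_yaml(list(
    model = "binomial-logit",
    gmrf = if (spec$spatial) "icar-rook-sum-to-zero" else "none",
    covariates = as.list(spec$covariates),
    survey_years = as.list(spec$survey_years),
    priors = spec$priors,
    grid = list(nrows = spec$nrows, ncols = spec$ncols,
                xll = spec$grid$xll, yll = spec$grid$yll,
                cellsize = spec$grid$cellsize)
  ), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  y <- yaml::read_yaml(path)
  g <- y$grid
  model_spec(
    grid = grid_raster(matrix(NA_real_, g$nrows, g$ncols), xll = g$xll,
                       yll = g$yll, cellsize = g$cellsize),
    covariates = unlist(y$covariates) %||% character(),
    survey_years = unlist(y$survey_years),
    spatial = identical(y$gmrf, "icar-rook-sum-to-zero"),
    priors = y$priors
  )
}

# linear predictor for a state; alpha may be a scalar or a per-survey vector
# named by year
linear_predictor <- function(state, X, survey_year, cell = NULL) {
  alpha <- state$alpha
  a <- if (length(alpha) == 1) rep(unname(alpha), length(survey_year)) else {
    if (is.null(names(alpha))) stop("multi-survey `alpha` must be named by year")
    ai <- match(as.character(survey_year), names(alpha))
    if (anyNA(ai)) stop("survey years missing from `alpha`: ",
                        paste(unique(survey_year[is.na(ai)]), collapse = ", "))
    unname(alpha)[ai]
  }
  eta <- a
  if (length(state$beta)) eta <- eta + drop(X %*% state$beta)
  if (!is.null(state$zeta) && !is.null(cell)) eta <- eta + state$zeta[cell]
  eta
}

#' Binomial log-likelihood of the spatial model
#'
#' Evaluates the exact binomial log-likelihood at a parameter state, using a
#' log-sum formulation that stays finite at extreme linear predictors
#' (|eta| ~ 40 and beyond).
#'
#' @param state list with `alpha` (scalar or per-survey named vector), `beta`
#'   (vector, may be empty), optional `zeta` (field vector) and `sigma_zeta`.
#' @param clusters cluster table with `births`, `deaths`, `survey_year`.
#' @param design standardized design matrix; its `"cell"` attribute (or the
#'   `cell` argument) maps clusters to lattice cells when `zeta` is used.
#' @param cell optional integer vector of cell indices per cluster.
#' @return total log-likelihood (scalar).
#' @export
log_likelihood <- function(state, clusters, design, cell = attr(design, "cell")) {
  check_clusters(clusters)
  if (!all(is.finite(unlist(state[c("alpha", "beta")])))) stop("non-finite state")
  eta <- linear_predictor(state, design, clusters$survey_year, cell)
  sum(binom_loglik(clusters$deaths, clusters$births, eta))
}

#' Log-posterior density (up to the constant data term)
#'
#' Sum of the binomial log-likelihood, Normal log-priors on intercepts and
#' coefficients, the constrained ICAR log-density of the field given
#' `sigma_zeta`, and the Half-Normal log-prior on `sigma_zeta`. With an empty
#' cluster table this is the joint log-prior.
#'
#' @inheritParams log_likelihood
#' @param spec a [model_spec()].
#' @return log-posterior density (scalar).
#' @export
log_posterior <- function(state, clusters, design, spec,
                          cell = attr(design, "cell")) {
  ll <- if (is.null(clusters) || nrow(clusters) == 0) 0 else {
    log_likelihood(state, clusters, design, cell)
  }
  lp <- sum(stats::dnorm(c(unname(state$alpha), unname(state$beta)),
                         0, spec$priors$fixed_sd, log = TRUE))
  if (spec$spatial) {
    if (is.null(state$zeta) || is.null(state$sigma_zeta)) {
      stop("spatial spec requires `zeta` and `sigma_zeta` in the state")
    }
    lp <- lp + gmrf_logdensity(state$zeta, state$sigma_zeta, spec$Q0, spec$logdet)
    lp <- lp + log(2) + stats::dnorm(state$sigma_zeta, 0, spec$priors$sigma_sd,
                                     log = TRUE)
  }
  ll + lp
}
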