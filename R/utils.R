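# numerically stable scalar helpers shared across modules

#' Logit and inverse-logit
#'
#' @param p probabilities in (0, 1).
#' @param x real-valued linear predictors.
#' @return `logit()` returns log(p / (1 - p)); `inv_logit()` its inverse.
#' @export
logit <- function(p) log(p) - log1p(-p)

#' @rdname logit
#' @export
inv_logit <- function(x) stats::plogis(x)

# log(1 + exp(x)) without overflow/underflow; accurate over the whole line
log1pexp <- function(x) {
  out <- x
  lo <- x <= -37
  mid <- x > -37 & x <= 18
  hi <- x > 18 & x <= 33.3
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out[hi] <- x[hi] + exp(-x[hi])
  # x > 33.3: log1p(exp(x)) == x in double precision
  out
}

# log(sum(exp(x))) / log(mean(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logmeanexp <- function(x) logsumexp(x) - log(length(x))

# column-wise log-mean-exp of a matrix (draws in rows)
col_logmeanexp <- function(L) {
  m <- apply(L, 2, max)
  m + log(colMeans(exp(sweep(L, 2, m))))
}

# binomial log-pmf on the linear-predictor scale:
# log C(n,y) + y*eta - n*log(1 + exp(eta)); stable at |eta| ~ 40
binom_loglik <- function(y, n, eta, lch = lchoose(n, y)) {
  lch + y * eta - n * log1pexp(eta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed) ||
      seed != round(seed) || abs(seed) > 2^31 - 1e7) {
    stop("`seed` must be a single integer below 2^31", call. = FALSE)
  }
  as.integer(seed)
}
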