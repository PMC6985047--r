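#' Component density families
#'
#' Two parametric families describe the age-at-diagnosis distribution of a
#' single onset component: the normal density and a semi-nonparametric (SNP)
#' density in which a squared polynomial modifies a normal kernel, permitting
#' skewness and heavier tails than the normal while remaining a proper
#' density with a closed-form normalizing constant.
#'
#' With \eqn{z = (x - \mu)/\sigma} and \eqn{P(z) = \sum_{j=0}^K a_j z^j}
#' (\eqn{a_0 = 1} for identifiability), the SNP density is
#' \deqn{f(x) = \frac{P(z)^2 \phi(z)}{\sigma C}, \qquad
#'       C = \sum_{j,k} a_j a_k m_{j+k},}
#' where \eqn{m_p} is the p-th raw moment of the standard normal
#' (\eqn{m_p = 0} for odd p, \eqn{(p-1)!!} for even p). At \eqn{K = 0} the
#' family reduces exactly to the normal.
#'
#' @name densities
NULL

#' Normal density parameters
#'
#' @param mu location (years at diagnosis)
#' @param sigma scale (years), must be positive
#' @return an object of class `normal_params`
#' @export
normal_params <- function(mu, sigma) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu))
    stop("`mu` must be a single finite number", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  structure(list(mu = mu, sigma = sigma),
            class = c("normal_params", "density_params"))
}

#' Semi-nonparametric density parameters
#'
#' @param mu location (years)
#' @param sigma scale (years), positive
#' @param coeffs polynomial coefficients `(a_0, ..., a_K)`; `a_0` must be 1
#'   and the degree `K = length(coeffs) - 1` must lie in 0..3
#' @return an object of class `snp_params`
#' @export
snp_params <- function(mu, sigma, coeffs = c(1)) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu))
    stop("`mu` must be a single finite number", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  if (!is.numeric(coeffs) || length(coeffs) < 1L || any(!is.finite(coeffs)))
    stop("`coeffs` must be a finite numeric vector", call. = FALSE)
  if (length(coeffs) > 4L)
    stop("polynomial degree K must be <= 3", call. = FALSE)
  if (coeffs[1L] != 1)
    stop("`coeffs[1]` (a_0) must equal 1 for identifiability", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, coeffs = as.numeric(coeffs)),
            class = c("snp_params", "density_params"))
}

# raw moments m_0..m_p of the standard normal
std_normal_moments <- function(pmax) {
  p <- 0:pmax
  m <- numeric(pmax + 1L)
  m[p %% 2L == 0L] <- vapply(p[p %% 2L == 0L], function(q) {
    if (q == 0L) 1 else prod(seq(q - 1L, 1L, by = -2L))
  }, numeric(1))
  m
}

#' Normalizing constant of the SNP polynomial
#'
#' `C = sum_{j,k} a_j a_k m_{j+k}` equals the integral of `P(z)^2 phi(z)`
#' over the real line.
#'
#' @param coeffs polynomial coefficients `(a_0, ..., a_K)`
#' @return positive scalar
#' @export
snp_normalizer <- function(coeffs) {
  if (all(coeffs == 0))
    stop("degenerate polynomial: all coefficients are zero", call. = FALSE)
  K <- length(coeffs) - 1L
  m <- std_normal_moments(2L * K)
  idx <- outer(0:K, 0:K, `+`)
  sum(outer(coeffs, coeffs) * m[idx + 1L])
}

#' Normal probability density
#'
#' @param x ages (years)
#' @param params a `normal_params` object
#' @param log return log density?
#' @return density values (per year)
#' @export
normal_pdf <- function(x, params, log = FALSE) {
  stopifnot(inherits(params, "normal_params"))
  stats::dnorm(x, mean = params$mu, sd = params$sigma, log = log)
}

#' Semi-nonparametric probability density
#'
#' @inheritParams normal_pdf
#' @param params an `snp_params` object
#' @export
snp_pdf <- function(x, params, log = FALSE) {
  stopifnot(inherits(params, "snp_params"))
  z <- (x - params$mu) / params$sigma
  P <- poly_eval(params$coeffs, z)
  C <- snp_normalizer(params$coeffs)
  lf <- 2 * log(abs(P)) + stats::dnorm(z, log = TRUE) - log(params$sigma) - log(C)
  lf[P == 0] <- -Inf
  if (log) lf else exp(lf)
}

poly_eval <- function(coeffs, z) {
  # Horner scheme
  out <- rep(coeffs[length(coeffs)], length(z))
  for (j in rev(seq_len(length(coeffs) - 1L))) out <- out * z + coeffs[j]
  out
}

#' Cumulative distribution function of an SNP density
#'
#' Closed form via the recursion
#' `I_p(z) = -z^(p-1) phi(z) + (p-1) I_(p-2)(z)` for the partial moments
#' `I_p(z) = integral_{-inf}^{z} t^p phi(t) dt`.
#'
#' @param x quantiles
#' @param params an `snp_params` object
#' @return CDF values in \[0, 1\]
#' @export
snp_cdf <- function(x, params) {
  stopifnot(inherits(params, "snp_params"))
  a <- params$coeffs
  K <- length(a) - 1L
  z <- (x - params$mu) / params$sigma
  phi <- stats::dnorm(z)
  I <- matrix(0, nrow = length(z), ncol = 2L * K + 1L)
  I[, 1L] <- stats::pnorm(z)
  if (ncol(I) >= 2L) I[, 2L] <- -phi
  if (ncol(I) >= 3L) for (p in 2L:(2L * K)) {
    I[, p + 1L] <- -z^(p - 1L) * phi + (p - 1L) * I[, p - 1L]
  }
  C <- snp_normalizer(a)
  w <- outer(a, a)
  idx <- outer(0:K, 0:K, `+`) + 1L
  out <- numeric(length(z))
  for (j in seq_along(w)) out <- out + w[j] * I[, idx[j]]
  pmin(pmax(out / C, 0), 1)
}

# cdf generic used by truncated likelihoods
density_cdf <- function(params, x) {
  if (inherits(params, "normal_params")) {
    stats::pnorm(x, params$mu, params$sigma)
  } else {
    snp_cdf(x, params)
  }
}

density_pdf <- function(params, x, log = FALSE) {
  if (inherits(params, "normal_params")) normal_pdf(x, params, log = log)
  else snp_pdf(x, params, log = log)
}

#' Draw samples from a component density
#'
#' Normal sampling is direct; SNP sampling inverts the closed-form CDF on a
#' cached 4096-point grid with monotone interpolation. Truncation is applied
#' by rejection from the untruncated sampler; if the truncation interval
#' carries negligible mass (< 1e-12) an error is raised.
#'
#' @param params `normal_params` or `snp_params`
#' @param n number of draws (>= 1)
#' @param seed optional integer; when given, draws are deterministic and the
#'   caller's RNG state is untouched
#' @param truncation optional `c(lo, hi)` bounds in years
#' @return numeric vector of length `n`
#' @export
sample_density <- function(params, n, seed = NULL, truncation = NULL) {
  stopifnot(inherits(params, "density_params"), n >= 1)
  if (!is.null(truncation)) {
    stopifnot(length(truncation) == 2L, truncation[1] < truncation[2])
    mass <- density_cdf(params, truncation[2]) - density_cdf(params, truncation[1])
    if (mass < 1e-12)
      stop("truncation interval carries negligible probability mass", call. = FALSE)
  }
  draw <- function() {
    out <- numeric(0)
    while (length(out) < n) {
      m <- max(2L * (n - length(out)), 64L)
      x <- if (inherits(params, "normal_params")) {
        stats::rnorm(m, params$mu, params$sigma)
      } else {
        snp_sample_raw(params, m)
      }
      if (!is.null(truncation))
        x <- x[x >= truncation[1] & x <= truncation[2]]
      out <- c(out, x)
    }
    out[seq_len(n)]
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

# inverse-CDF sampling on a 4096-point grid
snp_sample_raw <- function(params, m) {
  grid <- seq(params$mu - 10 * params$sigma, params$mu + 10 * params$sigma,
              length.out = 4096L)
  cdf <- snp_cdf(grid, params)
  keep <- c(TRUE, diff(cdf) > 0)   # monotone subset for interpolation
  u <- stats::runif(m, min = max(min(cdf), 1e-12), max = min(max(cdf), 1 - 1e-12))
  stats::approx(cdf[keep], grid[keep], xout = u, rule = 2, ties = "ordered")$y
}

#' Serialize density parameters to a JSON-ready list
#' @param params `normal_params` or `snp_params`
#' @return a list with fields `family`, `mu`, `sigma` (and `coeffs` for SNP)
#' @export
params_to_list <- function(params) {
  if (inherits(params, "normal_params")) {
    list(family = "normal", mu = params$mu, sigma = params$sigma)
  } else {
    list(family = "snp", mu = params$mu, sigma = params$sigma,
         coeffs = params$coeffs)
  }
}

#' Rebuild density parameters from a serialized list
#' @param x a list as produced by [params_to_list()]
#' @return `normal_params` or `snp_params`
#' @export
params_from_list <- function(x) {
  switch(x$family,
         normal = normal_params(x$mu, x$sigma),
         snp    = snp_params(x$mu, x$sigma, unlist(x$coeffs)),
         stop("unknown density family: ", x$family, call. = FALSE))
}
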