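#' Maximum-likelihood fitting of single densities and two-component mixtures
#'
#' Four models are fit per stratum: single normal, single SNP, two-component
#' normal mixture (EM), and two-component SNP mixture (direct numerical ML).
#' Free-parameter counts for AIC, after the `a_0 = 1` identifiability
#' constraint: single normal 2; single SNP `2 + K`; normal mixture 5; SNP
#' mixture `2(2 + K) + 1`.
#'
#' Likelihoods treat ages as continuous even when integer-valued. By default
#' densities are not truncation-adjusted; supplying `truncation = c(lo, hi)`
#' in the config renormalizes each density to `[lo, hi]` inside the
#' likelihood, appropriate when the ascertainment window is known.
#'
#' @name fitting
NULL

#' Fitting configuration
#'
#' @param n_random_starts random restarts added to deterministic starts
#' @param tol relative log-likelihood convergence tolerance (EM)
#' @param max_iter maximum EM iterations
#' @param sigma_floor smallest admissible component scale (years); a
#'   component shrinking below it counts as collapsed and the start is
#'   abandoned
#' @param truncation optional `c(lo, hi)` ascertainment bounds (years); when
#'   given every density is renormalized to the window inside the likelihood
#' @param seed master seed governing all random restarts
#' @param snp_starts random restarts for the SNP-mixture optimizer (kept
#'   smaller than `n_random_starts` because each start is costlier)
#' @return a `fit_config` list
#' @export
fit_config <- function(n_random_starts = 10L, tol = 1e-8, max_iter = 1000L,
                       sigma_floor = 0.5, truncation = NULL, seed = 1L,
                       snp_starts = 5L) {
  if (!is.null(truncation))
    stopifnot(length(truncation) == 2L, truncation[1] < truncation[2])
  structure(list(n_random_starts = as.integer(n_random_starts), tol = tol,
                 max_iter = as.integer(max_iter), sigma_floor = sigma_floor,
                 truncation = truncation, seed = as.integer(seed),
                 snp_starts = as.integer(snp_starts)),
            class = "fit_config")
}

#' Two-component mixture parameters
#'
#' Components are labeled so that the early component has the smaller mode.
#'
#' @param comp_early,comp_late component densities (same family)
#' @param pi_early mixing weight of the early component, in (0, 1)
#' @return a `mixture_params` object
#' @export
mixture_params <- function(comp_early, comp_late, pi_early) {
  stopifnot(inherits(comp_early, "density_params"),
            inherits(comp_late, "density_params"),
            is.numeric(pi_early), length(pi_early) == 1L,
            pi_early > 0, pi_early < 1)
  structure(list(comp_early = comp_early, comp_late = comp_late,
                 pi_early = pi_early),
            class = "mixture_params")
}

# mode of a single component density (normal: mu; SNP: grid + refine)
component_mode <- function(params) {
  if (inherits(params, "normal_params")) return(params$mu)
  lo <- params$mu - 5 * params$sigma
  hi <- params$mu + 5 * params$sigma
  grid <- seq(lo, hi, by = 0.1)
  f <- snp_pdf(grid, params)
  g0 <- grid[which.max(f)]
  stats::optimize(function(x) snp_pdf(x, params),
                  lower = max(lo, g0 - 0.2), upper = min(hi, g0 + 0.2),
                  maximum = TRUE, tol = 1e-6)$maximum
}

# order components so the early one has the smaller mode; tie-break: early
# label to the larger weight, with a warning
relabel_mixture <- function(comp1, comp2, pi1) {
  m1 <- component_mode(comp1)
  m2 <- component_mode(comp2)
  if (isTRUE(all.equal(m1, m2, tolerance = 1e-8))) {
    warning("component modes are equal; early label assigned to the larger weight",
            call. = FALSE)
    if (pi1 >= 0.5) mixture_params(comp1, comp2, pi1)
    else mixture_params(comp2, comp1, 1 - pi1)
  } else if (m1 < m2) {
    mixture_params(comp1, comp2, pi1)
  } else {
    mixture_params(comp2, comp1, 1 - pi1)
  }
}

#' Log-density of a two-component mixture
#' @param params a `mixture_params` object
#' @param x ages
#' @return log density values
#' @export
mixture_logpdf <- function(params, x) {
  l1 <- log(params$pi_early) + density_pdf(params$comp_early, x, log = TRUE)
  l2 <- log1p(-params$pi_early) + density_pdf(params$comp_late, x, log = TRUE)
  m <- pmax(l1, l2)
  out <- m + log(exp(l1 - m) + exp(l2 - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Mixture density
#' @inheritParams mixture_logpdf
#' @export
mixture_pdf <- function(params, x) exp(mixture_logpdf(params, x))

# probability mass a density places on a window
window_mass <- function(params, truncation) {
  if (inherits(params, "mixture_params")) {
    params$pi_early * window_mass(params$comp_early, truncation) +
      (1 - params$pi_early) * window_mass(params$comp_late, truncation)
  } else {
    density_cdf(params, truncation[2]) - density_cdf(params, truncation[1])
  }
}

# total log-likelihood, truncation-aware
model_loglik <- function(params, x, truncation = NULL) {
  ll <- if (inherits(params, "mixture_params")) sum(mixture_logpdf(params, x))
        else sum(density_pdf(params, x, log = TRUE))
  if (!is.null(truncation)) {
    mass <- window_mass(params, truncation)
    if (mass <= 0) return(-Inf)
    ll <- ll - length(x) * log(mass)
  }
  ll
}

new_fit_result <- function(model, params, loglik, k, converged,
                           n_starts_used = 1L, iterations = 0L) {
  structure(list(model = model, params = params, loglik = loglik, k = k,
                 aic = 2 * k - 2 * loglik, converged = converged,
                 n_starts_used = n_starts_used, iterations = iterations),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s>  loglik = %.4f  k = %d  AIC = %.4f  converged = %s\n",
              x$model, x$loglik, x$k, x$aic, x$converged))
  invisible(x)
}

check_ages <- function(ages, n_min, what) {
  ages <- ages[is.finite(ages)]
  if (length(ages) < n_min)
    stop(sprintf("%s requires at least %d finite ages", what, n_min), call. = FALSE)
  ages
}

#' Fit a single normal density by maximum likelihood
#'
#' Untruncated: closed form (`mu` = sample mean, `sigma` = 1/n standard
#' deviation). With a truncation window the truncated likelihood is
#' maximized numerically.
#'
#' @param ages numeric vector of ages at diagnosis
#' @param config a [fit_config()]
#' @return a `fit_result` with `k = 2`
#' @export
fit_single_normal <- function(ages, config = fit_config()) {
  ages <- check_ages(ages, 2L, "fit_single_normal")
  if (length(unique(ages)) < 2L)
    stop("degenerate variance: all ages identical", call. = FALSE)
  mu <- mean(ages)
  sigma <- sqrt(mean((ages - mu)^2))
  if (is.null(config$truncation)) {
    p <- normal_params(mu, sigma)
    return(new_fit_result("single_normal", p, model_loglik(p, ages), 2L, TRUE))
  }
  nll <- function(th) {
    p <- tryCatch(normal_params(th[1], exp(th[2])), error = function(e) NULL)
    if (is.null(p)) return(1e12)
    v <- -model_loglik(p, ages, config$truncation)
    if (!is.finite(v)) 1e12 else v
  }
  opt <- stats::optim(c(mu, log(sigma)), nll, method = "BFGS",
                      control = list(maxit = 500L))
  p <- normal_params(opt$par[1], exp(opt$par[2]))
  new_fit_result("single_normal", p, -opt$value, 2L, opt$convergence == 0L,
                 iterations = opt$counts[["function"]])
}

#' Fit a single SNP density by maximum likelihood
#'
#' Multi-start quasi-Newton optimization over `(mu, log sigma, a_1..a_K)`.
#' The normal MLE with zero higher-order coefficients is always among the
#' starts, so the fitted log-likelihood can never fall below the single
#' normal's (the normal is nested at `a_1 = ... = a_K = 0`).
#'
#' @inheritParams fit_single_normal
#' @param degree polynomial degree K in 0..3
#' @return a `fit_result` with `k = 2 + K`
#' @export
fit_single_snp <- function(ages, degree = 2L, config = fit_config()) {
  degree <- as.integer(degree)
  stopifnot(degree >= 0L, degree <= 3L)
  ages <- check_ages(ages, degree + 3L, "fit_single_snp")
  base <- fit_single_normal(ages, config)
  if (degree == 0L) {
    p <- snp_params(base$params$mu, base$params$sigma, c(1))
    return(new_fit_result("single_snp", p, base$loglik, 2L, base$converged))
  }
  nll <- function(th) {
    p <- tryCatch(snp_params(th[1], exp(th[2]), c(1, th[3:(2L + degree)])),
                  error = function(e) NULL)
    if (is.null(p)) return(1e12)
    v <- -model_loglik(p, ages, config$truncation)
    if (!is.finite(v)) 1e12 else v
  }
  th0 <- c(base$params$mu, log(base$params$sigma), rep(0, degree))
  # deterministic sign-pattern grid over the polynomial coefficients: the
  # likelihood has reflected basins (a skewed fit can be mimicked poorly by
  # the mirrored coefficient signs with a shifted mu), so cover both signs
  sign_grid <- as.matrix(expand.grid(rep(list(c(-0.5, 0.5)), degree)))
  med <- stats::median(ages)
  det_starts <- lapply(seq_len(nrow(sign_grid)), function(i)
    as.numeric(c(med, log(base$params$sigma), sign_grid[i, ])))
  starts <- c(list(th0), det_starts,
              withr::with_seed(config$seed, lapply(seq_len(config$n_random_starts),
                function(i) th0 + c(stats::rnorm(1, 0, 2), stats::rnorm(1, 0, 0.2),
                                    stats::rnorm(degree, 0, 0.3)))))
  best <- NULL; ok <- FALSE; iters <- 0L
  for (s in starts) {
    opt <- tryCatch(stats::optim(s, nll, method = "BFGS",
                                 control = list(maxit = 500L)),
                    error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) { best <- opt }
    if (opt$convergence == 0L) ok <- TRUE
    iters <- iters + opt$counts[["function"]]
  }
  if (is.null(best)) stop("SNP optimization failed on all starts", call. = FALSE)
  p <- snp_params(best$par[1], exp(best$par[2]), c(1, best$par[3:(2L + degree)]))
  new_fit_result("single_snp", p, -best$value, 2L + degree, ok,
                 n_starts_used = length(starts), iterations = iters)
}

# deterministic + random EM starts; each is list(mu1, s1, mu2, s2, pi)
em_starts <- function(ages, config) {
  mu <- mean(ages); sd0 <- stats::sd(ages)
  qsplit <- function(q) {
    cut <- stats::quantile(ages, q)
    lo <- ages[ages <= cut]; hi <- ages[ages > cut]
    if (length(lo) < 2L || length(hi) < 2L) return(NULL)
    list(mu1 = mean(lo), s1 = max(stats::sd(lo), config$sigma_floor),
         mu2 = mean(hi), s2 = max(stats::sd(hi), config$sigma_floor),
         pi = length(lo) / length(ages))
  }
  det <- Filter(Negate(is.null), lapply(c(0.3, 0.5, 0.7), qsplit))
  # identical-component start: a fixed point whose loglik equals the single fit
  det <- c(det, list(list(mu1 = mu, s1 = sd0, mu2 = mu, s2 = sd0, pi = 0.5)))
  # random starts: split at a random quantile (well-separated inits; plain
  # coin-flip partitions collapse onto the identical-component saddle)
  rnd <- withr::with_seed(config$seed, {
    us <- stats::runif(config$n_random_starts, 0.15, 0.85)
    Filter(Negate(is.null), lapply(us, qsplit))
  })
  c(det, rnd)
}

em_run <- function(ages, st, config) {
  n <- length(ages)
  mu1 <- st$mu1; s1 <- st$s1; mu2 <- st$mu2; s2 <- st$s2; pi1 <- min(max(st$pi, 0.01), 0.99)
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(config$max_iter)) {
    l1 <- log(pi1) + stats::dnorm(ages, mu1, s1, log = TRUE)
    l2 <- log1p(-pi1) + stats::dnorm(ages, mu2, s2, log = TRUE)
    m <- pmax(l1, l2)
    ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
    trace <- c(trace, ll)
    r1 <- 1 / (1 + exp(l2 - l1))
    n1 <- sum(r1)
    if (n1 < 1e-8 || n - n1 < 1e-8) return(list(collapsed = TRUE))
    mu1 <- sum(r1 * ages) / n1
    mu2 <- sum((1 - r1) * ages) / (n - n1)
    s1 <- sqrt(sum(r1 * (ages - mu1)^2) / n1)
    s2 <- sqrt(sum((1 - r1) * (ages - mu2)^2) / (n - n1))
    if (s1 < config$sigma_floor || s2 < config$sigma_floor)
      return(list(collapsed = TRUE))
    pi1 <- n1 / n
    if (is.finite(ll_old) && abs(ll - ll_old) <= config$tol * (abs(ll_old) + 1e-3))
      return(list(collapsed = FALSE, mu1 = mu1, s1 = s1, mu2 = mu2, s2 = s2,
                  pi = pi1, loglik = ll, iterations = it, converged = TRUE,
                  trace = trace))
    ll_old <- ll
  }
  list(collapsed = FALSE, mu1 = mu1, s1 = s1, mu2 = mu2, s2 = s2, pi = pi1,
       loglik = ll_old, iterations = config$max_iter, converged = FALSE,
       trace = trace)
}

#' Fit a two-component normal mixture
#'
#' Untruncated: EM from quantile-split, identical-component, and seeded
#' random-partition starts; the winning run's log-likelihood trace (strictly
#' non-decreasing) is attached as attribute `loglik_trace`. With a truncation
#' window, the truncated likelihood is maximized directly by multi-start
#' BFGS on `(mu1, log s1, mu2, log s2, logit pi)` since the truncated M-step
#' has no closed form.
#'
#' @inheritParams fit_single_normal
#' @return a `fit_result` with `k = 5`; `params` is a `mixture_params`
#' @export
fit_mixture_normal_em <- function(ages, config = fit_config()) {
  ages <- check_ages(ages, 10L, "fit_mixture_normal_em")
  starts <- em_starts(ages, config)
  if (!is.null(config$truncation))
    return(fit_mixture_normal_trunc(ages, starts, config))
  best <- NULL; n_used <- 0L
  for (st in starts) {
    n_used <- n_used + 1L
    res <- em_run(ages, st, config)
    if (isTRUE(res$collapsed)) next
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best))
    stop("degenerate fit: every EM start collapsed a component", call. = FALSE)
  params <- relabel_mixture(normal_params(best$mu1, best$s1),
                            normal_params(best$mu2, best$s2), best$pi)
  out <- new_fit_result("mixture_normal", params, best$loglik, 5L,
                        best$converged, n_starts_used = n_used,
                        iterations = best$iterations)
  attr(out, "loglik_trace") <- best$trace
  out
}

fit_mixture_normal_trunc <- function(ages, starts, config) {
  # the untruncated EM solution is usually an excellent start for the
  # truncated likelihood; prepend it
  em_untr <- tryCatch(
    fit_mixture_normal_em(ages, fit_config(
      n_random_starts = config$n_random_starts, tol = config$tol,
      max_iter = config$max_iter, sigma_floor = config$sigma_floor,
      truncation = NULL, seed = config$seed, snp_starts = config$snp_starts)),
    error = function(e) NULL)
  if (!is.null(em_untr)) {
    p <- em_untr$params
    starts <- c(list(list(mu1 = p$comp_early$mu, s1 = p$comp_early$sigma,
                          mu2 = p$comp_late$mu, s2 = p$comp_late$sigma,
                          pi = p$pi_early)), starts)
  }
  # identifiability walls inside the objective: the truncated likelihood is
  # unbounded at near-boundary point-mass components and admits vacuous
  # solutions with a component located far outside the observed ages acting
  # as a flat background. Component locations are therefore constrained to
  # the observed age range and scales to [sigma_floor, age range width].
  sig_hi <- diff(range(ages))
  mu_lo <- min(ages); mu_hi <- max(ages)
  nll <- function(th) {
    s1 <- exp(th[2]); s2 <- exp(th[4])
    if (!is.finite(s1) || !is.finite(s2) ||
        s1 < config$sigma_floor || s2 < config$sigma_floor ||
        s1 > sig_hi || s2 > sig_hi) return(1e12)
    if (th[1] < mu_lo || th[1] > mu_hi || th[3] < mu_lo || th[3] > mu_hi)
      return(1e12)
    pi1 <- min(max(stats::plogis(th[5]), 1e-12), 1 - 1e-12)
    p <- tryCatch(mixture_params(normal_params(th[1], s1),
                                 normal_params(th[3], s2), pi1),
                  error = function(e) NULL)
    if (is.null(p)) return(1e12)
    v <- -model_loglik(p, ages, config$truncation)
    if (!is.finite(v)) 1e12 else v
  }
  best <- NULL; ok <- FALSE; iters <- 0L
  for (st in starts) {
    th0 <- c(st$mu1, log(st$s1), st$mu2, log(st$s2),
             stats::qlogis(min(max(st$pi, 0.01), 0.99)))
    opt <- tryCatch(stats::optim(th0, nll, method = "BFGS",
                                 control = list(maxit = 500L)),
                    error = function(e) NULL)
    if (is.null(opt)) next
    if (exp(opt$par[2]) < config$sigma_floor || exp(opt$par[4]) < config$sigma_floor)
      next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0L) ok <- TRUE
    iters <- iters + opt$counts[["function"]]
  }
  if (is.null(best))
    stop("degenerate fit: truncated-mixture optimization failed on all starts",
         call. = FALSE)
  polish <- stats::optim(best$par, nll, method = "Nelder-Mead",
                         control = list(maxit = 2000L, reltol = 1e-12))
  if (polish$value < best$value) best <- polish
  params <- relabel_mixture(normal_params(best$par[1], exp(best$par[2])),
                            normal_params(best$par[3], exp(best$par[4])),
                            stats::plogis(best$par[5]))
  new_fit_result("mixture_normal", params, -best$value, 5L, ok,
                 n_starts_used = length(starts), iterations = iters)
}

#' Fit a two-component SNP mixture by direct numerical maximum likelihood
#'
#' Multi-start BFGS over the unconstrained vector
#' `(mu1, log s1, a1_1..a1_K, mu2, log s2, a2_1..a2_K, logit pi)`. The starts
#' always include (i) the normal-mixture EM solution with zero polynomial
#' coefficients and (ii) the single-SNP fit duplicated in both components at
#' `pi = 0.5` (a mixture of two identical densities IS that density), so the
#' fitted log-likelihood is bounded below by both nested models up to
#' optimizer slack.
#'
#' @inheritParams fit_single_snp
#' @return a `fit_result` with `k = 2(2 + K) + 1`
#' @export
fit_mixture_snp <- function(ages, degree = 2L, config = fit_config()) {
  degree <- as.integer(degree)
  stopifnot(degree >= 0L, degree <= 3L)
  ages <- check_ages(ages, 2L * (degree + 3L), "fit_mixture_snp")
  em <- fit_mixture_normal_em(ages, config)
  ssnp <- fit_single_snp(ages, degree, config)
  K <- degree
  pack <- function(c1, c2, pi1) {
    c(c1$mu, log(c1$sigma), if (K > 0) c1$coeffs[-1L] else NULL,
      c2$mu, log(c2$sigma), if (K > 0) c2$coeffs[-1L] else NULL,
      stats::qlogis(min(max(pi1, 1e-4), 1 - 1e-4)))
  }
  unpack <- function(th) {
    i <- 2L + K
    c1 <- snp_params(th[1], exp(th[2]), c(1, if (K > 0) th[3:(2L + K)] else NULL))
    c2 <- snp_params(th[i + 1L], exp(th[i + 2L]),
                     c(1, if (K > 0) th[(i + 3L):(2L * i)] else NULL))
    pi1 <- min(max(stats::plogis(th[2L * i + 1L]), 1e-12), 1 - 1e-12)
    mixture_params(c1, c2, pi1)
  }
  nll <- function(th) {
    p <- tryCatch(unpack(th), error = function(e) NULL)
    if (is.null(p)) return(1e12)
    v <- -model_loglik(p, ages, config$truncation)
    if (!is.finite(v)) 1e12 else v
  }
  emc <- list(snp_params(em$params$comp_early$mu, em$params$comp_early$sigma,
                         c(1, rep(0, K))),
              snp_params(em$params$comp_late$mu, em$params$comp_late$sigma,
                         c(1, rep(0, K))))
  th_em <- pack(emc[[1]], emc[[2]], em$params$pi_early)
  th_single <- pack(ssnp$params, ssnp$params, 0.5)
  starts <- c(list(th_em, th_single),
              withr::with_seed(config$seed + 1L,
                lapply(seq_len(config$snp_starts), function(i)
                  th_em + stats::rnorm(length(th_em), 0, 0.15))))
  best <- NULL; ok <- FALSE; iters <- 0L
  for (s in starts) {
    opt <- tryCatch(stats::optim(s, nll, method = "BFGS",
                                 control = list(maxit = 400L)),
                    error = function(e) NULL)
    if (is.null(opt)) next
    p <- tryCatch(unpack(opt$par), error = function(e) NULL)
    if (is.null(p)) next
    if (p$comp_early$sigma < config$sigma_floor ||
        p$comp_late$sigma < config$sigma_floor) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0L) ok <- TRUE
    iters <- iters + opt$counts[["function"]]
  }
  if (is.null(best))
    stop("SNP-mixture optimization failed on all starts", call. = FALSE)
  raw <- unpack(best$par)
  params <- relabel_mixture(raw$comp_early, raw$comp_late, raw$pi_early)
  new_fit_result("mixture_snp", params, -best$value, 2L * (2L + K) + 1L, ok,
                 n_starts_used = length(starts), iterations = iters)
}
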