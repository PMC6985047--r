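test_that("fit_single_normal is the closed-form MLE", {
  f <- fit_single_normal(c(40, 50))
  expect_equal(f$params$mu, 45)
  expect_equal(f$params$sigma, 5)
  expect_equal(f$k, 2L)
  expect_equal(f$aic, 2 * 2 - 2 * f$loglik, tolerance = 1e-9)
  expect_error(fit_single_normal(c(45, 45, 45)), "degenerate")
})

test_that("fit_single_normal recovers simulated truth", {
  x <- withr::with_seed(5, stats::rnorm(1e4, 50, 10))
  f <- fit_single_normal(x)
  expect_gt(f$params$mu, 49.5); expect_lt(f$params$mu, 50.5)
  expect_gt(f$params$sigma, 9.5); expect_lt(f$params$sigma, 10.5)
})

test_that("fit_single_snp nests the normal and reduces at K=0", {
  x <- withr::with_seed(11, stats::rnorm(800, 55, 8))
  fn <- fit_single_normal(x)
  f0 <- fit_single_snp(x, degree = 0)
  expect_equal(f0$loglik, fn$loglik, tolerance = 1e-9)
  expect_equal(f0$k, 2L)
  f2 <- fit_single_snp(x, degree = 2, config = fast_config())
  expect_gte(f2$loglik, fn$loglik - 1e-6)
  expect_equal(f2$k, 4L)
  # on normal data the SNP gain should be modest (no spurious structure)
  expect_lt(f2$loglik - fn$loglik, 3)
})

test_that("fit_single_snp recovers a skewed polynomial coefficient", {
  truth <- snp_params(50, 8, c(1, 0.8))
  x <- sample_density(truth, 1e4, seed = 21)
  f <- fit_single_snp(x, degree = 1, config = fast_config())
  expect_equal(f$params$coeffs[2], 0.8, tolerance = 0.1)
  expect_equal(f$params$mu, 50, tolerance = 1)
})

test_that("EM recovers mixture parameters and is monotone and deterministic", {
  x <- make_bimodal_ages(5000, seed = 2, w = 0.7, m1 = 45, s1 = 8, m2 = 65, s2 = 6)
  f <- fit_mixture_normal_em(x, fast_config())
  expect_gt(f$params$pi_early, 0.65); expect_lt(f$params$pi_early, 0.75)
  expect_equal(f$params$comp_early$mu, 45, tolerance = 1.5)
  expect_equal(f$params$comp_late$mu, 65, tolerance = 1.5)
  expect_equal(f$k, 5L)
  trace <- attr(f, "loglik_trace")
  expect_true(all(diff(trace) >= -1e-10))
  f2 <- fit_mixture_normal_em(x, fast_config())
  expect_identical(f[names(f) != "iterations"], f2[names(f2) != "iterations"])
  expect_identical(f$params, f2$params)
})

test_that("mixture fit on unimodal data shows only modest overfit gain", {
  x <- withr::with_seed(3, stats::rnorm(2000, 52, 9))
  fs <- fit_single_normal(x)
  fm <- fit_mixture_normal_em(x, fast_config())
  expect_gte(fm$loglik, fs$loglik - 1e-6)
  expect_lt(fm$loglik - fs$loglik, 5)
})

test_that("nesting chain and AIC identity hold across all four fits", {
  x <- make_bimodal_ages(1200, seed = 8)
  cfg <- fast_config()
  fsn <- fit_single_normal(x, cfg)
  fss <- fit_single_snp(x, 2, cfg)
  fmn <- fit_mixture_normal_em(x, cfg)
  fms <- fit_mixture_snp(x, 2, cfg)
  expect_gte(fss$loglik, fsn$loglik - 1e-4)
  expect_gte(fmn$loglik, fsn$loglik - 1e-4)
  expect_gte(fms$loglik, fss$loglik - 1e-4)
  expect_gte(fms$loglik, fmn$loglik - 1e-4)
  for (f in list(fsn, fss, fmn, fms))
    expect_equal(f$aic, 2 * f$k - 2 * f$loglik, tolerance = 1e-9)
  expect_equal(fms$k, 9L)  # 2(2+K)+1 at K=2
})

test_that("SNP mixture at K=0 agrees with the normal-mixture EM", {
  x <- make_bimodal_ages(900, seed = 13)
  cfg <- fast_config()
  fmn <- fit_mixture_normal_em(x, cfg)
  fm0 <- fit_mixture_snp(x, 0, cfg)
  expect_equal(fm0$loglik, fmn$loglik, tolerance = 1e-4)
  expect_equal(fm0$k, 5L)
})

test_that("component labels are ordered by mode regardless of input order", {
  c1 <- normal_params(45, 8); c2 <- normal_params(65, 6)
  a <- agemix:::relabel_mixture(c1, c2, 0.7)
  b <- agemix:::relabel_mixture(c2, c1, 0.3)
  expect_equal(a, b)
  expect_lt(a$comp_early$mu, a$comp_late$mu)
  expect_equal(a$pi_early, 0.7)
  expect_warning(agemix:::relabel_mixture(normal_params(50, 5),
                                          normal_params(50, 9), 0.6),
                 "equal")
})

test_that("small datasets fit without crashing", {
  x <- make_bimodal_ages(50, seed = 17)
  f <- fit_mixture_snp(x, 2, fast_config())
  expect_s3_class(f, "fit_result")
  expect_true(is.logical(f$converged))
})

test_that("truncated likelihood option renormalizes the fit", {
  co <- one_stratum_cohort(2860, 0.72, seed = 1001)
  f <- fit_mixture_normal_em(co$age, fast_config(truncation = c(20, 74)))
  expect_equal(f$params$pi_early, 0.72, tolerance = 0.05)
  expect_equal(f$params$comp_early$mu, 46, tolerance = 2)
  expect_equal(f$params$comp_late$mu, 67, tolerance = 2)
})
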