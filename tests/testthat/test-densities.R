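test_that("normal_pdf matches closed-form values and normalizes", {
  expect_equal(normal_pdf(0, normal_params(0, 1)), 0.3989423, tolerance = 1e-6)
  p <- normal_params(52.3, 7.7)
  expect_equal(normal_pdf(52.3, p), 1 / (7.7 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(integrate_pdf(p, 52.3 - 10 * 7.7, 52.3 + 10 * 7.7), 1,
               tolerance = 1e-8)
  expect_error(normal_params(50, 0), "sigma")
  expect_error(normal_params(50, -1), "sigma")
})

test_that("snp_normalizer reproduces moment arithmetic and quadrature", {
  expect_identical(snp_normalizer(c(1)), 1)
  expect_equal(snp_normalizer(c(1, 1)), 2)        # m0 + 2 m1 + m2
  expect_equal(snp_normalizer(c(1, 0, 1)), 6)     # 1 + 2*m2 + m4
  # independent oracle: quadrature of P(z)^2 phi(z)
  for (co in list(c(1, 1), c(1, 0, 1), c(1, -0.4, 0.3, 0.2))) {
    quad <- stats::integrate(function(z) {
      agemix:::poly_eval(co, z)^2 * stats::dnorm(z)
    }, -15, 15, rel.tol = 1e-11)$value
    expect_equal(snp_normalizer(co), quad, tolerance = 1e-8)
  }
  expect_error(snp_normalizer(c(0, 0)), "degenerate")
})

test_that("snp_pdf evaluates, normalizes, and reduces to the normal at K=0", {
  p <- snp_params(0, 1, c(1, 1))
  expect_equal(snp_pdf(0, p), stats::dnorm(0) / 2, tolerance = 1e-9)
  # K=0 reduction is exact in log space
  x <- seq(10, 90, by = 0.5)
  p0 <- snp_params(50, 10, c(1))
  expect_equal(snp_pdf(x, p0, log = TRUE),
               normal_pdf(x, normal_params(50, 10), log = TRUE),
               tolerance = 1e-12)
  expect_equal(snp_pdf(50, p0), normal_pdf(50, normal_params(50, 10)))
})

test_that("every valid SNP density integrates to 1 (randomized property)", {
  withr::with_seed(7, {
    for (i in 1:8) {
      K <- sample(1:3, 1)
      p <- snp_params(stats::runif(1, 30, 60), stats::runif(1, 4, 15),
                      c(1, stats::runif(K, -0.8, 0.8)))
      expect_equal(integrate_pdf(p, p$mu - 40 * p$sigma, p$mu + 40 * p$sigma),
                   1, tolerance = 1e-6)
    }
  })
})

test_that("SNP densities with even coefficients are symmetric about mu", {
  p <- snp_params(47, 8, c(1, 0, 0.6))
  d <- seq(0.5, 25, by = 0.5)
  expect_equal(snp_pdf(47 + d, p), snp_pdf(47 - d, p), tolerance = 1e-12)
})

test_that("snp_cdf agrees with quadrature of the pdf", {
  p <- snp_params(50, 9, c(1, 0.5, -0.2))
  for (q in c(35, 50, 62)) {
    quad <- stats::integrate(function(x) snp_pdf(x, p), p$mu - 30 * p$sigma, q,
                             rel.tol = 1e-10)$value
    expect_equal(snp_cdf(q, p), quad, tolerance = 1e-7)
  }
})

test_that("sample_density is seed-deterministic and respects truncation", {
  pn <- normal_params(50, 10)
  expect_identical(sample_density(pn, 5, seed = 123),
                   sample_density(pn, 5, seed = 123))
  s <- sample_density(pn, 2000, seed = 9, truncation = c(20, 74))
  expect_gte(min(s), 20)
  expect_lte(max(s), 74)
  ps <- snp_params(50, 10, c(1, 1))
  s2 <- sample_density(ps, 500, seed = 4, truncation = c(20, 74))
  expect_true(all(s2 >= 20 & s2 <= 74))
  expect_error(sample_density(pn, 10, seed = 1, truncation = c(500, 501)),
               "negligible")
})

test_that("SNP sampling matches the analytic CDF (KS oracle)", {
  p <- snp_params(0, 1, c(1, 1))
  s <- sort(sample_density(p, 1e5, seed = 31))
  ks <- max(abs(seq_along(s) / length(s) - snp_cdf(s, p)))
  expect_lt(ks, 0.01)
})

test_that("parameter serialization round-trips", {
  for (p in list(normal_params(46, 9), snp_params(67, 7, c(1, -0.3, 0.2)))) {
    expect_equal(params_from_list(params_to_list(p)), p)
  }
  expect_error(snp_params(0, 1, c(2, 1)), "a_0")
  expect_error(snp_params(0, 1, c(1, 1, 1, 1, 1)), "degree")
})
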