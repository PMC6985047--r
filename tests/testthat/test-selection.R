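test_that("delta_aic is the plain AIC difference", {
  expect_equal(delta_aic(21947.02, 21657.60), 289.42)
  expect_equal(delta_aic(1328.06, 1318.02), 10.04)
  expect_equal(delta_aic(100, 100), 0)
})

test_that("verdicts follow the delta-AIC thresholds", {
  expect_identical(verdict_from_delta(289.42), "substantial_mixture")
  expect_identical(verdict_from_delta(10.04), "supported_mixture")
  expect_identical(verdict_from_delta(10.6), "substantial_mixture")
  expect_identical(verdict_from_delta(10), "supported_mixture")
  expect_identical(verdict_from_delta(4), "supported_mixture")
  expect_identical(verdict_from_delta(7.92), "supported_mixture")
  expect_identical(verdict_from_delta(3.99), "inconclusive")
  expect_identical(verdict_from_delta(0), "inconclusive")
  expect_identical(verdict_from_delta(-3), "favors_single")
  # monotone: larger delta never moves away from the mixture
  ranks <- c(favors_single = 1, inconclusive = 2, supported_mixture = 3,
             substantial_mixture = 4)
  d <- seq(-20, 30, by = 0.5)
  expect_true(all(diff(ranks[verdict_from_delta(d)]) >= 0))
})

test_that("find_modes locates analytic modes", {
  expect_equal(round(find_modes(normal_params(46, 9))), 46)
  mix <- mixture_params(normal_params(45, 5), normal_params(65, 5), 0.5)
  expect_equal(round(find_modes(mix)), c(45, 65))
  # well-separated: modes agree with component means within 0.5 year
  mix2 <- mixture_params(normal_params(44, 4), normal_params(66, 4), 0.7)
  expect_equal(find_modes(mix2), c(44, 66), tolerance = 0.5 / 44)
})

test_that("find_modes falls back to component modes for merged peaks", {
  mix <- mixture_params(normal_params(50, 10), normal_params(55, 10), 0.5)
  expect_warning(m <- find_modes(mix), "unimodal")
  expect_equal(m, c(50, 55), tolerance = 1e-6)
})

test_that("run_tournament discriminates bimodal from unimodal data", {
  x <- make_bimodal_ages(2000, seed = 42, w = 0.6, m1 = 45, s1 = 9, m2 = 65, s2 = 7)
  cmp <- run_tournament(x, degree = 2, config = fast_config())
  expect_identical(cmp$verdict, "substantial_mixture")
  expect_gt(cmp$delta_aic, 10)
  expect_identical(cmp$top_single,
                   cmp$fits[[which.min(c(cmp$fits$single_normal$aic,
                                         cmp$fits$single_snp$aic))]])
  cmp2 <- run_tournament(x, degree = 2, config = fast_config())
  expect_equal(cmp$delta_aic, cmp2$delta_aic)
})

test_that("summarize_stratum produces a consistent table row", {
  x <- make_bimodal_ages(1500, seed = 6, w = 0.5, m1 = 45, s1 = 6, m2 = 65, s2 = 6)
  cmp <- run_tournament(x, degree = 0, config = fast_config())
  s <- summarize_stratum("sym", x, cmp)
  expect_equal(s$n, 1500L)
  expect_equal(s$p_early + s$p_late, 1)
  expect_equal(s$p_early, 0.5, tolerance = 0.06)
  expect_lt(s$mode_early, s$mode_late)
  expect_equal(s$median_age, round(stats::median(x)))
  expect_error(summarize_stratum("empty", numeric(0), cmp), "empty")
})

test_that("median convention: odd count gives the middle value", {
  ages <- c(40, 41, 43, 44, 45, 47, 48, 49, 50, 52, 50)
  x <- make_bimodal_ages(600, seed = 9)
  cmp <- run_tournament(x, degree = 0, config = fast_config())
  s <- summarize_stratum("odd", ages, cmp)
  expect_equal(s$median_age, sort(ages)[6])
})

test_that("density_curve is a normalized, symmetric-faithful KDE", {
  x <- withr::with_seed(12, stats::rnorm(500, 50, 5))
  xs <- c(x, 100 - x)  # exactly symmetric about 50
  cur <- density_curve(xs, grid = c(20, 80, 0.25))
  expect_true(all(cur$density >= 0))
  rev_d <- rev(cur$density)
  expect_equal(cur$density, rev_d, tolerance = 1e-9)
  integral <- sum(diff(cur$age_grid) *
                  (utils::head(cur$density, -1) + utils::tail(cur$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 0.05)
  expect_error(density_curve(rep(50, 10)), "variance")
  expect_error(density_curve(c(1, 2)), "n >= 5")
})

test_that("density_curve finds two peaks in large bimodal samples", {
  x <- make_bimodal_ages(8000, seed = 3, w = 0.5, m1 = 45, s1 = 6, m2 = 65, s2 = 6)
  cur <- density_curve(x, grid = c(25, 85, 0.1))
  d <- cur$density
  n <- length(d)
  peaks <- which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
  peaks <- peaks[d[peaks] > 0.2 * max(d)]
  expect_equal(length(peaks), 2L)
  expect_equal(cur$age_grid[peaks], c(45, 65), tolerance = 2 / 45)
})
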