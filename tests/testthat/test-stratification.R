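test_that("ER categories partition [0,100] with nested very-high flag", {
  er <- c(0, 0.5, 0.99, 1, 5, 9.99, 10, 39.9, 40, 79.9, 80, 94.9, 95, 96, 100)
  res <- assign_er_category(er)
  expect_identical(as.character(res$category),
                   c("negative", "negative", "negative", "borderline",
                     "borderline", "borderline", "low", "low", "intermediate",
                     "intermediate", "high", "high", "high", "high", "high"))
  expect_identical(res$very_high, er >= 95)
  # every very-high case is high: the >=95% group nests inside >=80%
  expect_true(all(res$category[res$very_high] == "high"))
  # exhaustive partition: each value maps to exactly one primary category
  grid <- seq(0, 100, by = 0.25)
  expect_false(anyNA(assign_er_category(grid)$category))
  expect_error(assign_er_category(c(50, 101)), "\\[0, 100\\]")
})

test_that("clinical ER cut points are closed at the boundary", {
  expect_identical(as.character(assign_clinical_er(5, 1)), "positive")
  expect_identical(as.character(assign_clinical_er(5, 10)), "negative")
  expect_identical(as.character(assign_clinical_er(10, 10)), "positive")
  expect_identical(as.character(assign_clinical_er(0.5, 1)), "negative")
  expect_error(assign_clinical_er(50, 5), "cutpoint")
})

test_that("ESR1 standardization yields mean 0, variance 1, order preserved", {
  z <- standardize_esr1(c(1, 2, 3))
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(stats::var(z), 1, tolerance = 1e-9)
  x <- withr::with_seed(22, stats::rnorm(1e4, 5, 2))
  z2 <- standardize_esr1(x)
  expect_equal(mean(z2), 0, tolerance = 1e-9)
  expect_equal(stats::var(z2), 1, tolerance = 1e-9)
  expect_identical(order(x), order(z2))
  expect_error(standardize_esr1(rep(3, 10)), "spread")
})

test_that("quartile sizes differ by <= 1 with remainder going to the top", {
  q <- assign_quartiles(withr::with_seed(1, stats::rnorm(1965)))
  expect_identical(as.integer(table(q)), c(491L, 491L, 491L, 492L))
  q8 <- assign_quartiles(c(5, 1, 7, 3, 8, 2, 6, 4))
  expect_identical(as.integer(table(q8)), rep(2L, 4L))
  expect_identical(as.character(q8[2]), "Q1")  # value 1 is lowest
  expect_identical(as.character(q8[5]), "Q4")  # value 8 is highest
  # monotone in value
  v <- withr::with_seed(2, stats::runif(103))
  qq <- assign_quartiles(v)
  expect_true(all(diff(as.integer(qq[order(v)])) >= 0))
  expect_true(diff(range(table(qq))) <= 1)
  expect_warning(qt <- assign_quartiles(rep(1, 8)), "ties")
  expect_identical(as.integer(table(qt)), rep(2L, 4L))
})

test_that("filter_pam50 drops Normal-like and missing, normalizes aliases, idempotent", {
  rec <- data.frame(
    age = 40 + 1:6,
    pam50 = c("LumA", "Luminal B", "HER2-enriched", "Basal-like", "Normal", NA))
  suppressMessages({
    kept <- filter_pam50(rec)
    expect_identical(as.character(kept$pam50), c("LumA", "LumB", "Her2", "Basal"))
    expect_equal(nrow(kept), 4L)
    expect_identical(filter_pam50(kept)$pam50, kept$pam50)
    expect_warning(filter_pam50(data.frame(pam50 = c("Normal", "normal-like"))),
                   "remain")
  })
})

test_that("tumor-characteristic strata use configurable cuts", {
  rec <- data.frame(grade = c("1", "2", "3", "x", NA),
                    tumor_size = c(1.5, 2, 2.5, NA, 0.8),
                    node_status = c(0, 1, 3, NA, 2))
  expect_warning(g <- assign_tumor_characteristic_strata(rec, "grade"), "unknown")
  expect_identical(as.character(g), c("grade_1", "grade_2", "grade_3", NA, NA))
  s <- assign_tumor_characteristic_strata(rec, "size", size_cut = 2)
  expect_identical(as.character(s), c("small", "large", "large", NA, "small"))
  nd <- assign_tumor_characteristic_strata(rec, "nodes")
  expect_identical(as.character(nd), c("negative", "1", "2+", NA, "2+"))
})
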