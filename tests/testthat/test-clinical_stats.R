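test_that("diagnostic performance computes the printed-percent ratios", {
  expect_equal(diagnostic_performance(9, 0, 10, 1),
               c(sensitivity = 90, specificity = 100, accuracy = 95))
  expect_equal(diagnostic_performance(10, 0, 10, 0),
               c(sensitivity = 100, specificity = 100, accuracy = 100))
  expect_equal(diagnostic_performance(0, 0, 5, 5),
               c(sensitivity = 0, specificity = 100, accuracy = 50))
  expect_error(diagnostic_performance(0, 3, 0, 0), "margin")
})

test_that("accuracy equals the prevalence-weighted mean of sensitivity and specificity", {
  for (seed in 1:5) {
    v <- withr::with_seed(seed, sample(1:30, 4))
    perf <- diagnostic_performance(v[1], v[2], v[3], v[4])
    prev <- (v[1] + v[4]) / sum(v)
    sens <- 100 * v[1] / (v[1] + v[4]); spec <- 100 * v[3] / (v[2] + v[3])
    expect_equal(unname(perf["accuracy"]),
                 retinexmed:::round_half_away(prev * sens + (1 - prev) * spec, 2))
  }
})

test_that("chi-square homogeneity matches hand-computed statistics", {
  flat <- rbind(c(10, 20, 5), c(10, 20, 5))
  r <- chi_square_homogeneity(flat)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- chi_square_homogeneity(rbind(c(31, 3, 1), c(16, 14, 5)))
  expect_equal(r2$statistic, 14.5715, tolerance = 1e-4)
  expect_equal(r2$df, 2)
  expect_equal(r2$p_value, exp(-r2$statistic / 2), tolerance = 1e-10)
  r3 <- chi_square_homogeneity(rbind(c(10, 0), c(0, 10)))
  expect_equal(r3$statistic, 20)   # all expected counts are 5
  expect_equal(r3$df, 1)
  expect_error(chi_square_homogeneity(rbind(c(1, 0), c(2, 0))), "positive")
})

test_that("chi-square statistic is invariant under row and column permutation", {
  tab <- rbind(c(31, 3, 1), c(16, 14, 5))
  base <- chi_square_homogeneity(tab)$statistic
  expect_equal(chi_square_homogeneity(tab[2:1, ])$statistic, base)
  expect_equal(chi_square_homogeneity(tab[, c(3, 1, 2)])$statistic, base)
})

test_that("fisher exact p agrees with full hypergeometric enumeration", {
  cases <- list(c(2, 33, 4, 31), c(10, 0, 0, 10), c(5, 5, 5, 5), c(1, 9, 7, 3))
  for (v in cases) {
    expect_equal(fisher_exact_2x2(rbind(v[1:2], v[3:4])),
                 oracle_fisher(v[1], v[2], v[3], v[4]), tolerance = 1e-10)
  }
  expect_equal(fisher_exact_2x2(rbind(c(2, 33), c(4, 31))), 0.673, tolerance = 1e-3)
  expect_equal(fisher_exact_2x2(rbind(c(6, 4), c(6, 4))), 1)
  expect_equal(fisher_exact_2x2(rbind(c(10, 0), c(0, 10))),
               2 / choose(20, 10), tolerance = 1e-12)
  expect_error(fisher_exact_2x2(matrix(1, 2, 3)), "2 x 2")
})

test_that("fisher p lies in (0,1] and is invariant to swapping rows", {
  for (seed in 1:5) {
    v <- withr::with_seed(seed, sample(0:20, 4, TRUE))
    if (sum(v) == 0) v <- v + 1
    p1 <- fisher_exact_2x2(rbind(v[1:2], v[3:4]))
    p2 <- fisher_exact_2x2(rbind(v[3:4], v[1:2]))
    expect_gt(p1, 0); expect_lte(p1, 1)
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("counts recovered from printed percentages are exact and unique", {
  expect_identical(counts_from_percentages(c(88.57, 8.57, 2.86), 35),
                   c(31L, 3L, 1L))
  expect_identical(counts_from_percentages(c(45.71, 40.00, 14.29), 35),
                   c(16L, 14L, 5L))
  expect_identical(counts_from_percentages(c(50, 50), 10), c(5L, 5L))
  expect_error(counts_from_percentages(c(33.33, 33.33, 33.33), 4), "no ")
})

test_that("percentage printing and count recovery are mutually inverse", {
  for (seed in 1:10) {
    n <- withr::with_seed(seed, sample(20:200, 1))
    parts <- withr::with_seed(seed + 1, {
      cuts <- sort(sample(0:n, 2, replace = TRUE))
      c(cuts[1], cuts[2] - cuts[1], n - cuts[2])
    })
    pct <- retinexmed:::round_half_away(100 * parts / n, 2)
    got <- tryCatch(counts_from_percentages(pct, n), error = function(e) e)
    if (inherits(got, "error")) {
      expect_match(conditionMessage(got), "ambiguous")  # only failure allowed
    } else {
      expect_identical(got, as.integer(parts))
    }
  }
})

test_that("welch t wrapper reports the expected inference on shifted samples", {
  x <- withr::with_seed(1, rnorm(30)); y <- withr::with_seed(2, rnorm(30, 2))
  r <- welch_t(x, y)
  expect_lt(r$p_value, 1e-6)
  expect_equal(welch_t(x, x)$p_value, 1)
})
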