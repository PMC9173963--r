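test_that("threshold function keeps near-unity ratios as printed, inverts in classic mode", {
  expect_equal(threshold_ratio(1.05, T = 0.1), 1.05)
  expect_equal(threshold_ratio(1.5, T = 0.1), 1)
  expect_equal(threshold_ratio(1.05, T = 0.1, mode = "classic"), 1)
  expect_equal(threshold_ratio(1.5, T = 0.1, mode = "classic"), 1.5)
  expect_error(threshold_ratio(-1, T = 0.1), "> 0")
  expect_error(threshold_ratio(1, T = 1.5), "in \\(0, 1\\)")
})

test_that("path_log_ratio matches a hand-summed term-by-term evaluation", {
  px <- matrix(c(10, 20, 40, 44, 5, 80, 3, 120, 60), 3, 3)
  path <- rbind(c(1, 1), c(2, 1), c(2, 2), c(3, 3))
  # hand evaluation: sum of thresholded log ratios of successive pixels
  vals <- log(px[cbind(path[, 1], path[, 2])] + 1e-6)
  d <- diff(vals)
  keep <- exp(d) >= 1 - 0.3 & exp(d) <= 1 + 0.3
  expect_equal(path_log_ratio(px, path, T = 0.3), sum(d[keep]))
  # constant image: every ratio is 1, log 1 = 0
  expect_equal(path_log_ratio(matrix(5, 3, 3), path, T = 0.3), 0)
  # two-pixel path with values (1, e) and a wide gate gives exactly 1
  two <- matrix(c(1, exp(1), 1, 1), 2, 2)
  expect_equal(path_log_ratio(two, rbind(c(1, 1), c(2, 1)), T = 0.99,
                              mode = "classic"),
               1, tolerance = 1e-5)
  expect_error(path_log_ratio(px, rbind(c(1, 1), c(4, 1))), "bounds")
})

test_that("random-path output is seeded-deterministic, scale-invariant, zero on constants", {
  img <- rand_img(12, 10, seed = 21, peak = 200) + 5
  a <- random_path_retinex(img, n_paths = 3, seed = 42)
  b <- random_path_retinex(img, n_paths = 3, seed = 42)
  expect_identical(a, b)
  c2 <- random_path_retinex(3.7 * img, n_paths = 3, seed = 42)
  expect_equal(a, c2, tolerance = 1e-6)
  expect_equal(random_path_retinex(matrix(9, 8, 8), n_paths = 2, seed = 1),
               matrix(0, 8, 8))
  expect_error(random_path_retinex(img, n_paths = 0), ">= 1")
})

test_that("initial spiral offset follows the floor-log2 rule", {
  expect_equal(conversion_operator(256, 256), 128)
  expect_equal(conversion_operator(512, 256), 128)
  expect_equal(conversion_operator(100, 100), 32)
  expect_error(conversion_operator(1, 100), ">= 2")
})

test_that("spiral offsets start at D, rotate clockwise, and halve until < 1", {
  offs <- retinexmed:::spiral_offsets(128)
  expect_equal(nrow(offs), 8)  # 128, 64, ..., 1: seven halvings after the start
  expect_equal(apply(abs(offs), 1, max), c(128, 64, 32, 16, 8, 4, 2, 1))
  expect_equal(offs[1, ], c(128, 0), ignore_attr = TRUE)
  expect_equal(offs[2, ], c(0, -64), ignore_attr = TRUE)   # 90 degrees clockwise
  expect_equal(offs[3, ], c(-32, 0), ignore_attr = TRUE)
})

test_that("Frankle-McCann is constant on constants, bounded by the reset ceiling", {
  expect_equal(frankle_mccann(matrix(7, 16, 16)), matrix(0, 16, 16))
  img <- rand_img(32, 32, seed = 5, peak = 250) + 1
  out <- frankle_mccann(img)
  expect_identical(dim(out), dim(img))
  expect_lte(max(out), 1e-12)  # estimates never exceed the log maximum
  expect_equal(out, frankle_mccann(0.25 * img), tolerance = 1e-6)
})

test_that("McCann99 pyramid reduces by 2x2 block means and respects the clamp", {
  x <- matrix(as.numeric(1:16), 4, 4)
  red <- retinexmed:::pyramid_reduce(x)
  expect_equal(red, rbind(c(mean(x[1:2, 1:2]), mean(x[1:2, 3:4])),
                          c(mean(x[3:4, 1:2]), mean(x[3:4, 3:4]))))
  expect_equal(mccann99(matrix(7, 8, 8)), matrix(0, 8, 8))
  img <- rand_img(16, 16, seed = 6, peak = 250) + 1
  out <- mccann99(img)
  expect_identical(dim(out), dim(img))
  expect_lte(max(out), 1e-12)
  expect_equal(out, mccann99(5 * img), tolerance = 1e-6)
  expect_error(mccann99(matrix(1, 3, 8)), "4 x 4")
})
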