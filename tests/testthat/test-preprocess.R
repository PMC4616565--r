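test_that("median filter matches an explicit neighborhood-sort oracle", {
  set.seed(7)
  for (rep in 1:5) {
    f <- matrix(sample(0:50, 36, replace = TRUE), 6, 6)
    expect_equal(median_filter_3x3(f), oracle_median_3x3(f))
  }
  # degenerate shapes fall back to the available neighborhood
  rowimg <- matrix(c(5, 1, 9, 2, 7), 1, 5)
  expect_equal(median_filter_3x3(rowimg), oracle_median_3x3(rowimg))
  expect_equal(median_filter_3x3(matrix(3, 1, 1)), matrix(3, 1, 1))
})

test_that("median filter preserves constants and rejects impulses", {
  expect_equal(median_filter_3x3(matrix(4.2, 5, 5)), matrix(4.2, 5, 5))
  f <- matrix(0, 7, 7); f[4, 4] <- 100
  expect_true(all(median_filter_3x3(f) == 0))
})

test_that("median filter stabilizes binary structure and invents no values", {
  # a coherent binary structure is a fixed point of the filter
  block <- matrix(0, 12, 12); block[4:9, 3:10] <- 1
  once <- median_filter_3x3(block)
  expect_equal(median_filter_3x3(once), once)
  # repeated filtering of binary noise reaches a fixed point quickly
  set.seed(8)
  b <- matrix(rbinom(100, 1, 0.4), 10, 10)
  for (i in 1:10) {
    nxt <- median_filter_3x3(b)
    if (identical(nxt, b)) break
    b <- nxt
  }
  expect_identical(median_filter_3x3(b), b)
  # output values always come from the input frame
  f <- matrix(sample(c(1, 3, 8, 20), 64, replace = TRUE), 8, 8)
  expect_true(all(median_filter_3x3(f) %in% f))
})

test_that("gaussian kernel reproduces the printed sigma=1 width=5 mask", {
  k <- gaussian_kernel(1, 5)
  expect_lt(abs(k$weights[3] - 0.4), 0.005)
  expect_lt(abs(k$weights[2] - 0.24), 0.005)
  expect_lt(abs(k$weights[1] - 0.054), 0.0005)
  expect_equal(k$weights, rev(k$weights))
})

test_that("gaussian kernel equals the closed form at any sigma", {
  k <- gaussian_kernel(2, 5)
  want <- exp(-(-2:2)^2 / (2 * 4)) / (sqrt(2 * pi) * 2)
  expect_equal(k$weights, want)
  expect_error(gaussian_kernel(0, 5), "positive")
  expect_error(gaussian_kernel(1, 4), "odd")
})

test_that("temporal smoothing preserves constants and curtails at the ends", {
  s <- frame_stack(array(rep(runif(16), 6), c(4, 4, 6)))
  sm <- temporal_smooth(s, gaussian_kernel(1, 5))
  expect_equal(sm$pixels, s$pixels, tolerance = 1e-12)
  one <- frame_stack(matrix(runif(9), 3, 3))
  expect_equal(temporal_smooth(one, gaussian_kernel(1, 5))$pixels, one$pixels)
})

test_that("temporal impulse response equals the renormalized mask", {
  px <- array(0, c(2, 2, 9)); px[1, 1, 5] <- 3
  sm <- temporal_smooth(frame_stack(px), gaussian_kernel(1, 5))
  w <- gaussian_kernel(1, 5)$weights
  expect_equal(sm$pixels[1, 1, 3:7], 3 * rev(w) / sum(w))
  expect_true(all(sm$pixels[2, 2, ] == 0))
})

test_that("temporal smoothing is linear", {
  set.seed(9)
  x <- array(runif(3 * 3 * 8), c(3, 3, 8))
  y <- array(runif(3 * 3 * 8), c(3, 3, 8))
  k <- gaussian_kernel(1.3, 5)
  lhs <- temporal_smooth(frame_stack(2 * x + 5 * y), k)$pixels
  rhs <- 2 * temporal_smooth(frame_stack(x), k)$pixels +
         5 * temporal_smooth(frame_stack(y), k)$pixels
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("background subtraction uses frame 1 and clamps negatives", {
  px <- array(runif(3 * 3 * 4), c(3, 3, 4))
  px[, , 1] <- 0
  expect_equal(subtract_background(frame_stack(px))$pixels, px)
  same <- array(rep(px[, , 2], 4), c(3, 3, 4))
  expect_true(all(subtract_background(frame_stack(same))$pixels == 0))
  two <- array(c(rep(5, 4), rep(3, 4)), c(2, 2, 2))
  out <- subtract_background(frame_stack(two))
  expect_true(all(out$pixels == 0))   # 3 - 5 clamps to 0
})

test_that("contrast stretch maps the sequence range onto [0, 1]", {
  px <- array(10, c(2, 2, 3)); px[1, 1, 2] <- 20; px[2, 2, 3] <- 15
  out <- contrast_stretch(frame_stack(px))
  expect_equal(out$pixels[2, 2, 3], 0.5)
  expect_equal(min(out$pixels), 0)
  expect_equal(max(out$pixels), 1)
  expect_error(contrast_stretch(frame_stack(array(7, c(2, 2, 2)))),
               "degenerate")
})

test_that("contrast stretch is idempotent and order-preserving", {
  set.seed(10)
  px <- array(runif(4 * 4 * 5, 3, 9), c(4, 4, 5))
  once <- contrast_stretch(frame_stack(px))
  twice <- contrast_stretch(once)
  expect_equal(twice$pixels, once$pixels, tolerance = 1e-12)
  expect_equal(order(px), order(once$pixels))
})

test_that("preprocess_red composes the four stages in order", {
  fx <- small_fixture()
  red <- split_channels(fx$stack, "auto")$red
  rec <- preprocess_red(red, sigma = 1, width = 5)
  expect_named(rec$stages, c("median", "background", "temporal", "stretch"))

  px <- red$pixels
  for (f in seq_len(dim(px)[3])) px[, , f] <- median_filter_3x3(px[, , f])
  manual <- contrast_stretch(
    temporal_smooth(subtract_background(frame_stack(px)),
                    gaussian_kernel(1, 5)))
  expect_equal(rec$stack$pixels, manual$pixels)
})

test_that("the full chain raises blob-to-background contrast on a fixture", {
  fx <- small_fixture()
  red <- split_channels(fx$stack, "auto")$red
  rec <- preprocess_red(red)
  blob <- fx$truth$injection_mask
  outside <- !fx$spec$cell_geometry$cell
  snr <- function(stk) {
    frame <- stk$pixels[, , 2]   # first post-conversion frame
    mean(frame[blob]) / max(stats::sd(frame[outside]), 1e-12)
  }
  expect_gt(snr(rec$stack), snr(red))
})
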