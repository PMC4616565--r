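test_that("mean and SD images match the brute-force definition", {
  set.seed(21)
  px <- array(runif(5 * 5 * 7), c(5, 5, 7))
  m <- build_stat_model(frame_stack(px))
  want <- oracle_stat_model(px)
  expect_equal(m$mean_image, want$mean, tolerance = 1e-12)
  expect_equal(m$sd_image, want$sd, tolerance = 1e-12)
  expect_equal(m$n_frames, 7L)
})

test_that("population divisor and degenerate stacks behave as defined", {
  const <- build_stat_model(frame_stack(array(3.5, c(4, 4, 6))))
  expect_true(all(const$mean_image == 3.5))
  expect_true(all(const$sd_image == 0))

  two <- build_stat_model(frame_stack(array(c(0, 1), c(1, 1, 2))))
  expect_equal(two$mean_image[1, 1], 0.5)
  expect_equal(two$sd_image[1, 1], 0.5)   # sqrt(((0-.5)^2+(1-.5)^2)/2)

  single <- build_stat_model(frame_stack(matrix(runif(9), 3, 3)))
  expect_true(all(single$sd_image == 0))
})

test_that("model is shift- and scale-equivariant", {
  set.seed(22)
  px <- array(runif(4 * 6 * 5), c(4, 6, 5))
  base <- build_stat_model(frame_stack(px))
  shifted <- build_stat_model(frame_stack(px + 2.5))
  expect_equal(shifted$mean_image, base$mean_image + 2.5)
  expect_equal(shifted$sd_image, base$sd_image)
  scaled <- build_stat_model(frame_stack(px * 3))
  expect_equal(scaled$mean_image, base$mean_image * 3)
  expect_equal(scaled$sd_image, base$sd_image * 3)
})

test_that("S^2 + M^2 equals the temporal mean of I^2", {
  set.seed(23)
  px <- array(runif(3 * 3 * 9), c(3, 3, 9))
  m <- build_stat_model(frame_stack(px))
  mean_sq <- apply(px^2, c(1, 2), mean)
  expect_equal(m$sd_image^2 + m$mean_image^2, mean_sq, tolerance = 1e-9)
})

test_that("mean and SD images export as readable TIFFs", {
  set.seed(24)
  m <- build_stat_model(frame_stack(array(runif(4 * 4 * 3), c(4, 4, 3))))
  p1 <- withr::local_tempfile(fileext = ".tif")
  p2 <- withr::local_tempfile(fileext = ".tif")
  export_stat_model(m, p1, p2)
  r <- read_stack(p1)$pixels[, , 1]
  unit <- (m$mean_image - min(m$mean_image)) / diff(range(m$mean_image))
  expect_equal(r, unit, tolerance = 1e-6)
})
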