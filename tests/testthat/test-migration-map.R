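# Helper: a stack whose SD image is exactly `s` (frames at m-s and m+s).
stack_with_sd <- function(s, m = 1) {
  frame_stack(array(c(m - s, m + s), c(dim(s), 2)))
}

test_that("the SD threshold is strict: a uniform SD image gives no cell", {
  model <- build_stat_model(stack_with_sd(matrix(0.5, 10, 10)))
  expect_message(mask <- segment_cell(model), "empty mask")
  expect_false(any(mask$mask))
  expect_equal(mask$threshold, 0.5)   # S-bar + 0
})

test_that("a block of high SD survives thresholding and opening", {
  s <- matrix(0, 40, 40); s[11:30, 11:30] <- 1
  model <- build_stat_model(stack_with_sd(s))
  mask <- segment_cell(model, opening_radius = 1)
  expect_equal(unname(mask$mask), s == 1)
})

test_that("opening removes isolated speckles but keeps the block", {
  s <- matrix(0, 40, 40); s[11:30, 11:30] <- 1
  s[2, 2] <- 1; s[5, 35] <- 1; s[38, 3] <- 1
  mask <- segment_cell(build_stat_model(stack_with_sd(s)), opening_radius = 1)
  expect_false(mask$mask[2, 2] || mask$mask[5, 35] || mask$mask[38, 3])
  expect_true(all(mask$mask[12:29, 12:29]))
})

test_that("constructed trajectories get their expected classes", {
  nf <- 20
  px <- array(0, c(2, 3, nf))
  px[1, 1, ] <- seq(0.9, 0.1, length.out = nf)   # bright but dims
  px[1, 2, ] <- seq(0.1, 0.9, length.out = nf)   # dim becoming bright
  px[1, 3, ] <- 1                                # pinned at saturation
  px[2, 1, ] <- 0.02                             # dark, no variation
  px[2, 2, ] <- rep(c(0.4, 0.6), nf / 2)         # varying, no endpoint trend
  mask <- manual_cell_mask(matrix(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), 2, 3),
                           threshold = 0.05)
  map <- classify_pixels(frame_stack(px), mask)
  expect_equal(map$labels[1, 1], "injection")
  expect_equal(map$labels[1, 2], "diffusion_toward")
  expect_equal(map$labels[1, 3], "accumulation")
  expect_equal(map$labels[2, 1], "background")   # in-cell but dark
  expect_equal(map$labels[2, 2], "unclassified")
  expect_equal(map$labels[2, 3], "background")   # outside the mask
})

test_that("every pixel gets exactly one label and counts add up", {
  fx <- small_fixture()
  pr <- preprocess_red(split_channels(fx$stack, "auto")$red)
  mask <- segment_cell(build_stat_model(pr$stack))
  map <- classify_pixels(pr$stack, mask)
  expect_true(all(map$labels %in% migration_classes()))
  expect_equal(sum(map$counts), prod(dim(map$labels)))
})

test_that("ratio/quantile rules are scale-free", {
  fx <- small_fixture()
  pr <- preprocess_red(split_channels(fx$stack, "auto")$red)
  mask <- segment_cell(build_stat_model(pr$stack))
  # disable the absolute-threshold rules, keep the scale-free ones
  p <- map_params(sat_threshold = 2, bright_floor = 0, dark_sd_factor = 0)
  m1 <- classify_pixels(pr$stack, mask, p)
  scaled <- frame_stack(pr$stack$pixels * 0.4)
  m2 <- classify_pixels(scaled, mask, p)
  expect_identical(m1$labels, m2$labels)
})

test_that("injection point is the centroid of the largest component", {
  lab <- matrix("background", 30, 40)
  lab[11:15, 21:25] <- "injection"
  map <- structure(list(labels = lab), class = "migration_map")
  expect_equal(unname(injection_point(map)), c(13L, 23L))

  lab2 <- matrix("background", 30, 40)
  lab2[1:6, 1:5] <- "injection"          # 30 px component
  lab2[25:29, 35] <- "injection"         # 5 px component
  map2 <- structure(list(labels = lab2), class = "migration_map")
  expect_equal(unname(injection_point(map2)), c(4L, 3L))

  empty <- structure(list(labels = matrix("background", 5, 5)),
                     class = "migration_map")
  expect_error(injection_point(empty), "no injection")
})

test_that("the estimated conversion point recovers the fixture truth", {
  fx <- small_fixture()
  pr <- preprocess_red(split_channels(fx$stack, "auto")$red)
  mask <- segment_cell(build_stat_model(pr$stack))
  map <- classify_pixels(pr$stack, mask)
  expect_false(is.null(map$injection_point))
  err <- sqrt(sum((map$injection_point - fx$spec$injection_center)^2))
  expect_lte(err, fx$spec$injection_radius)
  # and the reported point is itself injection-labeled
  expect_equal(map$labels[map$injection_point[1], map$injection_point[2]],
               "injection")
})

test_that("migration map exports with the five-level key and counts", {
  fx <- small_fixture()
  pr <- preprocess_red(split_channels(fx$stack, "auto")$red)
  mask <- segment_cell(build_stat_model(pr$stack))
  map <- classify_pixels(pr$stack, mask)
  img <- withr::local_tempfile(fileext = ".tif")
  csv <- withr::local_tempfile(fileext = ".csv")
  export_migration_map(map, img, csv)
  counts <- utils::read.csv(csv)
  expect_equal(counts$class, migration_classes())
  expect_equal(sum(counts$pixels), prod(dim(map$labels)))
  expect_true(file.exists(img) && file.size(img) > 0)
})
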