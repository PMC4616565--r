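test_that("region growing respects the pixel cap on a uniform image", {
  roi <- grow_region(matrix(1, 40, 40), c(20, 20))
  expect_equal(nrow(roi$members), 250L)
  expect_equal(roi$equivalence, "mean_intensity")
})

test_that("zero tolerance around a unique seed keeps only the seed", {
  img <- matrix(0.1, 10, 10); img[5, 5] <- 0.9
  roi <- grow_region(img, c(5, 5), tolerance = 0, cap = 250)
  expect_equal(roi$members, matrix(c(5L, 5L), 1, 2))
})

test_that("growing is deterministic and nested in tolerance", {
  set.seed(31)
  img <- median_filter_3x3(matrix(runif(900), 30, 30))  # smooth-ish field
  a <- grow_region(img, c(15, 15), tolerance = 0.05, cap = 200)
  b <- grow_region(img, c(15, 15), tolerance = 0.05, cap = 200)
  expect_identical(a$members, b$members)
  wide <- grow_region(img, c(15, 15), tolerance = 0.15, cap = 200)
  key <- function(m) paste(m[, 1], m[, 2])
  expect_true(all(key(a$members) %in% key(wide$members)))
})

test_that("region growing stays in the seeded compartment; fixed disks leak", {
  tc <- two_compartment_image()
  roi <- grow_region(tc$image, c(20, 20), tolerance = 0.2, cap = 250)
  in_disk <- tc$disk[cbind(roi$members[, 1], roi$members[, 2])]
  expect_equal(sum(!in_disk), 0L)            # zero leaked pixels

  fixed <- fixed_area_roi(c(20, 20), radius = 10, shape = dim(tc$image))
  leaked <- sum(!tc$disk[cbind(fixed$members[, 1], fixed$members[, 2])])
  expect_gte(leaked, 1L)
})

test_that("fixed-area ROIs are discrete Euclidean disks", {
  expect_equal(fixed_area_roi(c(5, 5), 0, c(9, 9))$members,
               matrix(c(5L, 5L), 1, 2, dimnames = list(NULL, c("row", "col"))))
  expect_equal(nrow(fixed_area_roi(c(5, 5), 2, c(9, 9))$members), 13L)
  expect_error(fixed_area_roi(c(0, 5), 2, c(9, 9)), "outside")
  expect_error(grow_region(matrix(1, 5, 5), c(6, 3)), "outside")
})

test_that("ROI traces match a per-frame brute-force loop", {
  set.seed(32)
  px <- array(runif(6 * 6 * 7), c(6, 6, 7))
  stack <- frame_stack(px)
  mask <- manual_cell_mask(matrix(rep(c(TRUE, FALSE), 18), 6, 6))
  roi <- grow_region(build_stat_model(stack)$mean_image, c(3, 3),
                     tolerance = 1, cap = 10)
  tr <- track_rois(stack, list(roi), mask)
  expect_equal(tr$roi_traces[[1]], oracle_roi_trace(px, roi$members),
               tolerance = 1e-12)
  flat <- matrix(px, ncol = 7)
  expect_equal(tr$background_trace, colMeans(flat[!as.vector(mask$mask), ]),
               tolerance = 1e-12)
  expect_equal(tr$total_trace, colSums(flat[as.vector(mask$mask), ]),
               tolerance = 1e-12)
})

test_that("a constant region yields a flat trace", {
  px <- array(0.3, c(8, 8, 5))
  mask <- manual_cell_mask(rbind(matrix(TRUE, 4, 8), matrix(FALSE, 4, 8)))
  roi <- fixed_area_roi(c(2, 4), 1, c(8, 8))
  tr <- track_rois(frame_stack(px), list(roi), mask)
  expect_equal(tr$roi_traces[[1]], rep(0.3, 5))
})

test_that("at most ten regions are tracked by default", {
  px <- array(runif(8 * 8 * 3), c(8, 8, 3))
  mask <- manual_cell_mask(rbind(matrix(TRUE, 4, 8), matrix(FALSE, 4, 8)))
  rois <- lapply(1:12, function(i) fixed_area_roi(c(4, 4), 1, c(8, 8)))
  expect_warning(tr <- track_rois(frame_stack(px), rois, mask), "first 10")
  expect_length(tr$roi_traces, 10L)
})

test_that("photobleach percentage is the signed first-to-last drop", {
  expect_equal(photobleach_report(rep(7, 10)), 0)
  expect_equal(photobleach_report(c(4, 6, 8)), -100)  # net gain
  k <- 0.01; total <- 120 * exp(-k * (0:49))
  expect_equal(photobleach_report(total), 100 * (1 - exp(-k * 49)))
  expect_error(photobleach_report(c(0, 1)), "positive")
  expect_error(photobleach_report(5), "at least 2")
})

test_that("bleach correction exactly inverts a global multiplicative decay", {
  set.seed(33)
  base <- runif(30, 0.4, 0.9)          # undecayed ROI signal
  decay <- exp(-0.02 * (0:29))
  tr <- structure(list(
    roi_traces = list(r1 = base * decay),
    background_trace = rep(0.01, 30),
    total_trace = 500 * decay,
    bleach_percent = NA_real_, corrected_traces = NULL,
    frames = 30L, frame_times = NULL), class = "trace_set")
  out <- bleach_correct(tr)
  expect_equal(out$corrected_traces$r1, base, tolerance = 1e-9)

  flat <- tr; flat$total_trace <- rep(500, 30)
  expect_equal(bleach_correct(flat)$corrected_traces$r1, flat$roi_traces$r1)
  bad <- tr; bad$total_trace[5] <- 0
  expect_error(bleach_correct(bad), "positive")
})

test_that("trace export round-trips through CSV and the plot is written", {
  set.seed(34)
  px <- array(runif(8 * 8 * 6), c(8, 8, 6))
  mask <- manual_cell_mask(rbind(matrix(TRUE, 4, 8), matrix(FALSE, 4, 8)))
  tr <- track_rois(frame_stack(px),
                   list(fixed_area_roi(c(3, 3), 1, c(8, 8), name = "site")),
                   mask)
  csv <- withr::local_tempfile(fileext = ".csv")
  export_traces(tr, csv)
  df <- utils::read.csv(csv)
  expect_equal(nrow(df), 6L)
  expect_equal(df$site, unname(tr$roi_traces$site), tolerance = 1e-6)
  expect_equal(df$background, unname(tr$background_trace), tolerance = 1e-6)

  png <- withr::local_tempfile(fileext = ".png")
  plot_traces(tr, png)
  expect_true(file.exists(png) && file.size(png) > 0)
})
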