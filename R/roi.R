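#' Grow a region of interest from a seed by seeded region growing
#'
#' Classic Adams-Bischof growth on the mean image: starting from the seed,
#' the 8-connected boundary of the current region is maintained and the
#' boundary pixel whose intensity is closest to the running region mean is
#' admitted, updating the mean after every admission. Growth stops when the
#' best candidate differs from the region mean by more than `tolerance`
#' (outliers adjacent to the region are thereby bypassed, never admitted)
#' or when the region reaches `cap` pixels. Ties on similarity are broken
#' by the lowest (row, col) in lexicographic order, so the result is
#' deterministic.
#'
#' Growing a region instead of tracking the single clicked pixel protects
#' the measurement from an outlier seed and from single-pixel noise.
#'
#' @param mean_image numeric matrix, the temporal mean image M on which
#'   seeds are placed.
#' @param seed integer (row, col) of the seed pixel.
#' @param tolerance maximum admissible |intensity - region mean|, in the
#'   image's intensity units (default 0.1, suited to unit-scaled data).
#' @param cap maximum region size in pixels (default 250).
#' @param name optional label for the region.
#' @return An `roi`: list with `seed`, `members` (n x 2 matrix of (row, col),
#'   admission order), `equivalence` (`"mean_intensity"`), `tolerance`,
#'   `cap`, `name`.
#' @examples
#' roi <- grow_region(matrix(1, 30, 30), c(15, 15), tolerance = 0.1)
#' nrow(roi$members)  # 250, the default cap
#' @export
grow_region <- function(mean_image, seed, tolerance = 0.1, cap = 250L,
                        name = NULL) {
  if (!is.matrix(mean_image) || !is.numeric(mean_image))
    stop("'mean_image' must be a numeric matrix")
  seed <- as.integer(seed)
  nr <- nrow(mean_image); nc <- ncol(mean_image)
  if (length(seed) != 2L || seed[1] < 1L || seed[1] > nr ||
      seed[2] < 1L || seed[2] > nc)
    stop(sprintf("seed (%s) lies outside the %d x %d image",
                 paste(seed, collapse = ", "), nr, nc))
  if (tolerance < 0) stop("'tolerance' must be >= 0")
  cap <- as.integer(cap)
  if (cap < 1L) stop("'cap' must be >= 1")

  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  in_region <- matrix(FALSE, nr, nc)
  in_cand <- matrix(FALSE, nr, nc)
  members <- matrix(0L, cap, 2L)

  cand_r <- integer(0); cand_c <- integer(0); cand_v <- numeric(0)
  push_neighbors <- function(r, cc) {
    for (k in 1:8) {
      rr <- r + dr[k]; ccc <- cc + dc[k]
      if (rr < 1L || rr > nr || ccc < 1L || ccc > nc) next
      if (in_region[rr, ccc] || in_cand[rr, ccc]) next
      in_cand[rr, ccc] <<- TRUE
      cand_r[length(cand_r) + 1L] <<- rr
      cand_c[length(cand_c) + 1L] <<- ccc
      cand_v[length(cand_v) + 1L] <<- mean_image[rr, ccc]
    }
  }

  in_region[seed[1], seed[2]] <- TRUE
  members[1L, ] <- seed
  n <- 1L
  total <- mean_image[seed[1], seed[2]]
  push_neighbors(seed[1], seed[2])

  while (n < cap && length(cand_r) > 0L) {
    d <- abs(cand_v - total / n)
    best <- order(d, cand_r, cand_c)[1L]
    if (d[best] > tolerance) break
    r <- cand_r[best]; cc <- cand_c[best]
    in_region[r, cc] <- TRUE
    in_cand[r, cc] <- FALSE
    n <- n + 1L
    members[n, ] <- c(r, cc)
    total <- total + cand_v[best]
    cand_r <- cand_r[-best]; cand_c <- cand_c[-best]; cand_v <- cand_v[-best]
    push_neighbors(r, cc)
  }

  structure(
    list(seed = seed, members = members[seq_len(n), , drop = FALSE],
         equivalence = "mean_intensity", tolerance = tolerance, cap = cap,
         name = name),
    class = "roi"
  )
}

#' Fixed-area circular region around a seed
#'
#' The naive comparator to [grow_region()]: the region is simply every
#' pixel within Euclidean distance `radius` of the seed, clipped to the
#' image. Unlike seeded region growing, a fixed disk cannot follow the
#' shape of a small structure and leaks into the surrounding compartment
#' whenever the radius exceeds the structure.
#'
#' @param seed integer (row, col).
#' @param radius disk radius in pixels (>= 0).
#' @param shape integer (rows, cols) image bounds.
#' @param name optional label.
#' @return An `roi` with `equivalence = "distance"`.
#' @export
fixed_area_roi <- function(seed, radius, shape, name = NULL) {
  seed <- as.integer(seed)
  if (length(shape) < 2L) stop("'shape' must give (rows, cols)")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (seed[1] < 1L || seed[1] > nr || seed[2] < 1L || seed[2] > nc)
    stop(sprintf("seed (%s) lies outside the %d x %d image",
                 paste(seed, collapse = ", "), nr, nc))
  if (radius < 0) stop("'radius' must be >= 0")
  rr <- max(1L, seed[1] - ceiling(radius)):min(nr, seed[1] + ceiling(radius))
  cc <- max(1L, seed[2] - ceiling(radius)):min(nc, seed[2] + ceiling(radius))
  grid <- expand.grid(row = rr, col = cc)
  keep <- (grid$row - seed[1])^2 + (grid$col - seed[2])^2 <= radius^2
  members <- as.matrix(grid[keep, c("row", "col"), drop = FALSE])
  members <- members[order(members[, 1], members[, 2]), , drop = FALSE]
  dimnames(members) <- list(NULL, c("row", "col"))
  structure(
    list(seed = seed, members = members, equivalence = "distance",
         tolerance = radius, cap = nrow(members), name = name),
    class = "roi"
  )
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("roi%s: %d pixel(s), seed (%d, %d), equivalence %s\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$members), x$seed[1], x$seed[2], x$equivalence))
  invisible(x)
}

#' Track mean fluorescence of ROIs, background and total over time
#'
#' For every frame, computes the mean intensity over each ROI's member
#' pixels, the mean over all pixels outside the cell mask (the background
#' trace), and the sum over all in-mask pixels (the total cellular
#' fluorescence trace, used to detect and correct photobleaching). The
#' photobleach percentage of the total trace is reported when the trace
#' starts above zero.
#'
#' @param stack a [frame_stack()] (normally the preprocessed red channel).
#' @param rois list of [grow_region()] / [fixed_area_roi()] objects (or a
#'   single `roi`). More than `max_rois` regions triggers a warning and
#'   only the first `max_rois` are tracked.
#' @param mask a [segment_cell()] result.
#' @param max_rois maximum number of tracked regions (default 10).
#' @return A `trace_set`: list with `roi_traces` (named list of per-frame
#'   means), `background_trace`, `total_trace`, `bleach_percent` (`NA` if
#'   the total trace starts at zero), `corrected_traces` (`NULL` until
#'   [bleach_correct()] is applied), `frames` and `frame_times`.
#' @export
track_rois <- function(stack, rois, mask, max_rois = 10L) {
  stopifnot(inherits(stack, "frame_stack"), inherits(mask, "cell_mask"))
  if (inherits(rois, "roi")) rois <- list(rois)
  if (length(rois) == 0L) stop("no ROIs supplied")
  if (length(rois) > max_rois) {
    warning(sprintf("%d ROIs supplied; only the first %d are tracked",
                    length(rois), max_rois))
    rois <- rois[seq_len(max_rois)]
  }
  d <- dim(stack$pixels)
  if (!identical(dim(mask$mask), d[1:2]))
    stop("mask shape does not match the stack")
  flat <- matrix(stack$pixels, nrow = d[1] * d[2], ncol = d[3])

  roi_traces <- vector("list", length(rois))
  names(roi_traces) <- vapply(seq_along(rois), function(i) {
    nm <- rois[[i]]$name
    if (is.null(nm) || !nzchar(nm)) sprintf("roi%d", i) else nm
  }, character(1))
  for (i in seq_along(rois)) {
    m <- rois[[i]]$members
    if (any(m[, 1] < 1L | m[, 1] > d[1] | m[, 2] < 1L | m[, 2] > d[2]))
      stop(sprintf("ROI %d has member pixels outside the image", i))
    lin <- (m[, 2] - 1L) * d[1] + m[, 1]
    roi_traces[[i]] <- colMeans(flat[lin, , drop = FALSE])
  }
  bg <- !as.vector(mask$mask)
  if (!any(bg)) stop("cell mask covers the whole image: no background pixels")
  background_trace <- colMeans(flat[bg, , drop = FALSE])
  inm <- as.vector(mask$mask)
  total_trace <- if (any(inm)) colSums(flat[inm, , drop = FALSE])
                 else rep(0, d[3])
  bleach <- if (d[3] >= 2L && total_trace[1] > 0)
    photobleach_report(total_trace) else NA_real_
  structure(
    list(roi_traces = roi_traces, background_trace = background_trace,
         total_trace = total_trace, bleach_percent = bleach,
         corrected_traces = NULL, frames = d[3],
         frame_times = stack$frame_times),
    class = "trace_set"
  )
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d ROI trace(s) over %d frame(s)%s\n",
              length(x$roi_traces), x$frames,
              if (is.null(x$corrected_traces)) "" else " (bleach-corrected)"))
  if (!is.na(x$bleach_percent))
    cat(sprintf("  photobleaching: %.3f%% drop in total fluorescence\n",
                x$bleach_percent))
  invisible(x)
}

#' Photobleaching of a total-fluorescence trace, as a percentage
#'
#' Reports the net drop in total cellular fluorescence between the first
#' and last frame: `100 * (total[1] - total[end]) / total[1]`. The value is
#' signed — a negative percentage means a net gain. A large drop flags a
#' low-quality (heavily bleached) dataset.
#'
#' @param total_trace numeric vector (length >= 2) of total in-cell
#'   fluorescence per frame; the first value must be positive.
#' @return signed percentage.
#' @examples
#' photobleach_report(c(10, 9, 8))  # 20
#' @export
photobleach_report <- function(total_trace) {
  if (length(total_trace) < 2L)
    stop("'total_trace' must have at least 2 frames")
  if (total_trace[1] <= 0)
    stop("initial total fluorescence must be positive")
  100 * (total_trace[1] - total_trace[length(total_trace)]) / total_trace[1]
}

#' Correct ROI traces for photobleaching
#'
#' Bleaching dims every pixel by a common multiplicative factor per frame,
#' so it is removed by normalizing each ROI trace against the total
#' cellular fluorescence at the same time point. The correction is
#' anchored to frame 1 (`corrected[t] = roi[t] * total[1] / total[t]`), so
#' corrected traces keep the raw intensity units and coincide with the raw
#' traces at the first frame.
#'
#' @param traces a [track_rois()] result whose `total_trace` is positive at
#'   every frame.
#' @return the `trace_set` with `corrected_traces` filled in.
#' @export
bleach_correct <- function(traces) {
  stopifnot(inherits(traces, "trace_set"))
  if (any(traces$total_trace <= 0))
    stop("total fluorescence must be positive at every frame to correct bleaching")
  factor <- traces$total_trace[1] / traces$total_trace
  traces$corrected_traces <- lapply(traces$roi_traces, function(tr) tr * factor)
  traces
}

#' Export traces as CSV
#'
#' One row per frame; columns: `time` (acquisition time, or frame index),
#' one column per ROI (corrected values when present, raw otherwise),
#' `background` and `total`.
#'
#' @param traces a [track_rois()] result.
#' @param path output CSV path.
#' @param corrected write corrected traces if available (default `TRUE`).
#' @return `path`, invisibly.
#' @export
export_traces <- function(traces, path, corrected = TRUE) {
  stopifnot(inherits(traces, "trace_set"))
  df <- traces_data_frame(traces, corrected)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

traces_data_frame <- function(traces, corrected = TRUE) {
  tt <- if (is.null(traces$frame_times)) seq_len(traces$frames)
        else traces$frame_times
  use <- if (corrected && !is.null(traces$corrected_traces))
    traces$corrected_traces else traces$roi_traces
  df <- data.frame(time = tt, check.names = FALSE)
  for (nm in names(use)) df[[nm]] <- use[[nm]]
  df$background <- traces$background_trace
  df$total <- traces$total_trace
  df
}

#' Plot ROI, background and total traces against time
#'
#' Writes a PNG line plot of every ROI trace (corrected when available)
#' plus the background trace. The total-fluorescence trace lives on a sum
#' scale and is exported in the CSV rather than drawn here.
#'
#' @param traces a [track_rois()] result.
#' @param path output PNG path.
#' @param corrected plot corrected traces if available (default `TRUE`).
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
plot_traces <- function(traces, path, corrected = TRUE,
                        main = "Mean fluorescence over time") {
  stopifnot(inherits(traces, "trace_set"))
  df <- traces_data_frame(traces, corrected)
  series <- df[, setdiff(names(df), c("time", "total")), drop = FALSE]
  grDevices::png(path, width = 900, height = 600)
  on.exit(grDevices::dev.off(), add = TRUE)
  cols <- grDevices::hcl.colors(ncol(series), "Dark 3")
  graphics::matplot(df$time, as.matrix(series), type = "l", lty = 1,
                    lwd = 2, col = cols, xlab = "time", ylab = "mean intensity",
                    main = main)
  graphics::legend("topright", legend = names(series), col = cols,
                   lty = 1, lwd = 2, bty = "n")
  invisible(path)
}
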