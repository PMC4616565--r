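#' Frame stack: a single-channel time-lapse image sequence
#'
#' A `frame_stack` is the in-memory carrier of the intensity field
#' \eqn{I(x, y, t)}: a rows x cols x frames numeric array together with a
#' channel tag, the value range of the storage type it came from, and
#' optional acquisition times.
#'
#' @param pixels numeric array of dimension rows x cols x frames, or a
#'   matrix (treated as a single frame). All values must be finite;
#'   raw (unprocessed) data must be non-negative.
#' @param channel one of `"green"`, `"red"`, `"unknown"`.
#' @param value_range length-2 numeric, the (min, max) representable by the
#'   storage dtype the data came from. Defaults to `range(pixels)` if the
#'   origin is unknown.
#' @param frame_times optional numeric vector of acquisition times, one per
#'   frame, strictly increasing. Frame index is used when absent.
#'
#' @return An object of class `frame_stack`: a list with elements `pixels`,
#'   `channel`, `value_range`, `frame_times`.
#' @examples
#' s <- frame_stack(array(runif(4 * 4 * 3), c(4, 4, 3)), channel = "red")
#' n_frames(s)
#' @export
frame_stack <- function(pixels, channel = c("unknown", "green", "red"),
                        value_range = NULL, frame_times = NULL) {
  channel <- match.arg(channel)
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("'pixels' must be a rows x cols x frames array")
  if (any(dim(pixels) < 1L)) stop("all stack dimensions must be >= 1")
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) stop("all intensities must be finite")
  if (is.null(value_range)) value_range <- range(pixels)
  if (length(value_range) != 2L || value_range[1] > value_range[2])
    stop("'value_range' must be (min, max) with min <= max")
  nf <- dim(pixels)[3]
  if (!is.null(frame_times)) {
    if (length(frame_times) != nf)
      stop("'frame_times' must have one entry per frame")
    if (nf > 1L && any(diff(frame_times) <= 0))
      stop("'frame_times' must be strictly increasing")
  }
  structure(
    list(pixels = pixels, channel = channel,
         value_range = as.numeric(value_range), frame_times = frame_times),
    class = "frame_stack"
  )
}

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  dim(stack$pixels)[3]
}

#' @export
dim.frame_stack <- function(x) dim(x$pixels)

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("frame_stack: %d x %d pixels, %d frame(s), channel=%s\n",
              d[1], d[2], d[3], x$channel))
  cat(sprintf("  intensity range [%.4g, %.4g], storage range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels),
              x$value_range[1], x$value_range[2]))
  invisible(x)
}

# Replace the pixel array, keeping metadata.
with_pixels <- function(stack, pixels, channel = stack$channel) {
  frame_stack(pixels, channel = channel, value_range = stack$value_range,
              frame_times = stack$frame_times)
}

#' Subset the frames of a stack
#'
#' Keeps channel and value-range metadata and the matching `frame_times`.
#'
#' @param stack a [frame_stack()].
#' @param idx frame indices to keep, in the desired order.
#' @return a [frame_stack()] with the selected frames.
#' @export
subset_frames <- function(stack, idx) {
  px <- stack$pixels[, , idx, drop = FALSE]
  ft <- if (is.null(stack$frame_times)) NULL else stack$frame_times[idx]
  frame_stack(px, channel = stack$channel, value_range = stack$value_range,
              frame_times = ft)
}

# Population variance (divisor n) of a numeric vector/array.
pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

pop_sd <- function(x) sqrt(pop_var(x))

#' Label 8-connected components of a binary mask
#'
#' Two foreground pixels are connected when they touch horizontally,
#' vertically or diagonally. Labels are assigned in raster order of each
#' component's first pixel, so labeling is deterministic.
#'
#' @param mask logical (or 0/1) matrix.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  # offsets of the 8-neighborhood in (row, col)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  fg <- which(mask)  # column-major order
  for (start in fg) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- integer(256L); queue[1L] <- start; head <- 1L; tail <- 1L
    labels[start] <- lab
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      pr <- ((p - 1L) %% nr) + 1L
      pc <- ((p - 1L) %/% nr) + 1L
      for (k in 1:8) {
        r <- pr + dr[k]; cc <- pc + dc[k]
        if (r < 1L || r > nr || cc < 1L || cc > nc) next
        q <- (cc - 1L) * nr + r
        if (mask[q] && labels[q] == 0L) {
          labels[q] <- lab
          tail <- tail + 1L
          if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[tail] <- q
        }
      }
    }
  }
  labels
}
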