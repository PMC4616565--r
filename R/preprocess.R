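#' 3x3 median filter of a single frame
#'
#' Replaces each pixel by the median of its 3x3 neighborhood, suppressing
#' spatial shot noise while preserving edges. Borders are handled by edge
#' replication (the nearest image row/column is repeated), so a 1x1 or 1xN
#' frame degrades gracefully to the available neighborhood.
#'
#' The median of the 9 neighborhood values is computed with a vectorized
#' compare-exchange network over shifted copies of the frame, so the whole
#' frame is filtered in a handful of `pmin`/`pmax` passes.
#'
#' @param frame numeric matrix (one image frame).
#' @return filtered matrix of the same shape.
#' @examples
#' f <- matrix(0, 5, 5); f[3, 3] <- 100   # isolated impulse
#' max(median_filter_3x3(f))              # 0: impulse rejected
#' @export
median_filter_3x3 <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("'frame' must be a numeric matrix")
  nr <- nrow(frame); nc <- ncol(frame)
  ri <- function(d) pmin(pmax(seq_len(nr) + d, 1L), nr)
  ci <- function(d) pmin(pmax(seq_len(nc) + d, 1L), nc)
  # 9 shifted copies (edge-replicated), then an odd-even transposition sort
  shifts <- vector("list", 9L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    shifts[[k]] <- frame[ri(dr), ci(dc), drop = FALSE]
  }
  for (pass in 1:8) {
    for (j in seq_len(9L - pass)) {
      lo <- pmin(shifts[[j]], shifts[[j + 1L]])
      hi <- pmax(shifts[[j]], shifts[[j + 1L]])
      shifts[[j]] <- lo; shifts[[j + 1L]] <- hi
    }
  }
  shifts[[5L]]
}

#' Temporal Gaussian smoothing kernel
#'
#' Samples the Gaussian density \eqn{G(t) = \frac{1}{\sqrt{2\pi}\sigma}
#' e^{-t^2 / 2\sigma^2}} at integer frame offsets centered on zero. The
#' raw density samples are returned without normalization; with
#' `sigma = 1, width = 5` this gives the mask
#' `[0.054, 0.242, 0.399, 0.242, 0.054]` (sum 0.988). [temporal_smooth()]
#' renormalizes by the included-weight sum at every frame, so the
#' unnormalized mask never dims the sequence.
#'
#' @param sigma standard deviation of the filter, in frames (> 0).
#' @param width odd kernel width in frames (>= 1).
#' @return A `gaussian_kernel`: list with `sigma`, `width`, `weights`.
#' @examples
#' round(gaussian_kernel(1, 5)$weights, 3)
#' @export
gaussian_kernel <- function(sigma, width = 5L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive number")
  if (!is.numeric(width) || length(width) != 1L || width < 1 ||
      width != round(width) || width %% 2 == 0)
    stop("'width' must be an odd positive integer")
  width <- as.integer(width)
  t_off <- seq_len(width) - 1L - (width - 1L) %/% 2L
  weights <- exp(-t_off^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  structure(list(sigma = sigma, width = width, weights = weights),
            class = "gaussian_kernel")
}

#' Smooth a stack along the time axis
#'
#' Convolves every pixel time series with a Gaussian kernel to damp sharp
#' frame-to-frame variation, which is characteristic of temporal noise
#' rather than of true signal changes. At the ends of the sequence the
#' kernel is curtailed to the frames that exist (no padding), and at every
#' frame the included weights are renormalized by their own sum, so a
#' time-constant series passes through unchanged everywhere including the
#' boundaries.
#'
#' @param stack a [frame_stack()].
#' @param kernel a [gaussian_kernel()].
#' @return smoothed [frame_stack()].
#' @export
temporal_smooth <- function(stack, kernel) {
  stopifnot(inherits(stack, "frame_stack"), inherits(kernel, "gaussian_kernel"))
  nf <- n_frames(stack)
  half <- (kernel$width - 1L) %/% 2L
  out <- array(0, dim = dim(stack$pixels))
  for (f in seq_len(nf)) {
    idx <- f + (seq_len(kernel$width) - 1L - half)
    keep <- idx >= 1L & idx <= nf
    w <- kernel$weights[keep] / sum(kernel$weights[keep])
    idx <- idx[keep]
    acc <- stack$pixels[, , idx[1]] * w[1]
    for (j in seq_along(idx)[-1])
      acc <- acc + stack$pixels[, , idx[j]] * w[j]
    out[, , f] <- acc
  }
  with_pixels(stack, out)
}

#' Subtract the pre-conversion background frame
#'
#' The first red frame of a photo-conversion sequence is acquired before
#' the conversion pulse and therefore images only background (autofluorescence,
#' camera offset, bleed-through). It is subtracted pixel-wise from every
#' frame, including itself; negative differences are clamped to zero, as
#' negative fluorescence is not physical.
#'
#' @param stack a [frame_stack()].
#' @return background-subtracted [frame_stack()] (frame 1 is all zero).
#' @export
subtract_background <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  bg <- stack$pixels[, , 1]
  out <- sweep(stack$pixels, c(1, 2), bg, "-")
  out[out < 0] <- 0
  with_pixels(stack, out)
}

#' Contrast-stretch a whole sequence to the unit interval
#'
#' Applies the linear transform \eqn{(I - I_{min}) / (I_{max} - I_{min})}
#' with the minimum and maximum taken over *all* pixels of *all* frames,
#' so the sequence-wide maximum maps to exactly 1 and the minimum to 0.
#' Stretching the sequence at once (rather than frame by frame) preserves
#' relative intensities over time; per-frame stretching would fabricate
#' apparent fluorescence changes.
#'
#' @param stack a [frame_stack()].
#' @return stretched [frame_stack()] with `value_range` (0, 1).
#' @export
contrast_stretch <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  lo <- min(stack$pixels); hi <- max(stack$pixels)
  if (hi == lo)
    stop("degenerate intensity range: sequence is constant (max == min), cannot stretch")
  out <- (stack$pixels - lo) / (hi - lo)
  frame_stack(out, channel = stack$channel, value_range = c(0, 1),
              frame_times = stack$frame_times)
}

#' Full preprocessing chain for the red channel
#'
#' Runs, in order: per-frame 3x3 median filtering, pre-conversion
#' background subtraction, temporal Gaussian smoothing, and sequence-wide
#' contrast stretching. The intermediate stack after each stage is kept
#' for inspection.
#'
#' Background subtraction precedes temporal smoothing: because the
#' smoother renormalizes its weights at every frame, subtracting first is
#' exactly equivalent to smoothing first and then subtracting the
#' *unsmoothed* pre-conversion frame. Smoothing the reference frame before
#' subtracting it would leak early post-conversion signal into the
#' background estimate and partially cancel the very signal of interest.
#'
#' @param stack the red-channel [frame_stack()].
#' @param sigma temporal Gaussian standard deviation in frames (default 1).
#' @param width temporal kernel width in frames (odd, default 5).
#' @return A `preprocess_record`: list with `stack` (the fully processed
#'   stack) and `stages`, a named list of the four intermediate stacks in
#'   order (`median`, `background`, `temporal`, `stretch`).
#' @export
preprocess_red <- function(stack, sigma = 1, width = 5L) {
  stopifnot(inherits(stack, "frame_stack"))
  px <- stack$pixels
  for (f in seq_len(dim(px)[3])) px[, , f] <- median_filter_3x3(px[, , f])
  med <- with_pixels(stack, px)
  bgsub <- subtract_background(med)
  smoothed <- temporal_smooth(bgsub, gaussian_kernel(sigma, width))
  stretched <- contrast_stretch(smoothed)
  structure(
    list(stack = stretched,
         stages = list(median = med, background = bgsub,
                       temporal = smoothed, stretch = stretched)),
    class = "preprocess_record"
  )
}

#' @export
print.preprocess_record <- function(x, ...) {
  cat(sprintf("preprocess_record: %s -> processed stack of %d frame(s)\n",
              paste(names(x$stages), collapse = " -> "), n_frames(x$stack)))
  invisible(x)
}
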