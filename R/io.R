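#' Read a multi-page TIFF time series into a frame stack
#'
#' Each TIFF page becomes one frame, in file order. Grayscale 8- and 16-bit
#' unsigned-integer pages are read as their raw integer values
#' (`value_range` set to the dtype range). 32-bit pages are interpreted on
#' the unit scale: IEEE-float pages are kept as stored, and 32-bit
#' unsigned-integer pages (the encoding [write_stack()] uses for float
#' data) are divided by 2^32 - 1; in both cases `value_range` is (0, 1).
#'
#' @param path path to a single- or multi-page grayscale TIFF.
#' @param channel channel tag to attach (default `"unknown"`).
#' @return A [frame_stack()].
#' @seealso [write_stack()], [split_channels()]
#' @export
read_stack <- function(path, channel = "unknown") {
  if (!is.character(path) || length(path) != 1L || !nzchar(path))
    stop("'path' must be a single non-empty file path")
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (is.matrix(pages) || !is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("no TIFF pages in ", path)

  ref_dim <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    d <- dim(pages[[i]])
    if (length(d) != 2L)
      stop(sprintf(
        "unsupported sample format at page %d: expected grayscale, got %d channel(s)",
        i, if (length(d) >= 3L) d[3] else 1L))
    if (!identical(d, ref_dim[1:2]))
      stop(sprintf("inconsistent page shape at page %d: %dx%d, expected %dx%d",
                   i, d[1], d[2], ref_dim[1], ref_dim[2]))
  }

  bits <- attr(pages[[1]], "bits.per.sample")
  fmt <- attr(pages[[1]], "sample.format")
  if (is.null(bits)) bits <- 8L
  if (is.null(fmt)) fmt <- "uint"
  px <- array(0, dim = c(ref_dim[1], ref_dim[2], length(pages)))
  for (i in seq_along(pages)) px[, , i] <- pages[[i]]
  if (identical(fmt, "float")) {
    value_range <- c(0, 1)
  } else if (bits >= 32L) {
    px[px < 0] <- px[px < 0] + 2^32  # uint32 read back through signed ints
    px <- px / (2^32 - 1)
    value_range <- c(0, 1)
  } else if (bits > 8L) {
    value_range <- c(0, 65535)
  } else {
    value_range <- c(0, 255)
  }
  frame_stack(px, channel = channel, value_range = value_range)
}

#' Write a frame stack as a multi-page TIFF
#'
#' Integer-valued stacks are stored losslessly as 8- or 16-bit unsigned
#' integers (one page per frame), so `read_stack(write_stack(s))`
#' reproduces the pixels exactly. Float-valued stacks must lie in the unit
#' interval and are stored as 32-bit samples (precision 2^-32), which
#' [read_stack()] maps back to (0, 1).
#'
#' @param stack a [frame_stack()].
#' @param path output path; parent directory must exist.
#' @param dtype `"auto"` (default; chooses from the data), `"uint8"`,
#'   `"uint16"` or `"float"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, dtype = c("auto", "uint8", "uint16", "float")) {
  stopifnot(inherits(stack, "frame_stack"))
  dtype <- match.arg(dtype)
  if (!is.character(path) || length(path) != 1L || !nzchar(path))
    stop("'path' must be a single non-empty file path")
  px <- stack$pixels
  if (dtype == "auto") {
    integral <- all(px == round(px)) && min(px) >= 0
    dtype <- if (integral && max(px) <= 255) "uint8"
             else if (integral && max(px) <= 65535) "uint16"
             else "float"
  }
  enc <- switch(dtype,
    uint8  = list(scale = 255, bits = 8L),
    uint16 = list(scale = 65535, bits = 16L),
    float  = list(scale = 1, bits = 32L))
  if (dtype != "float" && (any(px != round(px)) || min(px) < 0 || max(px) > enc$scale))
    stop(sprintf("stack values are not representable as %s", dtype))
  if (dtype == "float" && (min(px) < 0 || max(px) > 1))
    stop("float stacks must lie in [0, 1] for TIFF storage")
  frames <- lapply(seq_len(dim(px)[3]), function(i) px[, , i] / enc$scale)
  ok <- tryCatch(
    tiff::writeTIFF(frames, path, bits.per.sample = enc$bits, reduce = FALSE),
    error = function(e) stop("cannot write TIFF to '", path, "': ",
                             conditionMessage(e)))
  invisible(path)
}

#' Separate a mixed two-channel sequence into green and red stacks
#'
#' Dual-color photo-conversion acquisitions are often saved as one TIFF in
#' which green (pre-conversion) and red (post-conversion) frames share a
#' single page sequence. The channels are told apart statistically: the
#' green channel images the full cellular signal and has consistently
#' higher per-frame variance, while the red channel starts essentially
#' empty. Frames are partitioned into two streams according to `layout`,
#' and the stream with the higher mean per-frame (population) variance is
#' labeled green.
#'
#' @param stack a [frame_stack()] holding the mixed sequence (>= 2 frames).
#' @param layout `"interleaved"` (alternating frames), `"blocked"` (first
#'   half / second half) or `"auto"` (default), which picks the layout
#'   whose two streams have the larger ratio of mean variances.
#' @param tie_ratio mean-variance ratio at or below which the split is
#'   considered ambiguous (default 1.01) and an error is raised.
#' @return A `channel_split`: list with `green` and `red` frame stacks,
#'   `per_frame_variance` (one value per input frame), `assignment`
#'   (per-frame `"green"`/`"red"` labels), `layout` and `variance_ratio`.
#' @examples
#' g <- matrix(runif(64), 8, 8); r <- matrix(0, 8, 8)
#' mixed <- frame_stack(array(c(g, r, g, r), c(8, 8, 4)))
#' split_channels(mixed, "interleaved")$assignment
#' @export
split_channels <- function(stack, layout = c("auto", "interleaved", "blocked"),
                           tie_ratio = 1.01) {
  stopifnot(inherits(stack, "frame_stack"))
  layout <- match.arg(layout)
  nf <- n_frames(stack)
  if (nf < 2L) stop("channel splitting needs at least 2 frames")
  v <- vapply(seq_len(nf), function(i) pop_var(stack$pixels[, , i]), numeric(1))

  streams_for <- function(lay) {
    if (lay == "interleaved")
      list(a = seq(1L, nf, by = 2L), b = seq(2L, nf, by = 2L))
    else
      list(a = seq_len(nf %/% 2L), b = seq((nf %/% 2L) + 1L, nf))
  }
  ratio_for <- function(s) {
    m <- c(mean(v[s$a]), mean(v[s$b]))
    if (max(m) == 0) 1 else max(m) / max(min(m), .Machine$double.xmin)
  }
  if (layout == "auto") {
    cand <- c("interleaved", "blocked")
    ratios <- vapply(cand, function(l) ratio_for(streams_for(l)), numeric(1))
    layout <- cand[which.max(ratios)]
  }
  s <- streams_for(layout)
  ratio <- ratio_for(s)
  if (is.nan(ratio) || ratio <= tie_ratio)
    stop(sprintf(paste0(
      "ambiguous split: mean variance ratio %.4g is within the tie band ",
      "(<= %.4g); the two streams cannot be told apart"), ratio, tie_ratio))

  green_first <- mean(v[s$a]) >= mean(v[s$b])
  gi <- if (green_first) s$a else s$b
  ri <- if (green_first) s$b else s$a
  assignment <- character(nf)
  assignment[gi] <- "green"; assignment[ri] <- "red"
  green <- subset_frames(stack, gi); green$channel <- "green"
  red <- subset_frames(stack, ri); red$channel <- "red"
  structure(
    list(green = green, red = red,
         per_frame_variance = v, assignment = assignment,
         layout = layout, variance_ratio = ratio),
    class = "channel_split"
  )
}

#' @export
print.channel_split <- function(x, ...) {
  cat(sprintf("channel_split (%s layout): %d green + %d red frames, variance ratio %.3g\n",
              x$layout, n_frames(x$green), n_frames(x$red), x$variance_ratio))
  invisible(x)
}
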