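#' Per-pixel statistical model of an image sequence
#'
#' Summarizes a processed time series by two images: the temporal mean
#' \eqn{M(x,y) = \frac{1}{N}\sum_t I(x,y,t)}, an averaged (noise-reduced)
#' picture of the whole cell, and the temporal standard deviation
#' \eqn{S(x,y) = \sqrt{\frac{1}{N}\sum_t (I(x,y,t) - M(x,y))^2}}, which
#' lights up the pixels with the highest temporal variation — the areas the
#' converted protein actually moved through. The population divisor
#' \eqn{1/N} is used, so a single-frame stack yields \eqn{S \equiv 0}.
#'
#' @param stack a [frame_stack()].
#' @return A `stat_model`: list with `mean_image`, `sd_image` (matrices of
#'   the frame shape) and `n_frames`.
#' @examples
#' s <- frame_stack(array(c(0, 1), c(1, 1, 2)))
#' build_stat_model(s)$sd_image  # 0.5: population divisor
#' @export
build_stat_model <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$pixels)
  flat <- matrix(stack$pixels, nrow = d[1] * d[2], ncol = d[3])
  m <- rowMeans(flat)
  s <- sqrt(rowMeans((flat - m)^2))
  structure(
    list(mean_image = matrix(m, d[1], d[2]),
         sd_image = matrix(s, d[1], d[2]),
         n_frames = d[3]),
    class = "stat_model"
  )
}

#' @export
print.stat_model <- function(x, ...) {
  cat(sprintf("stat_model over %d frame(s): M in [%.4g, %.4g], S in [%.4g, %.4g]\n",
              x$n_frames, min(x$mean_image), max(x$mean_image),
              min(x$sd_image), max(x$sd_image)))
  invisible(x)
}

#' Export the mean and SD images as float TIFFs
#'
#' Both images are rescaled to the unit interval of their own range before
#' writing (TIFF storage is unit-scaled); constant images are written as
#' zeros.
#'
#' @param model a [build_stat_model()] result.
#' @param mean_path,sd_path output TIFF paths.
#' @return named character vector of the written paths, invisibly.
#' @export
export_stat_model <- function(model, mean_path, sd_path) {
  stopifnot(inherits(model, "stat_model"))
  unit <- function(img) {
    r <- range(img)
    if (r[2] > r[1]) (img - r[1]) / (r[2] - r[1]) else img * 0
  }
  write_stack(frame_stack(unit(model$mean_image)), mean_path, dtype = "float")
  write_stack(frame_stack(unit(model$sd_image)), sd_path, dtype = "float")
  invisible(c(mean = mean_path, sd = sd_path))
}
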