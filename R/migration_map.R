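#' Segment the cell from the standard-deviation image
#'
#' The converted protein moves only within the cell, so the cell region is
#' where temporal variation is high. A pixel belongs to the cell when its
#' temporal standard deviation exceeds the global threshold
#' \eqn{\bar{S} + \sigma_S} (mean of the SD image plus one population
#' standard deviation of it); the comparison is strict, so a uniform SD
#' image yields an empty mask. The thresholded mask is then cleaned by
#' morphological opening with a disk structuring element, which removes
#' spurious blobs smaller than the element.
#'
#' @param model a [build_stat_model()] result.
#' @param opening_radius disk radius in pixels for the opening (default 1,
#'   i.e. a 3x3-scale element); 0 disables the opening.
#' @return A `cell_mask`: list with `mask` (logical matrix), `threshold`
#'   (the value of \eqn{\bar{S} + \sigma_S}) and `opening_radius`.
#' @export
segment_cell <- function(model, opening_radius = 1L) {
  stopifnot(inherits(model, "stat_model"))
  if (opening_radius < 0) stop("'opening_radius' must be >= 0")
  s <- model$sd_image
  threshold <- mean(s) + pop_sd(s)
  mask <- s > threshold
  if (opening_radius > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2L * as.integer(opening_radius) + 1L,
                                shape = "disc")
    opened <- EBImage::opening(mask * 1, brush)
    mask <- opened > 0.5
  }
  if (!any(mask))
    message("cell segmentation produced an empty mask (no pixel exceeds the SD threshold)")
  structure(list(mask = mask, threshold = threshold,
                 opening_radius = as.integer(opening_radius)),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("cell_mask: %d of %d pixels in cell (SD threshold %.4g, opening radius %d)\n",
              sum(x$mask), length(x$mask), x$threshold, x$opening_radius))
  invisible(x)
}

#' Classification thresholds for the migration map
#'
#' The trajectory classes are defined from three per-pixel summaries of
#' the processed (unit-scaled) sequence: the early-window mean E, the
#' late-window mean L (windows of `ceil(early_fraction * frames)` frames),
#' and the overall temporal mean. All values are tunable; the defaults are
#' the package's concrete reading of "bright but dims" (injection), "dim
#' becoming bright" (migration target), and "extreme brightness"
#' (accumulation).
#'
#' @param early_fraction fraction of the sequence defining the early/late
#'   windows (default 0.1).
#' @param delta required relative endpoint contrast: injection needs
#'   `L <= (1 - delta) * E`, diffusion toward needs `E <= (1 - delta) * L`
#'   (default 0.2).
#' @param sat_threshold absolute late-window intensity treated as
#'   saturation on the unit scale (default 0.95). Note the data is already
#'   normalized, so this flags sequence-scale maxima rather than true
#'   sensor saturation.
#' @param bright_quantile quantile of in-cell temporal means above which a
#'   pixel's late signal counts as extreme relative brightness (default 0.99).
#' @param bright_floor minimum endpoint-window mean for a pixel to count
#'   as "bright" at all (default 0.2, unit scale).
#' @param dark_sd_factor in-cell pixels with temporal SD below
#'   `dark_sd_factor` times the cell-segmentation threshold are classified
#'   background ("relatively dark with minimal variation"); default 0.5.
#'   With a mask from [segment_cell()] this rule is usually vacuous, since
#'   in-cell pixels already exceed the full threshold.
#' @return A named list of class `map_params`.
#' @export
map_params <- function(early_fraction = 0.1, delta = 0.2, sat_threshold = 0.95,
                       bright_quantile = 0.99, bright_floor = 0.2,
                       dark_sd_factor = 0.5) {
  p <- list(early_fraction = early_fraction, delta = delta,
            sat_threshold = sat_threshold, bright_quantile = bright_quantile,
            bright_floor = bright_floor, dark_sd_factor = dark_sd_factor)
  if (early_fraction <= 0 || early_fraction > 0.5)
    stop("'early_fraction' must be in (0, 0.5]")
  if (delta < 0 || delta >= 1) stop("'delta' must be in [0, 1)")
  if (bright_quantile < 0 || bright_quantile > 1)
    stop("'bright_quantile' must be in [0, 1]")
  if (bright_floor < 0) stop("'bright_floor' must be >= 0")
  if (dark_sd_factor < 0) stop("'dark_sd_factor' must be >= 0")
  structure(p, class = "map_params")
}

#' Classify pixel trajectories into a migration map
#'
#' Each in-cell pixel's time course is summarized by its early-window mean
#' E, late-window mean L and overall mean, and assigned one of five
#' classes, in priority order:
#'
#' * **accumulation** — sustained extreme brightness: the late mean L is at
#'   or above the `bright_quantile` quantile of in-cell temporal means
#'   (relative extremity) or at or above `sat_threshold` (absolute). A
#'   transiently bright pixel that dims again is *not* accumulation.
#' * **injection** — bright but dimming: `E >= bright_floor` and
#'   `L <= (1 - delta) * E`. These pixels mark the original photo-conversion
#'   site.
#' * **diffusion_toward** — dim becoming bright: `L >= bright_floor` and
#'   `E <= (1 - delta) * L`.
#' * **background** — outside the cell mask, or in-cell with temporal SD
#'   below `dark_sd_factor` times the segmentation threshold.
#' * **unclassified** — in-cell pixels matching none of the above.
#'
#' The injection point is estimated as the centroid of the largest
#' 8-connected injection component (see [injection_point()]).
#'
#' @param stack the fully preprocessed red [frame_stack()] (unit scale).
#' @param mask a [segment_cell()] result.
#' @param params a [map_params()] list.
#' @return A `migration_map`: list with `labels` (character matrix over
#'   the five classes), `injection_point` ((row, col) or `NULL`),
#'   `parameters`, and `counts` (named class pixel counts).
#' @export
classify_pixels <- function(stack, mask, params = map_params()) {
  stopifnot(inherits(stack, "frame_stack"), inherits(mask, "cell_mask"))
  if (!inherits(params, "map_params")) params <- do.call(map_params, params)
  d <- dim(stack$pixels)
  if (!identical(dim(mask$mask), d[1:2]))
    stop("mask shape does not match the stack")
  nf <- d[3]
  k <- max(1L, as.integer(ceiling(params$early_fraction * nf)))
  flat <- matrix(stack$pixels, nrow = d[1] * d[2], ncol = nf)
  e_mean <- rowMeans(flat[, seq_len(k), drop = FALSE])
  l_mean <- rowMeans(flat[, seq(nf - k + 1L, nf), drop = FALSE])
  a_mean <- rowMeans(flat)
  t_sd <- sqrt(rowMeans((flat - a_mean)^2))
  in_cell <- as.vector(mask$mask)

  labels <- rep("background", d[1] * d[2])
  if (any(in_cell)) {
    bright_cut <- stats::quantile(a_mean[in_cell], params$bright_quantile,
                                  names = FALSE, type = 7)
    acc <- l_mean >= bright_cut | l_mean >= params$sat_threshold
    inj <- e_mean >= params$bright_floor &
           l_mean <= (1 - params$delta) * e_mean
    dif <- l_mean >= params$bright_floor &
           e_mean <= (1 - params$delta) * l_mean
    dark <- t_sd < params$dark_sd_factor * mask$threshold
    lab_cell <- ifelse(acc, "accumulation",
                ifelse(inj, "injection",
                ifelse(dif, "diffusion_toward",
                ifelse(dark, "background", "unclassified"))))
    labels[in_cell] <- lab_cell[in_cell]
  }
  labels <- matrix(labels, d[1], d[2])
  counts <- vapply(migration_classes(), function(cl) sum(labels == cl),
                   integer(1))
  map <- structure(
    list(labels = labels, injection_point = NULL, parameters = params,
         counts = counts),
    class = "migration_map"
  )
  if (counts[["injection"]] > 0L) map$injection_point <- injection_point(map)
  map
}

#' The five migration-map classes, in display priority order
#' @return character vector of class names.
#' @export
migration_classes <- function() {
  c("accumulation", "injection", "diffusion_toward", "background",
    "unclassified")
}

#' @export
print.migration_map <- function(x, ...) {
  cat("migration_map class counts:\n")
  print(x$counts)
  if (!is.null(x$injection_point))
    cat(sprintf("injection point: (%d, %d)\n",
                x$injection_point[1], x$injection_point[2]))
  invisible(x)
}

#' Estimate the photo-conversion point
#'
#' The approximate conversion site is the centroid (mean row, mean column,
#' rounded to the nearest pixel) of the largest 8-connected component of
#' injection-labeled pixels. If the rounded centroid itself is not
#' injection-labeled (possible for non-convex components), the component
#' pixel nearest to it is returned, so the estimate always lies inside the
#' injection region.
#'
#' @param map a [classify_pixels()] result.
#' @return integer (row, col).
#' @export
injection_point <- function(map) {
  stopifnot(inherits(map, "migration_map"))
  inj <- map$labels == "injection"
  if (!any(inj))
    stop("no injection-labeled pixels: cannot estimate the conversion point")
  comp <- label_components(inj)
  sizes <- tabulate(comp[comp > 0L])
  largest <- which.max(sizes)
  idx <- which(comp == largest, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  if (comp[ctr[1], ctr[2]] != largest) {
    d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
    ctr <- idx[which.min(d2), ]
  }
  stats::setNames(as.integer(ctr), c("row", "col"))
}

#' Export a migration map as a grayscale image plus class counts
#'
#' Writes the map with the standard five-level key (white = accumulation,
#' light grey = diffusion toward, dark grey = injection, darkest grey =
#' background, black = unclassified) as a TIFF, and the class pixel counts
#' as a CSV. The injection point, when present, is marked by a white cross.
#'
#' @param map a [classify_pixels()] result.
#' @param image_path output TIFF path.
#' @param counts_path optional CSV path for the class counts.
#' @return named character vector of written paths, invisibly.
#' @export
export_migration_map <- function(map, image_path, counts_path = NULL) {
  stopifnot(inherits(map, "migration_map"))
  levels <- c(accumulation = 1, diffusion_toward = 0.75, injection = 0.5,
              background = 0.25, unclassified = 0)
  img <- matrix(levels[map$labels], nrow(map$labels), ncol(map$labels))
  if (!is.null(map$injection_point)) {
    p <- map$injection_point
    arm <- -2:2
    r <- pmin(pmax(p[1] + arm, 1L), nrow(img))
    cc <- pmin(pmax(p[2] + arm, 1L), ncol(img))
    img[r, p[2]] <- 1; img[p[1], cc] <- 1
  }
  write_stack(frame_stack(img), image_path, dtype = "float")
  paths <- c(image = image_path)
  if (!is.null(counts_path)) {
    utils::write.csv(
      data.frame(class = names(map$counts), pixels = as.integer(map$counts)),
      counts_path, row.names = FALSE)
    paths <- c(paths, counts = counts_path)
  }
  invisible(paths)
}
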