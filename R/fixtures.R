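#' Specification for a synthetic photo-conversion time-lapse
#'
#' Describes a ground-truthed single-cell experiment: a static green
#' (pre-conversion) channel imaging the whole cell, and a red channel that
#' is empty before the conversion pulse and afterwards carries a Gaussian
#' blob of converted protein that spreads diffusively from the conversion
#' site, optionally accumulating in a small nuclear compartment (a
#' nucleolus / nuclear-body analog), under exponential photobleaching and
#' camera noise.
#'
#' Geometry defaults scale with `shape`: an elliptical cell containing an
#' elliptical nucleus and a small disk compartment inside the nucleus; the
#' conversion site sits in the nucleoplasm away from the compartment.
#' The default bleach rate of 0.00165 per frame loses about 15% of total
#' fluorescence over the default 100-frame series, the magnitude typical
#' of real spinning-disk photo-conversion acquisitions.
#'
#' @param shape integer (rows, cols); default `c(128, 128)`.
#' @param frames frames per channel (>= 2); default 100.
#' @param layout `"interleaved"` (green/red alternating, green first) or
#'   `"blocked"` (all green, then all red).
#' @param cell_geometry optional list of logical matrices `cell`,
#'   `nucleus`, `compartment` (must be nested); built from `shape` if `NULL`.
#' @param injection_center (row, col) of the conversion site; default is
#'   a nucleoplasmic point scaled from `shape`.
#' @param injection_radius initial Gaussian radius (sigma) of the converted
#'   blob, pixels; default 4.
#' @param diffusion_coefficient D in px^2/frame; the blob variance grows as
#'   `injection_radius^2 + 2 * D * t`. Default 1.5.
#' @param accumulation_rate per-frame fraction of free converted protein
#'   captured by the compartment (0 disables accumulation; default 0).
#' @param bleach_rate per-frame decay exponent k: frame t is scaled by
#'   `exp(-k * t)`. Default 0.00165.
#' @param peak_intensity intensity of the blob center at conversion
#'   (unit scale); default 0.8.
#' @param noise_sd Gaussian camera-noise standard deviation (unit scale);
#'   default 0.005.
#' @param poisson add Poisson shot noise (at `photons` counts per intensity
#'   unit) before the Gaussian read noise; default `FALSE`.
#' @param photons photon scale for the Poisson noise; default 1000.
#' @param seed RNG seed for reproducibility; default 1.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(shape = c(128L, 128L), frames = 100L,
                         layout = c("interleaved", "blocked"),
                         cell_geometry = NULL,
                         injection_center = NULL, injection_radius = 4,
                         diffusion_coefficient = 1.5, accumulation_rate = 0,
                         bleach_rate = 0.00165, peak_intensity = 0.8,
                         noise_sd = 0.005, poisson = FALSE, photons = 1000,
                         seed = 1L) {
  layout <- match.arg(layout)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 16L))
    stop("'shape' must be (rows, cols), each >= 16")
  frames <- as.integer(frames)
  if (frames < 2L) stop("'frames' must be >= 2 per channel")
  if (is.null(cell_geometry)) cell_geometry <- default_geometry(shape)
  g <- cell_geometry
  if (!all(c("cell", "nucleus", "compartment") %in% names(g)))
    stop("'cell_geometry' needs masks 'cell', 'nucleus', 'compartment'")
  for (nm in names(g)) {
    if (!is.matrix(g[[nm]]) || !identical(dim(g[[nm]]), shape))
      stop("geometry mask '", nm, "' must be a logical matrix of dim shape")
  }
  if (any(g$compartment & !g$nucleus) || any(g$nucleus & !g$cell))
    stop("geometry masks must be nested: compartment within nucleus within cell")
  if (is.null(injection_center))
    injection_center <- round(c(0.55, 0.41) * shape)
  injection_center <- as.integer(injection_center)
  if (!g$cell[injection_center[1], injection_center[2]])
    stop("'injection_center' must lie inside the cell mask")
  if (injection_radius <= 0 || diffusion_coefficient < 0 ||
      accumulation_rate < 0 || accumulation_rate >= 1 || bleach_rate < 0 ||
      peak_intensity <= 0 || noise_sd < 0)
    stop("invalid fixture rates: radii/intensities must be positive, rates >= 0, accumulation_rate < 1")
  structure(
    list(shape = shape, frames = frames, layout = layout,
         cell_geometry = g, injection_center = injection_center,
         injection_radius = injection_radius,
         diffusion_coefficient = diffusion_coefficient,
         accumulation_rate = accumulation_rate, bleach_rate = bleach_rate,
         peak_intensity = peak_intensity, noise_sd = noise_sd,
         poisson = poisson, photons = photons, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# Elliptical cell + nucleus + disk compartment, scaled to the image shape.
default_geometry <- function(shape) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ell <- function(ctr, semi)
    ((rr - ctr[1]) / semi[1])^2 + ((cc - ctr[2]) / semi[2])^2 <= 1
  cell <- ell(0.5 * shape, c(0.36, 0.30) * shape)
  nucleus <- ell(c(0.484, 0.5) * shape, c(0.19, 0.16) * shape)
  comp_ctr <- c(0.44, 0.59) * shape
  comp_r <- max(2, 0.04 * min(shape))
  compartment <- (rr - comp_ctr[1])^2 + (cc - comp_ctr[2])^2 <= comp_r^2
  nucleus <- nucleus | compartment   # keep nesting exact after rounding
  cell <- cell | nucleus
  list(cell = cell, nucleus = nucleus, compartment = compartment)
}

#' Generate a ground-truthed synthetic photo-conversion dataset
#'
#' Builds the mixed two-channel stack described by a [fixture_spec()] plus
#' its ground truth. Green frames image the static cell (cytoplasm dimmer
#' than nucleus, compartment brightest). Red frame 1 is the empty
#' pre-conversion image; from the next frame on, a Gaussian blob of unit
#' total mass spreads from the conversion site with variance
#' `injection_radius^2 + 2 D t`, confined to the cell by renormalized
#' clipping (mass falling outside the cell is redistributed inside, so
#' total mass is conserved), while `accumulation_rate` transfers a fixed
#' fraction of the remaining free mass into the compartment each frame.
#' Every red frame t is scaled by `exp(-bleach_rate * t)`, then noise is
#' added. All randomness derives from `spec$seed`.
#'
#' @param spec a [fixture_spec()].
#' @return A `pc_fixture`: list with `stack` (the mixed [frame_stack()]),
#'   `truth` (list: `channel_labels`, `injection_mask` — the 1/e^2 disk
#'   (radius `2 * injection_radius`) of the initial Gaussian spot, the
#'   standard laser-spot extent —, `accumulation_mask`, `clean_red` (noise-free red
#'   stack), `green_base`, `true_total_decay` (expected total red mass of
#'   the post-conversion frames, normalized to the first),
#'   `expected_bleach_percent`) and `spec`.
#' @examples
#' fx <- generate_fixture(fixture_spec(shape = c(48, 48), frames = 10))
#' fx$truth$expected_bleach_percent
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  shp <- spec$shape; nf <- spec$frames
  g <- spec$cell_geometry
  rr <- matrix(seq_len(shp[1]), shp[1], shp[2])
  cc <- matrix(seq_len(shp[2]), shp[1], shp[2], byrow = TRUE)
  d2 <- (rr - spec$injection_center[1])^2 + (cc - spec$injection_center[2])^2

  green_base <- 0.05 + 0.30 * g$cell + 0.20 * g$nucleus + 0.20 * g$compartment
  mass0 <- spec$peak_intensity * 2 * pi * spec$injection_radius^2
  n_comp <- sum(g$compartment)

  clean_red <- array(0, dim = c(shp, nf))
  keep <- (1 - spec$accumulation_rate)^(0:(nf - 2L))  # free fraction at t = 1..nf-1
  for (t in seq_len(nf - 1L)) {
    s2 <- spec$injection_radius^2 + 2 * spec$diffusion_coefficient * t
    blob <- exp(-d2 / (2 * s2)) * g$cell
    blob <- blob / sum(blob) * mass0 * keep[t]
    frame <- blob
    if (spec$accumulation_rate > 0 && n_comp > 0) {
      acc_mass <- mass0 * (1 - keep[t])
      frame <- frame + g$compartment * (acc_mass / n_comp)
    }
    clean_red[, , t + 1L] <- frame * exp(-spec$bleach_rate * t)
  }

  add_noise <- function(img) {
    if (spec$poisson)
      img <- stats::rpois(length(img), pmax(img, 0) * spec$photons) / spec$photons
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
    matrix(pmin(pmax(img, 0), 1), shp[1], shp[2])
  }

  green <- array(0, dim = c(shp, nf))
  red <- array(0, dim = c(shp, nf))
  for (t in seq_len(nf)) {
    green[, , t] <- add_noise(green_base)
    red[, , t] <- add_noise(clean_red[, , t])
  }

  if (spec$layout == "interleaved") {
    order_idx <- as.vector(rbind(seq_len(nf), nf + seq_len(nf)))
  } else {
    order_idx <- c(seq_len(nf), nf + seq_len(nf))
  }
  all_frames <- array(c(green, red), dim = c(shp, 2L * nf))
  mixed <- all_frames[, , order_idx, drop = FALSE]
  labels <- c(rep("green", nf), rep("red", nf))[order_idx]

  spot_r <- 2 * spec$injection_radius  # 1/e^2 radius of the Gaussian spot
  truth <- list(
    channel_labels = labels,
    injection_mask = d2 <= spot_r^2,
    accumulation_mask = g$compartment,
    clean_red = frame_stack(clean_red, channel = "red", value_range = c(0, 1)),
    green_base = green_base,
    true_total_decay = exp(-spec$bleach_rate * (0:(nf - 2L))),
    expected_bleach_percent = 100 * (1 - exp(-spec$bleach_rate * (nf - 2L)))
  )
  structure(
    list(stack = frame_stack(mixed, channel = "unknown", value_range = c(0, 1)),
         truth = truth, spec = spec),
    class = "pc_fixture"
  )
}

#' @export
print.pc_fixture <- function(x, ...) {
  cat(sprintf("pc_fixture: %d x %d, %d frames/channel (%s), D=%.3g, accum=%.3g, bleach k=%.4g\n",
              x$spec$shape[1], x$spec$shape[2], x$spec$frames, x$spec$layout,
              x$spec$diffusion_coefficient, x$spec$accumulation_rate,
              x$spec$bleach_rate))
  invisible(x)
}

#' Write a synthetic fixture to disk
#'
#' Writes the mixed stack as a multi-page TIFF, the truth masks as
#' single-page TIFFs, and the generating parameters as a YAML file that
#' [read_fixture_spec()] re-parses to an equal [fixture_spec()].
#'
#' @param fixture a [generate_fixture()] result.
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "pc_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    stack = file.path(dir, "stack.tif"),
    injection_mask = file.path(dir, "injection_mask.tif"),
    accumulation_mask = file.path(dir, "accumulation_mask.tif"),
    spec = file.path(dir, "fixture.yaml"))
  write_stack(fixture$stack, paths[["stack"]], dtype = "float")
  write_stack(frame_stack(fixture$truth$injection_mask * 1),
              paths[["injection_mask"]], dtype = "uint8")
  write_stack(frame_stack(fixture$truth$accumulation_mask * 1),
              paths[["accumulation_mask"]], dtype = "uint8")
  sp <- fixture$spec
  flat <- list(
    shape = as.integer(sp$shape), frames = sp$frames, layout = sp$layout,
    injection_center = as.integer(sp$injection_center),
    injection_radius = sp$injection_radius,
    diffusion_coefficient = sp$diffusion_coefficient,
    accumulation_rate = sp$accumulation_rate, bleach_rate = sp$bleach_rate,
    peak_intensity = sp$peak_intensity, noise_sd = sp$noise_sd,
    poisson = sp$poisson, photons = sp$photons, seed = sp$seed)
  yaml::write_yaml(flat, paths[["spec"]])
  invisible(paths)
}

#' Re-read a fixture specification written by [write_fixture()]
#'
#' Geometry masks are rebuilt from `shape` with the default geometry, so
#' only fixtures using the default geometry round-trip exactly.
#'
#' @param path path to `fixture.yaml`.
#' @return A [fixture_spec()].
#' @export
read_fixture_spec <- function(path) {
  y <- yaml::read_yaml(path)
  fixture_spec(shape = y$shape, frames = y$frames, layout = y$layout,
               injection_center = y$injection_center,
               injection_radius = y$injection_radius,
               diffusion_coefficient = y$diffusion_coefficient,
               accumulation_rate = y$accumulation_rate,
               bleach_rate = y$bleach_rate, peak_intensity = y$peak_intensity,
               noise_sd = y$noise_sd, poisson = y$poisson,
               photons = y$photons, seed = y$seed)
}
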