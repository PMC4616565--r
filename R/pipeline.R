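#' Configuration for a full pipeline run
#'
#' Collects every tunable of the workflow with its default: channel-split
#' layout, temporal-filter shape, cell-segmentation opening radius,
#' migration-map thresholds, ROI seeds and growth parameters (at most
#' `max_seeds` regions of at most `cap` pixels each), and whether bleach
#' correction is applied.
#'
#' @param input path to the mixed two-channel multi-page TIFF.
#' @param out_dir output directory for all artifacts.
#' @param seeds ROI seeds: a list of (row, col) pairs, optionally named, or
#'   an n x 2 matrix. `NULL` tracks no user ROI (background and total are
#'   still reported).
#' @param layout frame layout for [split_channels()] (default `"auto"`).
#' @param sigma,width temporal Gaussian parameters (defaults 1, 5).
#' @param opening_radius [segment_cell()] disk radius (default 1).
#' @param early_fraction,delta,sat_threshold,bright_quantile,bright_floor,dark_sd_factor
#'   migration-map thresholds, see [map_params()].
#' @param tolerance,cap [grow_region()] parameters (defaults 0.1, 250).
#' @param max_seeds maximum tracked ROIs (default 10).
#' @param bleach_correction apply [bleach_correct()] (default `TRUE`).
#' @param log_level `"info"` or `"quiet"`.
#' @return A `pipeline_config` list with defaults resolved.
#' @export
pipeline_config <- function(input, out_dir, seeds = NULL,
                            layout = c("auto", "interleaved", "blocked"),
                            sigma = 1, width = 5L, opening_radius = 1L,
                            early_fraction = 0.1, delta = 0.2,
                            sat_threshold = 0.95, bright_quantile = 0.99,
                            bright_floor = 0.2, dark_sd_factor = 0.5,
                            tolerance = 0.1, cap = 250L, max_seeds = 10L,
                            bleach_correction = TRUE,
                            log_level = c("info", "quiet")) {
  layout <- match.arg(layout)
  log_level <- match.arg(log_level)
  if (cap < 1L) stop("'cap' must be >= 1")
  if (max_seeds < 1L) stop("'max_seeds' must be >= 1")
  if (width %% 2 == 0) stop("'width' must be odd")
  if (!is.null(seeds)) {
    if (is.matrix(seeds))
      seeds <- stats::setNames(lapply(seq_len(nrow(seeds)),
                                      function(i) seeds[i, 1:2]),
                               rownames(seeds))
    if (!is.list(seeds) || !all(vapply(seeds, length, 1L) == 2L))
      stop("'seeds' must be a list of (row, col) pairs or an n x 2 matrix")
  }
  structure(
    list(input = input, out_dir = out_dir, seeds = seeds, layout = layout,
         sigma = sigma, width = as.integer(width),
         opening_radius = as.integer(opening_radius),
         early_fraction = early_fraction, delta = delta,
         sat_threshold = sat_threshold, bright_quantile = bright_quantile,
         bright_floor = bright_floor, dark_sd_factor = dark_sd_factor,
         tolerance = tolerance, cap = as.integer(cap),
         max_seeds = as.integer(max_seeds),
         bleach_correction = isTRUE(bleach_correction),
         log_level = log_level),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' The effective configuration (all defaults resolved) is written next to
#' the outputs of every run, so a run can be reproduced exactly from its
#' own artifact directory.
#'
#' @param config a [pipeline_config()].
#' @param path YAML path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- unclass(config)
  y$seeds <- if (is.null(y$seeds)) list() else
    lapply(y$seeds, function(s) as.integer(s))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seeds <- if (length(y$seeds) == 0L) NULL else y$seeds
  pipeline_config(
    input = y$input, out_dir = y$out_dir, seeds = seeds, layout = y$layout,
    sigma = y$sigma, width = y$width, opening_radius = y$opening_radius,
    early_fraction = y$early_fraction, delta = y$delta,
    sat_threshold = y$sat_threshold, bright_quantile = y$bright_quantile,
    bright_floor = y$bright_floor, dark_sd_factor = y$dark_sd_factor,
    tolerance = y$tolerance, cap = y$cap, max_seeds = y$max_seeds,
    bleach_correction = y$bleach_correction, log_level = y$log_level)
}

#' Run the full photo-conversion analysis workflow
#'
#' Executes, in order: stack ingest, variance-based channel split, red
#' preprocessing (median, temporal Gaussian, background subtraction,
#' contrast stretch), statistical model, cell segmentation, migration-map
#' classification, seeded ROI growth on the mean image, trace tracking,
#' photobleach reporting and (optionally) correction, and artifact export.
#'
#' The pre-conversion red frame serves as the background reference and is
#' excluded from trace tracking and bleach accounting (its total signal is
#' zero after background subtraction). The photobleach percentage is
#' measured on the median-filtered, unstretched stack, where totals still
#' carry physical units; bleach *correction* of the ROI traces uses the
#' total trace of the same processed stack the traces are measured on.
#'
#' Artifacts written to `out_dir`: `mean.tif`, `sd.tif`,
#' `migration_map.tif`, `class_counts.csv`, `traces.csv`, `traces.png`,
#' `config.yaml`, `run.log`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a `pipeline_result`: list with `split`, `preprocess`,
#'   `model`, `mask`, `map`, `rois`, `traces`, `bleach_percent`, and
#'   `artifacts` (named file paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, log_con)
    if (config$log_level == "info") message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  say("input: %s", config$input)
  mixed <- stage("read", read_stack(config$input))
  say("read %d frames of %d x %d", n_frames(mixed), dim(mixed)[1], dim(mixed)[2])

  split <- stage("split", split_channels(mixed, config$layout))
  say("channel split (%s): %d green / %d red, variance ratio %.3g",
      split$layout, n_frames(split$green), n_frames(split$red),
      split$variance_ratio)

  prep <- stage("preprocess",
                preprocess_red(split$red, config$sigma, config$width))
  model <- stage("stat_model", build_stat_model(prep$stack))
  mask <- stage("segment", segment_cell(model, config$opening_radius))
  say("cell mask: %d px above SD threshold %.4g", sum(mask$mask), mask$threshold)

  params <- map_params(config$early_fraction, config$delta,
                       config$sat_threshold, config$bright_quantile,
                       config$bright_floor, config$dark_sd_factor)
  map <- stage("migration_map", classify_pixels(prep$stack, mask, params))
  say("migration map: %s",
      paste(sprintf("%s=%d", names(map$counts), map$counts), collapse = ", "))
  if (!is.null(map$injection_point))
    say("estimated conversion point: (%d, %d)",
        map$injection_point[1], map$injection_point[2])

  rois <- list()
  if (!is.null(config$seeds)) {
    seeds <- config$seeds
    if (length(seeds) > config$max_seeds) {
      warning(sprintf("%d seeds supplied; only the first %d are used",
                      length(seeds), config$max_seeds))
      say("WARNING: %d seeds supplied; truncated to %d",
          length(seeds), config$max_seeds)
      seeds <- seeds[seq_len(config$max_seeds)]
    }
    nm <- names(seeds)
    rois <- stage("grow_rois", lapply(seq_along(seeds), function(i)
      grow_region(model$mean_image, seeds[[i]], config$tolerance, config$cap,
                  name = if (!is.null(nm) && nzchar(nm[i])) nm[i]
                         else sprintf("roi%d", i))))
    for (r in rois)
      say("roi '%s': %d px from seed (%d, %d)", r$name, nrow(r$members),
          r$seed[1], r$seed[2])
  }

  # Post-conversion frames only: the pre-conversion frame is the
  # background reference and has no converted signal to track.
  post <- seq(2L, n_frames(prep$stack))
  bleach_percent <- NA_real_
  if (any(mask$mask) && length(post) >= 2L) {
    raw_total <- colSums(matrix(prep$stages$median$pixels,
                                ncol = n_frames(prep$stack))[as.vector(mask$mask),
                                                             post, drop = FALSE])
    if (raw_total[1] > 0) bleach_percent <- photobleach_report(raw_total)
  }
  if (!is.na(bleach_percent))
    say("photobleaching: %.3f%% drop in total cell fluorescence", bleach_percent)

  traces <- NULL
  if (any(mask$mask) && !all(mask$mask)) {
    traces <- stage("track",
                    track_rois(subset_frames(prep$stack, post),
                               if (length(rois)) rois else
                                 list(fixed_area_roi(which_max_rc(model$mean_image),
                                                     2, dim(model$mean_image),
                                                     name = "auto_peak")),
                               mask, config$max_seeds))
    if (config$bleach_correction && all(traces$total_trace > 0))
      traces <- stage("bleach_correct", bleach_correct(traces))
  }

  art <- c(mean = file.path(config$out_dir, "mean.tif"),
           sd = file.path(config$out_dir, "sd.tif"),
           map = file.path(config$out_dir, "migration_map.tif"),
           counts = file.path(config$out_dir, "class_counts.csv"),
           traces = file.path(config$out_dir, "traces.csv"),
           plot = file.path(config$out_dir, "traces.png"),
           config = file.path(config$out_dir, "config.yaml"),
           log = log_path)
  stage("export", {
    export_stat_model(model, art[["mean"]], art[["sd"]])
    export_migration_map(map, art[["map"]], art[["counts"]])
    if (!is.null(traces)) {
      export_traces(traces, art[["traces"]])
      plot_traces(traces, art[["plot"]])
    }
    write_pipeline_config(config, art[["config"]])
  })
  for (p in art) say("artifact: %s", p)

  invisible(structure(
    list(split = split, preprocess = prep, model = model, mask = mask,
         map = map, rois = rois, traces = traces,
         bleach_percent = bleach_percent, artifacts = art),
    class = "pipeline_result"
  ))
}

# (row, col) of the maximum of a matrix (first in column-major order).
which_max_rc <- function(m) {
  i <- which.max(m)
  c(((i - 1L) %% nrow(m)) + 1L, ((i - 1L) %/% nrow(m)) + 1L)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$split); print(x$mask); print(x$map)
  if (!is.na(x$bleach_percent))
    cat(sprintf("photobleaching: %.3f%%\n", x$bleach_percent))
  invisible(x)
}
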