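#' Analysis configuration for a single-cell mask track
#'
#' Bundles the physical calibration of a time-lapse sequence with the
#' thresholds used downstream: the minimum centroid displacement below which
#' a step is treated as stationary, the elongation below which the fitted
#' major axis is considered unreliable, the coarse-grain band table and the
#' behaviour-rule thresholds.
#'
#' @param pixel_size_um Pixel size in micrometres per pixel (> 0).
#' @param frame_interval_s Time between consecutive frames in seconds (> 0).
#' @param min_displacement_px Centroid displacements shorter than this many
#'   pixels are flagged as zero displacement and yield no direction-dependent
#'   descriptors. Default 0.25 px: sub-quarter-pixel centroid shifts are
#'   dominated by segmentation noise.
#' @param low_elongation_cutoff Elongation at or below which the major-axis
#'   orientation is considered unreliable (near-circular shape). Default 0.1,
#'   the upper edge of the "low" elongation band.
#' @param dphi_clockwise_positive If `TRUE` (default) major-axis dynamics are
#'   signed clockwise-positive on screen, the same handedness as the turning
#'   angle. Set `FALSE` to flip the sign of the reported M.A. dynamics.
#' @param bands Coarse-grain band table, see [coarse_bands()].
#' @param rules Behaviour-rule thresholds, see [behaviour_rules()].
#'
#' @return An object of class `track_config` (a named list).
#' @seealso [read_track_config()], [write_track_config()]
#' @export
#' @examples
#' cfg <- track_config(pixel_size_um = 0.65, frame_interval_s = 20)
#' cfg$min_displacement_px
track_config <- function(pixel_size_um = 1,
                         frame_interval_s = 1,
                         min_displacement_px = 0.25,
                         low_elongation_cutoff = 0.1,
                         dphi_clockwise_positive = TRUE,
                         bands = coarse_bands(),
                         rules = behaviour_rules()) {
  stopifnot(
    is.numeric(pixel_size_um), length(pixel_size_um) == 1,
    is.finite(pixel_size_um), pixel_size_um > 0,
    is.numeric(frame_interval_s), length(frame_interval_s) == 1,
    is.finite(frame_interval_s), frame_interval_s > 0,
    is.numeric(min_displacement_px), is.finite(min_displacement_px),
    min_displacement_px >= 0,
    is.numeric(low_elongation_cutoff), is.finite(low_elongation_cutoff),
    low_elongation_cutoff >= 0, low_elongation_cutoff < 1,
    is.logical(dphi_clockwise_positive), length(dphi_clockwise_positive) == 1
  )
  validate_bands(bands)
  structure(
    list(
      pixel_size_um = pixel_size_um,
      frame_interval_s = frame_interval_s,
      min_displacement_px = min_displacement_px,
      low_elongation_cutoff = low_elongation_cutoff,
      dphi_clockwise_positive = dphi_clockwise_positive,
      bands = bands,
      rules = rules
    ),
    class = "track_config"
  )
}

#' @export
print.track_config <- function(x, ...) {
  cat("<track_config>\n")
  cat("  pixel size        :", x$pixel_size_um, "um/px\n")
  cat("  frame interval    :", x$frame_interval_s, "s\n")
  cat("  min displacement  :", x$min_displacement_px, "px\n")
  cat("  low-elongation cut:", x$low_elongation_cutoff, "\n")
  cat("  dphi clockwise +  :", x$dphi_clockwise_positive, "\n")
  invisible(x)
}

#' Read or write a track configuration as YAML
#'
#' Serializes every scalar threshold plus the band table; the behaviour rule
#' thresholds are stored under `rules`. Fields absent from the file fall back
#' to the defaults of [track_config()].
#'
#' @param path Path to a YAML file.
#' @return `read_track_config()` returns a `track_config`;
#'   `write_track_config()` invisibly returns `path`.
#' @export
read_track_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$pixel_size_um)) {
    stop("config file '", path, "' does not define pixel_size_um", call. = FALSE)
  }
  if (is.null(raw$frame_interval_s)) {
    stop("config file '", path, "' does not define frame_interval_s", call. = FALSE)
  }
  defaults <- formals(track_config)
  args <- list(
    pixel_size_um = raw$pixel_size_um,
    frame_interval_s = raw$frame_interval_s
  )
  for (f in c("min_displacement_px", "low_elongation_cutoff",
              "dphi_clockwise_positive")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$bands)) args$bands <- bands_from_list(raw$bands)
  if (!is.null(raw$rules)) args$rules <- do.call(behaviour_rules, raw$rules)
  do.call(track_config, args)
}

#' @rdname read_track_config
#' @param config A `track_config`.
#' @export
write_track_config <- function(config, path) {
  stopifnot(inherits(config, "track_config"))
  out <- list(
    pixel_size_um = config$pixel_size_um,
    frame_interval_s = config$frame_interval_s,
    min_displacement_px = config$min_displacement_px,
    low_elongation_cutoff = config$low_elongation_cutoff,
    dphi_clockwise_positive = config$dphi_clockwise_positive,
    bands = bands_to_list(config$bands),
    rules = unclass(config$rules)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
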