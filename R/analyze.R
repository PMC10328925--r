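#' Analyse a mask stack end to end
#'
#' Runs the full pipeline: single-component selection, second-moment ellipse
#' fits, per-step kinematics (displacement, uMM/sMM, turning angle, M.A.
#' dynamics), coarse-grain labelling, behaviour annotation and per-track
#' summary.
#'
#' @param stack A [mask_stack()] (or a path readable by
#'   [read_mask_stack()]).
#' @param config A [track_config()]; defaults to the stack's own config.
#' @param component_policy Passed to [select_components()].
#' @param resample_k Optional integer: analyse every k-th frame (see
#'   [resample_track()]).
#' @return A list of class `morphomig_analysis`: `shapes`, `track` (the
#'   annotated per-frame table), `segments`, `census`, `summary`, `config`.
#' @export
#' @examples
#' sim <- simulate_scenario("lateral_mover", n_frames = 12)
#' res <- analyze_stack(sim$stack)
#' table(res$track$behaviour)
analyze_stack <- function(stack, config = NULL,
                          component_policy = c("largest", "nearest"),
                          resample_k = 1L) {
  component_policy <- match.arg(component_policy)
  if (is.character(stack)) {
    stack <- read_mask_stack(stack, config %||% track_config())
  }
  stopifnot(inherits(stack, "mask_stack"))
  config <- config %||% stack$config
  stack$config <- config
  if (length(stack) < 2) stop("need >= 2 frames to analyse a track", call. = FALSE)
  if (resample_k > 1L) stack <- resample_track(stack, resample_k)
  stack <- select_components(stack, policy = component_policy)
  shapes <- fit_shapes(stack)
  steps <- compute_track(shapes, config)
  labelled <- label_track(steps, config)
  annotated <- annotate_behaviours(labelled, config$rules)
  segments <- attr(annotated, "segments")
  structure(
    list(shapes = shapes,
         track = annotated,
         segments = segments,
         census = behaviour_census(segments, config$frame_interval_s),
         summary = summarize_track(annotated),
         config = config),
    class = "morphomig_analysis"
  )
}

#' @export
print.morphomig_analysis <- function(x, ...) {
  n <- nrow(x$track)
  cat("<morphomig_analysis> ", n, " frames, ",
      sum(!is.na(x$track$smm_deg)), " valid sMM steps\n", sep = "")
  print(x$summary$stats)
  invisible(x)
}

#' Write every table of an analysis to a directory
#'
#' Writes `steps.csv` (the per-frame step table), `segments.csv`,
#' `census.csv`, `summary_stats.csv` and `histograms.csv`.
#'
#' @param analysis A `morphomig_analysis` from [analyze_stack()].
#' @param dir Output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "morphomig_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    steps = file.path(dir, "steps.csv"),
    segments = file.path(dir, "segments.csv"),
    census = file.path(dir, "census.csv"),
    summary_stats = file.path(dir, "summary_stats.csv"),
    histograms = file.path(dir, "histograms.csv")
  )
  write_step_table(analysis$track, paths["steps"])
  utils::write.csv(analysis$segments, paths["segments"], row.names = FALSE, na = "")
  utils::write.csv(analysis$census, paths["census"], row.names = FALSE, na = "")
  utils::write.csv(analysis$summary$stats, paths["summary_stats"],
                   row.names = FALSE, na = "")
  utils::write.csv(analysis$summary$histograms, paths["histograms"],
                   row.names = FALSE, na = "")
  invisible(paths)
}
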