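#' Per-track summary of the morphomigrational descriptors
#'
#' Signed arithmetic mean and sample standard deviation of sMM, turning
#' angle, M.A. dynamics and elongation over the steps where each descriptor
#' is defined and unflagged, plus fixed-width histograms and the paired
#' per-step value tables behind sMM-versus-X scatter plots. Means are signed:
#' a cell migrating laterally with occasional side changes can average near
#' zero even though its |sMM| is not small, which is the intended reading.
#'
#' @param track A computed (optionally labelled/annotated) track.
#' @param bin_width_deg Histogram bin width in degrees (default 10).
#' @return A list of class `track_summary`: `stats` (tibble with
#'   `descriptor`, `mean`, `sd`, `n`), `histograms` (tibble with
#'   `descriptor`, `bin_lo`, `bin_hi`, `count`), `pairs` (tibble with one
#'   row per step carrying `smm_deg`, `turning_deg`, `ma_dynamics_deg`,
#'   `elongation` and, when present, `behaviour`).
#' @export
summarize_track <- function(track, bin_width_deg = 10) {
  stopifnot(is.data.frame(track), bin_width_deg > 0)
  desc <- list(
    smm_deg = c(-90, 90),
    turning_deg = c(-180, 180),
    ma_dynamics_deg = c(-90, 90),
    elongation = c(0, 1)
  )
  stats <- dplyr::bind_rows(lapply(names(desc), function(d) {
    v <- track[[d]][!is.na(track[[d]])]
    tibble::tibble(descriptor = d,
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                   n = length(v))
  }))
  hists <- dplyr::bind_rows(lapply(
    c("smm_deg", "turning_deg", "ma_dynamics_deg"), function(d) {
      v <- track[[d]][!is.na(track[[d]])]
      dom <- desc[[d]]
      edges <- seq(dom[1], dom[2], by = bin_width_deg)
      if (edges[length(edges)] < dom[2]) edges <- c(edges, dom[2])
      counts <- if (length(v)) {
        tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                 nbins = length(edges) - 1)
      } else {
        integer(length(edges) - 1)
      }
      tibble::tibble(descriptor = d,
                     bin_lo = edges[-length(edges)],
                     bin_hi = edges[-1],
                     count = counts)
    }))
  keep <- c("frame", "time_s", "smm_deg", "turning_deg", "ma_dynamics_deg",
            "elongation", "behaviour")
  pairs <- tibble::as_tibble(track[, intersect(keep, names(track))])
  structure(list(stats = stats, histograms = hists, pairs = pairs),
            class = "track_summary")
}

#' @export
print.track_summary <- function(x, ...) {
  cat("<track_summary>\n")
  print(x$stats)
  invisible(x)
}

#' Long-format behaviour profiles across tracks
#'
#' One row per (track, frame) with the behaviour label and the absolute
#' descriptor values plus elongation: the data behind parallel-coordinate
#' comparisons of behaviours shared between cells. Steps without a behaviour
#' label are dropped.
#'
#' @param tracks A named list of annotated tracks (see
#'   [annotate_behaviours()]); names identify the tracks in the output.
#' @return Tibble with `track`, `frame`, `behaviour`, `abs_smm_deg`,
#'   `abs_turning_deg`, `abs_dphi_deg`, `elongation`.
#' @export
compare_behaviour_profiles <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  if (is.data.frame(tracks)) tracks <- list(track1 = tracks)
  if (is.null(names(tracks)) || any(names(tracks) == "")) {
    names(tracks) <- paste0("track", seq_along(tracks))
  }
  dplyr::bind_rows(lapply(names(tracks), function(nm) {
    tr <- tracks[[nm]]
    stopifnot(is.data.frame(tr), "behaviour" %in% names(tr))
    keep <- !is.na(tr$behaviour)
    tibble::tibble(
      track = nm,
      frame = tr$frame[keep],
      behaviour = tr$behaviour[keep],
      abs_smm_deg = abs(tr$smm_deg[keep]),
      abs_turning_deg = abs(tr$turning_deg[keep]),
      abs_dphi_deg = abs(tr$ma_dynamics_deg[keep]),
      elongation = tr$elongation[keep]
    )
  }))
}
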