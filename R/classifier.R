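#' Default coarse-grain band table
#'
#' The mapping of numeric descriptor values onto verbal categories. Signed
#' descriptors (sMM, turning angle, M.A. dynamics) are banded on their
#' absolute value, with the sign reported separately; the negative and
#' positive ranges carry identical labels. Intervals are left-open,
#' right-closed, except the first which also contains its lower edge, so the
#' bands partition each parameter's domain exactly:
#'
#' * sMM angle (deg): very_low \[0, 15\], low (15, 45\], moderate (45, 70\],
#'   high (70, 90\]
#' * turning angle (deg): low \[0, 60\], moderate (60, 90\], high (90, 135\],
#'   very_high (135, 180\]
#' * M.A. dynamics (deg): very_low \[0, 10\], low (10, 20\], moderate
#'   (20, 45\], high (45, 60\], very_high (60, 90\]
#' * elongation: low \[0, 0.1\], moderate (0.1, 0.6\], high (0.6, 1\]
#'
#' @return A named list with elements `smm`, `alpha`, `dphi`, `eps`; each a
#'   list with numeric `breaks` (band edges including both domain ends) and
#'   character `labels` (one fewer than breaks).
#' @export
#' @examples
#' coarse_bands()$smm
coarse_bands <- function() {
  list(
    smm   = list(breaks = c(0, 15, 45, 70, 90),
                 labels = c("very_low", "low", "moderate", "high")),
    alpha = list(breaks = c(0, 60, 90, 135, 180),
                 labels = c("low", "moderate", "high", "very_high")),
    dphi  = list(breaks = c(0, 10, 20, 45, 60, 90),
                 labels = c("very_low", "low", "moderate", "high", "very_high")),
    eps   = list(breaks = c(0, 0.1, 0.6, 1),
                 labels = c("low", "moderate", "high"))
  )
}

validate_bands <- function(bands) {
  stopifnot(is.list(bands),
            all(c("smm", "alpha", "dphi", "eps") %in% names(bands)))
  for (p in c("smm", "alpha", "dphi", "eps")) {
    b <- bands[[p]]
    if (!is.numeric(b$breaks) || any(!is.finite(b$breaks)) ||
        is.unsorted(b$breaks, strictly = TRUE) ||
        length(b$labels) != length(b$breaks) - 1 ||
        b$breaks[1] != 0) {
      stop("invalid band definition for parameter '", p,
           "': breaks must be strictly increasing from 0 with one label per interval",
           call. = FALSE)
    }
  }
  invisible(bands)
}

bands_to_list <- function(bands) {
  lapply(bands, function(b) list(breaks = b$breaks, labels = b$labels))
}

bands_from_list <- function(x) {
  validate_bands(lapply(x, function(b) {
    list(breaks = as.numeric(b$breaks), labels = as.character(b$labels))
  }))
}

#' Classify descriptor values into coarse-grain bands
#'
#' Maps numeric values of one descriptor onto its verbal category. The label
#' depends only on the absolute value (for signed descriptors) and the band
#' table; neighbouring frames play no role. `NA` input yields `NA` output.
#'
#' @param value Numeric vector of descriptor values. Domains: sMM and M.A.
#'   dynamics in \[-90, 90\]; turning angle in \[-180, 180\]; elongation in
#'   \[0, 1\].
#' @param parameter One of `"smm"`, `"alpha"`, `"dphi"`, `"eps"`.
#' @param bands Band table as produced by [coarse_bands()].
#' @return Character vector of labels.
#' @export
#' @examples
#' classify_value(c(13.5, -75.9), "dphi")
#' classify_value(0, "eps")
classify_value <- function(value, parameter = c("smm", "alpha", "dphi", "eps"),
                           bands = coarse_bands()) {
  parameter <- match.arg(parameter)
  b <- bands[[parameter]]
  domain_max <- b$breaks[length(b$breaks)]
  v <- if (parameter == "eps") value else abs(value)
  bad <- !is.na(v) & (v < 0 | v > domain_max)
  if (any(bad)) {
    stop("value out of domain for parameter '", parameter, "': ",
         paste(utils::head(value[bad], 3), collapse = ", "), call. = FALSE)
  }
  as.character(cut(v, breaks = b$breaks, labels = b$labels,
                   include.lowest = TRUE, right = TRUE))
}

descriptor_sign <- function(value) {
  ifelse(is.na(value), NA_character_, ifelse(value < 0, "-", "+"))
}

#' Attach coarse-grain labels to a computed track
#'
#' Adds, for each per-frame step record, the band label of sMM, turning
#' angle, M.A. dynamics and elongation plus the sign of the three signed
#' descriptors. Steps whose descriptors are undefined (flagged or at track
#' edges) receive `NA` labels; the low-elongation flag is carried through.
#'
#' @param steps A step table from [compute_track()].
#' @param config A [track_config()] supplying the band table.
#' @return `steps` with columns `smm_label`, `alpha_label`, `dphi_label`,
#'   `eps_label`, `smm_sign`, `alpha_sign`, `dphi_sign` appended.
#' @export
label_track <- function(steps, config = track_config()) {
  stopifnot(is.data.frame(steps))
  bands <- config$bands
  steps$smm_label <- classify_value(steps$smm_deg, "smm", bands)
  steps$alpha_label <- classify_value(steps$turning_deg, "alpha", bands)
  steps$dphi_label <- classify_value(steps$ma_dynamics_deg, "dphi", bands)
  steps$eps_label <- classify_value(steps$elongation, "eps", bands)
  steps$smm_sign <- descriptor_sign(steps$smm_deg)
  steps$alpha_sign <- descriptor_sign(steps$turning_deg)
  steps$dphi_sign <- descriptor_sign(steps$ma_dynamics_deg)
  steps
}
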