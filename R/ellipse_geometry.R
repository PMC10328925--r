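#' Central image moments of a binary mask
#'
#' Pixels are treated as unit point masses at their integer centre
#' coordinates (x = column, y = row). Second moments are central and
#' normalized by the pixel count, i.e. they are the population (co)variances
#' of the foreground pixel coordinates.
#'
#' @param mask Matrix; nonzero pixels are foreground.
#' @return Named numeric vector with `m00` (pixel count), `cx`, `cy`
#'   (centroid, px) and `mu20`, `mu11`, `mu02` (central second moments, px^2).
#' @export
#' @examples
#' m <- matrix(0, 3, 5); m[1, 1:3] <- 1
#' central_moments(m) # horizontal 3-px bar: mu20 = 2/3, mu02 = 0
central_moments <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) stop("mask contains no foreground pixels", call. = FALSE)
  x <- idx[, 2]
  y <- idx[, 1]
  cx <- mean(x)
  cy <- mean(y)
  dx <- x - cx
  dy <- y - cy
  c(m00 = n, cx = cx, cy = cy,
    mu20 = sum(dx * dx) / n,
    mu11 = sum(dx * dy) / n,
    mu02 = sum(dy * dy) / n)
}

#' Fit the ellipse of identical second moments to a binary mask
#'
#' Returns the ellipse sharing the mask's centroid and central second
#' moments. With eigenvalues `l1 >= l2` of the pixel-coordinate covariance
#' matrix, the full axis lengths are `b = 4*sqrt(l1)` and `a = 4*sqrt(l2)`
#' (for an exactly elliptical region these equal its true axis lengths), the
#' orientation is `0.5 * atan2(2*mu11, mu20 - mu02)` mapped into \[0, 180)
#' degrees measured from +x toward +y (downward on screen; the axis is
#' undirected), and the elongation is `eps = 1 - a/b` in \[0, 1). Eigenvalues
#' are obtained in closed form from the 2x2 covariance, not by an iterative
#' eigendecomposition.
#'
#' Semi-axes are clamped from below to half a pixel so that degenerate masks
#' (single pixels, 1-px lines) yield finite geometry; such frames are marked
#' `degenerate`. Near-circular shapes are not an error: their orientation is
#' merely unstable, which downstream code tracks through the elongation.
#'
#' @param mask Matrix; nonzero pixels are foreground.
#' @param config A [track_config()] supplying the pixel size.
#' @param frame_index Frame number stored in the output row.
#' @param time_s Acquisition time stored in the output row.
#' @return One-row tibble: `frame`, `time_s`, `centroid_x_um`,
#'   `centroid_y_um`, `major_um`, `minor_um` (full axis lengths),
#'   `orientation_deg`, `elongation`, `area_um2`, `degenerate`.
#' @export
fit_shape <- function(mask, config = track_config(), frame_index = 1L,
                      time_s = (frame_index - 1) * config$frame_interval_s) {
  mom <- central_moments(mask)
  eig <- ellipse_from_moments(mom["mu20"], mom["mu11"], mom["mu02"])
  px <- config$pixel_size_um
  tibble::tibble(
    frame = as.integer(frame_index),
    time_s = time_s,
    centroid_x_um = unname(mom["cx"]) * px,
    centroid_y_um = unname(mom["cy"]) * px,
    major_um = eig$major_px * px,
    minor_um = eig$minor_px * px,
    orientation_deg = eig$phi_deg,
    elongation = eig$eps,
    area_um2 = unname(mom["m00"]) * px^2,
    degenerate = eig$degenerate
  )
}

# closed-form axes/orientation from central second moments (pixel units)
ellipse_from_moments <- function(mu20, mu11, mu02) {
  tr2 <- (mu20 + mu02) / 2
  det_part <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr2 + det_part
  l2 <- max(tr2 - det_part, 0)
  phi <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  phi <- phi %% 180
  semi_major <- 2 * sqrt(l1)
  semi_minor <- 2 * sqrt(l2)
  degenerate <- semi_minor < 0.5 || semi_major < 0.5
  semi_major <- max(semi_major, 0.5)
  semi_minor <- max(semi_minor, 0.5)
  list(
    major_px = unname(2 * semi_major),
    minor_px = unname(2 * semi_minor),
    phi_deg = unname(phi),
    eps = unname(1 - semi_minor / semi_major),
    degenerate = degenerate
  )
}

#' Fit shapes to every frame of a mask stack
#'
#' @param stack A [mask_stack()]; each frame should contain a single
#'   foreground component (see [select_components()]).
#' @return Tibble with one [fit_shape()] row per frame.
#' @export
fit_shapes <- function(stack) {
  stopifnot(inherits(stack, "mask_stack"))
  rows <- lapply(seq_along(stack$masks), function(i) {
    fit_shape(stack$masks[[i]], stack$config,
              frame_index = stack$frame_index[i], time_s = stack$time_s[i])
  })
  dplyr::bind_rows(rows)
}
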