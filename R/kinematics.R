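#' Signed angle between two vectors, clockwise-positive on screen
#'
#' In screen coordinates (x right, y down) a rotation from `p` to `q` that
#' appears clockwise has a positive angle. Computed as
#' `atan2(px*qy - py*qx, p . q)` in degrees, in the half-open range
#' (-180, 180].
#'
#' @param px,py,qx,qy Numeric vectors: components of `p` and `q`.
#' @return Numeric vector of angles in degrees; `NA` where either vector is
#'   zero or any component is `NA`.
#' @export
#' @examples
#' signed_angle(1, 0, 0, 1)  # right -> down on screen: +90
#' signed_angle(1, 0, 0, -1) # right -> up on screen:   -90
signed_angle <- function(px, py, qx, qy) {
  cross <- px * qy - py * qx
  dot <- px * qx + py * qy
  ang <- atan2(cross, dot) * 180 / pi
  ang[!is.na(ang) & ang <= -180] <- 180
  zero <- (px == 0 & py == 0) | (qx == 0 & qy == 0)
  ang[!is.na(zero) & zero] <- NA_real_
  unname(ang)
}

#' Propagate major-axis directions along a track
#'
#' The fitted major axis is undirected: orientations live in \[0, 180). To
#' compare axes across frames each is given a direction such that
#' consecutive unit vectors satisfy `u_n . u_(n-1) >= 0`; the first frame
#' uses `(cos phi_1, sin phi_1)`. This continuity bounds the frame-to-frame
#' axis rotation to \[-90, 90\] degrees. An exact perpendicular tie
#' (`dot == 0`) is resolved so the rotation from `u_(n-1)` to `u_n` is +90
#' degrees (clockwise on screen).
#'
#' @param phi_deg Numeric vector of orientations in degrees, one per frame.
#' @return An n x 2 matrix of unit vectors (columns `ux`, `uy`).
#' @export
propagate_axis_directions <- function(phi_deg) {
  n <- length(phi_deg)
  rad <- phi_deg * pi / 180
  u <- cbind(ux = cos(rad), uy = sin(rad))
  if (n < 2) return(u)
  for (i in 2:n) {
    d <- u[i, 1] * u[i - 1, 1] + u[i, 2] * u[i - 1, 2]
    if (d < 0) {
      u[i, ] <- -u[i, ]
    } else if (d == 0) {
      # tie: orient so the step from u[i-1] to u[i] is +90 (cross > 0)
      cross <- u[i - 1, 1] * u[i, 2] - u[i - 1, 2] * u[i, 1]
      if (cross < 0) u[i, ] <- -u[i, ]
    }
  }
  u
}

#' Unsigned morphomigrational angle
#'
#' The acute angle between the (undirected) major axis and the displacement
#' vector: `acos(|u . d| / |d|)` in degrees, in \[0, 90\]. Flipping the axis
#' direction leaves it unchanged.
#'
#' @param ux,uy Unit axis direction components.
#' @param dx,dy Displacement components.
#' @return Numeric vector in \[0, 90\] degrees; `NA` for zero displacement.
#' @export
umm_angle <- function(ux, uy, dx, dy) {
  len <- sqrt(dx^2 + dy^2)
  cosv <- abs(ux * dx + uy * dy) / len
  out <- acos(pmin(pmax(cosv, 0), 1)) * 180 / pi
  out[!is.na(len) & len == 0] <- NA_real_
  out
}

#' Compute per-step kinematic descriptors for a track of fitted shapes
#'
#' For a track of N frames, row n of the result describes the step from
#' frame n to frame n + 1 (displacement, speed, uMM, sMM, M.A. dynamics),
#' while the turning angle at row n is measured between the previous and the
#' current displacement and therefore exists for n = 2..N-1. The last row
#' carries shape descriptors only.
#'
#' The sMM sign follows a first-frame side reference: `side` is the sign of
#' the 2-D cross product between the propagated axis direction and the
#' displacement; the reference side is the side at the first unflagged step
#' with nonzero side and is never reset. Steps on the reference side get
#' `+uMM`, steps on the opposite side `-uMM`, and motion exactly along the
#' axis `+0`. Steps preceding the first side-defining step are flagged
#' `flag_no_reference_side` and reported with positive sign.
#'
#' Steps whose centroid displacement is below `min_displacement_px` are
#' flagged `flag_zero_displacement` and yield no uMM/sMM; turning angles
#' adjacent to such steps are undefined. Frames with elongation at or below
#' `low_elongation_cutoff` are flagged `flag_low_elongation`: their
#' orientation-dependent descriptors are still computed but should be read
#' with caution, as a near-circular shape orients its fitted axis almost
#' randomly.
#'
#' @param shapes Tibble from [fit_shapes()] (>= 2 rows).
#' @param config A [track_config()].
#' @return Tibble with one row per frame: the [fit_shape()] columns plus
#'   `axis_ux`, `axis_uy`, `disp_x_um`, `disp_y_um`, `disp_um`,
#'   `speed_um_s`, `umm_deg`, `smm_deg`, `side`, `turning_deg`,
#'   `ma_dynamics_deg`, `flag_zero_displacement`, `flag_low_elongation`,
#'   `flag_no_reference_side`, `flag_degenerate`.
#' @export
compute_track <- function(shapes, config = track_config()) {
  stopifnot(is.data.frame(shapes))
  n <- nrow(shapes)
  if (n < 2) stop("need >= 2 frames to compute a track", call. = FALSE)
  dt <- diff(shapes$time_s)
  if (any(dt <= 0)) stop("frame times must be strictly increasing", call. = FALSE)

  u <- propagate_axis_directions(shapes$orientation_deg)

  dx <- c(diff(shapes$centroid_x_um), NA_real_)
  dy <- c(diff(shapes$centroid_y_um), NA_real_)
  dlen <- sqrt(dx^2 + dy^2)
  speed <- dlen / c(dt, NA_real_)
  zero_flag <- dlen < config$min_displacement_px * config$pixel_size_um
  valid <- !is.na(zero_flag) & !zero_flag

  umm <- ifelse(valid, umm_angle(u[, 1], u[, 2], dx, dy), NA_real_)

  cross <- u[, 1] * dy - u[, 2] * dx
  side <- ifelse(valid, sign(cross), NA_real_)

  ref_candidates <- which(valid & side != 0)
  ref_idx <- if (length(ref_candidates)) ref_candidates[1] else NA_integer_
  ref_side <- if (is.na(ref_idx)) NA_real_ else side[ref_idx]

  no_ref <- valid & (if (is.na(ref_idx)) TRUE else seq_len(n) < ref_idx)
  smm_sign <- rep(1, n)
  if (!is.na(ref_idx)) {
    opposite <- valid & side != 0 & side != ref_side & seq_len(n) >= ref_idx
    smm_sign[opposite] <- -1
  }
  smm <- ifelse(valid, smm_sign * umm, NA_real_)

  # turning angle at row n: previous displacement (n-1) vs current (n)
  alpha <- rep(NA_real_, n)
  if (n >= 3) {
    idx <- 2:(n - 1)
    ok <- valid[idx - 1] & valid[idx]
    alpha[idx[ok]] <- signed_angle(dx[idx[ok] - 1], dy[idx[ok] - 1],
                                   dx[idx[ok]], dy[idx[ok]])
  }

  # M.A. dynamics at row n: axis in frame n vs frame n+1
  dphi <- rep(NA_real_, n)
  dphi[seq_len(n - 1)] <- signed_angle(u[seq_len(n - 1), 1], u[seq_len(n - 1), 2],
                                       u[2:n, 1], u[2:n, 2])
  if (!config$dphi_clockwise_positive) dphi <- -dphi

  out <- tibble::as_tibble(shapes)
  out$axis_ux <- u[, 1]
  out$axis_uy <- u[, 2]
  out$disp_x_um <- dx
  out$disp_y_um <- dy
  out$disp_um <- dlen
  out$speed_um_s <- speed
  out$umm_deg <- umm
  out$smm_deg <- smm
  out$side <- side
  out$turning_deg <- alpha
  out$ma_dynamics_deg <- dphi
  out$flag_zero_displacement <- zero_flag
  out$flag_low_elongation <- out$elongation <= config$low_elongation_cutoff
  out$flag_no_reference_side <- c(no_ref)
  out$flag_degenerate <- out$degenerate
  out$degenerate <- NULL
  out
}

#' Resample a track to a coarser frame interval
#'
#' Keeps frames 1, 1+k, 1+2k, ... and rescales the time metadata so that
#' downstream descriptors are computed at the interval `k * dt`. Works on a
#' [mask_stack()] or on a fitted-shape table. The per-step descriptors of
#' the sMM family are interval-dependent by nature, so results at different
#' `k` are different views of the same motion, not noise.
#'
#' @param x A [mask_stack()] or a tibble from [fit_shapes()].
#' @param k Positive integer subsampling factor, smaller than the number of
#'   frames.
#' @return An object of the same type as `x` with `ceiling(N / k)` frames.
#' @export
resample_track <- function(x, k) {
  stopifnot(length(k) == 1, k == as.integer(k), k >= 1)
  k <- as.integer(k)
  if (inherits(x, "mask_stack")) {
    n <- length(x$masks)
    if (k >= n && k > 1) stop("k must be smaller than the number of frames", call. = FALSE)
    keep <- seq(1L, n, by = k)
    cfg <- x$config
    cfg$frame_interval_s <- cfg$frame_interval_s * k
    return(mask_stack(x$masks[keep], cfg))
  }
  stopifnot(is.data.frame(x))
  n <- nrow(x)
  if (k >= n && k > 1) stop("k must be smaller than the number of frames", call. = FALSE)
  keep <- seq(1L, n, by = k)
  out <- x[keep, , drop = FALSE]
  out$frame <- seq_along(keep)
  out
}
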