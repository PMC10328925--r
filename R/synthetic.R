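#' Rasterize an elliptical mask
#'
#' Pixel-centre inclusion test, no anti-aliasing: pixel (x, y) is foreground
#' iff `((D.e1)/semi_major)^2 + ((D.e2)/semi_minor)^2 <= 1` where `D` is the
#' offset from the centre and `e1` the major-axis direction at `theta_deg`
#' (degrees from +x toward +y). The result is exactly binary so the
#' second-moment fit has an analytic ground truth.
#'
#' @param center `c(x, y)` in pixel coordinates.
#' @param semi_minor,semi_major Semi-axis lengths in pixels (>= 2).
#' @param theta_deg Major-axis orientation in degrees.
#' @param canvas `c(rows, cols)` of the output matrix.
#' @return A 0/1 integer matrix.
#' @export
render_ellipse_mask <- function(center, semi_minor, semi_major, theta_deg,
                                canvas = c(512, 512)) {
  stopifnot(semi_minor >= 2, semi_major >= semi_minor)
  th <- theta_deg * pi / 180
  # axis-aligned bounding half-extents of the rotated ellipse
  rx <- sqrt((semi_major * cos(th))^2 + (semi_minor * sin(th))^2)
  ry <- sqrt((semi_major * sin(th))^2 + (semi_minor * cos(th))^2)
  if (center[1] - rx < 1 || center[1] + rx > canvas[2] ||
      center[2] - ry < 1 || center[2] + ry > canvas[1]) {
    stop("ellipse extends beyond the canvas", call. = FALSE)
  }
  x <- matrix(seq_len(canvas[2]), canvas[1], canvas[2], byrow = TRUE) - center[1]
  y <- matrix(seq_len(canvas[1]), canvas[1], canvas[2]) - center[2]
  p1 <- (x * cos(th) + y * sin(th)) / semi_major
  p2 <- (-x * sin(th) + y * cos(th)) / semi_minor
  (p1 * p1 + p2 * p2 <= 1) * 1L
}

# horizontal tapering tail attached at (cx, cy), extending towards -x:
# half-width w0 at the root, 1 px at the tip, length len
render_tail_mask <- function(center, len, w0, canvas) {
  m <- matrix(0L, canvas[1], canvas[2])
  if (len < 1) return(m)
  cx <- round(center[1]); cy <- round(center[2])
  cols <- seq.int(max(1L, cx - round(len)), cx)
  if (cx - round(len) < 1) stop("tail extends beyond the canvas", call. = FALSE)
  for (col in cols) {
    w <- max(1, w0 * (1 - (cx - col) / len))
    rows <- seq.int(floor(cy - w), ceiling(cy + w))
    m[rows, col] <- 1L
  }
  m
}

#' Perturb a mask boundary with a seeded noise field
#'
#' Emulates segmentation noise: a smoothed pseudo-random field locally
#' dilates or erodes the shape by up to `amplitude` pixels, by thresholding
#' the signed distance to the boundary against the field. `amplitude = 0`
#' returns the mask unchanged; a fixed seed reproduces the same field.
#'
#' @param mask A 0/1 matrix.
#' @param amplitude Maximum boundary displacement in pixels (>= 0).
#' @param seed Integer seed for the noise field.
#' @return A 0/1 integer matrix.
#' @export
add_boundary_noise <- function(mask, amplitude, seed = 1L) {
  stopifnot(amplitude >= 0)
  if (amplitude == 0) {
    storage.mode(mask) <- "integer"
    return(mask)
  }
  fg <- (mask != 0) * 1
  sdist <- EBImage::distmap(fg) - EBImage::distmap(1 - fg)
  noise <- withr::with_seed(seed, {
    matrix(stats::runif(length(mask), -1, 1), nrow(mask), ncol(mask))
  })
  smooth <- EBImage::gblur(noise, sigma = 2)
  # scale to RMS amplitude/2 and clip so no pixel moves more than amplitude
  smooth <- smooth / stats::sd(smooth) * (amplitude / 2)
  smooth <- pmin(pmax(smooth, -amplitude), amplitude)
  (sdist > smooth) * 1L
}

scenario_names <- c(
  "perpendicular_glider", "lateral_mover", "lateral_u_turn", "askew_mover",
  "rounding_cell", "perpendicular_stretch", "lateral_stretch",
  "tail_retraction", "rotating_ellipse", "disc_random_walk"
)

#' Simulate a synthetic single-cell mask sequence with ground truth
#'
#' Generates rasterized elliptical (or composite) shapes moving and morphing
#' according to one of ten scripted scenarios, each an idealisation of a
#' morphomigrational archetype:
#'
#' * `perpendicular_glider` — keratocyte-like fan translating perpendicular
#'   to its major axis.
#' * `lateral_mover` — elongated cell translating nearly along its major
#'   axis (heading 8 degrees off-axis so the displacement has a definite
#'   side).
#' * `lateral_u_turn` — lateral mover that reverses its heading at
#'   `event_frame`.
#' * `askew_mover` — elongated cell translating at 55 degrees to its axis.
#' * `rounding_cell` — elongated cell that rounds up (elongation ramps from
#'   0.30 down to 0.04 within four frames) while drifting.
#' * `perpendicular_stretch` — cell extending protrusions alternately on
#'   both sides of its axis (centroid oscillates perpendicular to the axis)
#'   while its major axis grows.
#' * `lateral_stretch` — elongated growing cell whose centroid reverses
#'   direction repeatedly along the axis.
#' * `tail_retraction` — body ellipse oriented across the travel direction
#'   plus a long tapering tail along it; the tail is withdrawn at
#'   `event_frame`, flipping the fitted axis by ~90 degrees in one step
#'   while the travel direction is unchanged.
#' * `rotating_ellipse` — stationary ellipse rigidly rotating at
#'   `rotation_deg_per_frame`.
#' * `disc_random_walk` — near-circular disc taking seeded random-direction
#'   steps.
#'
#' The ground-truth table records the programmed centroid and orientation
#' (`NA` where the construction has no simple closed form, e.g. the
#' composite tailed shape), the nominal elongation, and the behaviour label
#' each step is constructed to express (`NA` at the track edges, where
#' turning angles do not exist, and for the two scenarios that are not
#' behaviour archetypes). With `noise_amplitude = 0` everything is
#' deterministic except `disc_random_walk`, which is deterministic given
#' `seed`.
#'
#' @param name Scenario name, one of
#'   `morphomig:::scenario_names`.
#' @param n_frames Number of frames (scenario-specific defaults, 28-36).
#' @param seed Integer seed for the scenario's random draws (random-walk
#'   headings, boundary noise).
#' @param speed_px Step length in pixels per frame where the scenario
#'   translates.
#' @param event_frame Frame of the scripted event (reversal, retraction).
#' @param rotation_deg_per_frame Rigid rotation rate for `rotating_ellipse`.
#' @param noise_amplitude Boundary-noise amplitude in pixels (default 0).
#' @param canvas Canvas size `c(rows, cols)`.
#' @param config A [track_config()] for the generated stack.
#' @return A list of class `morphomig_simulation`: `stack` (a
#'   [mask_stack()]), `truth` (tibble `frame`, `cx_px`, `cy_px`,
#'   `orientation_deg`, `eps_true`, `behaviour`), `name`, `event_frame`.
#' @export
#' @examples
#' sim <- simulate_scenario("perpendicular_glider", n_frames = 10)
#' sim$truth$behaviour[5]
simulate_scenario <- function(name,
                              n_frames = NULL,
                              seed = 1L,
                              speed_px = NULL,
                              event_frame = NULL,
                              rotation_deg_per_frame = 5,
                              noise_amplitude = 0,
                              canvas = c(512, 512),
                              config = track_config()) {
  if (!name %in% scenario_names) {
    stop("unknown scenario '", name, "'; valid names: ",
         paste(scenario_names, collapse = ", "), call. = FALSE)
  }
  build <- switch(
    name,
    perpendicular_glider = build_perpendicular_glider,
    lateral_mover = build_lateral_mover,
    lateral_u_turn = build_lateral_u_turn,
    askew_mover = build_askew_mover,
    rounding_cell = build_rounding_cell,
    perpendicular_stretch = build_perpendicular_stretch,
    lateral_stretch = build_lateral_stretch,
    tail_retraction = build_tail_retraction,
    rotating_ellipse = build_rotating_ellipse,
    disc_random_walk = build_disc_random_walk
  )
  sc <- build(n_frames = n_frames, seed = seed, speed_px = speed_px,
              event_frame = event_frame,
              rotation_deg_per_frame = rotation_deg_per_frame,
              canvas = canvas)
  masks <- sc$masks
  if (noise_amplitude > 0) {
    masks <- lapply(seq_along(masks), function(i) {
      add_boundary_noise(masks[[i]], noise_amplitude,
                         seed = seed + 1000L + i)
    })
  }
  stack <- tryCatch(mask_stack(masks, config), error = function(e) {
    stop("scenario '", name, "': ", conditionMessage(e), call. = FALSE)
  })
  structure(
    list(stack = stack, truth = sc$truth, name = name,
         event_frame = sc$event_frame),
    class = "morphomig_simulation"
  )
}

#' @export
print.morphomig_simulation <- function(x, ...) {
  cat("<morphomig_simulation> scenario '", x$name, "', ",
      length(x$stack), " frames\n", sep = "")
  invisible(x)
}

truth_table <- function(n, cx, cy, orient, eps, behaviour) {
  tibble::tibble(
    frame = seq_len(n),
    cx_px = cx, cy_px = cy,
    orientation_deg = orient,
    eps_true = eps,
    behaviour = behaviour
  )
}

# steps exist at rows 1..n-1; turning angles at rows 2..n-1, so behaviour
# ground truth is declared on interior rows 2..n-1 only
interior_truth <- function(n, label) {
  b <- rep(NA_character_, n)
  b[2:(n - 1)] <- label
  b
}

build_perpendicular_glider <- function(n_frames, speed_px, canvas, ...) {
  n <- n_frames %||% 30L
  v <- speed_px %||% 5
  cx <- rep(canvas[2] / 2, n)
  cy <- 150 + v * (seq_len(n) - 1)
  masks <- lapply(seq_len(n), function(i) {
    render_ellipse_mask(c(cx[i], cy[i]), 20, 60, 0, canvas)
  })
  list(masks = masks,
       truth = truth_table(n, cx, cy, rep(0, n), rep(1 - 20 / 60, n),
                           interior_truth(n, "PERPENDICULAR_DISPLACEMENT")),
       event_frame = NA_integer_)
}

build_lateral_mover <- function(n_frames, speed_px, canvas, heading_deg = 8,
                                label = "LATERAL_DISPLACEMENT", ...) {
  n <- n_frames %||% 30L
  v <- speed_px %||% 6
  h <- heading_deg * pi / 180
  cx <- 140 + v * cos(h) * (seq_len(n) - 1)
  cy <- 200 + v * sin(h) * (seq_len(n) - 1)
  masks <- lapply(seq_len(n), function(i) {
    render_ellipse_mask(c(cx[i], cy[i]), 20, 60, 0, canvas)
  })
  list(masks = masks,
       truth = truth_table(n, cx, cy, rep(0, n), rep(1 - 20 / 60, n),
                           interior_truth(n, label)),
       event_frame = NA_integer_)
}

build_lateral_u_turn <- function(n_frames, speed_px, event_frame, canvas, ...) {
  n <- n_frames %||% 30L
  v <- speed_px %||% 6
  e <- event_frame %||% 15L
  stopifnot(e > 2, e < n - 1)
  h <- 8 * pi / 180
  step <- ifelse(seq_len(n - 1) < e, 1, -1)  # d_e reverses: p_{e+1} = p_e - v
  cx <- 260 + c(0, cumsum(v * cos(h) * step))
  cy <- 200 + c(0, cumsum(v * sin(h) * step))
  masks <- lapply(seq_len(n), function(i) {
    render_ellipse_mask(c(cx[i], cy[i]), 20, 60, 0, canvas)
  })
  b <- interior_truth(n, "LATERAL_DISPLACEMENT")
  b[e] <- "LATERAL_U_TURN"
  list(masks = masks,
       truth = truth_table(n, cx, cy, rep(0, n), rep(1 - 20 / 60, n), b),
       event_frame = as.integer(e))
}

build_askew_mover <- function(n_frames, speed_px, canvas, ...) {
  build_lateral_mover(n_frames = n_frames, speed_px = speed_px,
                      canvas = canvas, heading_deg = 55,
                      label = "ASKEW_DISPLACEMENT")
}

build_rounding_cell <- function(n_frames, speed_px, canvas, ...) {
  n <- n_frames %||% 30L
  v <- speed_px %||% 4
  eps <- c(0.30, 0.30, 0.22, 0.14, rep(0.04, n - 4))
  semi_minor <- 24
  semi_major <- semi_minor / (1 - eps)
  cx <- 120 + v * (seq_len(n) - 1)
  cy <- rep(canvas[1] / 2, n)
  masks <- lapply(seq_len(n), function(i) {
    render_ellipse_mask(c(cx[i], cy[i]), semi_minor, semi_major[i], 0, canvas)
  })
  b <- interior_truth(n, "ROUNDED_CHAOTIC")
  b[2:4] <- "LATERAL_DISPLACEMENT"   # still visibly elongated there
  list(masks = masks,
       truth = truth_table(n, cx, cy, c(rep(0, 4), rep(NA_real_, n - 4)),
                           eps, b),
       event_frame = 5L)
}

build_perpendicular_stretch <- function(n_frames, speed_px, canvas, ...) {
  n <- n_frames %||% 30L
  v <- speed_px %||% 5
  eps <- 0.5 + 0.008 * (seq_len(n) - 1)      # steady elongation ramp
  semi_major <- 20 / (1 - eps)
  cx <- rep(canvas[2] / 2, n)
  cy <- 256 + v * (seq_len(n) %% 2)          # oscillates across the axis
  masks <- lapply(seq_len(n), function(i) {
    render_ellipse_mask(c(cx[i], cy[i]), 20, semi_major[i], 0, canvas)
  })
  list(masks = masks,
       truth = truth_table(n, cx, cy, rep(0, n), eps,
                           interior_truth(n, "PERPENDICULAR_STRETCHING")),
       event_frame = NA_integer_)
}

build_lateral_stretch <- function(n_frames, speed_px, canvas, ...) {
  n <- n_frames %||% 30L
  stopifnot(n >= 20)
  v <- speed_px %||% 6
  # displacement direction per step: forward, two reversals, forward again
  step <- rep(1, n - 1)
  step[10:13] <- c(-1, 1, -1, 1)
  cx <- 160 + c(0, cumsum(v * step))
  cy <- rep(canvas[1] / 2, n)
  semi_major <- 60 + 0.5 * (seq_len(n) - 1)
  masks <- lapply(seq_len(n), function(i) {
    render_ellipse_mask(c(cx[i], cy[i]), 20, semi_major[i], 0, canvas)
  })
  b <- interior_truth(n, "LATERAL_DISPLACEMENT")
  b[10:13] <- "LATERAL_U_TURN"       # the reversal steps themselves
  b[c(9, 14)] <- "LATERAL_STRETCHING"
  list(masks = masks,
       truth = truth_table(n, cx, cy, rep(0, n), 1 - 20 / semi_major, b),
       event_frame = 10L)
}

build_tail_retraction <- function(n_frames, speed_px, event_frame, canvas, ...) {
  n <- n_frames %||% 28L
  v <- speed_px %||% 5
  e <- event_frame %||% 15L
  stopifnot(e > 3, e < n - 1)
  cx <- 180 + v * (seq_len(n) - 1)
  cy <- rep(canvas[1] / 2, n)
  masks <- lapply(seq_len(n), function(i) {
    body <- render_ellipse_mask(c(cx[i], cy[i]), 18, 30, 90, canvas)
    if (i < e) {
      tail <- render_tail_mask(c(cx[i], cy[i]), len = 100, w0 = 14, canvas)
      body <- ((body + tail) > 0) * 1L
    }
    body
  })
  b <- interior_truth(n, "PERPENDICULAR_DISPLACEMENT")
  b[2:(e - 1)] <- "LATERAL_DISPLACEMENT"
  b[e] <- "REAR_RETRACTION"
  orient <- c(rep(0, e - 1), rep(90, n - e + 1))
  list(masks = masks,
       truth = truth_table(n, rep(NA_real_, n), rep(NA_real_, n), orient,
                           c(rep(NA_real_, e - 1), rep(1 - 18 / 30, n - e + 1)),
                           b),
       event_frame = as.integer(e))
}

build_rotating_ellipse <- function(n_frames, rotation_deg_per_frame, canvas, ...) {
  n <- n_frames %||% 36L
  rate <- rotation_deg_per_frame
  theta <- (rate * (seq_len(n) - 1)) %% 180
  cx <- rep(canvas[2] / 2, n)
  cy <- rep(canvas[1] / 2, n)
  masks <- lapply(seq_len(n), function(i) {
    render_ellipse_mask(c(cx[i], cy[i]), 20, 60, theta[i], canvas)
  })
  list(masks = masks,
       truth = truth_table(n, cx, cy, theta, rep(1 - 20 / 60, n),
                           rep(NA_character_, n)),
       event_frame = NA_integer_)
}

build_disc_random_walk <- function(n_frames, speed_px, seed, canvas, ...) {
  n <- n_frames %||% 30L
  v <- speed_px %||% 6
  headings <- withr::with_seed(seed, stats::runif(n - 1, 0, 2 * pi))
  cx <- cy <- numeric(n)
  cx[1] <- canvas[2] / 2
  cy[1] <- canvas[1] / 2
  for (i in 2:n) {
    cx[i] <- cx[i - 1] + v * cos(headings[i - 1])
    cy[i] <- cy[i - 1] + v * sin(headings[i - 1])
    # steer back towards the centre if drifting near the border
    margin <- 40
    if (cx[i] < margin || cx[i] > canvas[2] - margin ||
        cy[i] < margin || cy[i] > canvas[1] - margin) {
      back <- atan2(canvas[1] / 2 - cy[i - 1], canvas[2] / 2 - cx[i - 1])
      cx[i] <- cx[i - 1] + v * cos(back)
      cy[i] <- cy[i - 1] + v * sin(back)
    }
  }
  masks <- lapply(seq_len(n), function(i) {
    render_ellipse_mask(c(cx[i], cy[i]), 25, 25, 0, canvas)
  })
  list(masks = masks,
       truth = truth_table(n, cx, cy, rep(NA_real_, n), rep(0, n),
                           interior_truth(n, "ROUNDED_CHAOTIC")),
       event_frame = NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
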