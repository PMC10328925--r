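# Independent second-moment ellipse oracle: covariance of the foreground
# pixel coordinates eigendecomposed with base eigen(). Deliberately a
# different computational route from the package's closed-form moments.
oracle_ellipse <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  pts <- cbind(idx[, 2], idx[, 1])  # x = col, y = row
  ctr <- colMeans(pts)
  cv <- crossprod(sweep(pts, 2, ctr)) / nrow(pts)
  e <- eigen(cv, symmetric = TRUE)
  list(
    cx = ctr[1], cy = ctr[2],
    major = 4 * sqrt(e$values[1]),
    minor = 4 * sqrt(max(e$values[2], 0)),
    phi = (atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi) %% 180,
    eps = 1 - sqrt(max(e$values[2], 0) / e$values[1])
  )
}

# smallest difference between two axial (mod-180) orientations, in degrees
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# random multi-lobed blob: union of a few overlapping random ellipses
random_blob <- function(seed, canvas = c(160, 160)) {
  withr::with_seed(seed, {
    k <- sample(1:3, 1)
    m <- matrix(0L, canvas[1], canvas[2])
    cx0 <- runif(1, 60, canvas[2] - 60)
    cy0 <- runif(1, 60, canvas[1] - 60)
    for (i in seq_len(k)) {
      sa <- runif(1, 5, 14)
      sb <- runif(1, sa, 30)
      th <- runif(1, 0, 180)
      cx <- cx0 + runif(1, -12, 12)
      cy <- cy0 + runif(1, -12, 12)
      m <- m | render_ellipse_mask(c(cx, cy), sa, sb, th, canvas)
    }
    m * 1L
  })
}

# fabricate a fitted-shape table without rasterization, for tests that
# exercise the kinematics layer alone
make_shapes <- function(cx, cy, phi, eps = 0.5, time_s = seq_along(cx) - 1) {
  n <- length(cx)
  tibble::tibble(
    frame = seq_len(n),
    time_s = time_s,
    centroid_x_um = cx,
    centroid_y_um = cy,
    major_um = 40,
    minor_um = 40 * (1 - rep_len(eps, n)),
    orientation_deg = rep_len(phi, n),
    elongation = rep_len(eps, n),
    area_um2 = 100,
    degenerate = FALSE
  )
}
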