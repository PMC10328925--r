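test_that("signed angles are clockwise-positive on screen and live in (-180, 180]", {
  expect_equal(signed_angle(1, 0, 0, 1), 90)    # right -> down: clockwise
  expect_equal(signed_angle(1, 0, 0, -1), -90)  # right -> up: anti-clockwise
  expect_equal(signed_angle(1, 0, 1, 1), 45)
  expect_equal(signed_angle(1, 0, -1, 0), 180)  # boundary maps to +180
  # near the boundary the result stays inside (-180, 180]
  near <- signed_angle(1, 0, c(-1, -1), c(1e-9, -1e-9))
  expect_true(all(near > -180 & near <= 180))
  expect_true(all(abs(abs(near) - 180) < 1e-6))
  expect_true(is.na(signed_angle(0, 0, 1, 1)))
})

test_that("axis continuity picks the direction with non-negative dot product", {
  u <- propagate_axis_directions(c(30, 30, 30))
  expect_equal(u[2, ], u[1, ])
  expect_equal(u[3, ], u[1, ])

  # 10 -> 170 degrees: the naive direction would turn +160; continuity
  # flips it so the axis turns -20
  u <- propagate_axis_directions(c(10, 170))
  expect_equal(signed_angle(u[1, 1], u[1, 2], u[2, 1], u[2, 2]), -20)
  expect_equal(sqrt(rowSums(u^2)), c(1, 1))
  expect_gte(sum(u[1, ] * u[2, ]), 0)

  # exact perpendicular tie resolves to +90
  u <- propagate_axis_directions(c(0, 90))
  expect_equal(signed_angle(u[1, 1], u[1, 2], u[2, 1], u[2, 2]), 90)
})

test_that("uMM is the acute axis-to-displacement angle, invariant to axis flips", {
  expect_equal(umm_angle(1, 0, 5, 0), 0)
  expect_equal(umm_angle(1, 0, 0, 3), 90)
  expect_equal(umm_angle(1, 0, 1, 1), 45)
  expect_equal(umm_angle(-1, 0, 1, 1), 45)  # flipped axis, same angle
  expect_true(is.na(umm_angle(1, 0, 0, 0)))
})

test_that("displacements, speeds and zero-displacement flags follow the definitions", {
  cfg <- track_config(frame_interval_s = 10)
  shp <- make_shapes(cx = c(0, 3, 3), cy = c(0, 4, 4), phi = 0)
  shp$time_s <- c(0, 10, 20)
  tr <- compute_track(shp, cfg)
  expect_equal(tr$disp_x_um[1], 3)
  expect_equal(tr$disp_y_um[1], 4)
  expect_equal(tr$disp_um[1], 5)
  expect_equal(tr$speed_um_s[1], 0.5)
  expect_false(tr$flag_zero_displacement[1])
  expect_true(tr$flag_zero_displacement[2])   # identical centroids
  expect_true(is.na(tr$smm_deg[2]))
  expect_true(is.na(tr$umm_deg[2]))
})

test_that("turning angles exist only between two valid displacements", {
  shp <- make_shapes(cx = c(0, 1, 2, 3, 4), cy = c(0, 0, 0, 1, 2), phi = 0)
  tr <- compute_track(shp, track_config())
  expect_true(is.na(tr$turning_deg[1]))        # no preceding step
  expect_true(is.na(tr$turning_deg[5]))        # no current step
  expect_equal(tr$turning_deg[2], 0)           # straight
  expect_equal(tr$turning_deg[3], 45)          # (1,0) -> (1,1), clockwise
  # exact reversal
  shp <- make_shapes(cx = c(0, 2, 0, 2), cy = 0.5 * c(0, 1, 0, 1), phi = 0)
  tr <- compute_track(shp, track_config())
  expect_equal(abs(tr$turning_deg[2]), 180)
})

test_that("sMM keeps the first-frame side as the positive reference", {
  # axis along x, displacement below the axis on screen (+y): cross > 0
  shp <- make_shapes(cx = c(0, 5, 10, 15, 20), cy = c(0, 2, 4, 2, 0), phi = 0)
  tr <- compute_track(shp, track_config())
  # steps 1-2 head +y (reference side), steps 3-4 cross to -y
  expect_gt(tr$smm_deg[1], 0)
  expect_gt(tr$smm_deg[2], 0)
  expect_lt(tr$smm_deg[3], 0)
  expect_lt(tr$smm_deg[4], 0)
  expect_equal(abs(tr$smm_deg), tr$umm_deg)
  expect_false(any(tr$flag_no_reference_side[1:4]))

  # motion exactly along the axis: sMM = +0 and no side reference arises
  shp <- make_shapes(cx = c(0, 5, 10), cy = c(0, 0, 0), phi = 0)
  tr <- compute_track(shp, track_config())
  expect_equal(tr$smm_deg[1:2], c(0, 0))
  expect_true(all(tr$flag_no_reference_side[1:2]))
})

test_that("steps before the first side-defining step carry the no-reference flag", {
  # first step along the axis (side 0), later steps off-axis
  shp <- make_shapes(cx = c(0, 5, 10, 15), cy = c(0, 0, 2, 4), phi = 0)
  tr <- compute_track(shp, track_config())
  expect_true(tr$flag_no_reference_side[1])
  expect_false(tr$flag_no_reference_side[2])
  expect_gt(tr$smm_deg[2], 0)   # establishes the reference
  expect_gt(tr$smm_deg[3], 0)
})

test_that("M.A. dynamics follow the propagated axes and the sign convention", {
  shp <- make_shapes(cx = seq(0, 20, 5), cy = 0, phi = c(0, 5, 10, 15, 20))
  tr <- compute_track(shp, track_config())
  expect_equal(tr$ma_dynamics_deg[1:4], rep(5, 4))
  cfg <- track_config(dphi_clockwise_positive = FALSE)
  tr2 <- compute_track(shp, cfg)
  expect_equal(tr2$ma_dynamics_deg[1:4], rep(-5, 4))
  # identical axes
  shp <- make_shapes(cx = c(0, 5), cy = 0, phi = 30)
  expect_equal(compute_track(shp, track_config())$ma_dynamics_deg[1], 0)
})

test_that("a track of N frames yields N-1 sMM values and N-2 turning angles", {
  n <- 91
  shp <- make_shapes(cx = seq_len(n), cy = 0.3 * seq_len(n), phi = 0)
  tr <- compute_track(shp, track_config())
  expect_equal(nrow(tr), n)
  expect_equal(sum(!is.na(tr$smm_deg)), n - 1)
  expect_equal(sum(!is.na(tr$ma_dynamics_deg)), n - 1)
  expect_equal(sum(!is.na(tr$turning_deg)), n - 2)
  expect_error(compute_track(shp[1, ]), ">= 2 frames")
})

test_that("an unchanging sequence has zero-flagged steps and zero axis dynamics", {
  shp <- make_shapes(cx = rep(3, 5), cy = rep(7, 5), phi = 40)
  tr <- compute_track(shp, track_config())
  expect_true(all(tr$flag_zero_displacement[1:4]))
  expect_true(all(is.na(tr$smm_deg)))
  expect_true(all(is.na(tr$turning_deg)))
  expect_equal(tr$ma_dynamics_deg[1:4], rep(0, 4))
})

test_that("low-elongation frames are flagged but still get axis descriptors", {
  shp <- make_shapes(cx = c(0, 4, 8), cy = c(0, 1, 2), phi = 0,
                     eps = c(0.05, 0.5, 0.5))
  tr <- compute_track(shp, track_config())
  expect_true(tr$flag_low_elongation[1])
  expect_false(tr$flag_low_elongation[2])
  expect_false(is.na(tr$smm_deg[1]))
  expect_false(is.na(tr$ma_dynamics_deg[1]))
})

test_that("resampling keeps every k-th frame and rescales time", {
  sim <- simulate_scenario("lateral_mover", n_frames = 10)
  expect_equal(length(resample_track(sim$stack, 1)), 10)
  r3 <- resample_track(sim$stack, 3)
  expect_equal(length(r3), 4)             # frames 1, 4, 7, 10
  expect_equal(r3$config$frame_interval_s, 3)
  expect_equal(r3$time_s, c(0, 3, 6, 9))
  expect_identical(r3$masks[[2]], sim$stack$masks[[4]])
  expect_error(resample_track(sim$stack, 10), "smaller")

  n <- 91
  shp <- make_shapes(cx = seq_len(n), cy = 0, phi = 0)
  expect_equal(nrow(resample_track(shp, 3)), 31)

  # constant-velocity glider: sMM is interval-independent
  shp <- make_shapes(cx = 4 * (1:30), cy = 1.5 * (1:30), phi = 0)
  t1 <- compute_track(shp, track_config())
  t3 <- compute_track(resample_track(shp, 3), track_config())
  expect_equal(mean(t3$smm_deg, na.rm = TRUE), mean(t1$smm_deg, na.rm = TRUE),
               tolerance = 1e-9)
})

test_that("integer translation of all masks leaves every descriptor identical", {
  sim <- simulate_scenario("askew_mover", n_frames = 8)
  tr1 <- compute_track(fit_shapes(sim$stack), track_config())
  shifted <- lapply(sim$stack$masks, function(m) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[8:nrow(m), 15:ncol(m)] <- m[1:(nrow(m) - 7), 1:(ncol(m) - 14)]
    out
  })
  tr2 <- compute_track(fit_shapes(mask_stack(shifted, sim$stack$config)),
                       track_config())
  for (col in c("ma_dynamics_deg", "elongation", "orientation_deg")) {
    expect_identical(tr1[[col]], tr2[[col]])
  }
  for (col in c("smm_deg", "umm_deg", "turning_deg")) {
    expect_equal(tr1[[col]], tr2[[col]], tolerance = 1e-9)
  }
})

test_that("rotating the image by 90 degrees preserves the unsigned descriptors", {
  sim <- simulate_scenario("askew_mover", n_frames = 10)
  tr1 <- compute_track(fit_shapes(sim$stack), track_config())
  rot <- lapply(sim$stack$masks, function(m) t(m[nrow(m):1, ]))
  tr2 <- compute_track(fit_shapes(mask_stack(rot, sim$stack$config)),
                       track_config())
  expect_equal(tr2$umm_deg, tr1$umm_deg, tolerance = 2)
  expect_equal(abs(tr2$turning_deg), abs(tr1$turning_deg), tolerance = 2)
  expect_equal(abs(tr2$ma_dynamics_deg), abs(tr1$ma_dynamics_deg), tolerance = 2)
  expect_equal(tr2$elongation, tr1$elongation, tolerance = 0.02)
})

test_that("|sMM| equals uMM on every valid step of every scenario", {
  for (nm in c("perpendicular_glider", "lateral_u_turn", "disc_random_walk")) {
    tr <- compute_track(fit_shapes(simulate_scenario(nm, seed = 2)$stack),
                        track_config())
    ok <- !is.na(tr$smm_deg)
    expect_true(any(ok))
    expect_identical(abs(tr$smm_deg[ok]), tr$umm_deg[ok])
  }
})
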