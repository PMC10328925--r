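annotate_scenario <- function(name, seed = 1, ...) {
  sim <- simulate_scenario(name, seed = seed, ...)
  cfg <- sim$stack$config
  tr <- annotate_behaviours(label_track(compute_track(fit_shapes(sim$stack), cfg), cfg),
                            cfg$rules)
  list(track = tr, truth = sim$truth, event = sim$event_frame)
}

test_that("a perpendicular glider is one perpendicular-displacement segment", {
  res <- annotate_scenario("perpendicular_glider")
  segs <- attr(res$track, "segments")
  perp <- segs[segs$behaviour == "PERPENDICULAR_DISPLACEMENT", ]
  expect_equal(nrow(perp), 1)
  expect_equal(perp$start_frame, 2)
  expect_equal(perp$end_frame, nrow(res$track) - 1)
})

test_that("a programmed reversal yields lateral runs around a single U-turn step", {
  res <- annotate_scenario("lateral_u_turn")
  beh <- res$track$behaviour
  expect_equal(sum(beh == "LATERAL_U_TURN", na.rm = TRUE), 1)
  expect_equal(which(beh == "LATERAL_U_TURN"), res$event)
  runs <- attr(res$track, "segments")
  lat <- runs[runs$behaviour == "LATERAL_DISPLACEMENT", ]
  expect_equal(nrow(lat), 2)   # one run before, one after the turn
})

test_that("a rounded random walker is chaotic on every interior step", {
  res <- annotate_scenario("disc_random_walk", seed = 5)
  interior <- 2:(nrow(res$track) - 1)
  expect_true(all(res$track$behaviour[interior] == "ROUNDED_CHAOTIC"))
})

test_that("low elongation dominates every other rule", {
  # a low-eps track that would otherwise be lateral displacement
  shp <- make_shapes(cx = seq(0, 40, 4), cy = seq(0, 4, 0.4), phi = 0,
                     eps = 0.05)
  cfg <- track_config()
  tr <- annotate_behaviours(label_track(compute_track(shp, cfg), cfg))
  interior <- 2:(nrow(tr) - 1)
  expect_true(all(tr$behaviour[interior] == "ROUNDED_CHAOTIC"))
})

test_that("rear retraction fires on the axis-flip step of the tail scenario", {
  res <- annotate_scenario("tail_retraction")
  beh <- res$track$behaviour
  expect_equal(which(beh == "REAR_RETRACTION"), res$event)
  expect_true(all(beh[2:(res$event - 1)] == "LATERAL_DISPLACEMENT"))
  expect_true(all(beh[(res$event + 1):(nrow(res$track) - 1)] ==
                    "PERPENDICULAR_DISPLACEMENT"))
})

test_that("stretching rules classify the growing-cell scenarios", {
  res <- annotate_scenario("perpendicular_stretch")
  interior <- 2:(nrow(res$track) - 1)
  expect_true(all(res$track$behaviour[interior] == "PERPENDICULAR_STRETCHING"))

  res <- annotate_scenario("lateral_stretch")
  beh <- res$track$behaviour
  expect_true(all(beh[10:13] == "LATERAL_U_TURN"))
  expect_true(all(beh[c(9, 14)] == "LATERAL_STRETCHING"))
  expect_true(all(beh[c(3:8, 16:25)] == "LATERAL_DISPLACEMENT"))
})

test_that("the rule engine is deterministic and steps map to exactly one segment", {
  res1 <- annotate_scenario("lateral_stretch")
  res2 <- annotate_scenario("lateral_stretch")
  expect_identical(res1$track$behaviour, res2$track$behaviour)
  segs <- attr(res1$track, "segments")
  expect_true(all(segs$start_frame <= segs$end_frame))
  # segments tile the annotated rows without overlap
  expect_equal(sum(segs$n_steps), sum(!is.na(res1$track$behaviour)))
  expect_equal(segs$start_frame[-1], segs$end_frame[-nrow(segs)] + 1)
})

test_that("undefined steps are UNCLASSIFIED, the final frame is unannotated", {
  shp <- make_shapes(cx = c(0, 0, 5, 10), cy = c(0, 0, 2, 4), phi = 0)
  cfg <- track_config()
  tr <- annotate_behaviours(label_track(compute_track(shp, cfg), cfg))
  expect_equal(tr$behaviour[1], "UNCLASSIFIED")  # zero-displacement step
  expect_true(is.na(tr$behaviour[4]))
})

test_that("the behaviour census counts segments and durations", {
  res <- annotate_scenario("lateral_u_turn")
  cen <- behaviour_census(res$track, frame_interval_s = 2)
  lat <- cen[cen$behaviour == "LATERAL_DISPLACEMENT", ]
  expect_equal(lat$n_segments, 2)
  ut <- cen[cen$behaviour == "LATERAL_U_TURN", ]
  expect_equal(ut$total_steps, 1)
  expect_equal(ut$mean_duration_s, 2)

  empty <- behaviour_census(tibble::tibble(behaviour = character(),
                                           start_frame = integer(),
                                           end_frame = integer(),
                                           n_steps = integer()))
  expect_equal(nrow(empty), 0)

  one <- behaviour_census(tibble::tibble(behaviour = "LATERAL_DISPLACEMENT",
                                         start_frame = 1L, end_frame = 10L,
                                         n_steps = 10L))
  expect_equal(one$n_segments, 1)
  expect_equal(one$mean_duration_steps, 10)
})

test_that("behaviour recovery holds under mild boundary noise", {
  for (nm in c("perpendicular_glider", "lateral_mover")) {
    sim <- simulate_scenario(nm, seed = 7, noise_amplitude = 1)
    res <- analyze_stack(sim$stack)
    interior <- which(!is.na(sim$truth$behaviour))
    acc <- mean(res$track$behaviour[interior] == sim$truth$behaviour[interior])
    expect_gte(acc, 0.9)
  }
})
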