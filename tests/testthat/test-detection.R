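# frame-level rest/onset tests and the per-keypoint movement mask

test_that("default keypoint derivation returns the documented sets", {
  ts <- generate_recording(scenario_spec(20, seed = 1))
  rec <- ts$recording

  both <- derive_default_keypoints(rec, "both")
  expect_length(both, 8)
  expect_setequal(names(both),
                  c("l_wrist", "l_forearm", "lh_index_tip", "lh_thumb_tip",
                    "r_wrist", "r_forearm", "rh_index_tip", "rh_thumb_tip"))

  left <- derive_default_keypoints(rec, "left")
  expect_length(left, 4)
  expect_true(all(startsWith(names(left), "l")))
  right <- derive_default_keypoints(rec, "right")
  expect_length(right, 4)
  expect_true(all(startsWith(names(right), "r")))
})

test_that("mid-forearm is the elbow/wrist midpoint with the lower confidence", {
  tracks25 <- replicate(25, constant_track(3), simplify = FALSE)
  tracks25[[7]] <- keypoint_track(rep(100, 3), rep(200, 3), rep(0.9, 3),
                                  fps = 25, label = "l_elbow")
  tracks25[[8]] <- keypoint_track(rep(150, 3), rep(250, 3), rep(0.5, 3),
                                  fps = 25, label = "l_wrist")
  tracks21 <- replicate(21, constant_track(3), simplify = FALSE)
  rec <- pose_recording(tracks25, tracks21, tracks21, fps = 25)
  fa <- derive_default_keypoints(rec, "left")$l_forearm
  expect_equal(fa$x, rep(125, 3))
  expect_equal(fa$y, rep(225, 3))
  expect_equal(fa$confidence, rep(0.5, 3))
})

test_that("coordinate distance implements both metrics", {
  kp <- keypoint_track(c(0, 3), c(0, 4), c(1, 1), fps = 25)
  expect_equal(coordinate_distance(kp, 1, 2), 5)
  expect_equal(coordinate_distance(kp, 2, 1), 5)  # symmetric
  expect_equal(coordinate_distance(kp, 1, 2, "per-axis-max"), 4)
  expect_equal(coordinate_distance(kp, 1, 1), 0)
  expect_error(coordinate_distance(kp, 1, 3), "out of range")
})

test_that("rest state requires 70% of the window within tolerance", {
  p <- detection_params()
  k <- 8  # midpoint of a 15-frame track: full window available

  expect_true(is_rest_state(constant_track(15), k, p))

  displaced <- function(n_out) {
    x <- rep(100, 15)
    out <- setdiff(seq_len(15), k)[seq_len(n_out)]
    x[out] <- 100 + 50
    keypoint_track(x, rep(100, 15), rep(0.9, 15), fps = 25)
  }
  # 4 displaced -> 11/15 = 0.733 >= 0.7 is rest
  expect_true(is_rest_state(displaced(4), k, p))
  # 5 displaced -> 10/15 = 0.667 < 0.7 is not
  expect_false(is_rest_state(displaced(5), k, p))
})

test_that("rest window clamps at sequence edges using available frames", {
  # 8 frames: at k = 1 the window is frames 1..8 only
  kp <- keypoint_track(c(rep(0, 6), 50, 50) + 100, rep(100, 8),
                       rep(0.9, 8), fps = 25)
  # 6 of 8 within tolerance = 0.75 >= 0.7
  expect_true(is_rest_state(kp, 1, detection_params()))
  kp2 <- keypoint_track(c(rep(0, 5), 50, 50, 50) + 100, rep(100, 8),
                        rep(0.9, 8), fps = 25)
  # 5 of 8 = 0.625 < 0.7
  expect_false(is_rest_state(kp2, 1, detection_params()))
})

test_that("movement onset needs a >5 px step confirmed by the lookahead", {
  p <- detection_params()

  kp <- constant_track(30)
  expect_false(any(vapply(seq_len(30), is_movement_onset, logical(1),
                          track = kp, params = p)))

  # 6 px/frame ramp: step 6 > 5 and all lookahead distances exceed 5
  ramp <- ramp_track(pre = 10, len = 15, post = 10, step = 6)
  expect_true(is_movement_onset(ramp, 11, p))

  # a sudden shift that then stays put: no lookahead frame departs from the
  # shifted position, so the onset is not confirmed
  x <- c(rep(100, 14), rep(120, 16))
  shift <- keypoint_track(x, rep(100, 30), rep(0.9, 30), fps = 25)
  expect_false(is_movement_onset(shift, 15, p))

  # a single-frame coordinate spike passes the raw onset test at the spike
  # frame, but the movement it starts collapses to one frame (the next frame
  # is already rest) and dies in post-processing
  xs <- rep(100, 60); xs[30] <- 120
  spike <- keypoint_track(xs, rep(100, 60), rep(0.9, 60), fps = 25)
  mask <- detect_movement_mask(spike, p)
  expect_equal(which(unclass(mask)), 30L)
  expect_equal(nrow(postprocess_segments(mask_to_segments(mask), p)), 0)

  # first frame is never an onset
  jump <- keypoint_track(c(0, 100, 200, 300, 400, 500, 600) + 1,
                         rep(1, 7), rep(0.9, 7), fps = 25)
  expect_false(is_movement_onset(jump, 1, p))
  expect_true(is_movement_onset(jump, 2, p))
})

test_that("constant and low-confidence tracks produce all-false masks", {
  p <- detection_params()
  expect_false(any(detect_movement_mask(constant_track(120), p)))

  # reliability gate: any track with confidence 0.2 < default 0.3
  moving <- ramp_track(pre = 30, len = 20, post = 30, step = 8, conf = 0.2)
  expect_false(any(detect_movement_mask(moving, p)))

  # the same track with good confidence does contain movement
  moving_ok <- ramp_track(pre = 30, len = 20, post = 30, step = 8)
  expect_true(any(detect_movement_mask(moving_ok, p)))
})

test_that("a ramp between rest spans is marked movement over the ramp", {
  p <- detection_params()
  mask <- detect_movement_mask(ramp_track(50, 20, 50, step = 6), p)
  seg <- mask_to_segments(mask)
  expect_equal(nrow(seg), 1)
  # onset at the first moving frame, end within window-edge slack of frame 70
  expect_equal(seg$start_frame, 51)
  expect_gte(seg$end_frame, 70 - 1)
  expect_lte(seg$end_frame, 70 + 5)
  # rest frames away from the ramp stay rest
  expect_false(any(mask[1:45]))
  expect_false(any(mask[80:120]))
})

test_that("no-person (0,0,0) frames flow through detection as no movement", {
  x <- rep(500, 60); y <- rep(400, 60); conf <- rep(0.9, 60)
  x[25:28] <- 0; y[25:28] <- 0; conf[25:28] <- 0
  kp <- keypoint_track(x, y, conf, fps = 25)
  expect_false(any(detect_movement_mask(kp, detection_params())))
})

test_that("movement with no subsequent rest runs to the final frame", {
  p <- detection_params(rest_search_limit = 10)
  # 20 rest frames then a ramp right to the end: growth retries are capped
  kp <- ramp_track(pre = 20, len = 80, post = 0, step = 8)
  mask <- detect_movement_mask(kp, p)
  expect_true(all(mask[21:100]))
  expect_false(any(mask[1:18]))
})

test_that("mask merging is a frame-wise union and checks lengths", {
  a <- movement_mask(c(rep(FALSE, 4), rep(TRUE, 5), rep(FALSE, 6)), "a")
  b <- movement_mask(c(rep(FALSE, 7), rep(TRUE, 5), rep(FALSE, 3)), "b")
  m <- merge_masks(list(a, b))
  expect_equal(which(unclass(m)), 5:12)
  expect_equal(attr(m, "provenance"), "merged")
  expect_equal(unclass(merge_masks(list(a))), unclass(a),
               ignore_attr = TRUE)
  expect_false(any(merge_masks(list(a & FALSE, b & FALSE))))
  expect_error(merge_masks(list(a, movement_mask(TRUE))), "length")
})

test_that("detection is deterministic and translation invariant", {
  p <- detection_params()
  for (seed in 1:10) {
    kp <- random_track(300, seed = seed)
    m1 <- detect_movement_mask(kp, p)
    m2 <- detect_movement_mask(kp, p)
    expect_identical(unclass(m1), unclass(m2))
    shifted <- translate_track(kp, dx = 137.5, dy = -401.25)
    expect_identical(unclass(detect_movement_mask(shifted, p)),
                     unclass(m1))
  }
})

test_that("raising the reliability threshold above max confidence silences detection", {
  kp <- random_track(400, seed = 99)
  p_hi <- detection_params(reliability_threshold = max(kp$confidence) + 0.01)
  expect_false(any(detect_movement_mask(kp, p_hi)))
})

test_that("adding a mask to a union never removes movement frames", {
  masks <- lapply(1:5, function(s)
    detect_movement_mask(random_track(200, seed = s), detection_params()))
  base <- merge_masks(masks[1:4])
  grown <- merge_masks(masks)
  expect_true(all(unclass(grown) | !unclass(base)))  # grown >= base
})

test_that("sub-threshold jitter around a fixed point yields an all-false mask", {
  p <- detection_params()
  for (seed in 1:20) {
    set.seed(seed)
    n <- 250
    kp <- keypoint_track(600 + rnorm(n), 400 + rnorm(n), rep(0.9, n),
                         fps = 25)
    expect_false(any(detect_movement_mask(kp, p)))
  }
})

test_that("the detector matches the literal flowchart transcription", {
  p <- detection_params()
  for (seed in 1:25) {
    kp <- random_track(sample(200:600, 1), seed = seed)
    expect_identical(as.logical(unclass(detect_movement_mask(kp, p))),
                     oracle_mask(kp, p),
                     info = paste("seed", seed))
  }
})
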