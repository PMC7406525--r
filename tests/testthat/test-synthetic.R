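# synthetic scenario generator: determinism, truth recovery, hold limitation

test_that("identical spec and seed reproduce the recording exactly", {
  spec <- scenario_spec(120, episodes = data.frame(
    onset = 41, duration = 25, amplitude = 150, shape = "ramp"), seed = 42)
  a <- generate_recording(spec)
  b <- generate_recording(spec)
  expect_identical(a$recording, b$recording)
  expect_identical(a$truth, b$truth)
  c_ <- generate_recording(scenario_spec(120, episodes = data.frame(
    onset = 41, duration = 25, amplitude = 150, shape = "ramp"), seed = 43))
  expect_false(identical(a$recording, c_$recording))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(runif(0))
  generate_recording(scenario_spec(30, seed = 9))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("a movement-free scenario yields zero detected segments", {
  ts <- generate_recording(scenario_spec(400, rest_jitter_sd = 1, seed = 7))
  expect_equal(nrow(ts$truth), 0)
  det <- detect_movements(ts$recording)
  expect_equal(nrow(det$segments), 0)
})

test_that("a 30-frame 100-px ramp is recovered at >= 60% overlap", {
  spec <- scenario_spec(300, episodes = data.frame(
    onset = 101, duration = 30, amplitude = 100, shape = "ramp"), seed = 5)
  ts <- generate_recording(spec)
  expect_equal(ts$truth, data.frame(start_frame = 101, end_frame = 130))
  det <- detect_movements(ts$recording)
  rep <- match_segments(det$segments, ts$truth, criterion = 0.6)
  expect_equal(rep$recall, 1)
})

test_that("invalid scenario specs are rejected", {
  expect_error(scenario_spec(100, episodes = data.frame(
    onset = c(11, 20), duration = c(15, 10), amplitude = 50,
    shape = "ramp")), "overlap")
  expect_error(scenario_spec(100, episodes = data.frame(
    onset = 95, duration = 10, amplitude = 50, shape = "ramp")),
    "within frames")
  expect_error(scenario_spec(100, rest_jitter_sd = -1), "rest_jitter_sd")
  expect_error(scenario_spec(100, confidence_baseline = 1.5),
               "confidence_baseline")
  expect_error(scenario_spec(100, episodes = data.frame(
    onset = 11, duration = 10, amplitude = 50, shape = "out_hold_return",
    hold = 9)), "hold")
})

test_that("confidence dropouts zero coordinates and confidence", {
  ts <- generate_recording(scenario_spec(200, dropout_prob = 0.2, seed = 8))
  kp <- ts$recording$body[[8]]  # left wrist
  dropped <- kp$confidence == 0
  expect_gt(sum(dropped), 5)
  expect_true(all(kp$x[dropped] == 0))
  expect_true(all(kp$y[dropped] == 0))
})

test_that("isolated dropout frames are gated and never become movement", {
  # constant position with every 20th frame dropped to (0, 0, 0): the dropped
  # frame is excluded by the reliability gate and the jump it creates fails
  # the lookahead confirmation on its neighbours
  n <- 200
  x <- rep(500, n); y <- rep(400, n); conf <- rep(0.9, n)
  drop <- seq(20, n, by = 20)
  x[drop] <- 0; y[drop] <- 0; conf[drop] <- 0
  kp <- keypoint_track(x, y, conf, fps = 25)
  expect_false(any(detect_movement_mask(kp, detection_params())))
})

test_that("a long frozen hold is classified as rest inside the episode", {
  p <- detection_params()
  spec <- scenario_spec(300, episodes = data.frame(
    onset = 101, duration = 60, amplitude = 200, shape = "out_hold_return",
    hold = 30), seed = 21)
  ts <- generate_hold_scenario(spec)
  # truth marks the full episode
  expect_equal(ts$truth, data.frame(start_frame = 101, end_frame = 160))

  det <- detect_movements(ts$recording, p)
  mask <- det$merged_mask
  # hold frames: out phase is (60 - 30) %/% 2 = 15 frames, so hold spans
  # frames 116..145; its interior (window half-width inside) must be rest
  interior <- (116 + p$rest_halfwidth):(145 - p$rest_halfwidth)
  expect_false(any(mask[interior]))
  # but the out and return phases are detected as movement
  expect_true(any(mask[101:115]))
  expect_true(any(mask[146:160]))
})

test_that("a short hold stays inside a single detected movement", {
  spec <- scenario_spec(300, episodes = data.frame(
    onset = 101, duration = 25, amplitude = 200, shape = "out_hold_return",
    hold = 5), seed = 22)
  ts <- generate_recording(spec)
  det <- detect_movements(ts$recording)
  rep <- match_segments(det$segments, ts$truth, criterion = 0.6)
  expect_equal(nrow(det$segments), 1)
  expect_equal(rep$recall, 1)
})

test_that("generate_hold_scenario insists on a hold longer than the rest window", {
  spec <- scenario_spec(300, episodes = data.frame(
    onset = 101, duration = 30, amplitude = 200, shape = "out_hold_return",
    hold = 10), seed = 1)
  expect_error(generate_hold_scenario(spec), "rest window")
})

test_that("truth sets materialize to disk reproducibly", {
  spec <- scenario_spec(60, episodes = data.frame(
    onset = 21, duration = 12, amplitude = 80, shape = "ramp"), seed = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_truth_set(generate_recording(spec), file.path(d1, "s"))
  write_truth_set(generate_recording(spec), file.path(d2, "s"))
  for (f in c("s_body.csv", "s_left_hand.csv", "s_right_hand.csv",
              "s_truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  truth <- utils::read.csv(file.path(d1, "s_truth.csv"))
  expect_equal(truth$start_frame, 21)
  expect_equal(truth$end_frame, 32)
})

test_that("synthetic recall is perfect under the stated generator settings", {
  p <- detection_params()
  n_matched <- 0L; n_truth <- 0L
  for (seed in 1:30) {
    set.seed(seed + 1000)
    onsets <- c(61, 161, 261)
    durs <- sample(12:24, 3, replace = TRUE)  # gesture-scale: 0.5-1 s
    spec <- scenario_spec(360, rest_jitter_sd = 1, episodes = data.frame(
      onset = onsets, duration = durs,
      amplitude = pmax(60, durs * 6),  # >= 10x threshold, step > 5 px
      shape = "ramp"), seed = seed)
    ts <- generate_recording(spec)
    det <- detect_movements(ts$recording, p)
    rep <- match_segments(det$segments, ts$truth, criterion = 0.6)
    n_matched <- n_matched + rep$n_matched
    n_truth <- n_truth + rep$n_reference
  }
  expect_equal(n_matched, n_truth)  # recall 1.0 across all scenarios
})
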