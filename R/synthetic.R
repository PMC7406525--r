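#' Specify a synthetic recording scenario
#'
#' Describes a keypoint time series to simulate: rest spans with Gaussian
#' pixel jitter around fixed anchors, interrupted by movement episodes with
#' known ground truth, plus a simple confidence model (constant baseline with
#' random dropouts to confidence 0 at coordinates (0, 0), mimicking the
#' undetected-keypoint convention of pose estimators).
#'
#' @param n_frames Total frame count.
#' @param fps Frames per second (default 25, the usual video rate).
#' @param rest_jitter_sd Standard deviation, in pixels, of the i.i.d. Gaussian
#'   jitter added per frame and axis during rest (default 1).
#' @param episodes Data frame of movement episodes with columns `onset`
#'   (1-based first movement frame), `duration` (frames), `amplitude`
#'   (pixels), `shape` (`"ramp"`: monotone displacement to a new anchor;
#'   `"out_hold_return"`: move out, freeze for `hold` frames, return), and
#'   optionally `hold` (frames, used by `out_hold_return`). Episodes must be
#'   ordered, non-overlapping and inside the recording.
#' @param confidence_baseline Per-frame confidence during normal tracking
#'   (default 0.9).
#' @param dropout_prob Per-frame probability of a confidence dropout
#'   (default 0).
#' @param seed Integer seed; the generated recording is a pure function of
#'   the spec including this seed.
#' @return An object of class `scenario_spec`.
#' @examples
#' spec <- scenario_spec(300, episodes = data.frame(
#'   onset = 101, duration = 30, amplitude = 100, shape = "ramp"))
#' @export
scenario_spec <- function(n_frames, fps = 25, rest_jitter_sd = 1,
                          episodes = NULL, confidence_baseline = 0.9,
                          dropout_prob = 0, seed = 1L) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  if (rest_jitter_sd < 0) stop("rest_jitter_sd must be >= 0", call. = FALSE)
  if (confidence_baseline < 0 || confidence_baseline > 1)
    stop("confidence_baseline must lie in [0, 1]", call. = FALSE)
  if (dropout_prob < 0 || dropout_prob > 1)
    stop("dropout_prob must lie in [0, 1]", call. = FALSE)

  if (is.null(episodes) || nrow(episodes) == 0L) {
    episodes <- data.frame(onset = integer(0), duration = integer(0),
                           amplitude = numeric(0), shape = character(0),
                           hold = integer(0))
  } else {
    if (!all(c("onset", "duration", "amplitude", "shape") %in%
             names(episodes)))
      stop("episodes need onset, duration, amplitude and shape columns",
           call. = FALSE)
    if (is.null(episodes$hold)) episodes$hold <- 0L
    episodes$hold[is.na(episodes$hold)] <- 0L
    episodes <- episodes[order(episodes$onset), , drop = FALSE]
    rownames(episodes) <- NULL
    if (!all(episodes$shape %in% c("ramp", "out_hold_return")))
      stop("episode shape must be 'ramp' or 'out_hold_return'", call. = FALSE)
    if (any(episodes$duration < 1L) || any(episodes$amplitude <= 0))
      stop("episodes need duration >= 1 and amplitude > 0", call. = FALSE)
    ends <- episodes$onset + episodes$duration - 1L
    if (any(episodes$onset < 2L) || any(ends > n_frames))
      stop("episodes must lie within frames [2, n_frames]", call. = FALSE)
    if (nrow(episodes) > 1L &&
        any(episodes$onset[-1L] <= ends[-length(ends)]))
      stop("episodes must not overlap", call. = FALSE)
    ohr <- episodes$shape == "out_hold_return"
    if (any(ohr & (episodes$hold < 1L |
                   episodes$duration - episodes$hold < 2L)))
      stop("out_hold_return episodes need 1 <= hold <= duration - 2",
           call. = FALSE)
  }

  structure(
    list(n_frames = n_frames, fps = as.numeric(fps),
         rest_jitter_sd = as.numeric(rest_jitter_sd), episodes = episodes,
         confidence_baseline = as.numeric(confidence_baseline),
         dropout_prob = as.numeric(dropout_prob), seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' Generate a synthetic pose recording with ground truth
#'
#' Simulates a full [pose_recording()] following a [scenario_spec()]: all
#' eight default detector keypoints (both wrists and elbows, so the synthetic
#' mid-forearm moves too, plus index fingertips and thumb tips) execute every
#' movement episode, each with its own random anchor and movement direction;
#' every remaining keypoint sits at a static anchor with the same jitter
#' model. Frozen-hold frames carry exactly constant coordinates. Output is a
#' pure function of the spec (including its seed).
#'
#' @param spec A [scenario_spec()].
#' @return An object of class `truth_set`: a list with elements `recording`
#'   (the [pose_recording()]), `truth` (segment data frame of the episodes)
#'   and `spec`.
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n_frames
  driven_body <- c(.body_idx[["l_wrist"]], .body_idx[["l_elbow"]],
                   .body_idx[["r_wrist"]], .body_idx[["r_elbow"]])
  driven_hand <- c(.hand_idx[["index_tip"]], .hand_idx[["thumb_tip"]])

  make_block <- function(k, driven, labels) {
    xm <- matrix(0, n, k); ym <- matrix(0, n, k); cm <- matrix(0, n, k)
    for (i in seq_len(k)) {
      tr <- .simulate_track(spec, driven = i %in% driven)
      xm[, i] <- tr$x; ym[, i] <- tr$y; cm[, i] <- tr$confidence
    }
    .tracks_from_matrices(xm, ym, cm, spec$fps, labels)
  }

  rec <- pose_recording(
    body = make_block(25L, driven_body, body25_labels),
    left_hand = make_block(21L, driven_hand, paste0("lh_", hand21_labels)),
    right_hand = make_block(21L, driven_hand, paste0("rh_", hand21_labels)),
    fps = spec$fps
  )

  truth <- if (nrow(spec$episodes) == 0L) {
    data.frame(start_frame = integer(0), end_frame = integer(0))
  } else {
    data.frame(start_frame = spec$episodes$onset,
               end_frame = spec$episodes$onset + spec$episodes$duration - 1L)
  }

  structure(list(recording = rec, truth = truth, spec = spec),
            class = "truth_set")
}

# one simulated keypoint: anchored rest + (if driven) the episode path
.simulate_track <- function(spec, driven) {
  n <- spec$n_frames
  anchor <- c(stats::runif(1, 300, 1600), stats::runif(1, 200, 1000))
  pos <- matrix(0, n, 2L)
  frozen <- logical(n)
  cur <- anchor
  last_end <- 0L

  eps <- spec$episodes
  if (!driven) eps <- eps[0L, , drop = FALSE]
  for (r in seq_len(nrow(eps))) {
    o <- eps$onset[r]; d <- eps$duration[r]; a <- eps$amplitude[r]
    theta <- stats::runif(1, 0, 2 * pi)
    u <- c(cos(theta), sin(theta))
    if (o - 1L > last_end)
      pos[(last_end + 1L):(o - 1L), ] <- rep(cur, each = o - 1L - last_end)
    if (eps$shape[r] == "ramp") {
      frac <- seq_len(d) / d
      pos[o:(o + d - 1L), ] <- cbind(cur[1] + u[1] * a * frac,
                                     cur[2] + u[2] * a * frac)
      cur <- cur + u * a
    } else {
      hold <- eps$hold[r]
      out_len <- max(1L, (d - hold) %/% 2L)
      ret_len <- d - hold - out_len
      apex <- cur + u * a
      fo <- seq_len(out_len) / out_len
      pos[o:(o + out_len - 1L), ] <- cbind(cur[1] + u[1] * a * fo,
                                           cur[2] + u[2] * a * fo)
      hold_idx <- (o + out_len):(o + out_len + hold - 1L)
      pos[hold_idx, ] <- rep(apex, each = hold)
      frozen[hold_idx] <- TRUE
      fr <- 1 - seq_len(ret_len) / ret_len
      ret_idx <- (o + out_len + hold):(o + d - 1L)
      pos[ret_idx, ] <- cbind(cur[1] + u[1] * a * fr, cur[2] + u[2] * a * fr)
    }
    last_end <- o + d - 1L
  }
  if (last_end < n)
    pos[(last_end + 1L):n, ] <- rep(cur, each = n - last_end)

  jit <- matrix(stats::rnorm(2L * n, 0, spec$rest_jitter_sd), n, 2L)
  jit[frozen, ] <- 0
  x <- pos[, 1L] + jit[, 1L]
  y <- pos[, 2L] + jit[, 2L]
  conf <- rep(spec$confidence_baseline, n)
  if (spec$dropout_prob > 0) {
    drop <- stats::runif(n) < spec$dropout_prob
    conf[drop] <- 0
    x[drop] <- 0
    y[drop] <- 0
  }
  list(x = x, y = y, confidence = conf)
}

#' Generate a hold scenario
#'
#' Builds a [generate_recording()] truth set for a spec containing an
#' out-hold-return episode whose frozen hold outlasts the detector's rest
#' window. The truth marks the full episode; by construction the detector is
#' expected to classify the hold interior as rest and therefore split or
#' truncate the episode — the documented limitation of coordinate-change
#' detection for gesture holds.
#'
#' @param spec A [scenario_spec()] containing at least one `out_hold_return`
#'   episode with `hold` longer than the rest window.
#' @param params [detection_params()] defining the rest window the hold must
#'   exceed.
#' @return A `truth_set`.
#' @export
generate_hold_scenario <- function(spec, params = detection_params()) {
  stopifnot(inherits(spec, "scenario_spec"))
  window <- 2L * params$rest_halfwidth + 1L
  ohr <- spec$episodes$shape == "out_hold_return"
  if (!any(ohr & spec$episodes$hold > window))
    stop("spec needs an out_hold_return episode with hold > ", window,
         " frames (the rest window)", call. = FALSE)
  generate_recording(spec)
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("Synthetic truth set: %d frames at %g fps, %d true movement segment(s), seed %d\n",
              x$spec$n_frames, x$spec$fps, nrow(x$truth), x$spec$seed))
  invisible(x)
}

#' Write a truth set to disk
#'
#' Materializes the recording as keypoint CSVs (and optionally per-frame JSON
#' documents) plus a `<prefix>_truth.csv` with the ground-truth segments as
#' frame indices and a `<prefix>_truth_annotations.csv` in the annotation
#' dialect, directly consumable as an evaluation reference.
#'
#' @param truth_set A `truth_set` from [generate_recording()].
#' @param prefix Output path prefix.
#' @param format `"csv"`, `"openpose"` or `"both"`.
#' @return Invisibly, a named list of written paths.
#' @export
write_truth_set <- function(truth_set, prefix,
                            format = c("csv", "openpose", "both")) {
  stopifnot(inherits(truth_set, "truth_set"))
  format <- match.arg(format)
  out <- list()
  if (format %in% c("csv", "both"))
    out$keypoint_csvs <- write_keypoint_csvs(truth_set$recording, prefix)
  if (format %in% c("openpose", "both"))
    out$frames_dir <- {
      d <- paste0(prefix, "_frames")
      write_openpose_frames(truth_set$recording, d)
      d
    }
  truth_path <- paste0(prefix, "_truth.csv")
  utils::write.csv(truth_set$truth, truth_path, row.names = FALSE,
                   quote = FALSE)
  out$truth <- truth_path
  ann_path <- paste0(prefix, "_truth_annotations.csv")
  write_annotation_csv(
    segments_to_annotations(truth_set$truth, truth_set$spec$fps,
                            tier = "truth", value = "movement"),
    ann_path)
  out$truth_annotations <- ann_path
  invisible(out)
}
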