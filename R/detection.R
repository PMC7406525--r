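#' Default manual keypoint set
#'
#' Selects the eight keypoints the detector consumes by default: both wrists,
#' a synthesized mid-forearm point for each arm (the coordinate midpoint of
#' elbow and wrist, with per-frame confidence the minimum of the two), and the
#' index fingertip and thumb tip of each hand. With `hands = "left"` or
#' `"right"` only that side's four tracks are returned.
#'
#' @param recording A [pose_recording()].
#' @param hands `"both"`, `"left"` or `"right"`.
#' @return A named list of [keypoint_track()]s (8 for both hands, 4 for one).
#' @export
derive_default_keypoints <- function(recording,
                                     hands = c("both", "left", "right")) {
  stopifnot(inherits(recording, "pose_recording"))
  hands <- match.arg(hands)

  side_tracks <- function(side) {
    pre <- if (side == "left") "l" else "r"
    hand <- if (side == "left") recording$left_hand else recording$right_hand
    wrist <- recording$body[[.body_idx[[paste0(pre, "_wrist")]]]]
    elbow <- recording$body[[.body_idx[[paste0(pre, "_elbow")]]]]
    forearm <- keypoint_track(
      x = (elbow$x + wrist$x) / 2,
      y = (elbow$y + wrist$y) / 2,
      confidence = pmin(elbow$confidence, wrist$confidence),
      fps = recording$fps,
      label = paste0(pre, "_forearm")
    )
    out <- list(wrist, forearm,
                hand[[.hand_idx[["index_tip"]]]],
                hand[[.hand_idx[["thumb_tip"]]]])
    stats::setNames(out, c(paste0(pre, "_wrist"), paste0(pre, "_forearm"),
                           paste0(pre, "h_index_tip"),
                           paste0(pre, "h_thumb_tip")))
  }

  switch(hands,
         both = c(side_tracks("left"), side_tracks("right")),
         left = side_tracks("left"),
         right = side_tracks("right"))
}

#' Pixel distance between two frames of a track
#'
#' @param track A [keypoint_track()].
#' @param i,j Frame indices (1-based).
#' @param metric `"euclidean"` (`sqrt(dx^2 + dy^2)`) or `"per-axis-max"`
#'   (`max(|dx|, |dy|)`).
#' @return Pixel distance (numeric scalar; vectorized over `j`).
#' @examples
#' kp <- keypoint_track(c(0, 3), c(0, 4), c(1, 1), fps = 25)
#' coordinate_distance(kp, 1, 2)                       # 5
#' coordinate_distance(kp, 1, 2, "per-axis-max")       # 4
#' @export
coordinate_distance <- function(track, i, j,
                                metric = c("euclidean", "per-axis-max")) {
  metric <- match.arg(metric)
  n <- n_frames(track)
  if (any(c(i, j) < 1L) || any(c(i, j) > n))
    stop("frame index out of range [1, ", n, "]", call. = FALSE)
  dx <- track$x[j] - track$x[i]
  dy <- track$y[j] - track$y[i]
  if (metric == "euclidean") sqrt(dx^2 + dy^2) else pmax(abs(dx), abs(dy))
}

#' Rest-state test
#'
#' Frame `k` is part of a rest state when at least a proportion
#' `rest_certainty` of the frames in a window of half-width `rest_halfwidth`
#' centred on `k` (frame `k` included; 15 frames at the defaults) lie strictly
#' within `rest_pixel_tolerance` pixels of frame `k`. At sequence edges the
#' window is clamped to existing frames and the proportion is taken over the
#' available frames.
#'
#' @param track A [keypoint_track()].
#' @param k Frame index (1-based).
#' @param params A [detection_params()].
#' @return Logical scalar.
#' @export
is_rest_state <- function(track, k, params = detection_params()) {
  n <- n_frames(track)
  if (k < 1L || k > n) stop("frame index out of range", call. = FALSE)
  win <- max(1L, k - params$rest_halfwidth):min(n, k + params$rest_halfwidth)
  d <- coordinate_distance(track, k, win, params$distance_metric)
  mean(d < params$rest_pixel_tolerance) >= params$rest_certainty
}

#' Movement-onset test
#'
#' Frame `k` is a movement onset when it lies more than
#' `movement_pixel_threshold` pixels from frame `k - 1` AND at least
#' `lookahead_min_count` of the (up to) `lookahead_frames` frames following
#' `k` lie more than `movement_pixel_threshold` pixels from frame `k`. The
#' lookahead confirmation suppresses single-frame coordinate spikes. The first
#' frame has no predecessor and is never an onset.
#'
#' @inheritParams is_rest_state
#' @return Logical scalar.
#' @export
is_movement_onset <- function(track, k, params = detection_params()) {
  n <- n_frames(track)
  if (k < 1L || k > n) stop("frame index out of range", call. = FALSE)
  if (k < 2L) return(FALSE)
  thr <- params$movement_pixel_threshold
  if (coordinate_distance(track, k, k - 1L, params$distance_metric) <= thr)
    return(FALSE)
  if (k >= n) return(FALSE)
  ahead <- (k + 1L):min(n, k + params$lookahead_frames)
  d <- coordinate_distance(track, k, ahead, params$distance_metric)
  sum(d > thr) >= params$lookahead_min_count
}

#' Per-keypoint movement mask
#'
#' Classifies every frame of one keypoint track as movement or rest, following
#' the detector's flowchart: (1) a frame whose confidence is below the
#' reliability threshold is marked no-movement; (2) a frame passing the
#' rest-state test is marked no-movement; (3) a frame passing the
#' movement-onset test starts a movement that extends up to (but excluding)
#' the next frame whose rest-state test passes, searched within
#' `rest_search_limit` upcoming frames — when no rest frame is found the
#' search range is grown by `search_growth_factor` and retried, capped at the
#' final frame (a movement with no subsequent rest runs to the end of the
#' recording); (4) any other frame is no-movement. Scanning resumes at the
#' rest frame that terminated the movement.
#'
#' @param track A [keypoint_track()].
#' @param params A [detection_params()].
#' @return A `movement_mask`: a logical vector (TRUE = movement) with a
#'   `provenance` attribute naming the keypoint.
#' @export
detect_movement_mask <- function(track, params = detection_params()) {
  stopifnot(inherits(track, "keypoint_track"))
  n <- n_frames(track)
  mask <- logical(n)
  k <- 1L
  while (k <= n) {
    if (track$confidence[k] < params$reliability_threshold ||
        is_rest_state(track, k, params) ||
        !is_movement_onset(track, k, params)) {
      k <- k + 1L
      next
    }
    # movement starting at k: find the next rest frame
    rest_at <- NA_integer_
    limit <- as.numeric(params$rest_search_limit)
    repeat {
      hi <- min(n, k + as.integer(ceiling(limit)))
      j <- k + 1L
      while (j <= hi) {
        if (is_rest_state(track, j, params)) { rest_at <- j; break }
        j <- j + 1L
      }
      if (!is.na(rest_at) || hi == n) break
      limit <- limit * params$search_growth_factor
    }
    if (is.na(rest_at)) {
      mask[k:n] <- TRUE
      k <- n + 1L
    } else {
      mask[k:(rest_at - 1L)] <- TRUE
      k <- rest_at
    }
  }
  movement_mask(mask, provenance = track$label)
}

#' Construct a movement mask
#'
#' @param mask Logical vector, one element per frame (TRUE = movement).
#' @param provenance Keypoint label, or `"merged"`.
#' @return An object of class `movement_mask`.
#' @export
movement_mask <- function(mask, provenance = "mask") {
  mask <- as.logical(mask)
  if (anyNA(mask)) stop("movement mask must not contain NA", call. = FALSE)
  structure(mask, provenance = as.character(provenance),
            class = "movement_mask")
}

#' @export
print.movement_mask <- function(x, ...) {
  cat(sprintf("Movement mask [%s]: %d / %d frames movement\n",
              attr(x, "provenance"), sum(x), length(unclass(x))))
  invisible(x)
}

#' Merge movement masks across keypoints
#'
#' Frame-wise logical OR of per-keypoint masks, so that a movement visible at
#' any consumed keypoint is kept even when other keypoints have low
#' reliability.
#'
#' @param masks A list of `movement_mask` objects of equal length.
#' @return A `movement_mask` with provenance `"merged"`.
#' @export
merge_masks <- function(masks) {
  if (length(masks) == 0L) stop("no masks to merge", call. = FALSE)
  lens <- vapply(masks, function(m) length(unclass(m)), integer(1))
  if (length(unique(lens)) != 1L)
    stop("masks differ in length: ", paste(unique(lens), collapse = ", "),
         call. = FALSE)
  merged <- Reduce(`|`, lapply(masks, function(m) as.logical(unclass(m))))
  movement_mask(merged, provenance = "merged")
}
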