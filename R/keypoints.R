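#' Keypoint label layouts
#'
#' Labels for the standard 25-keypoint body layout and 21-keypoint hand layout
#' used by common pose estimators, in on-disk order.
#'
#' @name keypoint_layouts
#' @keywords internal
NULL

body25_labels <- c(
  "nose", "neck",
  "r_shoulder", "r_elbow", "r_wrist",
  "l_shoulder", "l_elbow", "l_wrist",
  "mid_hip",
  "r_hip", "r_knee", "r_ankle",
  "l_hip", "l_knee", "l_ankle",
  "r_eye", "l_eye", "r_ear", "l_ear",
  "l_big_toe", "l_small_toe", "l_heel",
  "r_big_toe", "r_small_toe", "r_heel"
)

hand21_labels <- c(
  "wrist",
  "thumb1", "thumb2", "thumb3", "thumb_tip",
  "index1", "index2", "index3", "index_tip",
  "middle1", "middle2", "middle3", "middle_tip",
  "ring1", "ring2", "ring3", "ring_tip",
  "pinky1", "pinky2", "pinky3", "pinky_tip"
)

# 1-based positions of the keypoints the detector consumes
.body_idx <- c(r_elbow = 4L, r_wrist = 5L, l_elbow = 7L, l_wrist = 8L)
.hand_idx <- c(thumb_tip = 5L, index_tip = 9L)

#' Construct a keypoint track
#'
#' One tracked 2-D landmark over all frames of a recording: pixel x/y
#' coordinates plus a per-frame confidence score in \[0, 1\].
#'
#' @param x,y Numeric vectors of pixel coordinates, one element per frame.
#' @param confidence Numeric vector of per-frame confidences in \[0, 1\].
#' @param fps Frames per second of the source video (> 0).
#' @param label Keypoint name.
#' @return An object of class `keypoint_track`.
#' @examples
#' kp <- keypoint_track(x = rep(100, 30), y = rep(200, 30),
#'                      confidence = rep(0.9, 30), fps = 25, label = "l_wrist")
#' n_frames(kp)
#' @export
keypoint_track <- function(x, y, confidence, fps, label = "keypoint") {
  x <- as.numeric(x); y <- as.numeric(y); confidence <- as.numeric(confidence)
  n <- length(x)
  if (n < 1L) stop("a keypoint track needs at least one frame", call. = FALSE)
  if (length(y) != n || length(confidence) != n)
    stop("x, y and confidence must have identical length", call. = FALSE)
  if (anyNA(x) || anyNA(y) || anyNA(confidence))
    stop("keypoint tracks must not contain NA", call. = FALSE)
  if (any(confidence < 0 | confidence > 1))
    stop("confidence must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number", call. = FALSE)
  structure(
    list(x = x, y = y, confidence = confidence,
         fps = as.numeric(fps), label = as.character(label)),
    class = "keypoint_track"
  )
}

#' Number of frames
#'
#' @param x A `keypoint_track`, `pose_recording` or `movement_mask`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.keypoint_track <- function(x) length(x$x)

#' @export
n_frames.pose_recording <- function(x) x$n_frames

#' @export
n_frames.movement_mask <- function(x) length(unclass(x))

#' @export
print.keypoint_track <- function(x, ...) {
  cat(sprintf("Keypoint track '%s': %d frames at %g fps (mean confidence %.2f)\n",
              x$label, n_frames(x), x$fps, mean(x$confidence)))
  invisible(x)
}

#' Construct a pose recording
#'
#' Aligned body and hand keypoint tracks for one person over all frames:
#' 25 body keypoints and 21 keypoints per hand, each an (x, y, confidence)
#' track.
#'
#' @param body List of exactly 25 `keypoint_track`s in standard body order.
#' @param left_hand,right_hand Lists of exactly 21 `keypoint_track`s each, in
#'   standard hand order.
#' @param fps Frames per second; must match every track.
#' @return An object of class `pose_recording` with elements `body`,
#'   `left_hand`, `right_hand`, `n_frames` and `fps`.
#' @export
pose_recording <- function(body, left_hand, right_hand, fps) {
  if (length(body) != 25L)
    stop("body must contain exactly 25 keypoint tracks", call. = FALSE)
  if (length(left_hand) != 21L || length(right_hand) != 21L)
    stop("each hand must contain exactly 21 keypoint tracks", call. = FALSE)
  all_tracks <- c(body, left_hand, right_hand)
  if (!all(vapply(all_tracks, inherits, logical(1), "keypoint_track")))
    stop("all elements must be keypoint_track objects", call. = FALSE)
  lens <- vapply(all_tracks, n_frames, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all tracks must share the same number of frames", call. = FALSE)
  if (!all(vapply(all_tracks, function(t) isTRUE(all.equal(t$fps, fps)),
                  logical(1))))
    stop("all tracks must share fps = ", fps, call. = FALSE)
  names(body) <- body25_labels
  names(left_hand) <- paste0("lh_", hand21_labels)
  names(right_hand) <- paste0("rh_", hand21_labels)
  structure(
    list(body = body, left_hand = left_hand, right_hand = right_hand,
         n_frames = lens[[1L]], fps = as.numeric(fps)),
    class = "pose_recording"
  )
}

#' @export
print.pose_recording <- function(x, ...) {
  cat(sprintf("Pose recording: %d frames at %g fps (%.1f s)\n",
              x$n_frames, x$fps, x$n_frames / x$fps))
  cat("  25 body keypoints, 21 left-hand, 21 right-hand\n")
  invisible(x)
}

# build a track list from column-major matrices (n_frames x k)
.tracks_from_matrices <- function(xm, ym, cm, fps, labels) {
  lapply(seq_along(labels), function(i) {
    keypoint_track(xm[, i], ym[, i], cm[, i], fps = fps, label = labels[i])
  })
}
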