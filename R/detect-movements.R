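#' Detect hand movements in a pose recording
#'
#' The end-to-end detector: selects the default manual keypoints for the
#' requested hand(s), classifies every frame of each keypoint as rest or
#' movement with the thresholded window tests, merges the per-keypoint masks
#' (frame-wise OR), extracts movement segments, applies post-processing
#' (short-segment removal and gap merging) and converts the surviving
#' segments to time-stamped annotations.
#'
#' @param recording A [pose_recording()].
#' @param params A [detection_params()]; `params$hands` selects the keypoint
#'   set.
#' @param tier Tier label used for the exported annotations.
#' @return An object of class `movement_detection`: a list with the selected
#'   `keypoints`, per-keypoint `masks`, the `merged_mask`, `segments_raw`
#'   (before post-processing), `segments` (after), `annotations`, plus
#'   `n_frames`, `fps` and `params`.
#' @examples
#' ts <- generate_recording(scenario_spec(200, episodes = data.frame(
#'   onset = 81, duration = 30, amplitude = 120, shape = "ramp"), seed = 7))
#' det <- detect_movements(ts$recording)
#' det$segments
#' @export
detect_movements <- function(recording, params = detection_params(),
                             tier = "movement") {
  stopifnot(inherits(recording, "pose_recording"),
            inherits(params, "detection_params"))
  tracks <- derive_default_keypoints(recording, params$hands)
  masks <- lapply(tracks, detect_movement_mask, params = params)
  merged <- merge_masks(masks)
  segments_raw <- mask_to_segments(merged)
  segments <- postprocess_segments(segments_raw, params)
  structure(
    list(
      keypoints = names(tracks),
      masks = masks,
      merged_mask = merged,
      segments_raw = segments_raw,
      segments = segments,
      annotations = segments_to_annotations(segments, recording$fps,
                                            tier = tier),
      n_frames = recording$n_frames,
      fps = recording$fps,
      params = params
    ),
    class = "movement_detection"
  )
}

#' @export
print.movement_detection <- function(x, ...) {
  cat(sprintf("Movement detection: %d segment(s) in %d frames (%.1f s at %g fps)\n",
              nrow(x$segments), x$n_frames, x$n_frames / x$fps, x$fps))
  cat(sprintf("  keypoints: %s\n", paste(x$keypoints, collapse = ", ")))
  cat(sprintf("  segments before/after post-processing: %d / %d\n",
              nrow(x$segments_raw), nrow(x$segments)))
  invisible(x)
}

#' @export
summary.movement_detection <- function(object, ...) {
  per_kp <- vapply(object$masks, function(m) sum(unclass(m)), integer(1))
  out <- list(
    n_frames = object$n_frames,
    fps = object$fps,
    movement_frames_per_keypoint = per_kp,
    movement_frames_merged = sum(unclass(object$merged_mask)),
    n_segments_raw = nrow(object$segments_raw),
    n_segments = nrow(object$segments),
    total_movement_s = sum(segment_duration_frames(object$segments)) /
      object$fps,
    segments = object$segments
  )
  class(out) <- "summary.movement_detection"
  out
}

#' @export
print.summary.movement_detection <- function(x, ...) {
  cat(sprintf("Movement detection over %d frames at %g fps\n",
              x$n_frames, x$fps))
  cat("Movement frames per keypoint:\n")
  for (nm in names(x$movement_frames_per_keypoint))
    cat(sprintf("  %-14s %6d\n", nm, x$movement_frames_per_keypoint[[nm]]))
  cat(sprintf("Merged movement frames : %d (%.1f%%)\n",
              x$movement_frames_merged,
              100 * x$movement_frames_merged / x$n_frames))
  cat(sprintf("Segments raw -> final  : %d -> %d\n",
              x$n_segments_raw, x$n_segments))
  cat(sprintf("Total movement time    : %.2f s\n", x$total_movement_s))
  invisible(x)
}

#' @export
as.data.frame.movement_detection <- function(x, ...) {
  x$annotations
}

#' Plot a movement detection timeline
#'
#' Draws the per-keypoint movement masks as horizontal raster rows over time
#' and the final post-processed segments as a bottom band.
#'
#' @param x A `movement_detection`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.movement_detection <- function(x, ...) {
  k <- length(x$masks)
  tt <- (seq_len(x$n_frames) - 0.5) / x$fps
  graphics::plot(NA, xlim = c(0, x$n_frames / x$fps),
                 ylim = c(0, k + 1.5), yaxt = "n",
                 xlab = "time (s)", ylab = "",
                 main = "Detected movement", ...)
  graphics::axis(2, at = c(seq_len(k), k + 1),
                 labels = c(names(x$masks), "final"), las = 1, cex.axis = 0.7)
  for (i in seq_len(k)) {
    on <- which(unclass(x$masks[[i]]))
    if (length(on))
      graphics::segments(tt[on] - 0.5 / x$fps, i, tt[on] + 0.5 / x$fps, i,
                         col = "grey40", lwd = 4)
  }
  for (r in seq_len(nrow(x$segments)))
    graphics::rect((x$segments$start_frame[r] - 1) / x$fps, k + 0.8,
                   x$segments$end_frame[r] / x$fps, k + 1.2,
                   col = "firebrick", border = NA)
  invisible(x)
}
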