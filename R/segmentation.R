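#' Extract movement segments from a mask
#'
#' Maximal runs of movement frames, as a data frame of 1-based inclusive
#' frame indices, sorted and separated by at least one rest frame.
#'
#' @param mask A `movement_mask` or logical vector.
#' @return A data frame with columns `start_frame` and `end_frame`.
#' @examples
#' m <- rep(FALSE, 20); m[4:8] <- TRUE; m[11] <- TRUE
#' mask_to_segments(m)  # rows (4, 8) and (11, 11)
#' @export
mask_to_segments <- function(mask) {
  mask <- as.logical(unclass(mask))
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  if (length(mask) == 0L || !any(mask)) return(.empty_segments())
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_frame = starts[keep], end_frame = ends[keep])
}

.empty_segments <- function() {
  data.frame(start_frame = integer(0), end_frame = integer(0))
}

.validate_segments <- function(segments, what = "segments") {
  if (!is.data.frame(segments) ||
      !all(c("start_frame", "end_frame") %in% names(segments)))
    stop(what, " must be a data frame with start_frame and end_frame columns",
         call. = FALSE)
  if (nrow(segments) == 0L) return(invisible(segments))
  if (any(segments$start_frame < 1L) ||
      any(segments$end_frame < segments$start_frame))
    stop(what, " must satisfy 1 <= start_frame <= end_frame", call. = FALSE)
  if (nrow(segments) > 1L) {
    s <- segments$start_frame; e <- segments$end_frame
    if (any(s[-1L] <= e[-length(e)]))
      stop(what, " must be sorted and non-overlapping", call. = FALSE)
  }
  invisible(segments)
}

#' Segment duration in frames
#'
#' @param segments A segment data frame.
#' @return Integer vector of inclusive frame counts.
#' @export
segment_duration_frames <- function(segments) {
  segments$end_frame - segments$start_frame + 1L
}

#' Remove short movement segments
#'
#' Drops every segment shorter than `min_segment_frames` (default 4) to
#' reduce false positives from brief coordinate flickers.
#'
#' @param segments A sorted, non-overlapping segment data frame.
#' @param params A [detection_params()].
#' @return The filtered segment data frame, order preserved.
#' @export
drop_short_segments <- function(segments, params = detection_params()) {
  .validate_segments(segments)
  keep <- segment_duration_frames(segments) >= params$min_segment_frames
  segments[keep, , drop = FALSE]
}

#' Merge movement segments separated by short gaps
#'
#' Consecutive segments whose gap (frames strictly between them,
#' `next$start_frame - prev$end_frame - 1`) is at most `max_merge_gap_frames`
#' (default 4) are coalesced, transitively left-to-right, to absorb brief
#' pauses or holds inside one movement.
#'
#' @inheritParams drop_short_segments
#' @return The merged segment data frame.
#' @export
merge_close_segments <- function(segments, params = detection_params()) {
  .validate_segments(segments)
  n <- nrow(segments)
  if (n <= 1L) return(segments)
  starts <- segments$start_frame
  ends <- segments$end_frame
  out_s <- starts[1L]; out_e <- ends[1L]
  for (i in 2L:n) {
    gap <- starts[i] - out_e[length(out_e)] - 1L
    if (gap <= params$max_merge_gap_frames) {
      out_e[length(out_e)] <- ends[i]
    } else {
      out_s <- c(out_s, starts[i])
      out_e <- c(out_e, ends[i])
    }
  }
  data.frame(start_frame = out_s, end_frame = out_e)
}

#' Post-process raw movement segments
#'
#' Applies short-segment removal then gap merging (or the reverse, per
#' `params$rule_order`).
#'
#' @inheritParams drop_short_segments
#' @return The post-processed segment data frame.
#' @export
postprocess_segments <- function(segments, params = detection_params()) {
  if (params$rule_order == "drop_first") {
    merge_close_segments(drop_short_segments(segments, params), params)
  } else {
    drop_short_segments(merge_close_segments(segments, params), params)
  }
}

#' Convert a frame boundary to an hh:mm:ss.ms timestamp
#'
#' A boundary of `b` frames corresponds to `b * 1000 / fps` milliseconds
#' (40 ms per frame at 25 fps), rounded to the nearest millisecond (ties away
#' from zero) and rendered zero-padded as `hh:mm:ss.ms`. Frame `i` (1-based)
#' spans boundaries `i - 1` to `i`.
#'
#' @param frame_boundary Non-negative frame count(s).
#' @param fps Frames per second (> 0).
#' @return Character timestamp(s) `"hh:mm:ss.mmm"`.
#' @examples
#' frame_to_timestamp(1, 25)      # "00:00:00.040"
#' frame_to_timestamp(93025, 25)  # "01:02:01.000"
#' @export
frame_to_timestamp <- function(frame_boundary, fps) {
  if (any(frame_boundary < 0))
    stop("frame boundaries must be non-negative", call. = FALSE)
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0", call. = FALSE)
  ms <- floor(frame_boundary * 1000 / fps + 0.5)
  .format_ms(ms)
}

.format_ms <- function(ms) {
  ms <- as.numeric(ms)
  h <- ms %/% 3600000
  m <- (ms %% 3600000) %/% 60000
  s <- (ms %% 60000) %/% 1000
  r <- ms %% 1000
  sprintf("%02d:%02d:%02d.%03d", h, m, s, r)
}

#' Parse an hh:mm:ss.ms timestamp to milliseconds
#'
#' @param ts Character timestamp(s) in `hh:mm:ss.ms` form.
#' @return Numeric milliseconds.
#' @export
timestamp_to_ms <- function(ts) {
  m <- regmatches(ts, regexec("^(\\d+):([0-5]\\d):([0-5]\\d)\\.(\\d{1,3})$",
                              as.character(ts)))
  vapply(seq_along(m), function(i) {
    g <- m[[i]]
    if (length(g) != 5L)
      stop("unparseable timestamp: '", ts[i], "'", call. = FALSE)
    frac <- g[5L]
    ms <- as.numeric(frac) * 10^(3L - nchar(frac))
    as.numeric(g[2L]) * 3600000 + as.numeric(g[3L]) * 60000 +
      as.numeric(g[4L]) * 1000 + ms
  }, numeric(1))
}

#' Convert movement segments to time-stamped annotations
#'
#' Begin is the segment's leading frame boundary (`start_frame - 1`), end the
#' exclusive trailing boundary (`end_frame`), so a segment's duration equals
#' its frame count times the frame duration.
#'
#' @param segments A sorted, non-overlapping segment data frame.
#' @param fps Frames per second.
#' @param tier Tier label for the annotations.
#' @param value Annotation text.
#' @return A data frame with columns `tier`, `begin`, `end`, `value`
#'   (timestamps as `hh:mm:ss.ms` character).
#' @export
segments_to_annotations <- function(segments, fps, tier = "movement",
                                    value = "movement") {
  .validate_segments(segments)
  if (nrow(segments) == 0L)
    return(data.frame(tier = character(0), begin = character(0),
                      end = character(0), value = character(0)))
  data.frame(
    tier = tier,
    begin = frame_to_timestamp(segments$start_frame - 1L, fps),
    end = frame_to_timestamp(segments$end_frame, fps),
    value = value
  )
}

#' Convert annotations back to frame segments
#'
#' Inverse of [segments_to_annotations()] at the same fps; exact whenever the
#' frame duration `1000 / fps` is an integral number of milliseconds.
#'
#' @param annotations Annotation data frame with `begin` and `end` timestamps.
#' @param fps Frames per second.
#' @return A sorted segment data frame.
#' @export
annotations_to_segments <- function(annotations, fps) {
  if (nrow(annotations) == 0L) return(.empty_segments())
  b <- timestamp_to_ms(annotations$begin)
  e <- timestamp_to_ms(annotations$end)
  seg <- data.frame(
    start_frame = as.integer(floor(b * fps / 1000 + 0.5)) + 1L,
    end_frame = as.integer(floor(e * fps / 1000 + 0.5))
  )
  seg <- seg[order(seg$start_frame), , drop = FALSE]
  rownames(seg) <- NULL
  .validate_segments(seg, "annotations")
  seg
}

#' Paint segments onto a frame mask
#'
#' @param segments A segment data frame.
#' @param n_frames Total frame count of the timeline.
#' @return A `movement_mask` of length `n_frames`.
#' @export
segments_to_mask <- function(segments, n_frames) {
  .validate_segments(segments)
  if (nrow(segments) > 0L && max(segments$end_frame) > n_frames)
    stop("segments extend past n_frames", call. = FALSE)
  mask <- logical(n_frames)
  for (i in seq_len(nrow(segments)))
    mask[segments$start_frame[i]:segments$end_frame[i]] <- TRUE
  movement_mask(mask, provenance = "segments")
}
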