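#' Detection parameters
#'
#' Bundle of every tunable threshold used by the movement detector and the
#' segment post-processing, with the defaults the method was calibrated with
#' at 25 frames per second.
#'
#' @param reliability_threshold Minimum keypoint confidence; frames whose
#'   confidence falls below it are never classified as movement. Default 0.3.
#' @param rest_halfwidth Half-width, in frames, of the rest-state window
#'   centred on the frame under test. Default 7, i.e. a 15-frame window
#'   (600 ms at 25 fps).
#' @param rest_pixel_tolerance Pixel distance below which a window frame
#'   counts as "at rest" relative to the centre frame. Default 10.
#' @param rest_certainty Proportion of window frames that must lie within
#'   `rest_pixel_tolerance` for the centre frame to be a rest state.
#'   Default 0.7.
#' @param movement_pixel_threshold Pixel distance that must be exceeded, both
#'   against the previous frame and in the lookahead test, for a movement
#'   onset. Default 5.
#' @param lookahead_frames Number of frames after a candidate onset inspected
#'   by the confirmation test. Default 5.
#' @param lookahead_min_count Minimum number of lookahead frames that must
#'   exceed `movement_pixel_threshold` from the candidate onset. Default 3.
#' @param rest_search_limit Number of upcoming frames searched for a rest
#'   state once a movement has started (about 12 s at 25 fps). Default 300.
#' @param search_growth_factor Multiplier applied to the search range when no
#'   rest state is found within it; the retry is capped at the final frame.
#'   Default 1.5.
#' @param min_segment_frames Segments shorter than this many frames are
#'   removed in post-processing. Default 4.
#' @param max_merge_gap_frames Segments separated by at most this many frames
#'   are merged in post-processing. Default 4.
#' @param hands Which hands to analyse: `"both"`, `"left"` or `"right"`.
#' @param distance_metric `"euclidean"` (default) or `"per-axis-max"`
#'   (`max(|dx|, |dy|)`).
#' @param rule_order Post-processing order: `"drop_first"` (default; remove
#'   short segments, then merge close ones) or `"merge_first"`.
#'
#' @return An object of class `detection_params` (a validated list).
#' @examples
#' p <- detection_params()
#' p$rest_halfwidth * 2 + 1  # 15-frame rest window
#' @export
detection_params <- function(reliability_threshold = 0.3,
                             rest_halfwidth = 7,
                             rest_pixel_tolerance = 10,
                             rest_certainty = 0.7,
                             movement_pixel_threshold = 5,
                             lookahead_frames = 5,
                             lookahead_min_count = 3,
                             rest_search_limit = 300,
                             search_growth_factor = 1.5,
                             min_segment_frames = 4,
                             max_merge_gap_frames = 4,
                             hands = c("both", "left", "right"),
                             distance_metric = c("euclidean", "per-axis-max"),
                             rule_order = c("drop_first", "merge_first")) {
  hands <- match.arg(hands)
  distance_metric <- match.arg(distance_metric)
  rule_order <- match.arg(rule_order)

  p <- list(
    reliability_threshold = as.numeric(reliability_threshold),
    rest_halfwidth = as.integer(rest_halfwidth),
    rest_pixel_tolerance = as.numeric(rest_pixel_tolerance),
    rest_certainty = as.numeric(rest_certainty),
    movement_pixel_threshold = as.numeric(movement_pixel_threshold),
    lookahead_frames = as.integer(lookahead_frames),
    lookahead_min_count = as.integer(lookahead_min_count),
    rest_search_limit = as.integer(rest_search_limit),
    search_growth_factor = as.numeric(search_growth_factor),
    min_segment_frames = as.integer(min_segment_frames),
    max_merge_gap_frames = as.integer(max_merge_gap_frames),
    hands = hands,
    distance_metric = distance_metric,
    rule_order = rule_order
  )

  counts <- c("rest_halfwidth", "lookahead_frames", "lookahead_min_count",
              "rest_search_limit", "min_segment_frames",
              "max_merge_gap_frames")
  for (nm in counts) {
    if (is.na(p[[nm]]) || p[[nm]] < 1L)
      stop("'", nm, "' must be a count >= 1", call. = FALSE)
  }
  if (!is.finite(p$reliability_threshold) || p$reliability_threshold < 0)
    stop("'reliability_threshold' must be non-negative", call. = FALSE)
  if (!is.finite(p$rest_certainty) ||
      p$rest_certainty <= 0 || p$rest_certainty > 1)
    stop("'rest_certainty' must lie in (0, 1]", call. = FALSE)
  for (nm in c("rest_pixel_tolerance", "movement_pixel_threshold")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("'", nm, "' must be > 0", call. = FALSE)
  }
  if (!is.finite(p$search_growth_factor) || p$search_growth_factor <= 1)
    stop("'search_growth_factor' must be > 1", call. = FALSE)

  class(p) <- "detection_params"
  p
}

#' @export
print.detection_params <- function(x, ...) {
  cat("Movement-detection parameters\n")
  cat(sprintf("  reliability threshold : %.3g\n", x$reliability_threshold))
  cat(sprintf("  rest window           : %d frames (half-width %d), tolerance %g px, certainty %g\n",
              2L * x$rest_halfwidth + 1L, x$rest_halfwidth,
              x$rest_pixel_tolerance, x$rest_certainty))
  cat(sprintf("  movement onset        : > %g px vs previous frame; >= %d of %d lookahead frames > %g px\n",
              x$movement_pixel_threshold, x$lookahead_min_count,
              x$lookahead_frames, x$movement_pixel_threshold))
  cat(sprintf("  rest search           : %d frames, growth x%g\n",
              x$rest_search_limit, x$search_growth_factor))
  cat(sprintf("  post-processing       : drop < %d frames, merge gaps <= %d frames (%s)\n",
              x$min_segment_frames, x$max_merge_gap_frames, x$rule_order))
  cat(sprintf("  hands = %s, distance = %s\n", x$hands, x$distance_metric))
  invisible(x)
}
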