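#' Temporal overlap between two segments
#'
#' Proportion of shared frames: intersection over union by default (0 for
#' disjoint segments, 1 iff identical), or intersection over the longer
#' segment's duration with `method = "max"`.
#'
#' @param a,b Segments, each either a numeric `c(start_frame, end_frame)` or a
#'   one-row segment data frame (1-based inclusive frames).
#' @param method `"union"` (default, Jaccard) or `"max"` (intersection over
#'   the longer duration).
#' @return Overlap proportion in \[0, 1\].
#' @examples
#' temporal_overlap(c(1, 10), c(6, 15))  # 5 / 15
#' @export
temporal_overlap <- function(a, b, method = c("union", "max")) {
  method <- match.arg(method)
  a <- .as_span(a); b <- .as_span(b)
  inter <- min(a[2L], b[2L]) - max(a[1L], b[1L]) + 1
  if (inter <= 0) return(0)
  da <- a[2L] - a[1L] + 1
  db <- b[2L] - b[1L] + 1
  denom <- if (method == "union") da + db - inter else max(da, db)
  inter / denom
}

.as_span <- function(s) {
  if (is.data.frame(s)) s <- c(s$start_frame[[1L]], s$end_frame[[1L]])
  s <- as.numeric(s)
  if (length(s) != 2L || s[2L] < s[1L])
    stop("a segment is c(start_frame, end_frame) with start <= end",
         call. = FALSE)
  s
}

#' Match detected segments against reference segments
#'
#' Greedy one-to-one matching in timeline order: walking both sorted lists, a
#' detected/reference pair is matched when their [temporal_overlap()] reaches
#' `criterion` (default 0.6, the conventional 60% overlap criterion for
#' event-level agreement); otherwise the segment that ends earlier is skipped.
#'
#' @param detected,reference Sorted, non-overlapping segment data frames.
#' @param criterion Minimum overlap proportion for a match (default 0.6).
#' @param method Overlap definition passed to [temporal_overlap()].
#' @return An object of class `agreement_report`: a list with `n_reference`,
#'   `n_detected`, `n_matched`, `recall` (1 when there are no reference
#'   segments), `precision` (1 when there are no detections),
#'   `overlap_criterion`, and `matches` (data frame of matched index pairs).
#' @export
match_segments <- function(detected, reference, criterion = 0.6,
                           method = c("union", "max")) {
  method <- match.arg(method)
  .validate_segments(detected, "detected")
  .validate_segments(reference, "reference")
  if (criterion <= 0 || criterion > 1)
    stop("criterion must lie in (0, 1]", call. = FALSE)

  nd <- nrow(detected); nr <- nrow(reference)
  i <- 1L; j <- 1L
  mi <- integer(0); mj <- integer(0)
  while (i <= nd && j <= nr) {
    ov <- temporal_overlap(detected[i, ], reference[j, ], method)
    if (ov >= criterion) {
      mi <- c(mi, i); mj <- c(mj, j)
      i <- i + 1L; j <- j + 1L
    } else if (detected$end_frame[i] < reference$end_frame[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  n_matched <- length(mi)
  structure(
    list(
      n_reference = nr, n_detected = nd, n_matched = n_matched,
      recall = if (nr == 0L) 1 else n_matched / nr,
      precision = if (nd == 0L) 1 else n_matched / nd,
      overlap_criterion = criterion,
      matches = data.frame(detected = mi, reference = mj)
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Segment-matching agreement\n")
  cat(sprintf("  overlap criterion : %.0f%%\n", 100 * x$overlap_criterion))
  cat(sprintf("  reference segments: %d\n", x$n_reference))
  cat(sprintf("  detected segments : %d\n", x$n_detected))
  cat(sprintf("  matched           : %d\n", x$n_matched))
  cat(sprintf("  recall            : %.3f\n", x$recall))
  cat(sprintf("  precision         : %.3f\n", x$precision))
  if (!is.null(x$raw_agreement))
    cat(sprintf("  raw agreement     : %.3f\n", x$raw_agreement))
  invisible(x)
}

#' Frame-wise raw agreement between two masks
#'
#' Proportion of frames on which two movement/no-movement label sequences
#' agree.
#'
#' @param mask_a,mask_b Movement masks or logical vectors of equal length.
#' @return Proportion in \[0, 1\].
#' @export
raw_agreement <- function(mask_a, mask_b) {
  a <- as.logical(unclass(mask_a))
  b <- as.logical(unclass(mask_b))
  if (length(a) != length(b))
    stop("masks differ in length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  if (length(a) == 0L) stop("masks are empty", call. = FALSE)
  mean(a == b)
}

#' Full agreement report between detected and reference segments
#'
#' Combines [match_segments()] with frame-wise [raw_agreement()] over a
#' shared timeline.
#'
#' @inheritParams match_segments
#' @param n_frames Timeline length in frames; defaults to the largest end
#'   frame present in either list.
#' @return An `agreement_report` with an additional `raw_agreement` element.
#' @export
evaluate_agreement <- function(detected, reference, criterion = 0.6,
                               n_frames = NULL,
                               method = c("union", "max")) {
  method <- match.arg(method)
  report <- match_segments(detected, reference, criterion, method)
  if (is.null(n_frames)) {
    n_frames <- max(1L, detected$end_frame, reference$end_frame)
  }
  report$raw_agreement <- raw_agreement(
    segments_to_mask(detected, n_frames),
    segments_to_mask(reference, n_frames)
  )
  report$n_frames <- n_frames
  report
}
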