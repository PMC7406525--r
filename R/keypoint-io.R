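#' Read per-frame pose-estimator JSON documents
#'
#' Reads the one-document-per-frame JSON dialect emitted by common pose
#' estimators (a `people` array whose entries carry flat
#' `pose_keypoints_2d` / `hand_left_keypoints_2d` / `hand_right_keypoints_2d`
#' triplet vectors) into a [pose_recording()].
#'
#' A frame whose document lists no detected person yields all-zero coordinates
#' with confidence 0 at every keypoint. If a document lists several people the
#' first is taken and a warning is issued; the detector is designed for a
#' single individual.
#'
#' @param frames A directory containing `*.json` frame documents (sorted by
#'   name), a character vector of file paths in frame order, or a list of
#'   already-parsed documents in frame order.
#' @param fps Frames per second of the source video.
#' @return A [pose_recording()] with `n_frames` equal to the number of
#'   documents.
#' @export
read_openpose_frames <- function(frames, fps) {
  docs <- .collect_frame_docs(frames)
  n <- length(docs)
  if (n == 0L) stop("no frame documents supplied", call. = FALSE)

  body <- matrix(0, n, 75L)
  lh <- matrix(0, n, 63L)
  rh <- matrix(0, n, 63L)
  multi <- FALSE

  for (i in seq_len(n)) {
    doc <- docs[[i]]
    people <- doc$people
    if (is.null(people) || length(people) == 0L) next  # no person: stay zero
    if (is.data.frame(people)) {
      if (nrow(people) == 0L) next
      if (nrow(people) > 1L) multi <- TRUE
      person <- lapply(people, function(col) col[[1L]])
    } else {
      if (length(people) > 1L) multi <- TRUE
      person <- people[[1L]]
    }
    body[i, ] <- .frame_block(person$pose_keypoints_2d, 75L, i, "body")
    lh[i, ] <- .frame_block(person$hand_left_keypoints_2d, 63L, i, "left hand")
    rh[i, ] <- .frame_block(person$hand_right_keypoints_2d, 63L, i, "right hand")
  }
  if (multi)
    warning("some frames contain multiple people; using the first person",
            call. = FALSE)

  .recording_from_flat(body, lh, rh, fps)
}

.collect_frame_docs <- function(frames) {
  if (is.character(frames) && length(frames) == 1L && dir.exists(frames)) {
    frames <- sort(list.files(frames, pattern = "\\.json$", full.names = TRUE))
  }
  if (is.character(frames)) {
    missing <- frames[!file.exists(frames)]
    if (length(missing))
      stop("frame document not found: ", missing[[1L]], call. = FALSE)
    return(lapply(frames, jsonlite::fromJSON, simplifyVector = TRUE,
                  simplifyDataFrame = TRUE))
  }
  if (is.list(frames)) return(frames)
  stop("'frames' must be a directory, file paths, or a list of documents",
       call. = FALSE)
}

.frame_block <- function(values, expected, frame, what) {
  values <- as.numeric(unlist(values, use.names = FALSE))
  if (length(values) != expected)
    stop(sprintf("frame %d: %s block has %d numbers, expected %d",
                 frame, what, length(values), expected), call. = FALSE)
  values
}

# flat (n x 3k) triplet matrices -> pose_recording
.recording_from_flat <- function(body, lh, rh, fps) {
  split3 <- function(m) {
    k <- ncol(m) / 3L
    idx <- 3L * (seq_len(k) - 1L)
    list(x = m[, idx + 1L, drop = FALSE],
         y = m[, idx + 2L, drop = FALSE],
         c = m[, idx + 3L, drop = FALSE])
  }
  b <- split3(body); l <- split3(lh); r <- split3(rh)
  pose_recording(
    body = .tracks_from_matrices(b$x, b$y, b$c, fps, body25_labels),
    left_hand = .tracks_from_matrices(l$x, l$y, l$c, fps,
                                      paste0("lh_", hand21_labels)),
    right_hand = .tracks_from_matrices(r$x, r$y, r$c, fps,
                                       paste0("rh_", hand21_labels)),
    fps = fps
  )
}

#' Write per-frame pose-estimator JSON documents
#'
#' Inverse of [read_openpose_frames()]: one JSON document per frame under
#' `dir`, named `frame_%06d_keypoints.json`.
#'
#' @param recording A [pose_recording()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_openpose_frames <- function(recording, dir) {
  stopifnot(inherits(recording, "pose_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flat <- function(tracks, i) {
    as.numeric(rbind(
      vapply(tracks, function(t) t$x[i], numeric(1)),
      vapply(tracks, function(t) t$y[i], numeric(1)),
      vapply(tracks, function(t) t$confidence[i], numeric(1))
    ))
  }
  paths <- character(recording$n_frames)
  for (i in seq_len(recording$n_frames)) {
    doc <- list(version = 1.3, people = list(list(
      pose_keypoints_2d = flat(recording$body, i),
      hand_left_keypoints_2d = flat(recording$left_hand, i),
      hand_right_keypoints_2d = flat(recording$right_hand, i)
    )))
    paths[i] <- file.path(dir, sprintf("frame_%06d_keypoints.json", i))
    jsonlite::write_json(doc, paths[i], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Write the three intermediate keypoint CSVs
#'
#' Writes one CSV per block (body, left hand, right hand): one row per frame,
#' a leading `frame` column (1-based), then `<label>_x`, `<label>_y`,
#' `<label>_c` per keypoint in layout order. Round-trips losslessly through
#' [read_keypoint_csvs()].
#'
#' @param recording A [pose_recording()].
#' @param prefix Path prefix; files are written as `<prefix>_body.csv`,
#'   `<prefix>_left_hand.csv`, `<prefix>_right_hand.csv`.
#' @return Invisibly, a named character vector of the three paths.
#' @export
write_keypoint_csvs <- function(recording, prefix) {
  stopifnot(inherits(recording, "pose_recording"))
  out <- c(body = paste0(prefix, "_body.csv"),
           left_hand = paste0(prefix, "_left_hand.csv"),
           right_hand = paste0(prefix, "_right_hand.csv"))
  for (block in names(out)) {
    tracks <- recording[[block]]
    cols <- vector("list", 1L + 3L * length(tracks))
    nms <- character(length(cols))
    cols[[1L]] <- seq_len(recording$n_frames); nms[1L] <- "frame"
    j <- 2L
    for (t in tracks) {
      cols[[j]] <- t$x; nms[j] <- paste0(t$label, "_x")
      cols[[j + 1L]] <- t$y; nms[j + 1L] <- paste0(t$label, "_y")
      cols[[j + 2L]] <- t$confidence; nms[j + 2L] <- paste0(t$label, "_c")
      j <- j + 3L
    }
    df <- stats::setNames(as.data.frame(cols), nms)
    utils::write.csv(df, out[[block]], row.names = FALSE, quote = FALSE)
  }
  invisible(out)
}

#' Read the three intermediate keypoint CSVs
#'
#' @param body_path,left_hand_path,right_hand_path Paths to the three CSVs in
#'   the layout written by [write_keypoint_csvs()].
#' @param fps Frames per second of the source video.
#' @return A [pose_recording()].
#' @export
read_keypoint_csvs <- function(body_path, left_hand_path, right_hand_path,
                               fps) {
  paths <- c(body_path, left_hand_path, right_hand_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("keypoint CSV not found: ", missing[[1L]], call. = FALSE)
  dfs <- lapply(paths, utils::read.csv, check.names = FALSE)
  nr <- vapply(dfs, nrow, integer(1))
  if (length(unique(nr)) != 1L)
    stop(sprintf(
      "frame counts disagree across keypoint CSVs: body %d, left hand %d, right hand %d",
      nr[1L], nr[2L], nr[3L]), call. = FALSE)

  read_block <- function(df, labels) {
    lapply(labels, function(lab) {
      need <- paste0(lab, c("_x", "_y", "_c"))
      if (!all(need %in% names(df)))
        stop("keypoint CSV is missing columns for '", lab, "'", call. = FALSE)
      keypoint_track(df[[need[1L]]], df[[need[2L]]], df[[need[3L]]],
                     fps = fps, label = lab)
    })
  }
  pose_recording(
    body = read_block(dfs[[1L]], body25_labels),
    left_hand = read_block(dfs[[2L]], paste0("lh_", hand21_labels)),
    right_hand = read_block(dfs[[3L]], paste0("rh_", hand21_labels)),
    fps = fps
  )
}
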