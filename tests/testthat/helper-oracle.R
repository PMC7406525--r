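# Independent, literal transcription of the detection flowchart, written
# frame-by-frame with explicit counting loops. Used only as a cross-check
# oracle for detect_movement_mask; deliberately shares no code with the
# package internals.

oracle_pixdist <- function(track, i, j, metric = "euclidean") {
  dx <- track$x[j] - track$x[i]
  dy <- track$y[j] - track$y[i]
  if (metric == "euclidean") sqrt(dx * dx + dy * dy) else max(abs(dx), abs(dy))
}

oracle_rest <- function(track, k, p) {
  n <- length(track$x)
  lo <- k - p$rest_halfwidth
  hi <- k + p$rest_halfwidth
  if (lo < 1) lo <- 1
  if (hi > n) hi <- n
  within <- 0L
  total <- 0L
  for (j in lo:hi) {
    total <- total + 1L
    if (oracle_pixdist(track, k, j, p$distance_metric) <
        p$rest_pixel_tolerance)
      within <- within + 1L
  }
  within / total >= p$rest_certainty
}

oracle_onset <- function(track, k, p) {
  n <- length(track$x)
  if (k < 2) return(FALSE)
  if (oracle_pixdist(track, k, k - 1, p$distance_metric) <=
      p$movement_pixel_threshold)
    return(FALSE)
  if (k >= n) return(FALSE)
  cnt <- 0L
  for (j in (k + 1):min(n, k + p$lookahead_frames)) {
    if (oracle_pixdist(track, k, j, p$distance_metric) >
        p$movement_pixel_threshold)
      cnt <- cnt + 1L
  }
  cnt >= p$lookahead_min_count
}

oracle_mask <- function(track, p) {
  n <- length(track$x)
  out <- rep(FALSE, n)
  k <- 1L
  while (k <= n) {
    if (track$confidence[k] < p$reliability_threshold) {
      k <- k + 1L
    } else if (oracle_rest(track, k, p)) {
      k <- k + 1L
    } else if (oracle_onset(track, k, p)) {
      found <- NA_integer_
      rng <- as.numeric(p$rest_search_limit)
      repeat {
        upper <- k + as.integer(ceiling(rng))
        if (upper > n) upper <- n
        for (j in (k + 1):upper) {
          if (oracle_rest(track, j, p)) { found <- j; break }
        }
        if (!is.na(found) || upper == n) break
        rng <- rng * p$search_growth_factor
      }
      if (is.na(found)) {
        for (j in k:n) out[j] <- TRUE
        k <- n + 1L
      } else {
        for (j in k:(found - 1L)) out[j] <- TRUE
        k <- found
      }
    } else {
      k <- k + 1L
    }
  }
  out
}

# random keypoint track mixing rest spans, displacement ramps, spikes and
# low-confidence frames
random_track <- function(n, seed, fps = 25) {
  set.seed(seed)
  x <- numeric(n); y <- numeric(n); conf <- numeric(n)
  pos <- c(runif(1, 200, 1200), runif(1, 200, 800))
  i <- 1L
  while (i <= n) {
    kind <- sample(c("rest", "ramp", "spike"), 1, prob = c(0.5, 0.35, 0.15))
    len <- min(n - i + 1L, sample(3:60, 1))
    if (kind == "rest") {
      sd <- runif(1, 0.3, 3)
      x[i:(i + len - 1L)] <- pos[1] + rnorm(len, 0, sd)
      y[i:(i + len - 1L)] <- pos[2] + rnorm(len, 0, sd)
    } else if (kind == "ramp") {
      step <- runif(1, 2, 18)
      ang <- runif(1, 0, 2 * pi)
      for (j in seq_len(len)) {
        pos <- pos + step * c(cos(ang), sin(ang))
        x[i + j - 1L] <- pos[1]
        y[i + j - 1L] <- pos[2]
      }
    } else {
      x[i:(i + len - 1L)] <- pos[1] + rnorm(len, 0, 1)
      y[i:(i + len - 1L)] <- pos[2] + rnorm(len, 0, 1)
      x[i] <- pos[1] + runif(1, 10, 40)  # single-frame spike
    }
    i <- i + len
  }
  conf <- runif(n, 0.35, 1)
  low <- runif(n) < 0.05
  conf[low] <- runif(sum(low), 0, 0.29)
  keypoint_track(x, y, conf, fps = fps, label = sprintf("random_%d", seed))
}

# brute-force optimal one-to-one interval matching (maximum number of pairs
# with overlap >= criterion); exponential, for small oracle instances only
bf_optimal_matches <- function(detected, reference, criterion,
                               method = "union") {
  nd <- nrow(detected); nr <- nrow(reference)
  if (nd == 0L || nr == 0L) return(0L)
  ok <- matrix(FALSE, nd, nr)
  for (i in seq_len(nd)) for (j in seq_len(nr))
    ok[i, j] <- temporal_overlap(detected[i, ], reference[j, ],
                                 method) >= criterion
  rec <- function(i, used) {
    if (i > nd) return(0L)
    best <- rec(i + 1L, used)
    for (j in seq_len(nr)) {
      if (!used[j] && ok[i, j]) {
        used[j] <- TRUE
        cand <- 1L + rec(i + 1L, used)
        used[j] <- FALSE
        if (cand > best) best <- cand
      }
    }
    best
  }
  rec(1L, rep(FALSE, nr))
}

# random sorted non-overlapping segment list on [1, horizon]
random_segments <- function(n, horizon, seed) {
  set.seed(seed)
  if (n == 0L) return(data.frame(start_frame = integer(0),
                                 end_frame = integer(0)))
  cuts <- sort(sample.int(horizon, 2L * n))
  data.frame(start_frame = cuts[seq(1, 2 * n, 2)],
             end_frame = cuts[seq(2, 2 * n, 2)])
}
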