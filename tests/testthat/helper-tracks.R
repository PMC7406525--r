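# small track builders used across detection tests

constant_track <- function(n, x = 500, y = 400, conf = 0.9, fps = 25) {
  keypoint_track(rep(x, n), rep(y, n), rep(conf, n), fps = fps,
                 label = "const")
}

# rest, then a straight ramp of `step` px/frame for `len` frames, then rest
ramp_track <- function(pre, len, post, step, conf = 0.9, fps = 25) {
  x <- c(rep(0, pre), step * seq_len(len), rep(step * len, post))
  n <- pre + len + post
  keypoint_track(x + 100, rep(100, n), rep(conf, n), fps = fps,
                 label = "ramp")
}

# recordings equal up to (x, y) translation of every track
translate_track <- function(track, dx, dy) {
  keypoint_track(track$x + dx, track$y + dy, track$confidence,
                 fps = track$fps, label = track$label)
}
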