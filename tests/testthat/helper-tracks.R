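# Hand-built trajectory fixtures.

# constant-pose tracks: one row per fly with x, y, heading, replicated over
# `frames` frames (optionally only for a subset of frames per fly)
staticTrackSet <- function(poses, frames, frameRateHz = 30,
                           frameSubset = NULL) {
  rows <- list()
  for (i in seq_len(nrow(poses))) {
    f <- if (is.null(frameSubset)) 0:(frames - 1L) else frameSubset[[i]]
    rows[[i]] <- data.frame(frame = f, fly_id = poses$fly_id[i],
                            x_mm = poses$x[i], y_mm = poses$y[i],
                            heading_rad = poses$h[i])
  }
  FlyTrackSet(do.call(rbind, rows), frameRateHz = frameRateHz)
}

# two flies facing each other along the x axis at the given separation,
# present for `frames` frames
facingPair <- function(sepMm, frames, frameRateHz = 30) {
  staticTrackSet(
    data.frame(fly_id = 0:1, x = c(0, sepMm), y = 0, h = c(0, pi)),
    frames, frameRateHz)
}
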