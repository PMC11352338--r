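# Trajectory file parsing, round-trips and gap interpolation.

writeLinesTmp <- function(lines) {
  p <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("a small valid file parses into one track", {
  p <- writeLinesTmp(c("frame,fly_id,x_mm,y_mm,heading_rad",
                       "0,0,1.0,2.0,0.5", "1,0,1.1,2.1,0.6",
                       "2,0,1.2,2.2,0.7"))
  ts <- readTrajectories(p)
  expect_equal(nFlies(ts), 1)
  expect_equal(nrow(trackData(ts)), 3)
  expect_equal(trackData(ts)$x_mm, c(1.0, 1.1, 1.2))
})

test_that("duplicate (frame, fly) is an integrity error; bad rows carry line numbers", {
  p <- writeLinesTmp(c("frame,fly_id,x_mm,y_mm,heading_rad",
                       "0,0,1,2,0.5", "0,0,1,2,0.5"))
  expect_error(readTrajectories(p), "integrity error")
  p2 <- writeLinesTmp(c("frame,fly_id,x_mm,y_mm,heading_rad",
                        "0,0,1,2,0.5", "1,0,oops,2,0.5"))
  expect_error(readTrajectories(p2), "line 3")
  p3 <- writeLinesTmp(c("frame,fly_id,x_mm,y_mm,heading_rad",
                        "0,0,1,2", "1,0,1,2,0.5"))
  expect_error(readTrajectories(p3), "line 2")
})

test_that("missing positions become gaps, not interpolations", {
  p <- writeLinesTmp(c("frame,fly_id,x_mm,y_mm,heading_rad",
                       "0,0,1,2,0.5", "1,0,NA,NA,NA", "2,0,3,4,0.5"))
  ts <- readTrajectories(p)
  expect_equal(nrow(trackData(ts)), 2)
  expect_equal(attr(trackData(ts), "n_gap_rows"), 1)
})

test_that("generator output round-trips losslessly, tab and comma", {
  trj <- simulateTrajectories(ArenaSpec(durationS = 3), 3, seed = 17)
  for (sep in c(",", "\t")) {
    p <- withr::local_tempfile(fileext = ".txt")
    writeTrajectories(trj, p, sep = sep)
    back <- readTrajectories(p)
    expect_equal(trackData(back), trackData(trj), ignore_attr = TRUE)
  }
})

test_that("a column mapping imports foreign tracker headers", {
  p <- writeLinesTmp(c("f,id,px,py,ang", "0,0,1,2,0.5", "1,0,2,3,0.6"))
  ts <- readTrajectories(p, colMap = c(frame = "f", fly_id = "id",
                                       x_mm = "px", y_mm = "py",
                                       heading_rad = "ang"))
  expect_equal(nrow(trackData(ts)), 2)
})

test_that("fillGaps interpolates linearly in position", {
  d <- data.frame(frame = c(0L, 2L), fly_id = 0L, x_mm = c(0, 2),
                  y_mm = c(0, 2), heading_rad = 0)
  d2 <- data.frame(frame = 0:2, fly_id = 1L, x_mm = 0, y_mm = 0,
                   heading_rad = 0)
  ts <- fillGaps(FlyTrackSet(rbind(d, d2)), maxGapFrames = 3)
  mid <- trackData(ts)[trackData(ts)$fly_id == 0 & trackData(ts)$frame == 1, ]
  expect_equal(c(mid$x_mm, mid$y_mm), c(1, 1))
})

test_that("heading interpolation crosses +/-pi along the shorter arc", {
  d <- data.frame(frame = c(0L, 2L), fly_id = 0L, x_mm = 0, y_mm = 0,
                  heading_rad = c(3.0, -3.0))
  ts <- fillGaps(FlyTrackSet(d), maxGapFrames = 3)
  h1 <- trackData(ts)$heading_rad[trackData(ts)$frame == 1]
  # circular-mean oracle of 3.0 and -3.0: mean resultant direction
  oracle <- atan2(mean(sin(c(3, -3))), mean(cos(c(3, -3))))
  oracle <- if (oracle <= -pi) oracle + 2 * pi else oracle
  # both ends are ~0.1416 rad from +/-pi, so the midpoint sits on pi
  expect_equal(abs(h1), pi, tolerance = 1e-9)
  expect_equal(sin(h1), sin(oracle), tolerance = 1e-9)
  expect_equal(cos(h1), cos(oracle), tolerance = 1e-9)
})

test_that("gaps longer than the maximum split the track and are flagged", {
  d <- data.frame(frame = c(0L, 10L), fly_id = 0L, x_mm = c(0, 5),
                  y_mm = 0, heading_rad = 0)
  ts <- fillGaps(FlyTrackSet(d), maxGapFrames = 3)
  expect_equal(nrow(trackData(ts)), 2)   # nothing interpolated
  sp <- attr(trackData(ts), "splits")
  expect_equal(nrow(sp), 1)
  expect_equal(sp$gap_length, 9)
})

test_that("fillGaps is idempotent and identity on gap-free tracks", {
  trj <- simulateTrajectories(ArenaSpec(durationS = 2), 2, seed = 3)
  once <- fillGaps(trj)
  expect_equal(trackData(once), trackData(trj), ignore_attr = TRUE)
  d <- data.frame(frame = c(0L, 2L, 3L, 20L), fly_id = 0L,
                  x_mm = c(0, 2, 3, 8), y_mm = 0, heading_rad = 0)
  d2 <- data.frame(frame = 0:1, fly_id = 1L, x_mm = 1, y_mm = 1,
                   heading_rad = 1)
  ts1 <- fillGaps(FlyTrackSet(rbind(d, d2)), maxGapFrames = 2)
  ts2 <- fillGaps(ts1, maxGapFrames = 2)
  expect_equal(trackData(ts2), trackData(ts1), ignore_attr = TRUE)
})
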