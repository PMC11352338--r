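# Interaction detection: distance / facing-angle geometry, the inclusive
# 0.6 s duration boundary, and event aggregation.

test_that("pairwise state obeys the distance threshold", {
  near <- pairwiseState(facingPair(4.9, 3), frame = 0)
  expect_true(near["0", "1"] && near["1", "0"])
  far <- pairwiseState(facingPair(5.1, 3), frame = 0)
  expect_false(any(far))
  # boundary: 5.0 mm is inclusive
  expect_true(pairwiseState(facingPair(5.0, 3), frame = 0)["0", "1"])
})

test_that("pairwise state obeys the facing half-angle", {
  deg <- function(d) d * pi / 180
  mk <- function(offsetDeg) staticTrackSet(
    data.frame(fly_id = 0:1, x = c(0, 3), y = 0,
               h = c(deg(offsetDeg), pi)), frames = 2)
  st79 <- pairwiseState(mk(79), frame = 0)
  st100 <- pairwiseState(mk(100), frame = 0)
  expect_true(st79["0", "1"])
  expect_false(st100["0", "1"])
  # target still faces the actor in both cases
  expect_true(st79["1", "0"] && st100["1", "0"])
  # full-angle convention widens the cone to 160 degrees
  crFull <- InteractionCriteria(angleConvention = "full")
  expect_true(pairwiseState(mk(100), crFull, frame = 0)["0", "1"])
})

test_that("missing fly at a frame gives state false", {
  ts <- staticTrackSet(data.frame(fly_id = 0:1, x = c(0, 3), y = 0,
                                  h = c(0, pi)),
                       frames = 4, frameSubset = list(0:3, 0:1))
  expect_true(pairwiseState(ts, frame = 1)["0", "1"])
  expect_false(any(pairwiseState(ts, frame = 3)))
})

test_that("minimum duration boundary is inclusive: 18 frames at 30 Hz", {
  ev18 <- detectEvents(facingPair(4, 18))
  expect_equal(nrow(ev18), 2)  # both directions
  expect_equal(ev18$duration_s, c(0.6, 0.6))
  expect_equal(nrow(detectEvents(facingPair(4, 17))), 0)
})

test_that("separated qualifying runs give separate events with hand-tallied durations", {
  # fly 1 faces fly 0 throughout; fly 0 turns away for 5 frames in the
  # middle, splitting fly 0's run but not fly 1's
  away <- rep(0, 65)
  away[31:35] <- pi   # actor heading flipped: faces away
  d0 <- data.frame(frame = 0:64, fly_id = 0L, x_mm = 0, y_mm = 0,
                   heading_rad = away)
  d1 <- data.frame(frame = 0:64, fly_id = 1L, x_mm = 3, y_mm = 0,
                   heading_rad = pi)
  ts <- FlyTrackSet(rbind(d0, d1), frameRateHz = 30)
  ev <- detectEvents(ts)
  e01 <- ev[ev$actor == 0, ]
  e10 <- ev[ev$actor == 1, ]
  expect_equal(nrow(e01), 2)
  expect_equal(e01$duration_s, c(30, 30) / 30)
  expect_equal(e01$start_frame, c(0L, 35L))
  expect_equal(nrow(e10), 1)
  expect_equal(e10$duration_s, 65 / 30)
})

test_that("network aggregation: isolates retained, weights summed", {
  empty <- buildNetwork(detectEvents(facingPair(20, 30)), nFlies = 12)
  expect_equal(nNodes(empty), 12L)
  expect_equal(nrow(edgeData(empty)), 0L)

  ev <- data.frame(actor = 0L, target = 1L, start_frame = c(0L, 40L, 80L),
                   end_frame = c(29L, 69L, 109L), duration_s = c(1, 1, 1))
  net <- buildNetwork(ev, nFlies = 3)
  e <- edgeData(net)
  expect_equal(e$count, 3L)
  expect_equal(e$duration_s, 3.0)
  expect_error(buildNetwork(ev, nFlies = 1), "0..nFlies-1")
})

test_that("events from a hand-built trajectory match a manual adjacency tally", {
  away <- rep(0, 65); away[31:35] <- pi
  d0 <- data.frame(frame = 0:64, fly_id = 0L, x_mm = 0, y_mm = 0,
                   heading_rad = away)
  d1 <- data.frame(frame = 0:64, fly_id = 1L, x_mm = 3, y_mm = 0,
                   heading_rad = pi)
  ts <- FlyTrackSet(rbind(d0, d1), frameRateHz = 30)
  net <- buildNetwork(detectEvents(ts), nFlies = 2)
  e <- edgeData(net)
  expect_equal(e[e$actor == 0, c("count", "duration_s")],
               data.frame(count = 2L, duration_s = 2.0),
               ignore_attr = TRUE)
  expect_equal(e[e$actor == 1, c("count", "duration_s")],
               data.frame(count = 1L, duration_s = 65 / 30),
               ignore_attr = TRUE)
})

test_that("mirror-symmetric tracks give symmetric events", {
  set.seed(7)
  n <- 200
  # fly 0 wanders near the origin, fly 1 is its point reflection: both
  # always face each other through the centre
  x <- cumsum(rnorm(n, 0, 0.05)) + 1.2
  y <- cumsum(rnorm(n, 0, 0.05))
  h <- atan2(-y - y, -x - x)  # toward the mirror fly
  d0 <- data.frame(frame = 0:(n - 1), fly_id = 0L, x_mm = x, y_mm = y,
                   heading_rad = flysin:::.wrapAngle(h))
  d1 <- data.frame(frame = 0:(n - 1), fly_id = 1L, x_mm = -x, y_mm = -y,
                   heading_rad = flysin:::.wrapAngle(h + pi))
  ts <- FlyTrackSet(rbind(d0, d1), frameRateHz = 30)
  e <- edgeData(buildNetwork(detectEvents(ts), 2))
  if (nrow(e)) {
    expect_equal(nrow(e), 2)
    expect_equal(e$count[1], e$count[2])
    expect_equal(e$duration_s[1], e$duration_s[2])
  }
})

test_that("enlarging distance or angle thresholds never decreases events", {
  set.seed(33)
  trj <- simulateTrajectories(ArenaSpec(durationS = 20), nFlies = 6,
                              SocialProfile(), seed = 5)
  nEvents <- function(dist, ang) {
    nrow(detectEvents(trj, InteractionCriteria(
      maxDistanceBodyLengths = dist, maxFacingAngleDeg = ang)))
  }
  base <- nEvents(2.5, 160)
  expect_gte(nEvents(4, 160), base)
  expect_gte(nEvents(2.5, 300), base)
  expect_gte(nEvents(4, 300), max(nEvents(4, 160), nEvents(2.5, 300)))
})

test_that("edge list and GraphML round-trip a network", {
  set.seed(2)
  W <- randomWeightMatrix(5, 0.5)
  net <- netFromMatrix(W)
  p1 <- withr::local_tempfile(fileext = ".txt")
  writeEdgeList(net, p1)
  back <- readEdgeList(p1)
  expect_equal(edgeData(back), edgeData(net))
  expect_equal(nNodes(back), nNodes(net))
  p2 <- withr::local_tempfile(fileext = ".graphml")
  writeGraphML(net, p2)
  g <- readGraphML(p2)
  expect_equal(edgeData(g), edgeData(net))
})
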