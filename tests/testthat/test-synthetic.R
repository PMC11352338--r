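# Synthetic-data generators: determinism, geometric sanity, planted ground
# truth and distributional calibration.

test_that("trajectory generator is deterministic and stays inside the arena", {
  arena <- ArenaSpec(durationS = 10)
  a <- simulateTrajectories(arena, 4, SocialProfile(), seed = 99)
  b <- simulateTrajectories(arena, 4, SocialProfile(), seed = 99)
  expect_identical(trackData(a), trackData(b))
  tr <- trackData(a)
  expect_true(all(sqrt(tr$x_mm^2 + tr$y_mm^2) <= arena@diameterMm / 2 + 1e-9))
  expect_true(all(is.finite(tr$heading_rad)))
  expect_true(all(tr$heading_rad > -pi & tr$heading_rad <= pi))
  # one gap-free track per fly
  expect_equal(nFlies(a), 4)
  expect_equal(nrow(tr), 4 * 10 * 30)
})

test_that("trajectory generator rejects bad geometry", {
  expect_error(ArenaSpec(frameRateHz = 0), "frameRateHz")
  expect_error(ArenaSpec(durationS = -1), "durationS")
  expect_error(simulateTrajectories(ArenaSpec(), 1, seed = 1), "nFlies")
})

test_that("null trajectories: near-contact frequency matches the uniform-placement oracle", {
  # Monte-Carlo oracle: two points uniform in the effective disc
  set.seed(1234)
  rEff <- 61 / 2 - 1
  nmc <- 2e5
  p1 <- cbind(rEff * sqrt(runif(nmc)), runif(nmc, -pi, pi))
  p2 <- cbind(rEff * sqrt(runif(nmc)), runif(nmc, -pi, pi))
  d <- sqrt((p1[, 1] * cos(p1[, 2]) - p2[, 1] * cos(p2[, 2]))^2 +
              (p1[, 1] * sin(p1[, 2]) - p2[, 1] * sin(p2[, 2]))^2)
  pOracle <- mean(d <= 5)

  arena <- ArenaSpec(durationS = 10)
  fracs <- vapply(1:100, function(s) {
    tr <- trackData(simulateTrajectories(arena, 2, SocialProfile(), seed = s))
    a <- tr[tr$fly_id == 0, ]; b <- tr[tr$fly_id == 1, ]
    mean(sqrt((a$x_mm - b$x_mm)^2 + (a$y_mm - b$y_mm)^2) <= 5)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - pOracle), 0.05)
})

test_that("planted groups with strong attraction cohere spatially", {
  prof <- SocialProfile(attractionStrength = 3,
                        groups = rep(1:2, each = 6))
  trj <- simulateTrajectories(ArenaSpec(durationS = 30), 12, prof, seed = 8)
  tr <- trackData(trj)
  lastFrames <- tr[tr$frame >= max(tr$frame) - 200, ]
  xy <- aggregate(cbind(x_mm, y_mm) ~ fly_id, lastFrames, mean)
  pd <- as.matrix(dist(xy[, c("x_mm", "y_mm")]))
  same <- outer(rep(1:2, each = 6), rep(1:2, each = 6), "==")
  diag(same) <- NA
  expect_lt(mean(pd[same & upper.tri(pd)]),
            mean(pd[!same & upper.tri(pd)]))
})

test_that("activity generator: determinism, zero rate, planted bouts", {
  prof <- ActivityProfile(meanCountsPerMin = 3)
  a <- simulateActivity(prof, nDays = 2, seed = 4)
  b <- simulateActivity(prof, nDays = 2, seed = 4)
  expect_identical(beamCounts(a), beamCounts(b))
  expect_equal(length(beamCounts(a)), 2 * 1440)

  z <- simulateActivity(ActivityProfile(meanCountsPerMin = 0,
                                        sleepBoutRatePerH = 0),
                        nDays = 1, seed = 1)
  expect_true(all(beamCounts(z) == 0L))

  # every planted bout is a run of >= its length of zeros
  cnt <- beamCounts(a)
  pb <- a@planted$bouts
  for (i in seq_len(nrow(pb))) {
    idx <- (pb$start_min[i] + 1):(pb$start_min[i] + pb$length_min[i])
    expect_true(all(cnt[idx] == 0L))
  }
  expect_error(simulateActivity(prof, nDays = 1, seed = 1,
                                lightsOnH = 8, lightsOffH = 8),
               "differ")
})

test_that("24 h profile autocorrelation peaks at lag 1440 min", {
  s <- simulateActivity(ActivityProfile(meanCountsPerMin = 3,
                                        sleepBoutRatePerH = 0),
                        nDays = 5, seed = 10)
  a <- acf(as.numeric(beamCounts(s)), lag.max = 2000, plot = FALSE)$acf[, 1, 1]
  lags <- seq_along(a) - 1
  sel <- lags >= 600   # away from the lag-0 peak
  peakLag <- lags[sel][which.max(a[sel])]
  # Poisson noise jitters the argmax of the smooth 24 h peak by a few min
  expect_lt(abs(peakLag - 1440), 15)
  expect_gt(a[lags == 1440], a[lags == 720])
})

test_that("geotaxis generator follows the binomial law", {
  one <- simulateGeotaxis(1, seed = 1)
  expect_true(all(one$n_climbed == one$n_flies))
  zero <- simulateGeotaxis(0, seed = 1)
  expect_true(all(zero$n_climbed == 0))
  big <- simulateGeotaxis(0.5, nGroups = 2000, fliesPerGroup = 10,
                          trialsPerGroup = 5, seed = 2)
  expect_lt(abs(mean(big$n_climbed / big$n_flies) - 0.5), 0.01)
  expect_error(simulateGeotaxis(1.2, seed = 1), "0, 1")
})

test_that("assay generator: noiseless reads and rejection of bad input", {
  r0 <- simulateAssayReadings(5, 0, noiseSd = 0)
  expect_equal(r0$value[r0$reading_type == "free"],
               r0$value[r0$reading_type == "total"])
  calib <- r0[r0$reading_type == "calib", ]
  expect_equal(calib$value, 0.02 * calib$concentration + 0.05)
  expect_error(simulateAssayReadings(-1, 0), "nonnegative")
  expect_error(simulateAssayReadings(1, 1, calibSlope = 0), "positive")
})
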