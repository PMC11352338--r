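# Monitor parsing, day/night summaries, sleep-bout detection and
# free-running period estimation.

test_that("a toy csv monitor file parses to the right series", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,flyA",
               "2024-01-01 08:00,1",
               "2024-01-01 08:01,0",
               "2024-01-01 08:02,2"), p)
  ser <- readMonitor(p, "csv")
  expect_length(ser, 1)
  expect_equal(beamCounts(ser[[1]]), c(1L, 0L, 2L))
  expect_equal(ser[[1]]@startHour, 8)
})

test_that("duplicate or non-monotone timestamps are parse errors; gaps warn", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,flyA",
               "2024-01-01 08:00,1",
               "2024-01-01 08:00,2"), p)
  expect_error(readMonitor(p, "csv"), "strictly increasing")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,flyA",
               "2024-01-01 08:00,1",
               "2024-01-01 08:03,2"), p2)
  expect_warning(ser <- readMonitor(p2, "csv"), "gap")
  expect_length(beamCounts(ser[[1]]), 4)
})

test_that("simulated series round-trip through both monitor dialects", {
  ser <- lapply(1:3, function(i) {
    simulateActivity(ActivityProfile(meanCountsPerMin = 2), nDays = 2,
                     seed = i, flyId = paste0("fly", i))
  })
  for (dia in c("csv", "trikinetics")) {
    p <- withr::local_tempfile()
    writeMonitor(ser, p, dia)
    back <- readMonitor(p, dia)
    expect_length(back, 3)
    for (i in 1:3) {
      expect_equal(beamCounts(back[[i]]), beamCounts(ser[[i]]))
    }
  }
})

test_that("phase summaries average the right minutes", {
  const2 <- ActivitySeries(rep(2L, 2 * 1440))
  expect_equal(phaseSummary(const2, "light"), 2.0)
  expect_equal(phaseSummary(const2, "dark"), 2.0)

  # 4 counts/min during light, 0 during dark (series starts at lights-on)
  day <- c(rep(4L, 720), rep(0L, 720))
  ld <- ActivitySeries(rep(day, 3))
  expect_equal(phaseSummary(ld, "light"), 4.0)
  expect_equal(phaseSummary(ld, "dark"), 0.0)

  expect_error(phaseSummary(ActivitySeries(rep(1L, 100)), "light"),
               "complete day")
  expect_error(phaseSummary(ActivitySeries(rep(1L, 2000),
                                           constantDark = TRUE), "light"),
               "light schedule")
})

test_that("simulated siesta profile matches direct averaging", {
  s <- simulateActivity(ActivityProfile(meanCountsPerMin = 2), nDays = 5,
                        seed = 77)
  cnt <- beamCounts(s)
  minOfDay <- (8 * 60 + seq_along(cnt) - 1) %% 1440
  lightSel <- minOfDay >= 480 & minOfDay < 1200
  expect_equal(phaseSummary(s, "light"), mean(cnt[lightSel]))
  expect_equal(phaseSummary(s, "dark"), mean(cnt[!lightSel]))
  # light/dark means weighted by phase length reproduce the whole-day mean
  expect_equal((phaseSummary(s, "light") * 720 + phaseSummary(s, "dark") * 720)
               / 1440, mean(cnt))
})

test_that("sleep rule is strictly longer than 5 min", {
  mk <- function(zeros) ActivitySeries(c(rep(2L, 10), rep(0L, zeros),
                                         rep(2L, 10)))
  expect_equal(nrow(detectSleep(mk(5))$bouts), 0)
  b6 <- detectSleep(mk(6))$bouts
  expect_equal(nrow(b6), 1)
  expect_equal(b6$length_min, 6)
  expect_equal(b6$start_min, 10)
  # the >= convention is a switch
  expect_equal(nrow(detectSleep(mk(5), strict = FALSE)$bouts), 1)
})

test_that("planted sleep bouts are recovered exactly at high baseline rate", {
  # flat high rate: incidental zero minutes (which would merge with a
  # planted bout and blur its boundaries) have probability ~ exp(-8)
  s <- simulateActivity(ActivityProfile(meanCountsPerMin = 8, siestaDepth = 0,
                                        nightDepth = 0,
                                        sleepBoutRatePerH = 0.5,
                                        sleepBoutLenMin = 30),
                        nDays = 3, seed = 21)
  planted <- s@planted$bouts
  planted <- planted[planted$length_min > 5, ]
  detected <- detectSleep(s)$bouts
  expect_true(nrow(planted) > 3)
  expect_equal(detected, planted, ignore_attr = TRUE)
})

test_that("per-phase sleep and awake minutes partition each phase", {
  s <- simulateActivity(ActivityProfile(meanCountsPerMin = 2), nDays = 3,
                        seed = 9)
  sl <- detectSleep(s)
  expect_true(all(sl$perPhase$sleep_min + sl$perPhase$awake_min == 720))
  # total per-phase sleep equals the summed bout minutes (all days complete)
  asleep <- logical(length(beamCounts(s)))
  for (i in seq_len(nrow(sl$bouts))) {
    asleep[(sl$bouts$start_min[i] + 1):
             (sl$bouts$start_min[i] + sl$bouts$length_min[i])] <- TRUE
  }
  expect_equal(sum(sl$perPhase$sleep_min), sum(asleep))
})

test_that("planted free-running periods are recovered", {
  for (P in c(20, 23.5, 24, 28)) {
    s <- simulateActivity(ActivityProfile(periodH = P, meanCountsPerMin = 3),
                          nDays = 5, seed = 31, constantDark = TRUE)
    pe <- estimatePeriod(s)
    tolH <- if (P == 24) 0.1 else 0.25
    expect_lte(abs(pe$period_h - P), tolH + 1e-9)
    expect_true(pe$significant)
  }
})

test_that("white noise has no significant periodogram peak", {
  set.seed(6)
  wn <- ActivitySeries(rpois(5 * 1440, 2), constantDark = TRUE)
  expect_false(estimatePeriod(wn)$significant)
})

test_that("period estimation preconditions", {
  s <- simulateActivity(ActivityProfile(), nDays = 5, seed = 1)
  expect_error(estimatePeriod(s), "constant-darkness")
  short <- ActivitySeries(rpois(1440, 2), constantDark = TRUE)
  expect_error(estimatePeriod(short), "too short")
})

test_that("autocorrelation method also finds the 24 h period", {
  s <- simulateActivity(ActivityProfile(meanCountsPerMin = 3), nDays = 5,
                        seed = 13, constantDark = TRUE)
  pe <- estimatePeriod(s, method = "acf")
  expect_lt(abs(pe$period_h - 24), 0.3)
})
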