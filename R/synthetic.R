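#' Simulate arena trajectories with optional planted sociality
#'
#' Generates tracker-style trajectories for `nFlies` flies in a circular
#' arena. Motion is a correlated random walk (heading diffuses with SD
#' `turningNoiseRad` per sqrt-second, constant speed) with reflective arena
#' walls. With `attractionStrength > 0`, each fly's heading is additionally
#' pulled toward the centroid of its planted group-mates, producing real
#' spatial sociality; with strength 0 the flies move independently (the
#' null condition for the random-network honesty checks).
#'
#' @param arena an [ArenaSpec-class].
#' @param nFlies number of flies (>= 2).
#' @param profile a [SocialProfile-class].
#' @param seed RNG seed (mandatory; identical seeds give identical tracks).
#' @param genotype,recordingId provenance labels.
#' @return a [FlyTrackSet-class], one gap-free track per fly.
#' @examples
#' trj <- simulateTrajectories(ArenaSpec(durationS = 5), nFlies = 2, seed = 1)
#' head(trackData(trj))
#' @export
simulateTrajectories <- function(arena = ArenaSpec(), nFlies = 12,
                                 profile = SocialProfile(), seed,
                                 genotype = "unknown", recordingId = "rec") {
  .stopIfNot(is(arena, "ArenaSpec"), "arena must be an ArenaSpec")
  validObject(arena)
  .stopIfNot(nFlies >= 2, "nFlies must be >= 2")
  .stopIfNot(!missing(seed), "seed is mandatory")
  .stopIfNot(arena@frameRateHz > 0 && arena@durationS > 0,
             "frame rate and duration must be positive")

  n <- as.integer(nFlies)
  fps <- arena@frameRateHz
  dt <- 1 / fps
  nFrames <- max(2L, as.integer(round(arena@durationS * fps)))
  rEff <- arena@diameterMm / 2 - arena@flyBodyLengthMm / 2

  groups <- profile@groups
  if (length(groups) == 0L) groups <- rep(1L, n)
  .stopIfNot(length(groups) == n, "profile@groups must have one label per fly")
  grpSize <- as.vector(table(factor(groups))[as.character(groups)])

  set.seed(seed)
  # uniform initial placement in the effective disc
  r0 <- rEff * sqrt(stats::runif(n))
  th0 <- stats::runif(n, -pi, pi)
  x <- r0 * cos(th0)
  y <- r0 * sin(th0)
  h <- stats::runif(n, -pi, pi)

  X <- matrix(0, nFrames, n)
  Y <- matrix(0, nFrames, n)
  H <- matrix(0, nFrames, n)
  X[1L, ] <- x; Y[1L, ] <- y; H[1L, ] <- .wrapAngle(h)

  att <- profile@attractionStrength
  k <- 1 - exp(-att * dt)          # per-frame heading pull in [0, 1)
  sdStep <- profile@turningNoiseRad * sqrt(dt)
  step <- profile@stepSpeedMmS * dt
  hasMates <- grpSize > 1L

  for (t in 2L:nFrames) {
    h <- h + stats::rnorm(n, 0, sdStep)
    if (att > 0 && any(hasMates)) {
      sx <- rowsum(x, groups); sy <- rowsum(y, groups)
      gi <- match(groups, rownames(sx))
      cx <- (sx[gi, 1L] - x) / pmax(grpSize - 1L, 1L)
      cy <- (sy[gi, 1L] - y) / pmax(grpSize - 1L, 1L)
      bear <- atan2(cy - y, cx - x)
      dh <- .angDiff(bear, h)
      h <- ifelse(hasMates, h + k * dh, h)
    }
    h <- .wrapAngle(h)
    xn <- x + step * cos(h)
    yn <- y + step * sin(h)
    rn <- sqrt(xn^2 + yn^2)
    out <- rn > rEff
    if (any(out)) {
      # reflect velocity about the wall tangent and fold the overshoot back
      nx <- xn[out] / rn[out]; ny <- yn[out] / rn[out]
      vx <- cos(h[out]); vy <- sin(h[out])
      dot <- vx * nx + vy * ny
      vx <- vx - 2 * dot * nx; vy <- vy - 2 * dot * ny
      h[out] <- atan2(vy, vx)
      fold <- pmax(2 * rEff - rn[out], 0) / rn[out]
      xn[out] <- xn[out] * fold
      yn[out] <- yn[out] * fold
    }
    x <- xn; y <- yn
    X[t, ] <- x; Y[t, ] <- y; H[t, ] <- h
  }

  tracks <- data.frame(
    frame = rep(0L:(nFrames - 1L), times = n),
    fly_id = rep(0L:(n - 1L), each = nFrames),
    x_mm = as.vector(X), y_mm = as.vector(Y), heading_rad = as.vector(H)
  )
  FlyTrackSet(tracks, frameRateHz = fps, arenaDiameterMm = arena@diameterMm,
              genotype = genotype, recordingId = recordingId)
}

#' Simulate a beam-break activity series
#'
#' Per-minute Poisson counts modulated by a bimodal circadian waveform
#' (morning and evening peaks, midday siesta, extended night trough), with
#' planted sleep
#' bouts injected as forced-zero windows so the ground truth is exact.
#' Under `constantDark = TRUE` the waveform free-runs at `profile@periodH`.
#'
#' @param profile an [ActivityProfile-class].
#' @param nDays number of recorded days (>= 1).
#' @param lightsOnH,lightsOffH light schedule (clock hours); must differ.
#' @param seed RNG seed (mandatory).
#' @param constantDark free-running (DD) recording flag.
#' @param flyId channel label.
#' @return an [ActivitySeries-class]; `x@planted$bouts` holds the merged
#'   forced-zero windows (0-based `start_min`, `length_min`) and
#'   `x@planted$period_h` the generating period.
#' @export
simulateActivity <- function(profile = ActivityProfile(), nDays = 5,
                             lightsOnH = 8, lightsOffH = 20, seed,
                             constantDark = FALSE, flyId = "fly") {
  .stopIfNot(is(profile, "ActivityProfile"), "profile must be an ActivityProfile")
  validObject(profile)
  .stopIfNot(nDays >= 1, "nDays must be >= 1")
  .stopIfNot(!missing(seed), "seed is mandatory")
  if (lightsOnH == lightsOffH) {
    stop("lightsOnH must differ from lightsOffH", call. = FALSE)
  }

  nMin <- as.integer(round(nDays * 1440))
  startHour <- lightsOnH
  tH <- startHour + (seq_len(nMin) - 1) / 60
  # circadian time: clock-equivalent phase of the free-running oscillator
  ct <- (tH %% profile@periodH) * 24 / profile@periodH

  circDistH <- function(ct, centre) {
    d <- abs(ct - centre) %% 24
    pmin(d, 24 - d)
  }
  peak <- function(centre, sigma) exp(-0.5 * (circDistH(ct, centre) / sigma)^2)
  base <- 0.5
  siestaCentre <- (profile@morningPeakH + profile@eveningPeakH) / 2
  nightCentre <- (siestaCentre + 12) %% 24
  # evening peak stronger than morning, as in typical LD actograms; the
  # asymmetry also keeps the rhythm 24 h- rather than 12 h-periodic
  w <- base +
    0.6 * peak(profile@morningPeakH, 1.5) +
    1.2 * peak(profile@eveningPeakH, 1.5) -
    profile@siestaDepth * base * peak(siestaCentre, 2.5) -
    profile@nightDepth * base * peak(nightCentre, 3)
  w <- pmax(w, 0)

  set.seed(seed)
  lam <- if (mean(w) > 0) w / mean(w) * profile@meanCountsPerMin else w * 0
  counts <- stats::rpois(nMin, lam)

  bouts <- data.frame(start_min = integer(0), length_min = integer(0))
  nBouts <- stats::rpois(1, profile@sleepBoutRatePerH * nDays * 24)
  if (nBouts > 0 && profile@sleepBoutLenMin > 0) {
    starts <- sort(sample.int(nMin, nBouts, replace = TRUE)) - 1L  # 0-based
    lens <- pmax(1L, stats::rpois(nBouts, profile@sleepBoutLenMin))
    zero <- logical(nMin)
    for (i in seq_len(nBouts)) {
      idx <- (starts[i] + 1L):min(starts[i] + lens[i], nMin)
      zero[idx] <- TRUE
    }
    counts[zero] <- 0L
    r <- rle(zero)
    ends <- cumsum(r$lengths)
    keep <- r$values
    bouts <- data.frame(start_min = (ends - r$lengths)[keep],
                        length_min = r$lengths[keep])
  }

  ActivitySeries(counts, startHour = startHour, lightsOnH = lightsOnH,
                 lightsOffH = lightsOffH, constantDark = constantDark,
                 flyId = flyId,
                 planted = list(bouts = bouts, period_h = profile@periodH))
}

#' Simulate a negative-geotaxis trial table
#'
#' Each trial drops `fliesPerGroup` flies and records how many climb 5 cm
#' within 5 s; outcomes are Binomial(`fliesPerGroup`, `pClimb`). The study
#' design is five groups of ten flies, five trials each.
#'
#' @param pClimb per-fly climbing probability in \[0, 1\].
#' @param nGroups,fliesPerGroup,trialsPerGroup design sizes.
#' @param seed RNG seed (mandatory).
#' @param genotype genotype label.
#' @return data.frame with columns `genotype`, `group`, `trial`, `n_flies`,
#'   `n_climbed`.
#' @export
simulateGeotaxis <- function(pClimb, nGroups = 5, fliesPerGroup = 10,
                             trialsPerGroup = 5, seed, genotype = "genotype") {
  .stopIfNot(pClimb >= 0 && pClimb <= 1, "pClimb must lie in [0, 1]")
  .stopIfNot(!missing(seed), "seed is mandatory")
  set.seed(seed)
  g <- rep(seq_len(nGroups), each = trialsPerGroup)
  tr <- rep(seq_len(trialsPerGroup), times = nGroups)
  data.frame(
    genotype = genotype, group = g, trial = tr,
    n_flies = as.integer(fliesPerGroup),
    n_climbed = stats::rbinom(length(g), fliesPerGroup, pClimb)
  )
}

#' Simulate Ellman-assay absorbance readings
#'
#' Emulates a glutathione plate run: a free-GSH read, a post-reduction
#' (total) read, and a calibration series of known GSH concentrations.
#' Absorbance at 415 nm is linear in concentration
#' (`value = slope * conc + intercept + noise`). Reduction converts each
#' GSSG into two GSH, so the total read corresponds to
#' `gsh + 2 * gssg` micromolar.
#'
#' @param trueGshUM,trueGssgUM ground-truth concentrations, micromolar (>= 0).
#' @param calibSlope,calibIntercept calibration line (slope > 0).
#' @param noiseSd absorbance noise SD (0 for a noiseless run).
#' @param seed RNG seed (mandatory when `noiseSd > 0`).
#' @param calibConcs calibration concentrations, micromolar.
#' @param sampleId sample label.
#' @return data.frame with columns `sample_id`, `reading_type`
#'   (`free|total|calib`), `concentration` (calibration rows only), `value`.
#' @export
simulateAssayReadings <- function(trueGshUM, trueGssgUM,
                                  calibSlope = 0.02, calibIntercept = 0.05,
                                  noiseSd = 0, seed = 1,
                                  calibConcs = c(0, 2.5, 5, 10, 20, 40),
                                  sampleId = "sample") {
  .stopIfNot(trueGshUM >= 0 && trueGssgUM >= 0,
             "concentrations must be nonnegative")
  .stopIfNot(calibSlope > 0, "calibSlope must be positive")
  set.seed(seed)
  totalUM <- trueGshUM + 2 * trueGssgUM
  n <- 2L + length(calibConcs)
  noise <- if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else numeric(n)
  data.frame(
    sample_id = sampleId,
    reading_type = c("free", "total", rep("calib", length(calibConcs))),
    concentration = c(NA_real_, NA_real_, calibConcs),
    value = calibSlope * c(trueGshUM, totalUM, calibConcs) +
      calibIntercept + noise
  )
}
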