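#' @import methods
NULL

# ---------------------------------------------------------------------------
# Parameter specs
# ---------------------------------------------------------------------------

#' Arena and recording geometry
#'
#' Describes the circular recording arena and the sampling of the video:
#' a 61 mm diameter open-field arena, flies of ~2 mm body length (so the
#' 2.5-body-length interaction distance is ~5 mm), sampled at a fixed frame
#' rate for a fixed duration (the default recording is 25 min at 30 Hz).
#'
#' @slot diameterMm arena diameter, millimetres.
#' @slot flyBodyLengthMm nominal fly body length, millimetres.
#' @slot frameRateHz video frame rate, Hz.
#' @slot durationS recording duration, seconds.
#' @export
setClass("ArenaSpec",
  representation(
    diameterMm = "numeric",
    flyBodyLengthMm = "numeric",
    frameRateHz = "numeric",
    durationS = "numeric"
  ),
  prototype(
    diameterMm = 61, flyBodyLengthMm = 2,
    frameRateHz = 30, durationS = 1500
  ),
  validity = function(object) {
    msg <- character(0)
    if (length(object@diameterMm) != 1L || !is.finite(object@diameterMm) ||
        object@diameterMm <= 0) {
      msg <- c(msg, "diameterMm must be a single positive number")
    }
    if (length(object@flyBodyLengthMm) != 1L || object@flyBodyLengthMm <= 0) {
      msg <- c(msg, "flyBodyLengthMm must be positive")
    }
    if (length(object@frameRateHz) != 1L || !is.finite(object@frameRateHz) ||
        object@frameRateHz <= 0) {
      msg <- c(msg, "frameRateHz must be positive")
    }
    if (length(object@durationS) != 1L || !is.finite(object@durationS) ||
        object@durationS <= 0) {
      msg <- c(msg, "durationS must be positive")
    }
    if (length(msg)) msg else TRUE
  }
)

#' @rdname ArenaSpec-class
#' @param diameterMm,flyBodyLengthMm,frameRateHz,durationS see slots.
#' @return an `ArenaSpec` object.
#' @examples
#' ArenaSpec(durationS = 60)
#' @export
ArenaSpec <- function(diameterMm = 61, flyBodyLengthMm = 2,
                      frameRateHz = 30, durationS = 1500) {
  new("ArenaSpec", diameterMm = diameterMm, flyBodyLengthMm = flyBodyLengthMm,
      frameRateHz = frameRateHz, durationS = durationS)
}

#' Social motion profile for the trajectory generator
#'
#' Ground-truth knob for synthetic trajectories: flies follow a correlated
#' random walk; `attractionStrength > 0` additionally biases each fly's
#' heading toward the centroid of its group-mates. `attractionStrength = 0`
#' yields motion that is independent across flies (the null condition).
#'
#' @slot attractionStrength dimensionless, >= 0; 0 means no sociality.
#' @slot stepSpeedMmS walking speed, mm/s.
#' @slot turningNoiseRad SD of the heading increment per sqrt(second).
#' @slot groups optional integer partition of fly ids into planted groups
#'   (one label per fly; length 0 means all flies form one group).
#' @export
setClass("SocialProfile",
  representation(
    attractionStrength = "numeric",
    stepSpeedMmS = "numeric",
    turningNoiseRad = "numeric",
    groups = "integer"
  ),
  prototype(
    attractionStrength = 0, stepSpeedMmS = 8,
    turningNoiseRad = 1.5, groups = integer(0)
  ),
  validity = function(object) {
    msg <- character(0)
    if (object@attractionStrength < 0) {
      msg <- c(msg, "attractionStrength must be >= 0")
    }
    if (object@stepSpeedMmS < 0) msg <- c(msg, "stepSpeedMmS must be >= 0")
    if (object@turningNoiseRad < 0) msg <- c(msg, "turningNoiseRad must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname SocialProfile-class
#' @param attractionStrength,stepSpeedMmS,turningNoiseRad,groups see slots.
#' @return a `SocialProfile` object.
#' @export
SocialProfile <- function(attractionStrength = 0, stepSpeedMmS = 8,
                          turningNoiseRad = 1.5, groups = integer(0)) {
  new("SocialProfile", attractionStrength = attractionStrength,
      stepSpeedMmS = stepSpeedMmS, turningNoiseRad = turningNoiseRad,
      groups = as.integer(groups))
}

#' Circadian activity profile for the beam-break generator
#'
#' Parameters of the simulated locomotor rhythm: a bimodal waveform with
#' morning and evening peaks, a midday siesta, an overall mean count rate,
#' and stochastic planted sleep bouts (forced-zero windows).
#'
#' @slot periodH circadian period in hours (free-running under constant
#'   darkness); must lie in \[16, 32\].
#' @slot morningPeakH,eveningPeakH peak clock times, hours.
#' @slot siestaDepth fractional midday suppression in \[0, 1\].
#' @slot nightDepth fractional suppression of the night trough in \[0, 1\]
#'   (the extended inactive period between the evening and morning peaks).
#' @slot meanCountsPerMin mean beam-break rate, counts/min.
#' @slot sleepBoutRatePerH expected planted sleep bouts per hour.
#' @slot sleepBoutLenMin mean planted bout length, minutes.
#' @export
setClass("ActivityProfile",
  representation(
    periodH = "numeric", morningPeakH = "numeric", eveningPeakH = "numeric",
    siestaDepth = "numeric", nightDepth = "numeric",
    meanCountsPerMin = "numeric",
    sleepBoutRatePerH = "numeric", sleepBoutLenMin = "numeric"
  ),
  prototype(
    periodH = 24, morningPeakH = 8, eveningPeakH = 20, siestaDepth = 0.6,
    nightDepth = 0.8, meanCountsPerMin = 1.5, sleepBoutRatePerH = 0.3,
    sleepBoutLenMin = 20
  ),
  validity = function(object) {
    msg <- character(0)
    if (object@periodH < 16 || object@periodH > 32) {
      msg <- c(msg, "periodH must lie in [16, 32]")
    }
    if (object@siestaDepth < 0 || object@siestaDepth > 1) {
      msg <- c(msg, "siestaDepth must lie in [0, 1]")
    }
    if (object@nightDepth < 0 || object@nightDepth > 1) {
      msg <- c(msg, "nightDepth must lie in [0, 1]")
    }
    for (s in c("meanCountsPerMin", "sleepBoutRatePerH", "sleepBoutLenMin")) {
      if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be >= 0"))
    }
    if (length(msg)) msg else TRUE
  }
)

#' @rdname ActivityProfile-class
#' @param periodH,morningPeakH,eveningPeakH,siestaDepth,nightDepth see slots.
#' @param meanCountsPerMin,sleepBoutRatePerH,sleepBoutLenMin see slots.
#' @return an `ActivityProfile` object.
#' @export
ActivityProfile <- function(periodH = 24, morningPeakH = 8, eveningPeakH = 20,
                            siestaDepth = 0.6, nightDepth = 0.8,
                            meanCountsPerMin = 1.5,
                            sleepBoutRatePerH = 0.3, sleepBoutLenMin = 20) {
  new("ActivityProfile", periodH = periodH, morningPeakH = morningPeakH,
      eveningPeakH = eveningPeakH, siestaDepth = siestaDepth,
      nightDepth = nightDepth, meanCountsPerMin = meanCountsPerMin,
      sleepBoutRatePerH = sleepBoutRatePerH, sleepBoutLenMin = sleepBoutLenMin)
}

#' Interaction detection criteria
#'
#' Two flies interact (directed, actor toward target) when their centroids
#' are within 2.5 body lengths (~5 mm) of each other, the actor faces the
#' target within a 160 degree field-of-view cone, and the state persists for
#' at least 0.6 s. The angle is interpreted per actor: the absolute offset
#' between the actor's heading and the actor-to-target bearing must not
#' exceed half the stated cone (80 degrees); `angleConvention = "full"`
#' switches to comparing against the full value.
#'
#' @slot maxDistanceBodyLengths distance threshold, body lengths.
#' @slot bodyLengthMm nominal body length, mm (threshold = product of the two).
#' @slot maxFacingAngleDeg field-of-view cone, degrees (<= 360).
#' @slot minDurationS minimum bout duration, seconds (inclusive).
#' @slot angleConvention `"half"` (cone half-angle comparison, default) or
#'   `"full"`.
#' @export
setClass("InteractionCriteria",
  representation(
    maxDistanceBodyLengths = "numeric",
    bodyLengthMm = "numeric",
    maxFacingAngleDeg = "numeric",
    minDurationS = "numeric",
    angleConvention = "character"
  ),
  prototype(
    maxDistanceBodyLengths = 2.5, bodyLengthMm = 2,
    maxFacingAngleDeg = 160, minDurationS = 0.6, angleConvention = "half"
  ),
  validity = function(object) {
    msg <- character(0)
    for (s in c("maxDistanceBodyLengths", "bodyLengthMm",
                "maxFacingAngleDeg", "minDurationS")) {
      if (length(slot(object, s)) != 1L || slot(object, s) <= 0) {
        msg <- c(msg, paste(s, "must be a single positive number"))
      }
    }
    if (object@maxFacingAngleDeg > 360) {
      msg <- c(msg, "maxFacingAngleDeg must be <= 360")
    }
    if (!object@angleConvention %in% c("half", "full")) {
      msg <- c(msg, "angleConvention must be 'half' or 'full'")
    }
    if (length(msg)) msg else TRUE
  }
)

#' @rdname InteractionCriteria-class
#' @param maxDistanceBodyLengths,bodyLengthMm,maxFacingAngleDeg see slots.
#' @param minDurationS,angleConvention see slots.
#' @return an `InteractionCriteria` object.
#' @export
InteractionCriteria <- function(maxDistanceBodyLengths = 2.5, bodyLengthMm = 2,
                                maxFacingAngleDeg = 160, minDurationS = 0.6,
                                angleConvention = c("half", "full")) {
  new("InteractionCriteria",
      maxDistanceBodyLengths = maxDistanceBodyLengths,
      bodyLengthMm = bodyLengthMm, maxFacingAngleDeg = maxFacingAngleDeg,
      minDurationS = minDurationS,
      angleConvention = match.arg(angleConvention))
}

#' Distance threshold of a criteria object, mm
#' @param criteria an [InteractionCriteria-class] object.
#' @return threshold in millimetres.
#' @export
maxDistanceMm <- function(criteria) {
  criteria@maxDistanceBodyLengths * criteria@bodyLengthMm
}

#' Random-network null model specification
#'
#' The null reassembles chimeric groups: `groupSize` flies sampled without
#' replacement from the pooled (recording, fly) index of one experimental
#' group, never all from the same recording (`strict = TRUE` additionally
#' requires all flies to come from distinct recordings). Their trajectories
#' are overlaid in the common arena frame and interaction detection is
#' re-run as if they were co-housed.
#'
#' @slot nRandomNetworks number of random networks (10,000 default).
#' @slot groupSize flies per chimeric group (12 default).
#' @slot seed RNG seed (mandatory for reproducibility).
#' @slot strict require all flies from distinct recordings.
#' @export
setClass("NullModelSpec",
  representation(
    nRandomNetworks = "integer", groupSize = "integer",
    seed = "integer", strict = "logical"
  ),
  prototype(
    nRandomNetworks = 10000L, groupSize = 12L, seed = 1L, strict = FALSE
  ),
  validity = function(object) {
    msg <- character(0)
    if (object@nRandomNetworks < 1L) msg <- c(msg, "nRandomNetworks must be >= 1")
    if (object@groupSize < 2L) msg <- c(msg, "groupSize must be >= 2")
    if (length(object@seed) != 1L || is.na(object@seed)) {
      msg <- c(msg, "seed is mandatory")
    }
    if (length(msg)) msg else TRUE
  }
)

#' @rdname NullModelSpec-class
#' @param nRandomNetworks,groupSize,seed,strict see slots.
#' @return a `NullModelSpec` object.
#' @export
NullModelSpec <- function(nRandomNetworks = 10000, groupSize = 12, seed,
                          strict = FALSE) {
  if (missing(seed)) stop("NullModelSpec: an RNG seed is mandatory")
  new("NullModelSpec", nRandomNetworks = as.integer(nRandomNetworks),
      groupSize = as.integer(groupSize), seed = as.integer(seed),
      strict = strict)
}

# ---------------------------------------------------------------------------
# Data containers
# ---------------------------------------------------------------------------

#' Per-frame fly trajectories for one recording
#'
#' Holds the tracker-style trajectory table of one arena recording: one row
#' per (frame, fly) with position in arena-local millimetres (origin at the
#' arena centre) and body heading in radians, counter-clockwise from the +x
#' axis, in (-pi, pi]. Frames are 0-based. Missing (frame, fly) rows are
#' tracking gaps; [fillGaps()] interpolates short ones.
#'
#' @slot tracks data.frame with columns `frame`, `fly_id`, `x_mm`, `y_mm`,
#'   `heading_rad`, ordered by fly then frame.
#' @slot frameRateHz frame rate, Hz.
#' @slot arenaDiameterMm arena diameter, mm.
#' @slot genotype genotype / condition label.
#' @slot recordingId recording identifier.
#' @export
setClass("FlyTrackSet",
  representation(
    tracks = "data.frame",
    frameRateHz = "numeric",
    arenaDiameterMm = "numeric",
    genotype = "character",
    recordingId = "character"
  ),
  prototype(
    tracks = data.frame(frame = integer(0), fly_id = integer(0),
                        x_mm = numeric(0), y_mm = numeric(0),
                        heading_rad = numeric(0)),
    frameRateHz = 30, arenaDiameterMm = 61,
    genotype = "unknown", recordingId = "rec"
  ),
  validity = function(object) {
    msg <- character(0)
    need <- c("frame", "fly_id", "x_mm", "y_mm", "heading_rad")
    if (!all(need %in% names(object@tracks))) {
      return(paste("tracks must have columns:", paste(need, collapse = ", ")))
    }
    tr <- object@tracks
    if (object@frameRateHz <= 0) msg <- c(msg, "frameRateHz must be positive")
    if (nrow(tr)) {
      if (anyNA(tr$frame) || anyNA(tr$fly_id)) {
        msg <- c(msg, "frame and fly_id must not be NA")
      } else {
        if (any(duplicated(tr[c("frame", "fly_id")]))) {
          msg <- c(msg, "duplicated (frame, fly_id) rows")
        }
        spl <- split(tr$frame, tr$fly_id)
        if (any(vapply(spl, is.unsorted, logical(1), strictly = TRUE))) {
          msg <- c(msg, "frame indices must be strictly increasing per fly")
        }
      }
      ok <- is.finite(tr$x_mm) & is.finite(tr$y_mm)
      if (!all(ok)) msg <- c(msg, "positions must be finite")
      h <- tr$heading_rad
      if (any(!is.finite(h) | h <= -pi - 1e-9 | h > pi + 1e-9)) {
        msg <- c(msg, "headings must be finite and in (-pi, pi]")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' @rdname FlyTrackSet-class
#' @param tracks,frameRateHz,arenaDiameterMm,genotype,recordingId see slots.
#' @return a `FlyTrackSet` object.
#' @export
FlyTrackSet <- function(tracks, frameRateHz = 30, arenaDiameterMm = 61,
                        genotype = "unknown", recordingId = "rec") {
  tracks <- as.data.frame(tracks)
  tracks$frame <- as.integer(tracks$frame)
  tracks$fly_id <- as.integer(tracks$fly_id)
  tracks <- tracks[order(tracks$fly_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  new("FlyTrackSet", tracks = tracks, frameRateHz = frameRateHz,
      arenaDiameterMm = arenaDiameterMm, genotype = genotype,
      recordingId = recordingId)
}

#' Directed weighted social interaction network
#'
#' Nodes are the flies of one (possibly chimeric) group, 0-based ids
#' `0..nNodes-1`; a directed edge actor -> target records that the actor
#' interacted toward the target, weighted by the number of interaction
#' events (`count`) and their summed duration in seconds (`duration_s`).
#' Isolated nodes are retained; self-loops are forbidden.
#'
#' @slot nNodes number of flies (nodes).
#' @slot edges data.frame with columns `actor`, `target`, `count`,
#'   `duration_s`.
#' @slot provenance free-form list (recording id, genotype, ...).
#' @export
setClass("SocialNetwork",
  representation(
    nNodes = "integer", edges = "data.frame", provenance = "list"
  ),
  prototype(
    nNodes = 0L,
    edges = data.frame(actor = integer(0), target = integer(0),
                       count = integer(0), duration_s = numeric(0)),
    provenance = list()
  ),
  validity = function(object) {
    msg <- character(0)
    need <- c("actor", "target", "count", "duration_s")
    if (!all(need %in% names(object@edges))) {
      return(paste("edges must have columns:", paste(need, collapse = ", ")))
    }
    e <- object@edges
    if (nrow(e)) {
      if (any(e$actor == e$target)) msg <- c(msg, "self-loops are forbidden")
      if (any(e$actor < 0L | e$actor >= object@nNodes |
              e$target < 0L | e$target >= object@nNodes)) {
        msg <- c(msg, "node ids must lie in 0..nNodes-1")
      }
      if (any(duplicated(e[c("actor", "target")]))) {
        msg <- c(msg, "duplicated directed edges")
      }
      if (any(e$count < 1L) || any(e$duration_s <= 0)) {
        msg <- c(msg, "edge weights must be positive")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' @rdname SocialNetwork-class
#' @param nNodes,edges,provenance see slots.
#' @return a `SocialNetwork` object.
#' @export
SocialNetwork <- function(nNodes, edges = NULL, provenance = list()) {
  if (is.null(edges)) {
    edges <- data.frame(actor = integer(0), target = integer(0),
                        count = integer(0), duration_s = numeric(0))
  }
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    edges$actor <- as.integer(edges$actor)
    edges$target <- as.integer(edges$target)
    edges$count <- as.integer(edges$count)
    edges <- edges[order(edges$actor, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  new("SocialNetwork", nNodes = as.integer(nNodes), edges = edges,
      provenance = provenance)
}

#' Per-minute beam-break activity series for one fly
#'
#' One infrared-beam monitor channel: the number of beam crossings per
#' one-minute interval, with the light schedule (lights on 08:00, off 20:00
#' by default) or a constant-darkness flag. The series starts at `startHour`
#' on day 0 and minutes are contiguous.
#'
#' @slot counts nonnegative integer counts, one per minute.
#' @slot startHour clock time of the first minute, hours.
#' @slot lightsOnH,lightsOffH light schedule, hours.
#' @slot constantDark TRUE for free-running (DD) recordings.
#' @slot flyId channel / fly identifier.
#' @slot planted generator ground truth (list: `bouts` data.frame with
#'   `start_min`, `length_min`; `period_h`), empty for real data.
#' @export
setClass("ActivitySeries",
  representation(
    counts = "integer", startHour = "numeric",
    lightsOnH = "numeric", lightsOffH = "numeric",
    constantDark = "logical", flyId = "character", planted = "list"
  ),
  prototype(
    counts = integer(0), startHour = 8, lightsOnH = 8, lightsOffH = 20,
    constantDark = FALSE, flyId = "fly", planted = list()
  ),
  validity = function(object) {
    msg <- character(0)
    if (length(object@counts) && any(object@counts < 0L, na.rm = TRUE)) {
      msg <- c(msg, "counts must be nonnegative")
    }
    if (!object@constantDark && object@lightsOnH == object@lightsOffH) {
      msg <- c(msg, "lightsOnH must differ from lightsOffH")
    }
    if (length(msg)) msg else TRUE
  }
)

#' @rdname ActivitySeries-class
#' @param counts,startHour,lightsOnH,lightsOffH,constantDark,flyId,planted
#'   see slots.
#' @return an `ActivitySeries` object.
#' @export
ActivitySeries <- function(counts, startHour = 8, lightsOnH = 8,
                           lightsOffH = 20, constantDark = FALSE,
                           flyId = "fly", planted = list()) {
  new("ActivitySeries", counts = as.integer(counts), startHour = startHour,
      lightsOnH = lightsOnH, lightsOffH = lightsOffH,
      constantDark = constantDark, flyId = flyId, planted = planted)
}

# ---------------------------------------------------------------------------
# Accessors and show methods
# ---------------------------------------------------------------------------

#' @describeIn FlyTrackSet-class trajectory table accessor.
#' @param x object.
#' @export
setGeneric("trackData", function(x) standardGeneric("trackData"))
#' @rdname FlyTrackSet-class
#' @export
setMethod("trackData", "FlyTrackSet", function(x) x@tracks)

#' @describeIn FlyTrackSet-class frame rate accessor.
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname FlyTrackSet-class
#' @export
setMethod("frameRate", "FlyTrackSet", function(x) x@frameRateHz)

#' @describeIn FlyTrackSet-class distinct fly ids.
#' @export
setGeneric("flyIds", function(x) standardGeneric("flyIds"))
#' @rdname FlyTrackSet-class
#' @export
setMethod("flyIds", "FlyTrackSet", function(x) sort(unique(x@tracks$fly_id)))

#' @describeIn FlyTrackSet-class number of distinct flies.
#' @export
setGeneric("nFlies", function(x) standardGeneric("nFlies"))
#' @rdname FlyTrackSet-class
#' @export
setMethod("nFlies", "FlyTrackSet", function(x) length(flyIds(x)))

#' @describeIn SocialNetwork-class edge table accessor.
#' @param x object.
#' @export
setGeneric("edgeData", function(x) standardGeneric("edgeData"))
#' @rdname SocialNetwork-class
#' @export
setMethod("edgeData", "SocialNetwork", function(x) x@edges)

#' @describeIn SocialNetwork-class number of nodes.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname SocialNetwork-class
#' @export
setMethod("nNodes", "SocialNetwork", function(x) x@nNodes)

#' @describeIn ActivitySeries-class per-minute counts accessor.
#' @param x object.
#' @export
setGeneric("beamCounts", function(x) standardGeneric("beamCounts"))
#' @rdname ActivitySeries-class
#' @export
setMethod("beamCounts", "ActivitySeries", function(x) x@counts)

setMethod("show", "FlyTrackSet", function(object) {
  tr <- object@tracks
  cat(sprintf("FlyTrackSet '%s' (%s): %d flies, frames %s, %.4g Hz, arena %.4g mm\n",
              object@recordingId, object@genotype, nFlies(object),
              if (nrow(tr)) paste0(min(tr$frame), "..", max(tr$frame)) else "-",
              object@frameRateHz, object@arenaDiameterMm))
})

setMethod("show", "SocialNetwork", function(object) {
  cat(sprintf("SocialNetwork: %d nodes, %d directed edges (total count %d, total duration %.3g s)\n",
              object@nNodes, nrow(object@edges),
              sum(object@edges$count), sum(object@edges$duration_s)))
})

setMethod("show", "ActivitySeries", function(object) {
  cat(sprintf("ActivitySeries '%s': %d min (%.2f days), %s, mean %.3g counts/min\n",
              object@flyId, length(object@counts),
              length(object@counts) / 1440,
              if (object@constantDark) "DD" else
                sprintf("LD %02.0f:00-%02.0f:00", object@lightsOnH, object@lightsOffH),
              if (length(object@counts)) mean(object@counts) else NA_real_))
})
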