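#' Read a tracker-style trajectory table
#'
#' Parses the plain trajectory dialect (one header line; columns `frame`,
#' `fly_id`, `x_mm`, `y_mm`, `heading_rad`; tab- or comma-separated,
#' auto-detected). Rows with missing position are recorded as tracking gaps
#' and never silently interpolated — use [fillGaps()] for that. A column
#' mapping for tracker exports with different column names can be supplied
#' via `colMap` (e.g. FlyTracker per-fly tables), keeping the shim in
#' configuration rather than code.
#'
#' @param path file path.
#' @param frameRateHz,arenaDiameterMm,genotype,recordingId recording
#'   metadata attached to the returned object.
#' @param colMap named character vector mapping the dialect's canonical
#'   names to the file's column names, e.g.
#'   `c(frame = "frame_idx", fly_id = "id", ...)`.
#' @return a [FlyTrackSet-class]; the number of dropped gap rows is attached
#'   as `attr(trackData(x), "n_gap_rows")`.
#' @export
readTrajectories <- function(path, frameRateHz = 30, arenaDiameterMm = 61,
                             genotype = "unknown", recordingId = "rec",
                             colMap = NULL) {
  .stopIfNot(file.exists(path), paste("no such file:", path))
  lines <- readLines(path)
  .stopIfNot(length(lines) >= 2L, "trajectory file has no data rows")
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  header <- trimws(strsplit(lines[1L], sep, fixed = TRUE)[[1L]])

  canonical <- c("frame", "fly_id", "x_mm", "y_mm", "heading_rad")
  wanted <- if (is.null(colMap)) stats::setNames(canonical, canonical) else colMap
  .stopIfNot(all(canonical %in% names(wanted)),
             "colMap must map all of: frame, fly_id, x_mm, y_mm, heading_rad")
  idx <- match(wanted[canonical], header)
  if (anyNA(idx)) {
    stop("missing column(s): ",
         paste(wanted[canonical][is.na(idx)], collapse = ", "), call. = FALSE)
  }

  body <- lines[-1L]
  keep <- nzchar(trimws(body))
  body <- body[keep]
  lineNo <- (seq_along(lines)[-1L])[keep]
  parts <- strsplit(body, sep, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header))) {
    bad <- lineNo[which(nf != length(header))[1L]]
    stop(sprintf("parse error at line %d: expected %d fields, got %d",
                 bad, length(header), nf[which(nf != length(header))[1L]]),
         call. = FALSE)
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = length(header),
              byrow = TRUE)[, idx, drop = FALSE]
  suppressWarnings({
    frame <- as.integer(m[, 1L])
    fly <- as.integer(m[, 2L])
    xs <- as.numeric(m[, 3L]); ys <- as.numeric(m[, 4L])
    hs <- as.numeric(m[, 5L])
  })
  wasBlank <- function(col) !nzchar(trimws(m[, col])) | toupper(trimws(m[, col])) == "NA"
  badKey <- (is.na(frame) & !wasBlank(1L)) | (is.na(fly) & !wasBlank(2L)) |
    is.na(frame) | is.na(fly)
  if (any(badKey)) {
    stop(sprintf("parse error at line %d: unreadable frame/fly_id",
                 lineNo[which(badKey)[1L]]), call. = FALSE)
  }
  badNum <- (is.na(xs) & !wasBlank(3L)) | (is.na(ys) & !wasBlank(4L)) |
    (is.na(hs) & !wasBlank(5L))
  if (any(badNum)) {
    stop(sprintf("parse error at line %d: unreadable numeric field",
                 lineNo[which(badNum)[1L]]), call. = FALSE)
  }
  if (anyDuplicated(data.frame(frame, fly))) {
    stop("integrity error: duplicate (frame, fly_id) rows", call. = FALSE)
  }

  gap <- is.na(xs) | is.na(ys) | is.na(hs)
  tracks <- data.frame(frame = frame[!gap], fly_id = fly[!gap],
                       x_mm = xs[!gap], y_mm = ys[!gap],
                       heading_rad = hs[!gap])
  out <- FlyTrackSet(tracks, frameRateHz = frameRateHz,
                     arenaDiameterMm = arenaDiameterMm,
                     genotype = genotype, recordingId = recordingId)
  attr(out@tracks, "n_gap_rows") <- sum(gap)
  out
}

#' Write a trajectory table in the package dialect
#'
#' @param x a [FlyTrackSet-class].
#' @param path output path.
#' @param sep `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
writeTrajectories <- function(x, path, sep = ",") {
  tr <- trackData(x)
  num <- function(v) sprintf("%.17g", v)
  lines <- c(
    paste(c("frame", "fly_id", "x_mm", "y_mm", "heading_rad"), collapse = sep),
    paste(tr$frame, tr$fly_id, num(tr$x_mm), num(tr$y_mm),
          num(tr$heading_rad), sep = sep)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Interpolate short tracking gaps
#'
#' Gaps of at most `maxGapFrames` missing frames are filled by linear
#' interpolation of position and shorter-arc circular interpolation of
#' heading (ties exactly pi apart resolve toward positive rotation). Longer
#' gaps are left missing, which splits the track for interaction detection
#' (a missing frame breaks any interaction run). The operation is
#' idempotent.
#'
#' @param x a [FlyTrackSet-class].
#' @param maxGapFrames largest gap length (frames) to interpolate; the
#'   default is one tenth of a second of frames.
#' @return a [FlyTrackSet-class]; gaps left unfilled are listed in
#'   `attr(trackData(x), "splits")` (`fly_id`, `gap_start`, `gap_length`).
#' @export
fillGaps <- function(x, maxGapFrames = max(1L, round(frameRate(x) / 10))) {
  .stopIfNot(maxGapFrames >= 0, "maxGapFrames must be >= 0")
  tr <- trackData(x)
  outPieces <- list()
  splits <- list()
  for (fid in flyIds(x)) {
    d <- tr[tr$fly_id == fid, , drop = FALSE]
    present <- d$frame
    full <- seq(min(present), max(present))
    missingFrames <- setdiff(full, present)
    if (length(missingFrames)) {
      # gap runs: each adjacent present pair with frame step > 1
      gapAfter <- which(diff(present) > 1)
      for (gi in gapAfter) {
        a <- present[gi]; b <- present[gi + 1L]
        gapLen <- b - a - 1L
        if (gapLen <= maxGapFrames) {
          f <- (a + 1L):(b - 1L)
          t <- (f - a) / (b - a)
          ia <- which(d$frame == a); ib <- which(d$frame == b)
          d <- rbind(d, data.frame(
            frame = f, fly_id = fid,
            x_mm = d$x_mm[ia] + t * (d$x_mm[ib] - d$x_mm[ia]),
            y_mm = d$y_mm[ia] + t * (d$y_mm[ib] - d$y_mm[ia]),
            heading_rad = .circInterp(d$heading_rad[ia], d$heading_rad[ib], t)
          ))
        } else {
          splits[[length(splits) + 1L]] <-
            data.frame(fly_id = fid, gap_start = a + 1L, gap_length = gapLen)
        }
      }
      d <- d[order(d$frame), , drop = FALSE]
    }
    outPieces[[as.character(fid)]] <- d
  }
  tracks <- do.call(rbind, outPieces)
  out <- FlyTrackSet(tracks, frameRateHz = frameRate(x),
                     arenaDiameterMm = x@arenaDiameterMm,
                     genotype = x@genotype, recordingId = x@recordingId)
  attr(out@tracks, "splits") <- if (length(splits)) {
    do.call(rbind, splits)
  } else {
    data.frame(fly_id = integer(0), gap_start = integer(0),
               gap_length = integer(0))
  }
  out
}
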