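# Interaction detection: distance + facing-angle + minimum-duration criteria
# applied per ordered fly pair, frame by frame.

# Per-fly matrices over the recording's frame range (NA where the fly is
# missing). Columns follow `ids`; rows follow `frames`.
.trackMatrices <- function(x) {
  tr <- trackData(x)
  ids <- flyIds(x)
  frames <- seq(min(tr$frame), max(tr$frame))
  nF <- length(frames); nI <- length(ids)
  X <- matrix(NA_real_, nF, nI)
  Y <- matrix(NA_real_, nF, nI)
  H <- matrix(NA_real_, nF, nI)
  ri <- tr$frame - frames[1L] + 1L
  ci <- match(tr$fly_id, ids)
  idx <- cbind(ri, ci)
  X[idx] <- tr$x_mm; Y[idx] <- tr$y_mm; H[idx] <- tr$heading_rad
  list(frames = frames, ids = ids, X = X, Y = Y, H = H)
}

.facingThresholdRad <- function(criteria) {
  deg <- switch(criteria@angleConvention,
                half = criteria@maxFacingAngleDeg / 2,
                full = criteria@maxFacingAngleDeg)
  deg * pi / 180
}

#' Per-frame pairwise interaction state
#'
#' For one frame, returns the ordered-pair matrix of the instantaneous
#' interaction state: entry \[i, j\] is TRUE when fly `i` (actor) is within
#' the distance threshold of fly `j` and faces it, i.e. the absolute offset
#' between the actor's heading and the actor-to-target bearing is at most
#' the facing threshold (half of the 160 degree cone by default). A fly
#' missing at the frame gives FALSE in its rows and columns.
#'
#' @param x a [FlyTrackSet-class].
#' @param criteria an [InteractionCriteria-class].
#' @param frame 0-based frame index.
#' @return logical `nFlies x nFlies` matrix (rows: actor, cols: target),
#'   dimnames = fly ids; the diagonal is FALSE.
#' @export
pairwiseState <- function(x, criteria = InteractionCriteria(), frame) {
  tm <- .trackMatrices(x)
  .stopIfNot(frame >= tm$frames[1L] && frame <= tm$frames[length(tm$frames)],
             "frame outside recording")
  r <- frame - tm$frames[1L] + 1L
  xs <- tm$X[r, ]; ys <- tm$Y[r, ]; hs <- tm$H[r, ]
  n <- length(xs)
  dmax <- maxDistanceMm(criteria)
  thr <- .facingThresholdRad(criteria)
  st <- matrix(FALSE, n, n, dimnames = list(tm$ids, tm$ids))
  for (i in seq_len(n)) {
    if (is.na(xs[i])) next
    for (j in seq_len(n)) {
      if (i == j || is.na(xs[j])) next
      d <- sqrt((xs[j] - xs[i])^2 + (ys[j] - ys[i])^2)
      if (d > dmax) next
      bear <- atan2(ys[j] - ys[i], xs[j] - xs[i])
      st[i, j] <- abs(.angDiff(bear, hs[i])) <= thr
    }
  }
  st
}

# maximal TRUE runs of a logical vector (NA counts as FALSE); returns
# cbind(start, end) of 1-based indices for runs of length >= minFrames
.runsFromState <- function(st, minFrames) {
  st[is.na(st)] <- FALSE
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths >= minFrames - 1e-9)
  cbind(start = starts[keep], end = ends[keep])
}

#' Detect directed interaction events
#'
#' Scans every ordered fly pair for maximal runs of consecutive frames in
#' the instantaneous interaction state (see [pairwiseState()]); runs
#' shorter than the minimum duration are discarded (the comparison is
#' inclusive: at 30 Hz and 0.6 s, an 18-frame run is kept and a 17-frame
#' run is not). Duration is run length divided by the frame rate. Missing
#' frames break runs; interpolate short gaps first with [fillGaps()] if
#' desired.
#'
#' @param x a [FlyTrackSet-class].
#' @param criteria an [InteractionCriteria-class].
#' @param frameRateHz frame rate used for the duration threshold; defaults
#'   to the recording's.
#' @return data.frame with columns `actor`, `target`, `start_frame`,
#'   `end_frame`, `duration_s`.
#' @export
detectEvents <- function(x, criteria = InteractionCriteria(),
                         frameRateHz = frameRate(x)) {
  .stopIfNot(frameRateHz > 0, "frameRateHz must be positive")
  tm <- .trackMatrices(x)
  agg <- .pairEvents(tm$X, tm$Y, tm$H, criteria, frameRateHz,
                     frame0 = tm$frames[1L])
  ev <- agg$events
  ev$actor <- tm$ids[ev$actor]
  ev$target <- tm$ids[ev$target]
  ev[order(ev$actor, ev$target, ev$start_frame), , drop = FALSE] -> ev
  rownames(ev) <- NULL
  ev
}

# Core pairwise scan over column-index flies; returns the event table
# (actor/target as column indices) and count/duration aggregate matrices.
.pairEvents <- function(X, Y, H, criteria, fps, frame0 = 0L,
                        events = TRUE) {
  n <- ncol(X)
  dmax2 <- maxDistanceMm(criteria)^2
  thr <- .facingThresholdRad(criteria)
  minFrames <- criteria@minDurationS * fps
  CNT <- matrix(0L, n, n)
  DUR <- matrix(0, n, n)
  evList <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      dx <- X[, j] - X[, i]
      dy <- Y[, j] - Y[, i]
      near <- (dx * dx + dy * dy) <= dmax2
      near[is.na(near)] <- FALSE
      if (!any(near)) next
      bear <- atan2(dy, dx)
      stIJ <- near & (abs(.angDiff(bear, H[, i])) <= thr)
      stJI <- near & (abs(.angDiff(bear + pi, H[, j])) <= thr)
      for (dir in 1:2) {
        st <- if (dir == 1L) stIJ else stJI
        runs <- .runsFromState(st, minFrames)
        if (!nrow(runs)) next
        a <- if (dir == 1L) i else j
        b <- if (dir == 1L) j else i
        durs <- (runs[, "end"] - runs[, "start"] + 1L) / fps
        CNT[a, b] <- CNT[a, b] + nrow(runs)
        DUR[a, b] <- DUR[a, b] + sum(durs)
        if (events) {
          evList[[length(evList) + 1L]] <- data.frame(
            actor = a, target = b,
            start_frame = frame0 + runs[, "start"] - 1L,
            end_frame = frame0 + runs[, "end"] - 1L,
            duration_s = durs
          )
        }
      }
    }
  }
  ev <- if (length(evList)) {
    do.call(rbind, evList)
  } else {
    data.frame(actor = integer(0), target = integer(0),
               start_frame = integer(0), end_frame = integer(0),
               duration_s = numeric(0))
  }
  list(events = ev, count = CNT, duration = DUR)
}

#' Aggregate interaction events into a social network
#'
#' Builds the directed weighted graph on exactly `nFlies` nodes (isolated
#' flies are retained): the edge actor -> target carries the number of
#' events (`count`) and their summed duration (`duration_s`).
#'
#' @param events event table from [detectEvents()] (fly ids 0-based).
#' @param nFlies number of nodes; all event ids must be `< nFlies`.
#' @param provenance free-form provenance list.
#' @return a [SocialNetwork-class].
#' @export
buildNetwork <- function(events, nFlies, provenance = list()) {
  .stopIfNot(nFlies >= 1, "nFlies must be >= 1")
  if (nrow(events)) {
    .stopIfNot(all(events$actor < nFlies & events$target < nFlies &
                     events$actor >= 0 & events$target >= 0),
               "event fly ids must lie in 0..nFlies-1")
    key <- paste(events$actor, events$target)
    cnt <- tapply(rep(1L, nrow(events)), key, sum)
    dur <- tapply(events$duration_s, key, sum)
    at <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
    edges <- data.frame(actor = as.integer(at[, 1L]),
                        target = as.integer(at[, 2L]),
                        count = as.integer(cnt),
                        duration_s = as.numeric(dur))
  } else {
    edges <- NULL
  }
  SocialNetwork(nFlies, edges, provenance)
}

#' Write an event table as CSV
#' @param events event table from [detectEvents()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEvents <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a network as a weighted edge-list text file
#' @param net a [SocialNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  e <- edgeData(net)
  lines <- c(sprintf("# nodes %d", nNodes(net)),
             "actor,target,count,duration_s",
             sprintf("%d,%d,%d,%.17g", e$actor, e$target, e$count,
                     e$duration_s))
  writeLines(lines, path)
  invisible(path)
}

#' Read a weighted edge-list text file written by [writeEdgeList()]
#' @param path input path.
#' @return a [SocialNetwork-class].
#' @export
readEdgeList <- function(path) {
  lines <- readLines(path)
  .stopIfNot(grepl("^# nodes ", lines[1L]), "missing '# nodes' header")
  n <- as.integer(sub("^# nodes ", "", lines[1L]))
  if (length(lines) > 2L) {
    e <- utils::read.csv(text = lines[-1L])
  } else {
    e <- NULL
  }
  SocialNetwork(n, e)
}

#' Convert a social network to an igraph object
#' @param net a [SocialNetwork-class].
#' @return a directed `igraph` graph with edge attributes `count` and
#'   `duration_s`.
#' @export
asIgraph <- function(net) {
  e <- edgeData(net)
  g <- igraph::make_empty_graph(n = nNodes(net), directed = TRUE)
  igraph::V(g)$name <- as.character(seq_len(nNodes(net)) - 1L)
  if (nrow(e)) {
    g <- igraph::add_edges(g, rbind(e$actor + 1L, e$target + 1L),
                           count = e$count, duration_s = e$duration_s)
  }
  g
}

#' Export a social network as GraphML
#' @param net a [SocialNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(net, path) {
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}

#' Import a GraphML network
#'
#' Accepts graphs written by [writeGraphML()] or any directed GraphML graph
#' with numeric `count` and `duration_s` edge attributes.
#'
#' @param path input path.
#' @return a [SocialNetwork-class].
#' @export
readGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g, names = FALSE)
  ea <- igraph::edge_attr(g)
  .stopIfNot(all(c("count", "duration_s") %in% names(ea)),
             "GraphML must carry 'count' and 'duration_s' edge attributes")
  edges <- if (nrow(el)) {
    data.frame(actor = el[, 1L] - 1L, target = el[, 2L] - 1L,
               count = as.integer(round(ea$count)),
               duration_s = as.numeric(ea$duration_s))
  } else {
    NULL
  }
  SocialNetwork(igraph::vcount(g), edges)
}
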