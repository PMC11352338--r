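# Random-network null model: chimeric groups reassembled from flies drawn
# across recordings of the same experimental condition. Interactions in a
# chimeric group reflect spatial coincidence only, giving the null against
# which observed SIN metrics are z-scored.

# pooled per-fly matrices across recordings, truncated to the shortest
# common frame count
.pooledMatrices <- function(recordings) {
  tms <- lapply(recordings, .trackMatrices)
  fps <- vapply(recordings, frameRate, numeric(1))
  .stopIfNot(length(unique(fps)) == 1L,
             "all recordings must share one frame rate")
  nF <- min(vapply(tms, function(tm) nrow(tm$X), integer(1)))
  cut <- function(M) M[seq_len(nF), , drop = FALSE]
  list(
    X = do.call(cbind, lapply(tms, function(tm) cut(tm$X))),
    Y = do.call(cbind, lapply(tms, function(tm) cut(tm$Y))),
    H = do.call(cbind, lapply(tms, function(tm) cut(tm$H))),
    recording = rep(seq_along(tms),
                    vapply(tms, function(tm) ncol(tm$X), integer(1))),
    fps = fps[1L]
  )
}

# ordered-pair event aggregates (count, duration) over the pooled flies
.pooledPairAggregates <- function(recordings, criteria) {
  pool <- .pooledMatrices(recordings)
  agg <- .pairEvents(pool$X, pool$Y, pool$H, criteria, pool$fps,
                     events = FALSE)
  list(count = agg$count, duration = agg$duration,
       recording = pool$recording, fps = pool$fps)
}

.chimericNetwork <- function(agg, pick, provenance = list()) {
  cnt <- agg$count[pick, pick, drop = FALSE]
  dur <- agg$duration[pick, pick, drop = FALSE]
  hit <- which(cnt > 0, arr.ind = TRUE)
  edges <- if (nrow(hit)) {
    data.frame(actor = hit[, 1L] - 1L, target = hit[, 2L] - 1L,
               count = cnt[hit], duration_s = dur[hit])
  } else {
    NULL
  }
  SocialNetwork(length(pick), edges, provenance)
}

#' Build random (chimeric-group) networks
#'
#' Samples `spec@nRandomNetworks` chimeric groups of `spec@groupSize` flies
#' without replacement from the pooled (recording, fly) index of one
#' experimental group — never all from a single recording (with
#' `spec@strict`, each fly must come from a distinct recording) — overlays
#' their trajectories in the common arena frame, re-runs interaction
#' detection, and aggregates each chimeric group into a network. Sampling
#' is with replacement across networks and seeded by `spec@seed`.
#'
#' @param recordings list of [FlyTrackSet-class] objects (>= 2 recordings,
#'   same frame rate).
#' @param spec a [NullModelSpec-class].
#' @param criteria an [InteractionCriteria-class].
#' @return list of [SocialNetwork-class] objects of length
#'   `spec@nRandomNetworks`.
#' @export
buildRandomNetworks <- function(recordings, spec,
                                criteria = InteractionCriteria()) {
  .stopIfNot(is(spec, "NullModelSpec"), "spec must be a NullModelSpec")
  if (length(recordings) < 2L) {
    stop("configuration error: need >= 2 recordings in the group",
         call. = FALSE)
  }
  agg <- .pooledPairAggregates(recordings, criteria)
  .sampleChimeric(agg, spec)
}

# sampling core, reusable once aggregates are precomputed
.sampleChimeric <- function(agg, spec) {
  nTot <- length(agg$recording)
  gs <- spec@groupSize
  .stopIfNot(nTot >= gs, "fewer pooled flies than groupSize")
  if (spec@strict && length(unique(agg$recording)) < gs) {
    stop("configuration error: fewer distinct recordings than groupSize",
         call. = FALSE)
  }
  set.seed(spec@seed)
  lapply(seq_len(spec@nRandomNetworks), function(k) {
    repeat {
      if (spec@strict) {
        recs <- sample(unique(agg$recording), gs)
        pick <- vapply(recs, function(r) {
          cand <- which(agg$recording == r)
          cand[sample.int(length(cand), 1L)]
        }, integer(1))
        break
      }
      pick <- sample.int(nTot, gs)
      if (length(unique(agg$recording[pick])) > 1L) break
    }
    .chimericNetwork(agg, sort(pick), provenance = list(null_index = k))
  })
}

#' z-score an observed metric against null values
#'
#' `z = (observed - mean(null)) / sd(null)` with the n-1 sd denominator.
#' A degenerate null (sd = 0) gives z = 0 when the observation equals the
#' null mean and a flagged undefined z otherwise.
#'
#' @param observed observed metric value.
#' @param nullValues numeric vector of null metric values (>= 2).
#' @param metric,weightMode,level optional labels copied to the output.
#' @return one-row data.frame with columns `metric`, `weight_mode`,
#'   `level`, `observed`, `null_mean`, `null_sd`, `z`, `n_null`,
#'   `undefined`.
#' @export
zscore <- function(observed, nullValues, metric = NA_character_,
                   weightMode = NA_character_, level = NA_character_) {
  .stopIfNot(length(nullValues) >= 2, "need at least 2 null values")
  m <- mean(nullValues)
  s <- stats::sd(nullValues)
  undef <- FALSE
  if (s > 0) {
    z <- (observed - m) / s
  } else if (observed == m) {
    z <- 0
  } else {
    z <- NA_real_
    undef <- TRUE
  }
  data.frame(metric = metric, weight_mode = weightMode, level = level,
             observed = observed, null_mean = m, null_sd = s, z = z,
             n_null = length(nullValues), undefined = undef)
}

#' Observed-vs-null SIN metric z-scores for a group of recordings
#'
#' The end-to-end normalization stage: detects interactions and builds the
#' observed network of every recording, builds the chimeric-group null from
#' the same recordings, computes the four metrics (both weight modes) on
#' observed and null networks, and z-scores each observed value against the
#' null distribution. Global efficiency is z-scored at the network level;
#' local metrics at the node-mean level and (optionally) per node, where a
#' node's observed value is compared with the pooled distribution of node
#' values across null networks.
#'
#' @param recordings list of [FlyTrackSet-class] objects of one condition.
#' @param spec a [NullModelSpec-class].
#' @param criteria an [InteractionCriteria-class].
#' @param emitNodes also emit per-node z-scores (`level = "node"`).
#' @param closenessVariant passed to [closenessCentrality()].
#' @return tidy data.frame with columns `recording`, `genotype`, `node`,
#'   and the [zscore()] columns.
#' @export
sinZScores <- function(recordings, spec, criteria = InteractionCriteria(),
                       emitNodes = FALSE, closenessVariant = "wf") {
  if (length(recordings) < 2L) {
    stop("configuration error: need >= 2 recordings in the group",
         call. = FALSE)
  }
  agg <- .pooledPairAggregates(recordings, criteria)
  nulls <- .sampleChimeric(agg, spec)
  nullSum <- lapply(nulls, metricSummary, closenessVariant = closenessVariant)
  key <- function(df) paste(df$metric, df$weight_mode, df$level)
  nullMat <- vapply(nullSum, function(df) df$value,
                    numeric(nrow(nullSum[[1L]])))
  nullKeys <- key(nullSum[[1L]])
  nullNodes <- NULL
  if (emitNodes) {
    nn <- lapply(nulls, nodeMetrics, closenessVariant = closenessVariant)
    nullNodes <- do.call(rbind, nn)
  }

  out <- list()
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    net <- buildNetwork(detectEvents(rec, criteria), nFlies = nFlies(rec),
                        provenance = list(recording = rec@recordingId,
                                          genotype = rec@genotype))
    obs <- metricSummary(net, closenessVariant = closenessVariant)
    obsKeys <- key(obs)
    for (i in seq_len(nrow(obs))) {
      zr <- zscore(obs$value[i], nullMat[match(obsKeys[i], nullKeys), ],
                   metric = obs$metric[i], weightMode = obs$weight_mode[i],
                   level = obs$level[i])
      zr <- cbind(data.frame(recording = rec@recordingId,
                             genotype = rec@genotype, node = NA_integer_),
                  zr)
      out[[length(out) + 1L]] <- zr
    }
    if (emitNodes) {
      obsN <- nodeMetrics(net, closenessVariant = closenessVariant)
      for (i in seq_len(nrow(obsN))) {
        nv <- nullNodes$value[nullNodes$metric == obsN$metric[i] &
                                nullNodes$weight_mode == obsN$weight_mode[i]]
        zr <- zscore(obsN$value[i], nv, metric = obsN$metric[i],
                     weightMode = obsN$weight_mode[i], level = "node")
        zr <- cbind(data.frame(recording = rec@recordingId,
                               genotype = rec@genotype,
                               node = obsN$node[i]),
                    zr)
        out[[length(out) + 1L]] <- zr
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
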