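# Directed weighted SIN metrics.
#
# Edge weights (interaction count or total duration) measure tie strength,
# so path distance uses the standard conversion distance = 1/weight
# (stronger tie = closer). Shortest-path computations use an explicit tie
# tolerance: path lengths within `tol` (relative) are treated as equal, so
# that mathematically tied paths whose floating-point sums differ in the
# last bits (e.g. 1/3 + 1/3 + 1/3 vs 1) are counted as ties. This keeps
# betweenness path counts well defined and reproducible.

.metricTol <- 1e-9

.near <- function(a, b, tol = .metricTol) {
  abs(a - b) <= tol * pmax(1, abs(b))
}

# weight matrix (n x n, 0 = no edge)
.weightMatrix <- function(net, weightMode = c("count", "duration")) {
  weightMode <- match.arg(weightMode)
  n <- nNodes(net)
  e <- edgeData(net)
  W <- matrix(0, n, n)
  if (nrow(e)) {
    w <- if (weightMode == "count") e$count else e$duration_s
    W[cbind(e$actor + 1L, e$target + 1L)] <- w
  }
  W
}

# edge length matrix: 1/W, Inf where no edge; optionally weights rescaled
# by the maximum so lengths are >= 1 (used by closeness normalization)
.lengthMatrix <- function(W, normalize = FALSE) {
  if (normalize && any(W > 0)) W <- W / max(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- Inf   # no self-loops; self-distance handled separately
  L
}

# all-pairs shortest-path distances (Floyd-Warshall); D[i, i] = 0
.distMatrix <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# number of distinct shortest paths s -> v for every pair, under the tie
# tolerance; shortest paths have positive lengths so they are simple
.spCountMatrix <- function(L, D, tol = .metricTol) {
  n <- nrow(L)
  SIG <- matrix(0, n, n)
  finL <- is.finite(L)
  for (s in seq_len(n)) {
    ds <- D[s, ]
    # pred[u, v]: edge u -> v lies on a shortest s -> v path
    # (v itself is excluded because L[v, v] is Inf)
    tot <- ds + L                       # broadcast over columns of L
    pred <- finL & is.finite(ds) &
      abs(tot - rep(ds, each = n)) <= tol * pmax(1, abs(rep(ds, each = n)))
    sigma <- numeric(n)
    sigma[s] <- 1
    for (v in order(ds)) {
      if (v == s || !is.finite(ds[v])) next
      sigma[v] <- sum(sigma[pred[, v]])
    }
    SIG[s, ] <- sigma
  }
  SIG
}

#' Global efficiency of a social network
#'
#' Mean over ordered node pairs of the inverse shortest-path distance, with
#' edge distance = 1/weight; unreachable pairs contribute 0. High values
#' mean interactions can spread through few strong ties.
#'
#' @param net a [SocialNetwork-class] (>= 2 nodes).
#' @param weightMode `"count"` or `"duration"`.
#' @return a nonnegative scalar.
#' @export
globalEfficiency <- function(net, weightMode = c("count", "duration")) {
  .stopIfNot(nNodes(net) >= 2, "need at least 2 nodes")
  D <- .distMatrix(.lengthMatrix(.weightMatrix(net, weightMode)))
  n <- nrow(D)
  off <- D[row(D) != col(D)]
  sum(ifelse(is.finite(off) & off > 0, 1 / off, 0)) / (n * (n - 1))
}

#' Local clustering coefficient (directed, weighted)
#'
#' Per-node clustering for directed weighted graphs using the
#' geometric-mean-of-weights triangle formulation with total-degree
#' normalization: with W the weight matrix rescaled by its maximum and
#' S = W^(1/3) + (W')^(1/3), node i scores
#' `diag(S^3)_i / 2 / (dtot_i (dtot_i - 1) - 2 dbi_i)`, where `dtot` is the
#' binary in+out degree and `dbi` the number of bilateral neighbours.
#' Nodes with fewer than two distinct neighbours score 0. Values lie in
#' \[0, 1\] and proxy the tendency to form tightly knit groups.
#'
#' @param net a [SocialNetwork-class].
#' @param weightMode `"count"` or `"duration"`.
#' @return numeric vector, one value per node.
#' @export
localClustering <- function(net, weightMode = c("count", "duration")) {
  W <- .weightMatrix(net, weightMode)
  n <- nrow(W)
  if (n == 0L) return(numeric(0))
  if (any(W > 0)) W <- W / max(W)
  S <- W^(1 / 3) + t(W)^(1 / 3)
  num <- diag(S %*% S %*% S) / 2
  A <- (W > 0) * 1
  dtot <- rowSums(A) + colSums(A)
  dbi <- rowSums(A * t(A))
  den <- dtot * (dtot - 1) - 2 * dbi
  out <- ifelse(den > 0, num / den, 0)
  as.numeric(out)
}

#' Betweenness centrality (directed, weighted)
#'
#' Fraction of shortest paths (edge distance = 1/weight) between ordered
#' node pairs that pass through the node, normalized by (n-1)(n-2); values
#' lie in \[0, 1\]. Ties in path length are resolved with the package's
#' shortest-path tolerance, so all mathematically tied shortest paths are
#' counted.
#'
#' @param net a [SocialNetwork-class] (>= 2 nodes).
#' @param weightMode `"count"` or `"duration"`.
#' @return numeric vector, one value per node.
#' @export
betweennessCentrality <- function(net, weightMode = c("count", "duration")) {
  n <- nNodes(net)
  .stopIfNot(n >= 2, "need at least 2 nodes")
  L <- .lengthMatrix(.weightMatrix(net, weightMode))
  D <- .distMatrix(L)
  .betweennessFromD(L, D)
}

# betweenness accumulation given the length and distance matrices
.betweennessFromD <- function(L, D, tol = .metricTol) {
  n <- nrow(D)
  SIG <- .spCountMatrix(L, D, tol)
  bet <- numeric(n)
  for (s in seq_len(n)) {
    ds <- D[s, ]
    sig_s <- SIG[s, ]
    # on[v, t]: v lies on a shortest s -> t path
    tot <- ds + D                 # element (v, t) = D[s, v] + D[v, t]
    tgt <- rep(ds, each = n)      # element (v, t) = D[s, t]
    on <- is.finite(tot) & is.finite(tgt) &
      abs(tot - tgt) <= tol * pmax(1, abs(tgt))
    on[s, ] <- FALSE
    diag(on) <- FALSE             # v == t
    on[, s] <- FALSE
    valid <- sig_s > 0            # per t: any shortest path exists
    contrib <- (on * SIG) %*% ifelse(valid & seq_len(n) != s,
                                     1 / pmax(sig_s, 1), 0)
    bet <- bet + sig_s * contrib[, 1L]
  }
  if (n > 2) bet / ((n - 1) * (n - 2)) else bet
}

#' Closeness centrality (directed, weighted)
#'
#' Incoming-distance closeness with the Wasserman–Faust reachability
#' correction for disconnected graphs: for node i with R_i nodes able to
#' reach it, `C_i = (R_i / (n-1)) * (R_i / sum of incoming distances)`.
#' Edge weights are rescaled by the maximum weight before the 1/weight
#' distance conversion so all distances are >= 1 and the score lies in
#' \[0, 1\] (on a unit-weight complete digraph every node scores 1).
#' `variant = "harmonic"` switches to normalized harmonic closeness
#' (mean of inverse incoming distances).
#'
#' @param net a [SocialNetwork-class] (>= 2 nodes).
#' @param weightMode `"count"` or `"duration"`.
#' @param variant `"wf"` (Wasserman–Faust, default) or `"harmonic"`.
#' @return numeric vector, one value per node; isolated nodes score 0.
#' @export
closenessCentrality <- function(net, weightMode = c("count", "duration"),
                                variant = c("wf", "harmonic")) {
  variant <- match.arg(variant)
  n <- nNodes(net)
  .stopIfNot(n >= 2, "need at least 2 nodes")
  D <- .distMatrix(.lengthMatrix(.weightMatrix(net, weightMode),
                                 normalize = TRUE))
  out <- numeric(n)
  for (i in seq_len(n)) {
    din <- D[-i, i]
    if (variant == "wf") {
      reach <- is.finite(din)
      R <- sum(reach)
      out[i] <- if (R > 0) (R / (n - 1)) * (R / sum(din[reach])) else 0
    } else {
      out[i] <- mean(ifelse(is.finite(din) & din > 0, 1 / din, 0))
    }
  }
  out
}

# all four metrics for one weight mode from a single distance computation
# (closeness distances are the same matrix rescaled by the max weight)
.metricBundle <- function(net, weightMode, closenessVariant = "wf") {
  W <- .weightMatrix(net, weightMode)
  n <- nrow(W)
  L <- .lengthMatrix(W)
  D <- .distMatrix(L)
  off <- D[row(D) != col(D)]
  eff <- sum(ifelse(is.finite(off) & off > 0, 1 / off, 0)) / (n * (n - 1))
  bet <- .betweennessFromD(L, D)
  Dn <- D * if (any(W > 0)) max(W) else 1
  clo <- numeric(n)
  for (i in seq_len(n)) {
    din <- Dn[-i, i]
    if (closenessVariant == "wf") {
      reach <- is.finite(din)
      R <- sum(reach)
      clo[i] <- if (R > 0) (R / (n - 1)) * (R / sum(din[reach])) else 0
    } else {
      clo[i] <- mean(ifelse(is.finite(din) & din > 0, 1 / din, 0))
    }
  }
  list(global_efficiency = eff,
       clustering_coefficient = localClustering(net, weightMode),
       betweenness_centrality = bet,
       closeness_centrality = clo)
}

#' Tidy metric summary of one network
#'
#' Computes the four SIN metrics for both weight modes. Global efficiency
#' is a network-level (global) quantity; the three local metrics are
#' summarized by their mean over nodes (`level = "local_mean"`).
#'
#' @param net a [SocialNetwork-class].
#' @param closenessVariant passed to [closenessCentrality()].
#' @return data.frame with columns `metric`, `weight_mode`, `level`,
#'   `value`.
#' @export
metricSummary <- function(net, closenessVariant = "wf") {
  rows <- list()
  for (wm in c("count", "duration")) {
    b <- .metricBundle(net, wm, closenessVariant)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "global_efficiency", weight_mode = wm, level = "global",
      value = b$global_efficiency)
    for (m in c("clustering_coefficient", "betweenness_centrality",
                "closeness_centrality")) {
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, weight_mode = wm, level = "local_mean",
        value = mean(b[[m]]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-node metric table of one network
#'
#' @param net a [SocialNetwork-class].
#' @param closenessVariant passed to [closenessCentrality()].
#' @return data.frame with columns `node`, `metric`, `weight_mode`,
#'   `value`.
#' @export
nodeMetrics <- function(net, closenessVariant = "wf") {
  n <- nNodes(net)
  rows <- list()
  for (wm in c("count", "duration")) {
    b <- .metricBundle(net, wm, closenessVariant)
    loc <- b[c("clustering_coefficient", "betweenness_centrality",
               "closeness_centrality")]
    for (m in names(loc)) {
      rows[[length(rows) + 1L]] <- data.frame(
        node = seq_len(n) - 1L, metric = m, weight_mode = wm,
        value = loc[[m]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
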