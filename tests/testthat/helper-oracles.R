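# Brute-force network-metric oracles: exhaustive simple-path enumeration,
# independent of the package's Floyd-Warshall / path-counting machinery.
# Shared tie semantics: path lengths within 1e-9 (relative) are equal.

oracleNear <- function(a, b, tol = 1e-9) abs(a - b) <= tol * pmax(1, abs(b))

# all simple paths s -> t in weight matrix W (0 = no edge); returns a list
# of integer node sequences (including endpoints)
allSimplePaths <- function(W, s, t) {
  n <- nrow(W)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (W[v, u] > 0 && !(u %in% path)) walk(c(path, u))
    }
  }
  walk(s)
  paths
}

pathLength <- function(W, path) {
  if (length(path) < 2L) return(0)
  sum(1 / W[cbind(path[-length(path)], path[-1L])])
}

# shortest-path structure for every ordered pair: distance, number of tied
# shortest paths, and per-node through-counts
oracleShortestPaths <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n); diag(D) <- 0
  SIG <- matrix(0, n, n)
  THR <- array(0, c(n, n, n))   # [s, t, v] shortest s->t paths through v
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    ps <- allSimplePaths(W, s, t)
    if (!length(ps)) next
    lens <- vapply(ps, function(p) pathLength(W, p), numeric(1))
    dmin <- min(lens)
    tied <- ps[oracleNear(lens, dmin)]
    D[s, t] <- dmin
    SIG[s, t] <- length(tied)
    for (p in tied) {
      mid <- setdiff(p, c(s, t))
      if (length(mid)) THR[s, t, mid] <- THR[s, t, mid] + 1
    }
  }
  list(D = D, SIG = SIG, THR = THR)
}

oracleGlobalEfficiency <- function(W) {
  n <- nrow(W)
  sp <- oracleShortestPaths(W)
  off <- sp$D[row(sp$D) != col(sp$D)]
  sum(ifelse(is.finite(off) & off > 0, 1 / off, 0)) / (n * (n - 1))
}

oracleBetweenness <- function(W) {
  n <- nrow(W)
  sp <- oracleShortestPaths(W)
  bet <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || sp$SIG[s, t] == 0) next
    bet <- bet + sp$THR[s, t, ] / sp$SIG[s, t]
  }
  if (n > 2) bet / ((n - 1) * (n - 2)) else bet
}

oracleCloseness <- function(W) {
  n <- nrow(W)
  Wn <- if (any(W > 0)) W / max(W) else W
  sp <- oracleShortestPaths(Wn)
  out <- numeric(n)
  for (i in seq_len(n)) {
    din <- sp$D[-i, i]
    reach <- is.finite(din)
    R <- sum(reach)
    out[i] <- if (R > 0) (R / (n - 1)) * (R / sum(din[reach])) else 0
  }
  out
}

# direct triple-loop evaluation of the geometric-mean directed clustering
oracleClustering <- function(W) {
  n <- nrow(W)
  Wn <- if (any(W > 0)) W / max(W) else W
  A <- (W > 0) * 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      s <- s + (Wn[i, j]^(1 / 3) + Wn[j, i]^(1 / 3)) *
        (Wn[j, k]^(1 / 3) + Wn[k, j]^(1 / 3)) *
        (Wn[k, i]^(1 / 3) + Wn[i, k]^(1 / 3))
    }
    num <- s / 2
    dtot <- sum(A[i, ]) + sum(A[, i])
    dbi <- sum(A[i, ] * A[, i])
    den <- dtot * (dtot - 1) - 2 * dbi
    out[i] <- if (den > 0) num / den else 0
  }
  out
}

# SocialNetwork from a weight matrix: count = W, duration = W seconds
netFromMatrix <- function(W) {
  hit <- which(W > 0, arr.ind = TRUE)
  edges <- if (nrow(hit)) {
    data.frame(actor = hit[, 1L] - 1L, target = hit[, 2L] - 1L,
               count = W[hit], duration_s = as.numeric(W[hit]))
  } else NULL
  SocialNetwork(nrow(W), edges)
}

randomWeightMatrix <- function(n, pEdge = 0.5, weights = 1:3) {
  W <- matrix(0, n, n)
  off <- which(row(W) != col(W))
  on <- off[stats::runif(length(off)) < pEdge]
  W[on] <- sample(weights, length(on), replace = TRUE)
  W
}

expectMetricsMatchOracle <- function(W, tol = 1e-9) {
  net <- netFromMatrix(W)
  expect_equal(globalEfficiency(net, "count"), oracleGlobalEfficiency(W),
               tolerance = tol)
  expect_equal(betweennessCentrality(net, "count"), oracleBetweenness(W),
               tolerance = tol)
  expect_equal(closenessCentrality(net, "count"), oracleCloseness(W),
               tolerance = tol)
  expect_equal(localClustering(net, "count"), oracleClustering(W),
               tolerance = tol)
}
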