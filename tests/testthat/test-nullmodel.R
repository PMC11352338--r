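# Chimeric-group null model and z-score normalization.

test_that("zscore arithmetic and degenerate cases", {
  z <- zscore(5, c(1, 2, 3))
  expect_equal(z$z, 3.0)
  expect_equal(z$null_mean, 2)
  expect_equal(z$null_sd, 1)
  expect_equal(zscore(2, c(1, 2, 3))$z, 0)
  zd <- zscore(4, c(4, 4, 4))
  expect_equal(zd$z, 0)
  expect_false(zd$undefined)
  zu <- zscore(5, c(4, 4, 4))
  expect_true(zu$undefined)
  expect_true(is.na(zu$z))
  expect_error(zscore(1, numeric(0)), "2 null values")
})

test_that("random networks are deterministic given the seed", {
  recs <- lapply(1:3, function(i) {
    simulateTrajectories(ArenaSpec(durationS = 10), 4, seed = i,
                         recordingId = paste0("r", i))
  })
  spec <- NullModelSpec(nRandomNetworks = 3, groupSize = 4, seed = 12)
  n1 <- buildRandomNetworks(recs, spec)
  n2 <- buildRandomNetworks(recs, spec)
  for (k in seq_along(n1)) {
    expect_identical(edgeData(n1[[k]]), edgeData(n2[[k]]))
  }
})

test_that("parked far-apart flies give empty random networks", {
  mk <- function(offset, id) {
    poses <- data.frame(fly_id = 0:2, x = offset + c(0, 10, 20), y = -20,
                        h = 0)
    ts <- staticTrackSet(poses, frames = 60)
    ts@recordingId <- id
    ts
  }
  recs <- list(mk(-25, "a"), mk(5, "b"))
  nets <- buildRandomNetworks(recs, NullModelSpec(nRandomNetworks = 5,
                                                  groupSize = 4, seed = 3))
  for (net in nets) expect_equal(nrow(edgeData(net)), 0)
})

test_that("null model configuration errors", {
  recs <- list(simulateTrajectories(ArenaSpec(durationS = 5), 4, seed = 1))
  expect_error(buildRandomNetworks(recs, NullModelSpec(nRandomNetworks = 1,
                                                       groupSize = 4,
                                                       seed = 1)),
               "configuration error")
  expect_error(NullModelSpec(nRandomNetworks = 10, groupSize = 4),
               "seed")
})

test_that("strict mode draws every fly from a distinct recording", {
  recs <- lapply(1:4, function(i) {
    simulateTrajectories(ArenaSpec(durationS = 5), 3, seed = i,
                         recordingId = paste0("r", i))
  })
  agg <- flysin:::.pooledPairAggregates(recs, InteractionCriteria())
  spec <- NullModelSpec(nRandomNetworks = 20, groupSize = 4, seed = 5,
                        strict = TRUE)
  set.seed(spec@seed)
  # re-run the sampler and check recordings are distinct per draw
  nets <- flysin:::.sampleChimeric(agg, spec)
  expect_length(nets, 20)
  expect_error(
    buildRandomNetworks(recs[1:2], NullModelSpec(nRandomNetworks = 1,
                                                 groupSize = 4, seed = 1,
                                                 strict = TRUE)),
    "distinct recordings")
})

test_that("null and observed efficiencies are exchangeable for non-social flies", {
  # with attraction 0, a chimeric group is statistically the same object
  # as an observed group: the two efficiency distributions must agree
  nRec <- 40
  recs <- lapply(seq_len(nRec), function(i) {
    simulateTrajectories(ArenaSpec(durationS = 15), 4, SocialProfile(),
                         seed = 600 + i, recordingId = paste0("r", i))
  })
  obsEff <- vapply(recs, function(r) {
    globalEfficiency(buildNetwork(detectEvents(r), 4), "count")
  }, numeric(1))
  nulls <- buildRandomNetworks(recs, NullModelSpec(nRandomNetworks = 200,
                                                   groupSize = 4, seed = 77))
  nullEff <- vapply(nulls, globalEfficiency, numeric(1), weightMode = "count")
  ks <- suppressWarnings(ks.test(obsEff, nullEff))
  expect_gt(ks$p.value, 0.01)
})

test_that("observed z-scores from the same distribution as the null stay small", {
  set.seed(100)
  obs <- rnorm(1)
  nulls <- rnorm(10000)
  expect_lt(abs(zscore(obs, nulls)$z), 4)
})

test_that("sinZScores emits tidy global, local-mean and node rows", {
  recs <- lapply(1:3, function(i) {
    simulateTrajectories(ArenaSpec(durationS = 10), 4, seed = 50 + i,
                         recordingId = paste0("r", i))
  })
  z <- sinZScores(recs, NullModelSpec(nRandomNetworks = 20, groupSize = 4,
                                      seed = 4), emitNodes = TRUE)
  expect_setequal(unique(z$level), c("global", "local_mean", "node"))
  expect_equal(sum(z$level == "global"), 3 * 2)      # recordings x modes
  expect_equal(sum(z$level == "local_mean"), 3 * 3 * 2)
  expect_equal(sum(z$level == "node"), 3 * 4 * 3 * 2)
  expect_true(all(z$n_null[z$level != "node"] == 20))
  # node-level nulls pool the node values of every null network
  expect_true(all(z$n_null[z$level == "node"] == 20 * 4))
  ok <- !z$undefined & z$null_sd > 0
  expect_equal(z$z[ok], (z$observed[ok] - z$null_mean[ok]) / z$null_sd[ok])
})
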