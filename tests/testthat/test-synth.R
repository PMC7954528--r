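# The synthetic-data generator: determinism and fidelity to its own truth.

test_that("skeleton growth stops at the cable target and is deterministic", {
  cfg <- synthConfig(seed = 2, targetCableUm = 100, meanSegmentUm = 20,
                     nBranchPoints = 3)
  sk <- synthSkeleton(cfg)
  expect_gte(cableLength(sk), 100)
  # growth stopped at the first crossing: removing the last-added segment
  # (some terminal edge) drops below the target
  expect_lt(cableLength(sk) - max(sk@edgeLengths), 100)
  expect_equal(sum(skeletonNodes(sk)$tag == "axon_exit"), 1)

  f1 <- withr::local_tempfile(fileext = ".swc")
  f2 <- withr::local_tempfile(fileext = ".swc")
  writeSWC(synthSkeleton(cfg), f1)
  writeSWC(synthSkeleton(cfg), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("mean generated cable tracks the target over seeds", {
  cables <- vapply(1:30, function(s)
    cableLength(synthSkeleton(synthConfig(seed = s, targetCableUm = 800,
                                          meanSegmentUm = 25,
                                          nBranchPoints = 10))),
    numeric(1))
  expect_lt(abs(mean(cables) - 800) / 800, 0.1)
})

test_that("synapse placement respects counts, modes, and planted extents", {
  cfg <- synthConfig(seed = 4, targetCableUm = 2000, nSynapses = 150,
                     nPartners = 18, placementMode = "clustered",
                     plantedNClusters = 4, plantedExtentUm = 50)
  sk <- synthSkeleton(cfg)
  syn <- synthSynapses(sk, cfg)
  expect_equal(nrow(synapseRecords(syn$table)), 150)
  D <- pairwiseDistances(syn$skeleton, syn$table)
  truth <- syn$truth
  for (k in seq_len(4)) {
    ids <- names(truth$synapseCluster)[truth$synapseCluster == k]
    expect_lte(max(D[ids, ids]), 50 + 1e-9)
  }
  # aligned coupling: every planted cluster draws from one group
  g <- truth$partnerGroup
  recs <- synapseRecords(syn$table)
  for (k in seq_len(4)) {
    ids <- recs$synapse_id[truth$synapseCluster[recs$synapse_id] == k]
    expect_equal(length(unique(g[recs$partner_id[match(
      ids, recs$synapse_id)]])), 1L)
  }
  # determinism of the full output
  syn2 <- synthSynapses(sk, cfg)
  expect_identical(synapseRecords(syn2$table), synapseRecords(syn$table))
})

test_that("uniform placement spreads synapses in proportion to cable", {
  cfg0 <- synthConfig(seed = 6, targetCableUm = 1200, nSynapses = 100)
  sk <- synthSkeleton(cfg0)
  # pool positions over seeds; bin by soma distance quartiles of the cable
  dAll <- unlist(lapply(1:15, function(s) {
    syn <- synthSynapses(sk, synthConfig(seed = s, targetCableUm = 1200,
                                         nSynapses = 100))
    distanceToSoma(syn$skeleton, syn$table)
  }))
  # expected mass per soma-distance bin, from densely sampled cable points
  synDense <- synthSynapses(sk, synthConfig(seed = 999,
                                            targetCableUm = 1200,
                                            nSynapses = 2000))
  dRef <- distanceToSoma(synDense$skeleton, synDense$table)
  br <- quantile(dRef, c(0.25, 0.5, 0.75))
  binOf <- function(d) findInterval(d, br)
  obs <- tabulate(binOf(dAll) + 1, 4)
  expect_gt(chisq.test(obs, p = rep(0.25, 4))$p.value, 1e-3)
})

test_that("coherence draws follow the group centroids and noise model", {
  cfg <- synthConfig(seed = 3, nPartners = 12, zNoiseSd = 0)
  z <- synthCoherence(cfg)
  g <- attr(z, "groups")
  for (gg in 1:3)
    expect_equal(length(unique(z[g[names(z)] == gg])), 1L)
  expect_true(all(Mod(z) <= 1 + 1e-12))

  # single functional group: F over any grouping is 1 within noise-free tol
  cfg1 <- synthConfig(seed = 3, nPartners = 8, nFunctionalGroups = 1,
                      zNoiseSd = 0)
  z1 <- synthCoherence(cfg1)
  r <- complexFRatio(split(unname(z1), rep(1:2, each = 4)))
  expect_equal(r@f, 1)

  # displaced groups give F > 1 on the true grouping across seeds
  fs <- vapply(1:20, function(s) {
    zz <- synthCoherence(synthConfig(seed = s, nPartners = 24))
    complexFRatio(split(unname(zz), attr(zz, "groups")[names(zz)]))@f
  }, numeric(1))
  expect_true(all(fs > 1))

  # unmatched fraction shrinks the returned map
  zU <- synthCoherence(synthConfig(seed = 3, nPartners = 10,
                                   unmatchedFraction = 0.3))
  expect_equal(length(zU), 7)
})

test_that("generated trials carry the planted rhythm and phases", {
  cfg <- synthConfig(seed = 8, nPartners = 5, snr = 1e9, bleachFraction = 0)
  trial <- synthTimeseries(cfg)
  cm <- coherenceMap(trial)
  expect_equal(cm$magnitude[cm$cell_id == "ref"], 1, tolerance = 1e-9)
  planted <- attr(trial, "phases")
  err <- abs(Arg(exp(1i * (cm$phase - planted[cm$cell_id]))))
  expect_lt(max(err), 0.02)

  cfg10 <- synthConfig(seed = 9, nPartners = 5, snr = 10)
  trial10 <- synthTimeseries(cfg10)
  fhat <- dominantFrequency(trialTraces(trial10)[, "ref"], cfg10@dt,
                            spectralOptions(searchBand = c(0.5, 3)))
  expect_lte(abs(fhat - 2), 1 / cfg10@trialS)

  # determinism
  t2 <- synthTimeseries(cfg)
  expect_identical(trialTraces(t2), trialTraces(trial))
})
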