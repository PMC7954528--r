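# Complex F-ratio, permutation null, and the supporting statistics.

test_that("F-ratio reproduces hand-evaluated cases", {
  # one cluster holding everything: z_k0 = z_0, F = 1 exactly
  one <- complexFRatio(list(c(1 + 2i, 3 - 1i, 0.5 + 0i)))
  expect_identical(one@f, 1)
  # clusters {1, i} and {-1, -i}: ss_total 4, ss_within 2, F = 2
  two <- complexFRatio(list(c(1 + 0i, 0 + 1i), c(-1 + 0i, 0 - 1i)))
  expect_equal(two@ssTotal, 4)
  expect_equal(two@ssWithin, 2)
  expect_equal(two@f, 2)
  # symmetric +/-v pairs around a common centre: all centroids coincide
  v <- c(0.3 + 0.1i, -0.2 + 0.4i, 0.05 - 0.25i)
  cl <- lapply(v, function(vv) c(0.1 + 0.2i + vv, 0.1 + 0.2i - vv))
  expect_equal(complexFRatio(cl)@f, 1, tolerance = 1e-9)
})

test_that("sum of squares decomposes and F is rotation/translation invariant", {
  set.seed(10)
  for (rep in 1:100) {
    k <- sample(2:5, 1)
    cl <- lapply(seq_len(k), function(i)
      complex(real = rnorm(sample(2:6, 1)), imaginary = rnorm(1)))
    r <- complexFRatio(cl)
    expect_lt(abs(r@ssTotal - (r@ssWithin + r@ssBetween)) /
                max(r@ssTotal, 1e-12), 1e-9)
    expect_gte(r@f, 1 - 1e-9)
    expect_equal(r@f, oracleFRatio(cl), tolerance = 1e-12)
    rot <- exp(1i * runif(1, 0, 2 * pi))
    shift <- complex(real = rnorm(1), imaginary = rnorm(1))
    r2 <- complexFRatio(lapply(cl, function(z) rot * z + shift))
    expect_equal(r2@f, r@f, tolerance = 1e-9)
  }
})

test_that("degenerate F-ratio inputs are flagged, not mangled", {
  allEqual <- complexFRatio(list(c(1 + 1i, 1 + 1i), c(1 + 1i, 1 + 1i)))
  expect_identical(allEqual@f, 1)
  expect_identical(allEqual@degenerate, "zero_total")
  zeroWithin <- complexFRatio(list(c(1 + 0i, 1 + 0i), c(-1 + 0i, -1 + 0i)))
  expect_identical(zeroWithin@f, Inf)
  expect_identical(zeroWithin@degenerate, "zero_within")
  expect_error(complexFRatio(list(1 + 0i, 2 + 0i)), "two or more")
})

test_that("permutation p follows (m+1)/(N+1) and detects planted grouping", {
  z <- setNames(c(1 + 0i, 1 + 0.01i, 0.99 + 0i,
                  -1 + 0i, -1 - 0.01i, -0.99 + 0.01i,
                  0 + 1i, 0.01 + 1i, 0 + 0.99i), paste0("P", 1:9))
  clusters <- list(c("P1", "P2", "P3"), c("P4", "P5", "P6"),
                   c("P7", "P8", "P9"))
  r <- permutationP(clusters, z, nShuffles = 500, seed = 4)
  expect_gte(r@pHat, 1 / 501)
  expect_lte(r@pHat, 1)
  expect_equal(r@pHat, (r@m + 1) / (501))
  expect_lt(r@pHat, 0.05)
  # reproducible given the seed
  r2 <- permutationP(clusters, z, nShuffles = 500, seed = 4)
  expect_identical(r2@pHat, r@pHat)
  # missing partner values are reported
  expect_error(permutationP(list(c("P1", "PX")), z), "PX")

  # strongly grouped coherences from the generator: p < 0.05 in >= 95% of
  # 20 seeds when clusters follow the true functional groups
  hits <- vapply(1:20, function(s) {
    cfg <- synthConfig(seed = s, nPartners = 24, nFunctionalGroups = 3)
    z <- synthCoherence(cfg)
    g <- attr(z, "groups")
    clusters <- split(names(z), g[names(z)])
    permutationP(clusters, z, nShuffles = 200, seed = s)@pHat < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("proximity weight is the sum of inverse soma distances", {
  expect_equal(proximityWeight(c(10, 40)), 0.125)
  expect_equal(proximityWeight(100), 0.01)
  set.seed(2)
  d <- runif(20, 1, 500)
  expect_equal(proximityWeight(d), sum(1 / d), tolerance = 1e-12)
  expect_error(proximityWeight(c(10, 0)), "floor")
})

test_that("partner profiles aggregate counts, weights, and matches", {
  sk <- chainSkeleton(c(10, 30, 60))
  tab <- SynapseTable(data.frame(
    synapse_id = paste0("s", 1:5),
    attach_node = c(2, 3, 3, 4, 2),
    partner_id = c("A", "A", "B", "B", "C")))
  coh <- data.frame(cell_id = c("A", "B"), magnitude = c(0.5, 0.8),
                    re = c(0.5, 0.8), im = c(0, 0))
  prof <- buildPartnerProfiles(sk, tab, coh)
  expect_equal(prof$synapse_count[prof$partner_id == "A"], 2)
  expect_equal(prof$proximity_weight[prof$partner_id == "A"],
               1 / 10 + 1 / 40)
  expect_equal(prof$proximity_weight[prof$partner_id == "B"],
               1 / 40 + 1 / 100)
  expect_false(prof$vsd_matched[prof$partner_id == "C"])
})

test_that("count-coherence correlation matches the textbook formula", {
  prof <- data.frame(partner_id = c("A", "B", "C"),
                     synapse_count = c(2, 4, 6),
                     proximity_weight = c(0.1, 0.2, 0.3),
                     magnitude = c(0.1, 0.2, 0.3), vsd_matched = TRUE)
  expect_equal(partnerCoherenceCorrelation(prof)$r, 1, tolerance = 1e-12)
  prof$magnitude <- 0.5
  expect_error(partnerCoherenceCorrelation(prof), "zero variance")

  set.seed(8)
  prof <- data.frame(partner_id = paste0("P", 1:12),
                     synapse_count = sample(2:9, 12, replace = TRUE),
                     proximity_weight = runif(12),
                     magnitude = runif(12), vsd_matched = TRUE)
  got <- partnerCoherenceCorrelation(prof, "proximity_weight")
  x <- prof$proximity_weight; y <- prof$magnitude
  rOracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tOracle <- rOracle * sqrt(10 / (1 - rOracle^2))
  expect_equal(got$r, rOracle, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(tOracle), df = 10), tolerance = 1e-12)
})

test_that("across-trial t-test matches its closed form", {
  expect_equal(trialsTTest(c(0, 0, 0))[c("t", "p")], list(t = 0, p = 1))
  expect_equal(trialsTTest(c(0.2, -0.2))$t, 0)
  r <- c(0.1, 0.2, 0.3, 0.4)
  got <- trialsTTest(r)
  expect_equal(got$t, mean(r) / (sd(r) / 2), tolerance = 1e-12)
  oracle <- t.test(r)
  expect_equal(got$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(got$p, oracle$p.value, tolerance = 1e-12)
  const <- trialsTTest(c(0.3, 0.3))
  expect_true(const$degenerate)
  expect_identical(const$t, Inf)
})

test_that("cyclic greedy behavior assignment works the hand example", {
  m <- rbind(c1 = c(0.9, 0.5, 0.1),
             c2 = c(0.8, 0.7, 0.2),
             c3 = c(0.3, 0.4, 0.6))
  colnames(m) <- c("S", "C", "L")
  got <- assignBehaviors(m)
  expect_equal(got$assignment, c(c1 = "S", c2 = "C", c3 = "L"))
  expect_equal(got$log$cell, c("c1", "c2", "c3"))

  # one cell: its argmax behavior
  one <- assignBehaviors(m[1, , drop = FALSE])
  expect_equal(unname(one$assignment), "S")

  # counts differ by at most one; relabeling cells permutes the assignment
  set.seed(5)
  mm <- matrix(runif(21), 7, 3,
               dimnames = list(paste0("n", 1:7), c("S", "C", "L")))
  a <- assignBehaviors(mm)
  expect_lte(diff(range(table(factor(a$assignment,
                                     levels = colnames(mm))))), 1)
  perm <- sample(7)
  b <- assignBehaviors(mm[perm, ])
  expect_equal(b$assignment[names(a$assignment)], a$assignment)
})

test_that("spatial group comparison behaves at the extremes", {
  x <- c(1, 5, 9, 14, 20)
  same <- spatialGroupComparison(list(excitatory = x, unknown = x),
                                 nPerm = 200, seed = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  far <- spatialGroupComparison(
    list(excitatory = rep(10, 20) + runif(20), unknown = rep(200, 20)),
    nPerm = 2000, seed = 1)
  expect_lt(far$p, 0.01)
  expect_equal(far$statistic, 1)

  expect_warning(
    spatialGroupComparison(list(excitatory = 1, unknown = x),
                           nPerm = 50, seed = 1),
    "skipped")
})
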