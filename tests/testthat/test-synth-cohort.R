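test_that("base covariance is SPD, unit-diagonal, density-scaled and seeded", {
  expect_identical(makeBaseCovariance(10, 0, seed = 1), diag(10))
  S <- makeBaseCovariance(20, 0.4, seed = 3)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 20))
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_identical(S, makeBaseCovariance(20, 0.4, seed = 3))
  # stronger shared structure with larger density
  weak <- makeBaseCovariance(20, 0.1, seed = 3)
  off <- function(M) mean(abs(M[upper.tri(M)]))
  expect_gt(off(S), off(weak))
})

test_that("plantEffects shifts exactly the planted correlations", {
  S <- makeBaseCovariance(15, 0.2, seed = 11)
  expect_identical(plantEffects(S, NULL), S)
  expect_identical(plantEffects(S, data.frame()[0, ]), S)

  pe <- data.frame(i = 2, j = 9, delta = -0.3)
  P <- plantEffects(S, pe)
  expect_equal(P[2, 9], S[2, 9] - 0.3, tolerance = 0.05)
  expect_equal(P, t(P))
  expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), 0)
  # non-planted entries move at most by the repair perturbation
  mask <- upper.tri(S)
  mask[2, 9] <- FALSE
  expect_lt(max(abs((P - S)[mask])), 0.05)
})

test_that("plantEffects rejects shifts beyond the correlation bound", {
  S <- diag(5)
  expect_error(plantEffects(S, data.frame(i = 1, j = 2, delta = 1.5)),
               "0.99")
  expect_error(plantEffects(matrix(0, 4, 4), data.frame(i = 1, j = 2,
                                                        delta = 0.1)),
               "positive definite")
})

test_that("simulated cohorts have the configured shape and are seeded", {
  cfg <- simConfig(nPatients = 5, nControls = 5, nRegions = 10,
                   nTimepoints = 100, seed = 21)
  co <- simulateCohort(cfg)
  expect_s4_class(co, "FcCohort")
  expect_equal(nSubjects(co), 10)
  expect_equal(dim(subjectSeries(co, 1)), c(100, 10))
  expect_equal(sum(groupLabels(co) == -1), 5)
  co2 <- simulateCohort(cfg)
  expect_identical(co@series, co2@series)
  # a different seed changes the draws
  cfg2 <- simConfig(nPatients = 5, nControls = 5, nRegions = 10,
                    nTimepoints = 100, seed = 22)
  expect_false(identical(simulateCohort(cfg2)@series, co@series))
})

test_that("planted effects are realized in long-series empirical correlations", {
  pe <- data.frame(i = 1, j = 2, delta = -0.4)
  cfg <- simConfig(nPatients = 6, nControls = 6, nRegions = 6,
                   nTimepoints = 5000, plantedEdges = pe,
                   driftAmplitude = 0, noiseSd = 0, seed = 5)
  co <- simulateCohort(cfg)
  r12 <- vapply(seq_len(nSubjects(co)),
                function(s) cor(subjectSeries(co, s))[1, 2], numeric(1))
  g <- groupLabels(co)
  diff <- mean(r12[g == -1]) - mean(r12[g == 1])
  expect_equal(diff, -0.4, tolerance = 0.05)
})

test_that("null cohorts carry no group difference on any edge", {
  cfg <- simConfig(nPatients = 6, nControls = 6, nRegions = 6,
                   nTimepoints = 5000,
                   plantedEdges = data.frame(i = 1, j = 2, delta = -0.5),
                   driftAmplitude = 0, noiseSd = 0, seed = 9)
  co <- simulateNullCohort(cfg)  # planted edges must be ignored
  r12 <- vapply(seq_len(nSubjects(co)),
                function(s) cor(subjectSeries(co, s))[1, 2], numeric(1))
  g <- groupLabels(co)
  expect_lt(abs(mean(r12[g == -1]) - mean(r12[g == 1])), 0.05)
  expect_equal(dim(subjectSeries(co, 1)), c(5000, 6))
})

test_that("planted-edge sign is recovered in group mean correlations at T=1000", {
  # effect-realization property at near-study scale
  map <- edgeIndexMap(20)
  pe <- map[c(1, 25, 60, 100, 150), c("i", "j")]
  pe$delta <- c(-0.4, -0.4, -0.4, 0.4, -0.4)
  cfg <- simConfig(nPatients = 22, nControls = 22, nRegions = 20,
                   nTimepoints = 1000, plantedEdges = pe, seed = 13)
  co <- simulateCohort(cfg)
  g <- groupLabels(co)
  for (e in seq_len(nrow(pe))) {
    r <- vapply(seq_len(nSubjects(co)),
                function(s) cor(subjectSeries(co, s))[pe$i[e], pe$j[e]],
                numeric(1))
    expect_equal(sign(mean(r[g == -1]) - mean(r[g == 1])),
                 sign(pe$delta[e]))
  }
})

test_that("config validation rejects malformed planted edges", {
  expect_error(simConfig(plantedEdges = data.frame(i = 3, j = 2, delta = 0.1)),
               "i < j")
  expect_error(simConfig(nRegions = 5,
                         plantedEdges = data.frame(i = 1, j = 9, delta = 0.1)),
               "1..nRegions")
  expect_error(simConfig(plantedEdges = data.frame(i = c(1, 1), j = c(2, 2),
                                                   delta = c(0.1, 0.2))),
               "distinct")
  expect_error(simConfig(nRegions = 2), "nRegions")
  expect_error(simConfig(trSeconds = 2, bandLimit = c(0.01, 0.3)))
})
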