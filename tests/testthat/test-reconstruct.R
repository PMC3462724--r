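test_that("fold feature weights embed U w at the selected positions", {
  set.seed(71)
  # identity basis: Lambda equals w at the selected positions
  k <- 4
  U <- diag(k)
  p <- new("FcPca", center = rep(0, k), rotation = U,
           eigenvalues = rep(1, k), d = 4L)
  s <- new("FcSvm", w = c(0.5, -1, 2, 0), b = 0, cost = 1)
  sel <- c(2L, 5L, 7L, 9L)
  lam <- foldFeatureWeights(p, s, sel, D = 10)
  expect_equal(lam[sel], s@w)
  expect_identical(lam[-sel], rep(0, 6))

  # random case: the embedded weights reproduce the decision score
  kk <- 6; d <- 3
  U2 <- randomOrthonormal(kk, d)
  xbar <- rnorm(kk)
  p2 <- new("FcPca", center = xbar, rotation = U2,
            eigenvalues = sort(abs(rnorm(kk)), decreasing = TRUE), d = 3L)
  s2 <- new("FcSvm", w = rnorm(d), b = rnorm(1), cost = 1)
  sel2 <- sort(sample(20, kk))
  lam2 <- foldFeatureWeights(p2, s2, sel2, D = 20)
  for (r in 1:100) {
    x <- rnorm(20)
    expect_equal(sum(lam2[sel2] * (x[sel2] - xbar)) - s2@b,
                 decisionScore(p2, s2, x[sel2])$score, tolerance = 1e-10)
  }
  expect_error(foldFeatureWeights(p2, s2, sel2[-1], 20), "selection length")
})

test_that("averaging takes absolute values before the mean over folds", {
  a <- c(0, 0.6, 0)
  expect_equal(averageFoldWeights(list(a)), abs(a))
  expect_equal(averageFoldWeights(list(a, -a)), abs(a))
  # feature selected in 1 of N folds with |lambda| = v contributes v/N
  v <- 0.9
  folds <- list(c(v, 0), c(0, 0), c(0, 0))
  expect_equal(averageFoldWeights(folds), c(v / 3, 0))
  expect_error(averageFoldWeights(list()), "at least one fold")
})

test_that("region weights are the half-assignment and conserve total weight", {
  # edges (A,B) = 0.4 and (A,C) = 0.2 on a 3-region graph
  lam <- c(0.4, 0.2, 0)  # order (1,2), (1,3), (2,3)
  rw <- regionWeights(lam, 3, c("A", "B", "C"))
  expect_equal(rw$weight, c(0.3, 0.2, 0.1))
  expect_equal(rw$rank, c(1, 2, 3))
  # uniform weights on the complete graph give equal region weights
  R <- 6
  lamU <- rep(1, R * (R - 1) / 2)
  # each region touches R-1 unit edges, half-assigned: (R-1)/2 each
  expect_equal(unique(regionWeights(lamU, R)$weight), (R - 1) / 2)
  # conservation on random instances
  set.seed(72)
  for (rep in 1:100) {
    R2 <- sample(4:12, 1)
    lam2 <- abs(rnorm(R2 * (R2 - 1) / 2))
    expect_equal(sum(regionWeights(lam2, R2)$weight), sum(lam2),
                 tolerance = 1e-9)
  }
  expect_error(regionWeights(c(1, 2), 4), "R\\(R-1\\)/2")
})

test_that("cv feature weights are zero outside the union set and nonnegative", {
  co <- makeTestCohort(nPerGroup = 5, nRegions = 8, nTimepoints = 100)
  ds <- buildDataset(co)
  cv <- loocv(ds, k = 6, d = 2, C = 0.5)
  lam <- featureWeights(cv)
  expect_length(lam, 28)
  expect_true(all(lam >= 0))
  expect_true(all(lam[setdiff(1:28, unionFeatures(cv))] == 0))
  expect_true(all(lam[consensusFeatures(cv)] > 0))
})

test_that("edge report restricts, sorts and signs directions correctly", {
  co <- makeTestCohort(nPerGroup = 8, nRegions = 10, nTimepoints = 150,
                       delta = -0.5, nEdges = 4)
  ds <- buildDataset(co)
  cv <- loocv(ds, k = 8, d = 2, C = 0.5)
  lam <- featureWeights(cv)
  er <- edgeReport(ds, lam, consensusFeatures(cv))
  expect_setequal(er$k, consensusFeatures(cv))
  expect_true(all(diff(er$weight) <= 1e-15))
  expect_identical(er$direction, ifelse(er$tau > 0, "decreased", "increased"))
  # full-data tau in the report matches the ranking module
  rk <- rankFeatures(ds)
  expect_equal(er$tau, rk$tau[er$k], tolerance = 1e-12)
  # a planted decreased edge that reached the consensus reports "decreased"
  planted <- edgeIndex(1:4, c(2, 3, 4, 5), 10)[1:4]
  hit <- er[er$k %in% planted, ]
  if (nrow(hit) > 0) expect_true(all(hit$direction == "decreased"))
  expect_error(edgeReport(ds, lam, integer(0)), "empty feature set")
})

test_that("the hub region with most planted weight ranks first", {
  # region 1 participates in far more planted edges than any other
  pe <- data.frame(i = rep(1, 6), j = 2:7, delta = -0.5)
  cfg <- simConfig(nPatients = 10, nControls = 10, nRegions = 12,
                   nTimepoints = 150, plantedEdges = pe, seed = 73)
  ds <- buildDataset(simulateCohort(cfg))
  cv <- loocv(ds, k = 10, d = 3, C = 0.5)
  rw <- regionWeights(featureWeights(cv), 12, regionLabels(ds))
  expect_equal(rw$rank[1], 1)
})
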