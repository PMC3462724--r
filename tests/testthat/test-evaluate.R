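test_that("metrics reproduce the canonical worked example and edge cases", {
  # 22 controls all correct, 19 of 22 patients correct
  m <- classMetrics(TP = 19, TN = 22, FP = 0, FN = 3)
  expect_equal(unname(m["GR"]), 41 / 44)
  expect_equal(unname(m["SS"]), 19 / 22)
  expect_equal(unname(m["SC"]), 1)
  expect_equal(unname(classMetrics(10, 10, 0, 0)["GR"]), 1)
  expect_equal(unname(classMetrics(0, 0, 10, 10)["GR"]), 0)
  # undefined denominators are NA, not 0
  expect_true(is.na(classMetrics(0, 5, 0, 0)["SS"]))
  expect_error(classMetrics(0, 0, 0, 0), "positive")
  expect_error(classMetrics(-1, 2, 0, 0))
})

test_that("loocv produces one fold per subject with coherent aggregates", {
  co <- makeTestCohort(nPerGroup = 6, nRegions = 10, nTimepoints = 100)
  ds <- buildDataset(co)
  cv <- loocv(ds, k = 8, d = 2, C = 0.5)
  expect_length(cvFolds(cv), 12)
  cnt <- cvCounts(cv)
  expect_equal(sum(cnt), 12)
  expect_equal(unname(cvMetrics(cv)["GR"] * 12),
               unname(cnt["TP"] + cnt["TN"]))
  # every fold selected exactly k features; consensus within every fold
  sels <- lapply(cvFolds(cv), `[[`, "selection")
  expect_true(all(lengths(sels) == 8))
  for (s in sels) {
    expect_true(all(consensusFeatures(cv) %in% s))
    expect_true(all(s %in% unionFeatures(cv)))
  }
  expect_lte(length(consensusFeatures(cv)), 8)
  expect_gte(length(unionFeatures(cv)), 8)
  expect_error(loocv(ds, k = 0, d = 2, C = 0.5), "k must lie")
})

test_that("fold models depend only on the training subjects", {
  co <- makeTestCohort(nPerGroup = 5, nRegions = 8, nTimepoints = 80)
  ds <- buildDataset(co)
  cv <- loocv(ds, k = 6, d = 2, C = 0.5)
  X <- featureMatrix(ds)
  y <- groupLabels(ds)
  f <- 3
  # corrupt the held-out subject's features and label arbitrarily
  X2 <- X
  X2[f, ] <- rev(X2[f, ]) * 10 + 3
  y2 <- y
  y2[f] <- -y2[f]
  res2 <- restfc:::.loocvCore(X2, y2, 6, 2, 0.5)
  expect_identical(res2$folds[[f]]$selection, cvFolds(cv)[[f]]$selection)
  expect_equal(res2$folds[[f]]$pca@rotation, cvFolds(cv)[[f]]$pca@rotation)
  expect_equal(res2$folds[[f]]$svm@w, cvFolds(cv)[[f]]$svm@w)
  expect_equal(res2$folds[[f]]$svm@b, cvFolds(cv)[[f]]$svm@b)
})

test_that("a strongly planted cohort is classified nearly perfectly", {
  map <- edgeIndexMap(30)
  set.seed(61)
  picks <- sort(sample(nrow(map), 15))
  pe <- map[picks, c("i", "j")]
  pe$delta <- -0.5
  cfg <- simConfig(nPatients = 11, nControls = 11, nRegions = 30,
                   nTimepoints = 175, plantedEdges = pe, seed = 62)
  ds <- buildDataset(simulateCohort(cfg))
  cv <- loocv(ds, k = 30, d = 4, C = 0.5)
  expect_gte(unname(cvMetrics(cv)["GR"]), 0.9)
})

test_that("a null cohort classifies within the chance band", {
  cfg <- simConfig(nPatients = 10, nControls = 10, nRegions = 15,
                   nTimepoints = 120, seed = 63)
  ds <- buildDataset(simulateNullCohort(cfg))
  gr <- unname(cvMetrics(loocv(ds, k = 15, d = 3, C = 0.5))["GR"])
  expect_gte(gr, 0.25 - 1e-12)
  expect_lte(gr, 0.75 + 1e-12)
})

test_that("feature-number sweep reports the GR curve and the smallest best k", {
  co <- makeTestCohort(nPerGroup = 5, nRegions = 8, nTimepoints = 100)
  ds <- buildDataset(co)
  sw <- sweepFeatureNumber(ds, kGrid = c(4, 8, 12), d = 2, C = 0.5)
  expect_equal(sw$k, c(4, 8, 12))
  expect_true(all(sw$GR >= 0 & sw$GR <= 1))
  best <- attr(sw, "bestK")
  expect_equal(best, sw$k[which.max(sw$GR)])  # which.max takes the first max
})

test_that("grid selection is exhaustive with deterministic tie-breaking", {
  co <- makeTestCohort(nPerGroup = 5, nRegions = 8, nTimepoints = 100)
  ds <- buildDataset(co)
  gs <- gridSelect(ds, kGrid = c(4, 8), dGrid = c(2, 3), cGrid = c(0.1, 1))
  expect_equal(nrow(gs$table), 8)
  expect_equal(gs$best$GR, max(gs$table$GR))
  # the reported best is the first (smallest k, then d, then C) maximum
  mx <- gs$table[gs$table$GR == max(gs$table$GR), ]
  expect_equal(unlist(gs$best[c("k", "d", "C")]),
               unlist(mx[1, c("k", "d", "C")]))
  # singleton grids return that point
  gs1 <- gridSelect(ds, kGrid = 8, dGrid = 2, cGrid = 0.5)
  expect_equal(unlist(gs1$best[c("k", "d", "C")]), c(k = 8, d = 2, C = 0.5))
})

test_that("consensus and union obey set algebra on degenerate selections", {
  # identical selections across folds: intersection equals union
  co <- makeTestCohort(nPerGroup = 5, nRegions = 8, nTimepoints = 100,
                       delta = -0.6, nEdges = 2)
  ds <- buildDataset(co)
  cv <- loocv(ds, k = nrow(edgeIndexMap(8)), d = 2, C = 0.5)  # k = D
  expect_identical(consensusFeatures(cv), unionFeatures(cv))
  expect_length(consensusFeatures(cv), 28)
})

test_that("the permutation test is seeded, smoothed and self-consistent", {
  co <- makeTestCohort(nPerGroup = 5, nRegions = 8, nTimepoints = 100)
  ds <- buildDataset(co)
  pt1 <- permutationTest(ds, k = 6, d = 2, C = 0.5, nPerm = 10, seed = 7)
  pt2 <- permutationTest(ds, k = 6, d = 2, C = 0.5, nPerm = 10, seed = 7)
  expect_identical(permGr(pt1), permGr(pt2))
  expect_identical(permPValue(pt1), permPValue(pt2))
  expect_gte(permPValue(pt1), 1 / 11)
  expect_lte(permPValue(pt1), 1)
  # the identity permutation reproduces GR0 exactly: re-running the whole
  # LOOCV with unpermuted labels is deterministic
  gr0 <- unname(cvMetrics(loocv(ds, 6, 2, 0.5))["GR"])
  grId <- restfc:::classMetricsFromCore(
    restfc:::.loocvCore(featureMatrix(ds), groupLabels(ds), 6, 2, 0.5,
                        keepModels = FALSE))
  expect_identical(unname(grId), gr0)
  expect_identical(pt1@gr0, gr0)
})
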