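# Leave-one-out cross-validation with training-only feature selection,
# hyperparameter sweeps, consensus/union feature sets and the
# label-permutation test.

#' Classification performance metrics
#'
#' Generalization rate, sensitivity and specificity from confusion counts.
#' The positive class for these metrics is the patient group: TP = patients
#' correctly predicted, TN = controls correctly predicted, FP = controls
#' predicted as patients, FN = patients predicted as controls. A metric
#' whose denominator is zero is reported as `NA`, not 0.
#'
#' @param TP,TN,FP,FN nonnegative confusion counts, not all zero
#' @return named numeric vector: `GR = (TP+TN)/N`, `SS = TP/(TP+FN)`,
#'   `SC = TN/(TN+FP)`
#' @export
classMetrics <- function(TP, TN, FP, FN) {
  TP <- unname(TP); TN <- unname(TN); FP <- unname(FP); FN <- unname(FN)
  counts <- c(TP, TN, FP, FN)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  N <- sum(counts)
  if (N == 0) stop("at least one count must be positive")
  c(GR = (TP + TN) / N,
    SS = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    SC = if (TN + FP > 0) TN / (TN + FP) else NA_real_)
}

# Core LOOCV on plain matrices; shared by loocv(), the sweeps and the
# permutation test. Feature ranking, selection, PCA and SVM are fit on the
# N-1 training rows only; the held-out row is scored afterwards.
.loocvCore <- function(X, y, k, d, C, keepModels = TRUE) {
  N <- nrow(X)
  D <- ncol(X)
  if (N < 4) stop("LOOCV requires at least 4 subjects")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (k < 1 || k > D) stop(sprintf("k must lie in [1, %d]", D))
  dEff <- min(d, k, N - 2)
  if (dEff < d)
    warning(sprintf("d = %d exceeds the fold training rank; using d = %d",
                    d, dEff))
  folds <- vector("list", N)
  pred <- integer(N)
  scores <- numeric(N)
  for (f in seq_len(N)) {
    tr <- setdiff(seq_len(N), f)
    ytr <- y[tr]
    if (length(unique(ytr)) < 2)
      stop("a fold's training set lost one class entirely")
    rk <- rankFeatures(X[tr, , drop = FALSE], ytr)
    sel <- selectTopK(rk, k)
    pca <- fitPca(X[tr, sel, drop = FALSE], dEff)
    proj <- projectPca(pca, X[tr, sel, drop = FALSE])
    svm <- fitSvm(proj, ytr, C)
    ds <- decisionScore(pca, svm, X[f, sel])
    pred[f] <- ds$label
    scores[f] <- ds$score
    lambda <- numeric(D)
    lambda[sel] <- drop(pca@rotation %*% svm@w)
    folds[[f]] <- list(
      heldOut = f,
      selection = sel,
      pca = if (keepModels) pca else NULL,
      svm = if (keepModels) svm else NULL,
      lambda = lambda,
      score = ds$score,
      predicted = ds$label,
      truth = y[f]
    )
  }
  TP <- sum(y == -1 & pred == -1)
  TN <- sum(y ==  1 & pred ==  1)
  FP <- sum(y ==  1 & pred == -1)
  FN <- sum(y == -1 & pred ==  1)
  list(folds = folds, pred = pred, scores = scores,
       counts = c(TP = TP, TN = TN, FP = FP, FN = FN), d = dEff)
}

#' Leave-one-out cross-validated classification
#'
#' For each subject in turn: rank all edge features by cross-group Kendall
#' tau on the remaining subjects, select the top `k`, fit the PCA subspace
#' (`d` components) and linear SVM (cost `C`) on those subjects, and score
#' the held-out subject. Feature selection is therefore performed only on
#' training data in every fold.
#'
#' @param dataset an [FcDataset-class]
#' @param k number of top-ranked features per fold
#' @param d PCA dimensionality
#' @param C SVM cost parameter
#' @return an [FcCv-class]
#' @export
loocv <- function(dataset, k, d, C) {
  stopifnot(is(dataset, "FcDataset"))
  X <- featureMatrix(dataset)
  y <- groupLabels(dataset)
  res <- .loocvCore(X, y, k, d, C)
  sels <- lapply(res$folds, `[[`, "selection")
  cons <- sort(Reduce(intersect, sels))
  uni <- sort(Reduce(union, sels))
  cm <- classMetrics(res$counts["TP"], res$counts["TN"],
                     res$counts["FP"], res$counts["FN"])
  new("FcCv",
    folds = res$folds,
    counts = as.integer(res$counts) |> stats::setNames(names(res$counts)),
    metrics = cm,
    consensus = as.integer(cons),
    union = as.integer(uni),
    params = list(k = as.integer(k), d = as.integer(res$d), C = C),
    predictions = data.frame(
      subject = subjectIds(dataset),
      truth = y,
      predicted = res$pred,
      score = res$scores,
      stringsAsFactors = FALSE
    )
  )
}

#' Sweep the number of selected features
#'
#' Runs one LOOCV per value of `k` and reports the GR curve. The best `k`
#' (ties broken toward the smallest) is attached as attribute `"bestK"`.
#'
#' @param dataset an [FcDataset-class]
#' @param kGrid feature numbers to evaluate
#' @param d,C fixed PCA dimension and SVM cost
#' @return data.frame with columns `k` and `GR`
#' @export
sweepFeatureNumber <- function(dataset, kGrid = seq(50, 800, by = 50),
                               d = 6, C = 0.255) {
  kGrid <- sort(unique(as.integer(kGrid)))
  gr <- vapply(kGrid, function(k) cvMetrics(loocv(dataset, k, d, C))["GR"],
               numeric(1))
  out <- data.frame(k = kGrid, GR = unname(gr))
  attr(out, "bestK") <- kGrid[which.max(gr)]
  out
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates LOOCV GR over the full (k, d, C) grid and returns the best
#' combination, breaking ties toward smallest `k`, then `d`, then `C`. The
#' default grids span feature numbers 50-800, PCA dimensions 2-20 and SVM
#' costs 0.005 to 1.955 in steps of 0.05. Note that selecting
#' hyperparameters by the same LOOCV that reports performance is
#' optimistically biased; see the package vignette.
#'
#' @param dataset an [FcDataset-class]
#' @param kGrid,dGrid,cGrid grids to search
#' @return list with `best` (k, d, C, GR) and `table` (all grid points)
#' @export
gridSelect <- function(dataset, kGrid = seq(50, 800, by = 50),
                       dGrid = 2:20, cGrid = seq(0.005, 1.955, by = 0.05)) {
  grid <- expand.grid(C = cGrid, d = dGrid, k = kGrid)[, c("k", "d", "C")]
  grid <- grid[order(grid$k, grid$d, grid$C), , drop = FALSE]
  grid$GR <- vapply(seq_len(nrow(grid)), function(r)
    cvMetrics(loocv(dataset, grid$k[r], grid$d[r], grid$C[r]))["GR"],
    numeric(1))
  best <- grid[which.max(grid$GR), ]  # first max: smallest k, then d, then C
  list(best = as.list(best), table = grid)
}

#' Label-permutation test of the LOOCV generalization rate
#'
#' Permutes the full label vector `nPerm` times; for each permutation the
#' entire LOOCV - including per-fold feature selection, PCA and SVM - is
#' re-run to obtain a permuted GR*. The p-value is the add-one smoothed
#' exceedance probability `(1 + #\{GR* >= GR0\}) / (nPerm + 1)`.
#'
#' @param dataset an [FcDataset-class]
#' @param k,d,C classifier hyperparameters
#' @param nPerm number of label permutations (>= 1)
#' @param seed integer seed for the permutation sequence
#' @return an [FcPermutation-class]
#' @export
permutationTest <- function(dataset, k, d, C, nPerm = 1000, seed = 1L) {
  stopifnot(is(dataset, "FcDataset"), nPerm >= 1)
  X <- featureMatrix(dataset)
  y <- groupLabels(dataset)
  gr0 <- unname(classMetricsFromCore(.loocvCore(X, y, k, d, C,
                                                keepModels = FALSE)))
  grPerm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nPerm), function(p) {
      yp <- sample(y)
      unname(classMetricsFromCore(
        .loocvCore(X, yp, k, d, C, keepModels = FALSE)))
    }, numeric(1))
  })
  p <- (1 + sum(grPerm >= gr0)) / (nPerm + 1)
  new("FcPermutation", gr0 = gr0, grPerm = grPerm,
      nPerm = as.integer(nPerm), p = p, seed = as.integer(seed))
}

# GR from a .loocvCore result.
classMetricsFromCore <- function(res) {
  (res$counts["TP"] + res$counts["TN"]) / sum(res$counts)
}
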