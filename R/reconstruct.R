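# Back-projection of classifier weights. Within a fold, the decision score
# is Y = w' U'(x - xbar) - b = (Uw)'(x - xbar) - b, so Lambda = Uw assigns
# one weight per selected edge feature; |lambda_j| measures that feature's
# contribution to the discriminative score. Fold vectors are embedded into
# the full D-length feature space (zeros at unselected edges) and the
# absolute values averaged over folds. Region weights then assign half of
# each edge weight to each endpoint.

#' Per-fold feature weights in the full edge space
#'
#' Computes `Lambda = U w` for one fold and embeds it at the fold's selected
#' feature positions; all other positions are exactly zero.
#'
#' @param pca the fold's [FcPca-class]
#' @param svm the fold's [FcSvm-class]
#' @param selection integer indices of the fold's selected features
#' @param D total number of edge features
#' @return numeric vector of length D
#' @export
foldFeatureWeights <- function(pca, svm, selection, D) {
  stopifnot(is(pca, "FcPca"), is(svm, "FcSvm"))
  if (length(svm@w) != ncol(pca@rotation))
    stop("SVM dimension does not match the PCA subspace")
  if (nrow(pca@rotation) != length(selection))
    stop("selection length does not match the PCA feature dimension")
  if (max(selection) > D) stop("selection indices exceed D")
  lambda <- numeric(D)
  lambda[selection] <- drop(pca@rotation %*% svm@w)
  lambda
}

#' Average absolute feature weights over folds
#'
#' Elementwise mean of `|Lambda_i|` over all folds:
#' `Lambda_bar = (|Lambda_1| + ... + |Lambda_N|) / N`.
#'
#' @param foldVectors list of length-D numeric vectors, or a D x N matrix
#' @return nonnegative numeric vector of length D
#' @export
averageFoldWeights <- function(foldVectors) {
  if (is.list(foldVectors)) {
    if (length(foldVectors) == 0) stop("at least one fold is required")
    foldVectors <- do.call(cbind, foldVectors)
  }
  stopifnot(is.matrix(foldVectors), ncol(foldVectors) >= 1)
  rowMeans(abs(foldVectors))
}

#' @rdname restfc-generics
#' @details `featureWeights` on an [FcCv-class] returns the fold-averaged
#'   absolute feature-weight vector (length D).
#' @export
setMethod("featureWeights", "FcCv", function(x, ...) {
  averageFoldWeights(lapply(x@folds, `[[`, "lambda"))
})

#' Discriminative region weights
#'
#' Half of each edge's averaged feature weight is assigned to each of its
#' two endpoint regions and summed per region. The total region weight
#' therefore equals the total feature weight (conservation).
#'
#' @param lambdaBar length-D nonnegative feature-weight vector
#' @param nRegions number of regions R
#' @param regionLabels region names (length R)
#' @return data.frame with columns `region`, `weight`, `rank` (1 = largest),
#'   in region order
#' @export
regionWeights <- function(lambdaBar, nRegions, regionLabels = NULL) {
  map <- edgeIndexMap(nRegions)
  if (length(lambdaBar) != nrow(map))
    stop("lambdaBar length must equal R(R-1)/2")
  if (is.null(regionLabels))
    regionLabels <- sprintf("region_%03d", seq_len(nRegions))
  stopifnot(length(regionLabels) == nRegions)
  half <- lambdaBar / 2
  w <- as.numeric(
    rowsum(c(half, half), group = c(map$i, map$j),
           reorder = TRUE)
  )
  data.frame(
    region = regionLabels,
    weight = w,
    rank = rank(-w, ties.method = "min"),
    stringsAsFactors = FALSE
  )
}

#' Edge-level discriminative report
#'
#' For a chosen feature set (the cross-validation consensus set by
#' default), reports the two region names, the cross-group Kendall tau
#' recomputed on the full dataset, the averaged feature weight, and the
#' direction of the group difference: `"decreased"` (in patients) when
#' tau > 0, `"increased"` otherwise. Rows are sorted by weight, largest
#' first, ties by ascending edge index.
#'
#' @param dataset an [FcDataset-class]
#' @param lambdaBar length-D averaged feature-weight vector
#' @param features integer feature indices to report
#' @return data.frame: `k`, `region_a`, `region_b`, `tau`, `weight`,
#'   `direction`
#' @export
edgeReport <- function(dataset, lambdaBar, features) {
  stopifnot(is(dataset, "FcDataset"))
  map <- edgeMap(dataset)
  if (length(lambdaBar) != nrow(map))
    stop("lambdaBar length must equal the number of edge features")
  features <- sort(unique(as.integer(features)))
  if (length(features) == 0)
    stop("an empty feature set cannot be reported")
  tau <- .tauMatrix(featureMatrix(dataset)[, features, drop = FALSE],
                    groupLabels(dataset))
  out <- data.frame(
    k = features,
    region_a = map$region_a[features],
    region_b = map$region_b[features],
    tau = tau,
    weight = lambdaBar[features],
    direction = ifelse(tau > 0, "decreased", "increased"),
    stringsAsFactors = FALSE
  )
  out[order(-out$weight, out$k), , drop = FALSE]
}
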