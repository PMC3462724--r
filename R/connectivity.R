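# Edge-feature construction: Pearson correlation over regions, Fisher
# z-transform, and canonical upper-triangle vectorization.

#' Canonical edge index map
#'
#' The fixed bijection between edge index k and region pair (i, j), i < j,
#' ordered row-major by (i, j): (1,2), (1,3), ..., (1,R), (2,3), ... This
#' ordering is the serialization contract for feature vectors, fold-wise
#' feature selections and consensus sets.
#'
#' @param nRegions number of regions R (>= 2)
#' @return data.frame with columns `k`, `i`, `j`; D = R(R-1)/2 rows
#' @export
edgeIndexMap <- function(nRegions) {
  stopifnot(nRegions >= 2)
  i <- rep(seq_len(nRegions - 1), times = (nRegions - 1):1)
  j <- unlist(lapply(seq_len(nRegions - 1), function(a) (a + 1):nRegions))
  data.frame(k = seq_along(i), i = i, j = j)
}

#' Edge index of a region pair
#' @param i,j region indices with i < j (vectorized)
#' @param nRegions number of regions
#' @return edge index k in the canonical row-major order
#' @export
edgeIndex <- function(i, j, nRegions) {
  stopifnot(all(i < j), all(j <= nRegions), all(i >= 1))
  (i - 1) * (2 * nRegions - i) / 2 + (j - i)
}

#' Pearson correlation matrix of a regional time-series matrix
#'
#' @param series T x R numeric matrix, T >= 3
#' @param regionLabels optional region names used in error messages
#' @return symmetric R x R correlation matrix with unit diagonal
#' @export
correlationMatrix <- function(series, regionLabels = NULL) {
  series <- as.matrix(series)
  if (nrow(series) < 3) stop("correlation requires at least 3 timepoints")
  sds <- apply(series, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(regionLabels)) regionLabels[bad] else as.character(bad)
    stop("zero-variance region(s): ", paste(nm, collapse = ", "))
  }
  C <- stats::cor(series)
  dimnames(C) <- NULL
  C
}

#' Fisher z-transform of correlation values
#'
#' `z = arctanh(r)` with clipping at 1 - 1e-7 in absolute value, so that
#' numerically perfect correlations map to large finite values.
#'
#' @param r correlations in \[-1, 1\] (vectorized)
#' @return transformed values
#' @export
fisherZ <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Extracts the strict upper triangle in the canonical row-major edge order
#' of [edgeIndexMap()].
#'
#' @param mat square matrix
#' @param map optional precomputed edge index map (for repeated calls)
#' @return numeric vector of length R(R-1)/2
#' @export
vectorizeUpper <- function(mat, map = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (is.null(map)) map <- edgeIndexMap(nrow(mat))
  if (max(map$j) != nrow(mat))
    stop("edge map does not match matrix dimension")
  mat[cbind(map$i, map$j)]
}

#' Rebuild a symmetric matrix from an upper-triangle vector
#'
#' @param v vector of length R(R-1)/2 in canonical edge order
#' @param nRegions number of regions R
#' @param diag value placed on the diagonal (default 1)
#' @return symmetric R x R matrix
#' @export
devectorizeUpper <- function(v, nRegions, diag = 1) {
  D <- nRegions * (nRegions - 1) / 2
  if (length(v) != D)
    stop("vector length must equal R(R-1)/2")
  map <- edgeIndexMap(nRegions)
  M <- matrix(0, nRegions, nRegions)
  M[cbind(map$i, map$j)] <- v
  M[cbind(map$j, map$i)] <- v
  base::diag(M) <- diag
  M
}

#' Build the edge-feature dataset from a cohort
#'
#' Per subject: preprocess the series ([preprocessSeries()]), compute the
#' Pearson correlation matrix, Fisher z-transform, and vectorize the upper
#' triangle. With R = 90 regions each subject yields a 4005-dimensional
#' feature vector.
#'
#' @param cohort an [FcCohort-class]
#' @param detrend,band,order preprocessing settings, see [preprocessSeries()]
#' @param confounds optional named list of per-subject confound matrices
#' @return an [FcDataset-class] (features x subjects)
#' @export
buildDataset <- function(cohort, detrend = TRUE, band = c(0.01, 0.08),
                         confounds = NULL,
                         order = c("detrend", "bandpass", "regress")) {
  stopifnot(is(cohort, "FcCohort"))
  R <- nRegions(cohort)
  map <- edgeIndexMap(R)
  labels <- regionLabels(cohort)
  feats <- vapply(seq_len(nSubjects(cohort)), function(s) {
    cf <- if (!is.null(confounds)) confounds[[subjectIds(cohort)[s]]] else NULL
    X <- preprocessSeries(subjectSeries(cohort, s), trSeconds(cohort),
                          detrend = detrend, band = band, confounds = cf,
                          order = order)
    C <- correlationMatrix(X, labels)
    fisherZ(vectorizeUpper(C, map))
  }, numeric(nrow(map)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(z = feats),
    rowData = S4Vectors::DataFrame(
      i = map$i, j = map$j,
      region_a = labels[map$i], region_b = labels[map$j]
    ),
    colData = S4Vectors::DataFrame(
      group = groupLabels(cohort), row.names = subjectIds(cohort)
    ),
    metadata = list(nRegions = R, regionLabels = labels,
                    edgeOrder = "row-major upper triangle, i < j")
  )
  new("FcDataset", se)
}
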