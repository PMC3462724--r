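#' Cohort of regional time series
#'
#' Container for a two-group cohort of subjects, each observed as a T x R
#' matrix of regional time courses (T timepoints, R regions). Group labels
#' follow the convention -1 = patient, +1 = control.
#'
#' @slot series list of numeric T x R matrices, one per subject
#' @slot group integer vector in \{-1, +1\}, one per subject
#' @slot subjectIds character vector of unique subject identifiers
#' @slot regionLabels character vector of R region names
#' @slot trSeconds repetition time (sampling interval) in seconds
#'
#' @export
setClass("FcCohort",
  representation(
    series = "list",
    group = "integer",
    subjectIds = "character",
    regionLabels = "character",
    trSeconds = "numeric"
  )
)

setValidity("FcCohort", function(object) {
  msgs <- character()
  n <- length(object@series)
  if (length(object@group) != n || length(object@subjectIds) != n)
    msgs <- c(msgs, "series, group and subjectIds must have equal length")
  if (!all(object@group %in% c(-1L, 1L)))
    msgs <- c(msgs, "group labels must be -1 (patient) or +1 (control)")
  if (anyDuplicated(object@subjectIds))
    msgs <- c(msgs, "subject ids must be unique")
  if (length(object@trSeconds) != 1 || !is.finite(object@trSeconds) ||
      object@trSeconds <= 0)
    msgs <- c(msgs, "trSeconds must be a single positive number")
  if (n > 0) {
    dims <- vapply(object@series, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      msgs <- c(msgs, "all series must share the same T and R")
    if (dims[2, 1] != length(object@regionLabels))
      msgs <- c(msgs, "number of regions must match length of regionLabels")
    if (!all(vapply(object@series, function(m) all(is.finite(m)), logical(1))))
      msgs <- c(msgs, "series must contain only finite values")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an FcCohort
#'
#' @param series list of T x R numeric matrices, one per subject
#' @param group integer labels, -1 for patients and +1 for controls
#' @param subjectIds unique subject identifiers
#' @param regionLabels region names (length R)
#' @param trSeconds sampling interval in seconds
#' @return an [FcCohort-class] object
#' @export
FcCohort <- function(series, group, subjectIds, regionLabels, trSeconds) {
  new("FcCohort",
    series = lapply(series, function(m) {
      m <- as.matrix(m)
      dimnames(m) <- NULL
      storage.mode(m) <- "double"
      m
    }),
    group = as.integer(group),
    subjectIds = as.character(subjectIds),
    regionLabels = as.character(regionLabels),
    trSeconds = as.numeric(trSeconds)
  )
}

#' Edge-feature dataset
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the Fisher-z
#' connectivity features: one assay `"z"` of dimension D x N (D = R(R-1)/2
#' edge features as rows, N subjects as columns), `rowData` carrying the
#' canonical edge index map (region indices `i < j` in row-major order and
#' the corresponding region names), and `colData` carrying the group label.
#'
#' @export
setClass("FcDataset", contains = "SummarizedExperiment")

setValidity("FcDataset", function(object) {
  msgs <- character()
  if (!"z" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'z' is required")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msgs <- c(msgs, "colData column 'group' is required")
  else if (!all(object$group %in% c(-1L, 1L)))
    msgs <- c(msgs, "group labels must be -1 or +1")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("i", "j") %in% colnames(rd)))
    msgs <- c(msgs, "rowData must carry edge endpoints 'i' and 'j'")
  R <- S4Vectors::metadata(object)$nRegions
  if (is.null(R) || length(R) != 1)
    msgs <- c(msgs, "metadata 'nRegions' is required")
  else if (nrow(object) != R * (R - 1) / 2)
    msgs <- c(msgs, "number of features must equal R(R-1)/2")
  if (length(msgs)) msgs else TRUE
})

#' Principal-component subspace model
#'
#' Mean vector and orthonormal projection basis learned from training data.
#' Columns of `rotation` are the leading eigenvectors of the training
#' covariance matrix, sign-fixed so that each column's largest-magnitude
#' entry is positive; `eigenvalues` holds the full descending spectrum.
#'
#' @export
setClass("FcPca",
  representation(
    center = "numeric",
    rotation = "matrix",
    eigenvalues = "numeric",
    d = "integer"
  )
)

setValidity("FcPca", function(object) {
  msgs <- character()
  U <- object@rotation
  if (ncol(U) != object@d)
    msgs <- c(msgs, "rotation must have d columns")
  if (nrow(U) != length(object@center))
    msgs <- c(msgs, "rotation rows must match center length")
  if (ncol(U) > 0) {
    G <- crossprod(U)
    if (max(abs(G - diag(ncol(U)))) > 1e-8)
      msgs <- c(msgs, "rotation columns must be orthonormal")
  }
  ev <- object@eigenvalues
  if (any(ev < -1e-10) || any(diff(ev) > 1e-10))
    msgs <- c(msgs, "eigenvalues must be nonnegative and nonincreasing")
  if (length(msgs)) msgs else TRUE
})

#' Linear support-vector machine model
#'
#' Soft-margin linear SVM on PCA-reduced coordinates; the decision score is
#' `Y = w' x - b`, with `Y > 0` classified as control (+1) and `Y <= 0` as
#' patient (-1).
#'
#' @export
setClass("FcSvm",
  representation(w = "numeric", b = "numeric", cost = "numeric")
)

setValidity("FcSvm", function(object) {
  if (!all(is.finite(object@w)) || !is.finite(object@b))
    return("w and b must be finite")
  if (length(object@cost) != 1 || object@cost <= 0)
    return("cost must be a single positive number")
  TRUE
})

#' Leave-one-out cross-validation result
#'
#' Per-fold records (feature selection, PCA and SVM models, embedded
#' feature-weight vector, held-out decision score and prediction), the
#' aggregate confusion counts and GR/SS/SC metrics, and the consensus
#' (selected in every fold) and union (selected in any fold) feature sets.
#'
#' @export
setClass("FcCv",
  representation(
    folds = "list",
    counts = "integer",       # TP, TN, FP, FN
    metrics = "numeric",      # GR, SS, SC (NA when undefined)
    consensus = "integer",
    union = "integer",
    params = "list",
    predictions = "data.frame"
  )
)

setValidity("FcCv", function(object) {
  msgs <- character()
  if (!identical(names(object@counts), c("TP", "TN", "FP", "FN")))
    msgs <- c(msgs, "counts must be named TP, TN, FP, FN")
  if (sum(object@counts) != length(object@folds))
    msgs <- c(msgs, "confusion counts must sum to the number of folds")
  if (length(msgs)) msgs else TRUE
})

#' Label-permutation test result
#'
#' Observed generalization rate, the permuted-label GR distribution, and the
#' add-one smoothed p-value `(1 + #\{GR* >= GR0\}) / (nPerm + 1)`.
#'
#' @export
setClass("FcPermutation",
  representation(
    gr0 = "numeric",
    grPerm = "numeric",
    nPerm = "integer",
    p = "numeric",
    seed = "integer"
  )
)

setValidity("FcPermutation", function(object) {
  msgs <- character()
  if (length(object@grPerm) != object@nPerm)
    msgs <- c(msgs, "grPerm must have nPerm entries")
  lo <- 1 / (object@nPerm + 1)
  if (object@p < lo - 1e-12 || object@p > 1 + 1e-12)
    msgs <- c(msgs, "p must lie in [1/(nPerm+1), 1]")
  if (length(msgs)) msgs else TRUE
})
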