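# Accessors and show methods for the S4 containers.

#' @rdname restfc-generics
#' @export
setMethod("nRegions", "FcCohort", function(x) length(x@regionLabels))

#' @rdname restfc-generics
#' @export
setMethod("nSubjects", "FcCohort", function(x) length(x@series))

#' @rdname restfc-generics
#' @export
setMethod("regionLabels", "FcCohort", function(x) x@regionLabels)

#' @rdname restfc-generics
#' @export
setMethod("groupLabels", "FcCohort", function(x) x@group)

#' @rdname restfc-generics
#' @export
setMethod("subjectIds", "FcCohort", function(x) x@subjectIds)

#' Extract one subject's series
#' @param x an FcCohort
#' @param i subject index or id
#' @return T x R numeric matrix
#' @export
subjectSeries <- function(x, i) {
  stopifnot(is(x, "FcCohort"))
  if (is.character(i)) i <- match(i, x@subjectIds)
  x@series[[i]]
}

#' @rdname restfc-generics
#' @export
setMethod("trSeconds", "FcCohort", function(x) x@trSeconds)

setMethod("show", "FcCohort", function(object) {
  cat("FcCohort:", nSubjects(object), "subjects (",
      sum(object@group == -1L), "patients /",
      sum(object@group == 1L), "controls ),",
      nRegions(object), "regions\n")
  if (nSubjects(object) > 0)
    cat("  T =", nrow(object@series[[1]]),
        "timepoints, TR =", object@trSeconds, "s\n")
})

#' @rdname restfc-generics
#' @export
setMethod("nRegions", "FcDataset", function(x) S4Vectors::metadata(x)$nRegions)

#' @rdname restfc-generics
#' @export
setMethod("nSubjects", "FcDataset", function(x) ncol(x))

#' @rdname restfc-generics
#' @export
setMethod("regionLabels", "FcDataset",
          function(x) S4Vectors::metadata(x)$regionLabels)

#' @rdname restfc-generics
#' @export
setMethod("groupLabels", "FcDataset", function(x) as.integer(x$group))

#' @rdname restfc-generics
#' @export
setMethod("subjectIds", "FcDataset", function(x) colnames(x))

#' @rdname restfc-generics
#' @details `featureMatrix` returns subjects as rows (N x D), the orientation
#'   used by the ranking and classification functions.
#' @export
setMethod("featureMatrix", "FcDataset",
          function(x) t(SummarizedExperiment::assay(x, "z")))

#' @rdname restfc-generics
#' @export
setMethod("edgeMap", "FcDataset", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(
    k = seq_len(nrow(x)),
    i = rd$i, j = rd$j,
    region_a = rd$region_a, region_b = rd$region_b,
    stringsAsFactors = FALSE
  )
})

#' @rdname restfc-generics
#' @export
setMethod("consensusFeatures", "FcCv", function(x) x@consensus)

#' @rdname restfc-generics
#' @export
setMethod("unionFeatures", "FcCv", function(x) x@union)

#' Confusion counts of a cross-validation run
#' @param x an FcCv object
#' @return named integer vector TP, TN, FP, FN
#' @export
cvCounts <- function(x) {
  stopifnot(is(x, "FcCv"))
  x@counts
}

#' GR/SS/SC metrics of a cross-validation run
#' @param x an FcCv object
#' @return named numeric vector GR, SS, SC
#' @export
cvMetrics <- function(x) {
  stopifnot(is(x, "FcCv"))
  x@metrics
}

#' Per-fold records of a cross-validation run
#' @param x an FcCv object
#' @return list of fold records
#' @export
cvFolds <- function(x) {
  stopifnot(is(x, "FcCv"))
  x@folds
}

setMethod("show", "FcCv", function(object) {
  m <- object@metrics
  cat(sprintf("FcCv: %d-fold leave-one-out (k=%d, d=%d, C=%g)\n",
              length(object@folds), object@params$k, object@params$d,
              object@params$C))
  cat(sprintf("  GR = %.1f%%  SS = %.1f%%  SC = %.1f%%\n",
              100 * m["GR"], 100 * m["SS"], 100 * m["SC"]))
  cat(sprintf("  consensus features: %d  union features: %d\n",
              length(object@consensus), length(object@union)))
})

setMethod("show", "FcPca", function(object) {
  cat(sprintf("FcPca: %d features -> %d components\n",
              nrow(object@rotation), object@d))
})

setMethod("show", "FcSvm", function(object) {
  cat(sprintf("FcSvm: linear, d = %d, C = %g, b = %.4g\n",
              length(object@w), object@cost, object@b))
})

#' Permutation p-value
#' @param x an FcPermutation object
#' @return the add-one smoothed p-value
#' @export
permPValue <- function(x) {
  stopifnot(is(x, "FcPermutation"))
  x@p
}

#' Permuted-label GR distribution
#' @param x an FcPermutation object
#' @return numeric vector of GR values under permuted labels
#' @export
permGr <- function(x) {
  stopifnot(is(x, "FcPermutation"))
  x@grPerm
}

setMethod("show", "FcPermutation", function(object) {
  cat(sprintf(
    "FcPermutation: GR0 = %.3f, %d permutations, p = %.4g\n",
    object@gr0, object@nPerm, object@p))
})
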