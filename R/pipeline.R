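#' Run the full discrimination pipeline on a cohort
#'
#' Convenience wrapper tying the stages together: feature construction
#' ([buildDataset()]), leave-one-out cross-validated classification
#' ([loocv()]), optional label-permutation test, weight back-projection and
#' the region/edge reports. The default operating point (k = 550 features,
#' d = 6 components, C = 0.255) is the configuration the package's worked
#' examples use for a 90-region, 22 + 22 cohort.
#'
#' @param cohort an [FcCohort-class]
#' @param k,d,C classifier hyperparameters
#' @param nPerm number of label permutations (0 to skip the test)
#' @param seed seed for the permutation sequence
#' @param detrend,band,confounds,order preprocessing settings, see
#'   [preprocessSeries()]
#' @return list with elements `dataset`, `cv`, `lambdaBar`,
#'   `regionWeights`, `edgeReport` (consensus features) and `permutation`
#'   (NULL when `nPerm = 0`)
#' @export
runPipeline <- function(cohort, k = 550, d = 6, C = 0.255, nPerm = 0,
                        seed = 1L, detrend = TRUE, band = c(0.01, 0.08),
                        confounds = NULL,
                        order = c("detrend", "bandpass", "regress")) {
  dataset <- buildDataset(cohort, detrend = detrend, band = band,
                          confounds = confounds, order = order)
  cv <- loocv(dataset, k = k, d = d, C = C)
  lambdaBar <- featureWeights(cv)
  rw <- regionWeights(lambdaBar, nRegions(dataset), regionLabels(dataset))
  er <- edgeReport(dataset, lambdaBar, consensusFeatures(cv))
  perm <- if (nPerm > 0)
    permutationTest(dataset, k = k, d = d, C = C, nPerm = nPerm, seed = seed)
  list(dataset = dataset, cv = cv, lambdaBar = lambdaBar,
       regionWeights = rw, edgeReport = er, permutation = perm)
}
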