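# Synthetic two-group cohort generation: multivariate-normal regional time
# series with a planted set of edge-level correlation differences between
# the patient and control covariance structures.

#' Simulation configuration
#'
#' Validated parameter set for [simulateCohort()]. Defaults mirror the study
#' design the package targets: two groups of 22 subjects, 90 regions, 175
#' usable timepoints at TR = 2 s, signal band-limited to 0.01-0.08 Hz.
#'
#' @param nPatients,nControls group sizes
#' @param nRegions number of regions R (>= 3)
#' @param nTimepoints timepoints T per subject
#' @param trSeconds sampling interval in seconds
#' @param plantedEdges data.frame with columns `i`, `j` (1-based region
#'   indices, i < j) and `delta` (correlation shift applied to the patient
#'   covariance); NULL for none
#' @param baseDensity in \[0, 1\]; scales the shared (network-like) correlation
#'   structure of the base covariance. 0 gives the identity.
#' @param driftAmplitude amplitude of the per-region linear drift (signal sd
#'   units); slopes are drawn per subject and region
#' @param noiseSd standard deviation of added white measurement noise
#' @param bandLimit length-2 frequency band (Hz) the latent signal is
#'   restricted to, or NULL for white (unfiltered) signal
#' @param seed integer RNG seed; every draw in the simulator derives from it
#' @return a validated list of class `"fcSimConfig"`
#' @export
simConfig <- function(nPatients = 22, nControls = 22, nRegions = 90,
                      nTimepoints = 175, trSeconds = 2,
                      plantedEdges = NULL, baseDensity = 0.3,
                      driftAmplitude = 0.5, noiseSd = 0.2,
                      bandLimit = c(0.01, 0.08), seed = 1L) {
  stopifnot(
    nPatients >= 1, nControls >= 1, nRegions >= 3, nTimepoints >= 3,
    trSeconds > 0, baseDensity >= 0, baseDensity <= 1,
    driftAmplitude >= 0, noiseSd >= 0
  )
  if (!is.null(plantedEdges)) {
    plantedEdges <- as.data.frame(plantedEdges)
    stopifnot(all(c("i", "j", "delta") %in% names(plantedEdges)))
    if (any(plantedEdges$i >= plantedEdges$j))
      stop("planted edges must satisfy i < j")
    if (any(plantedEdges$j > nRegions) || any(plantedEdges$i < 1))
      stop("planted edge indices must lie in 1..nRegions")
    if (anyDuplicated(plantedEdges[, c("i", "j")]))
      stop("planted edges must be distinct region pairs")
  }
  if (!is.null(bandLimit)) {
    stopifnot(length(bandLimit) == 2, bandLimit[1] >= 0,
              bandLimit[1] < bandLimit[2],
              bandLimit[2] <= 1 / (2 * trSeconds))
  }
  structure(list(
    nPatients = as.integer(nPatients), nControls = as.integer(nControls),
    nRegions = as.integer(nRegions), nTimepoints = as.integer(nTimepoints),
    trSeconds = trSeconds, plantedEdges = plantedEdges,
    baseDensity = baseDensity, driftAmplitude = driftAmplitude,
    noiseSd = noiseSd, bandLimit = bandLimit, seed = as.integer(seed)
  ), class = "fcSimConfig")
}

# Eigenvalue-floor SPD repair followed by rescaling to unit diagonal.
# Deterministic and bounded: only eigenvalues below eps are lifted.
.spdRepair <- function(M, eps = 1e-6) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  M2 <- e$vectors %*% (vals * t(e$vectors))
  M2 <- (M2 + t(M2)) / 2
  d <- sqrt(diag(M2))
  M2 <- M2 / tcrossprod(d)
  diag(M2) <- 1
  M2
}

#' Base (control-group) correlation structure
#'
#' Builds a unit-diagonal symmetric positive-definite correlation matrix
#' from a sparse latent-factor model: regions are assigned round-robin to a
#' small number of latent components, giving block-like correlation similar
#' in flavour to resting-state networks. `baseDensity` scales the shared
#' variance; 0 returns the identity.
#'
#' @param nRegions number of regions (>= 3)
#' @param baseDensity in \[0, 1\]
#' @param seed integer RNG seed
#' @param nFactors number of latent components
#' @return an `nRegions` x `nRegions` correlation matrix
#' @export
makeBaseCovariance <- function(nRegions, baseDensity, seed, nFactors = 5) {
  stopifnot(nRegions >= 3, baseDensity >= 0, baseDensity <= 1)
  if (baseDensity == 0) return(diag(nRegions))
  withr::with_seed(as.integer(seed), {
    block <- rep_len(seq_len(nFactors), nRegions)
    load <- runif(nRegions, 0.4, 0.9) * sqrt(baseDensity)
    L <- matrix(0, nRegions, nFactors)
    L[cbind(seq_len(nRegions), block)] <- load
    S <- tcrossprod(L)
    diag(S) <- 1
    .spdRepair(S)
  })
}

#' Plant edge-level correlation differences
#'
#' Shifts selected off-diagonal correlations of a base covariance by
#' `delta`, then restores validity (symmetrize, floor eigenvalues at 1e-6,
#' rescale to unit diagonal). Non-planted entries change by at most the
#' repair perturbation.
#'
#' @param baseCov SPD correlation matrix
#' @param plantedEdges data.frame with columns `i`, `j`, `delta` (1-based,
#'   i < j); NULL or empty returns `baseCov` unchanged
#' @return the patient-group correlation matrix
#' @export
plantEffects <- function(baseCov, plantedEdges) {
  stopifnot(is.matrix(baseCov), nrow(baseCov) == ncol(baseCov))
  if (min(eigen(baseCov, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("base covariance must be symmetric positive definite")
  if (is.null(plantedEdges) || nrow(plantedEdges) == 0) return(baseCov)
  M <- baseCov
  idx <- cbind(plantedEdges$i, plantedEdges$j)
  shifted <- M[idx] + plantedEdges$delta
  bad <- abs(shifted) > 0.99
  if (any(bad))
    stop("planted shift pushes |r| beyond 0.99 for edge(s): ",
         paste(sprintf("(%d,%d)", plantedEdges$i[bad], plantedEdges$j[bad]),
               collapse = ", "))
  M[idx] <- shifted
  M[idx[, 2:1, drop = FALSE]] <- shifted
  .spdRepair(M)
}

# Ideal band-pass of the latent signal, applied per region. Filtering every
# region with the same mask leaves expected cross-correlations unchanged,
# so planted effects survive band-limiting.
.bandLimitSignal <- function(X, trSeconds, band) {
  .idealBandpass(X, trSeconds, band[1], band[2], keepMean = FALSE)
}

.simGroup <- function(n, Sigma, config, prefix) {
  Tn <- config$nTimepoints
  R <- config$nRegions
  lapply(seq_len(n), function(s) {
    X <- MASS::mvrnorm(Tn, mu = rep(0, R), Sigma = Sigma)
    if (!is.null(config$bandLimit))
      X <- .bandLimitSignal(X, config$trSeconds, config$bandLimit)
    if (config$driftAmplitude > 0) {
      slopes <- runif(R, -1, 1) * config$driftAmplitude
      tnorm <- seq(-0.5, 0.5, length.out = Tn)
      X <- X + outer(tnorm, slopes)
    }
    if (config$noiseSd > 0)
      X <- X + matrix(rnorm(Tn * R, sd = config$noiseSd), Tn, R)
    X
  })
}

#' Simulate a two-group cohort
#'
#' Controls are drawn from a zero-mean multivariate normal with the base
#' covariance; patients from the same covariance with the planted edge
#' shifts applied. Optional band-limiting of the latent signal, per-region
#' linear drift and white measurement noise are then added. Fully
#' reproducible from `config$seed`.
#'
#' @param config an `fcSimConfig` from [simConfig()]
#' @param regionLabels optional region names; defaults to `"region_001"`, ...
#' @return an [FcCohort-class]
#' @export
simulateCohort <- function(config, regionLabels = NULL) {
  stopifnot(inherits(config, "fcSimConfig"))
  if (is.null(regionLabels))
    regionLabels <- sprintf("region_%03d", seq_len(config$nRegions))
  stopifnot(length(regionLabels) == config$nRegions)
  base <- makeBaseCovariance(config$nRegions, config$baseDensity, config$seed)
  patCov <- plantEffects(base, config$plantedEdges)
  withr::with_seed(config$seed + 1L, {
    pat <- .simGroup(config$nPatients, patCov, config, "pat")
    ctl <- .simGroup(config$nControls, base, config, "ctl")
  })
  FcCohort(
    series = c(pat, ctl),
    group = c(rep(-1L, config$nPatients), rep(1L, config$nControls)),
    subjectIds = c(sprintf("pat%02d", seq_len(config$nPatients)),
                   sprintf("ctl%02d", seq_len(config$nControls))),
    regionLabels = regionLabels,
    trSeconds = config$trSeconds
  )
}

#' Simulate a null cohort
#'
#' As [simulateCohort()] but both groups are drawn from the base covariance:
#' the labels carry no information. Used for permutation-test calibration.
#'
#' @inheritParams simulateCohort
#' @return an [FcCohort-class]
#' @export
simulateNullCohort <- function(config, regionLabels = NULL) {
  stopifnot(inherits(config, "fcSimConfig"))
  config$plantedEdges <- NULL
  simulateCohort(config, regionLabels)
}
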