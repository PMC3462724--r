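# Time-series cleaning prior to connectivity: linear detrend, ideal
# frequency-domain band-pass, nuisance regression. All three are linear
# projections, hence idempotent.

# Least-squares residuals of each column of X on the design matrix Z,
# dropping linearly dependent design columns.
.lsResiduals <- function(X, Z, warnRankDeficient = TRUE) {
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    if (warnRankDeficient)
      warning("confound design is rank deficient; dropping ",
              ncol(Z) - qrz$rank, " dependent column(s)")
    Z <- Z[, qrz$pivot[seq_len(qrz$rank)], drop = FALSE]
    qrz <- qr(Z)
  }
  X - Z %*% qr.coef(qrz, X)
}

#' Remove the linear trend from each region's time course
#'
#' Subtracts the per-region least-squares line (intercept plus slope in
#' time), so output columns have zero mean and zero linear trend.
#'
#' @param series T x R numeric matrix
#' @return detrended T x R matrix
#' @export
detrendLinear <- function(series) {
  series <- as.matrix(series)
  Tn <- nrow(series)
  if (Tn < 3) stop("detrending requires at least 3 timepoints")
  Z <- cbind(1, seq_len(Tn))
  .lsResiduals(series, Z, warnRankDeficient = FALSE)
}

# Shared ideal-filter core: strict open band (fLow, fHigh); the mirrored
# negative-frequency bins are masked symmetrically so the output is real.
.idealBandpass <- function(X, trSeconds, fLow, fHigh, keepMean = FALSE) {
  Tn <- nrow(X)
  k <- 0:(Tn - 1)
  freq <- pmin(k, Tn - k) / (Tn * trSeconds)
  keep <- freq > fLow & freq < fHigh
  if (keepMean) keep[1] <- TRUE
  Xf <- stats::mvfft(X)
  Xf[!keep, ] <- 0
  Re(stats::mvfft(Xf, inverse = TRUE)) / Tn
}

#' Ideal band-pass filter in the discrete Fourier domain
#'
#' Retains only frequency bins strictly inside `(fLow, fHigh)`; all other
#' bins, including the DC component, are zeroed. This rectangular-mask
#' convention (rather than an IIR design such as Butterworth) matches the
#' filtering commonly applied to regional BOLD time courses, with the band
#' treated as an open interval.
#'
#' @param series T x R numeric matrix
#' @param trSeconds sampling interval in seconds
#' @param fLow,fHigh band edges in Hz; `fHigh` must not exceed the Nyquist
#'   frequency `1/(2 trSeconds)`
#' @return filtered, real-valued T x R matrix
#' @export
bandpassFilter <- function(series, trSeconds, fLow = 0.01, fHigh = 0.08) {
  series <- as.matrix(series)
  nyquist <- 1 / (2 * trSeconds)
  if (fLow < 0 || fLow >= fHigh)
    stop("band edges must satisfy 0 <= fLow < fHigh")
  if (fHigh > nyquist + 1e-12)
    stop(sprintf("fHigh (%g Hz) exceeds the Nyquist frequency (%g Hz)",
                 fHigh, nyquist))
  .idealBandpass(series, trSeconds, fLow, fHigh, keepMean = FALSE)
}

#' Regress nuisance covariates out of each region's time course
#'
#' Ordinary least-squares residuals of every region on the confound columns
#' plus an intercept (added internally). With an empty confound set this
#' reduces to mean removal. Rank-deficient confound sets are handled by
#' dropping dependent columns with a warning.
#'
#' @param series T x R numeric matrix
#' @param confounds T x C numeric matrix of nuisance regressors (e.g. motion
#'   parameters, global mean, white-matter and CSF signals), or NULL
#' @return residual T x R matrix, orthogonal to every confound column
#' @export
regressConfounds <- function(series, confounds = NULL) {
  series <- as.matrix(series)
  Tn <- nrow(series)
  Z <- matrix(1, Tn, 1)
  if (!is.null(confounds) && NCOL(confounds) > 0) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != Tn)
      stop("confound matrix must have the same number of timepoints")
    if (!all(is.finite(confounds)))
      stop("confounds must be finite")
    Z <- cbind(Z, confounds)
  }
  .lsResiduals(series, Z)
}

#' Standard preprocessing chain
#'
#' Applies, in order, linear detrending, band-pass filtering and nuisance
#' regression (each optional). The default order follows the usual
#' resting-state pipeline: detrend, then filter, then regress.
#'
#' @param series T x R numeric matrix
#' @param trSeconds sampling interval in seconds (needed for filtering)
#' @param detrend logical
#' @param band length-2 Hz band for filtering, or NULL to skip
#' @param confounds confound matrix or NULL; when NULL the regression step
#'   is skipped entirely (not even mean removal)
#' @param order character vector over `c("detrend", "bandpass", "regress")`
#' @return preprocessed T x R matrix
#' @export
preprocessSeries <- function(series, trSeconds, detrend = TRUE,
                             band = c(0.01, 0.08), confounds = NULL,
                             order = c("detrend", "bandpass", "regress")) {
  stopifnot(all(order %in% c("detrend", "bandpass", "regress")))
  X <- as.matrix(series)
  for (step in order) {
    X <- switch(step,
      detrend = if (detrend) detrendLinear(X) else X,
      bandpass = if (!is.null(band))
        bandpassFilter(X, trSeconds, band[1], band[2]) else X,
      regress = if (!is.null(confounds))
        regressConfounds(X, confounds) else X
    )
  }
  X
}
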