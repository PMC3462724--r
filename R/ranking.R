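# Cross-group Kendall tau feature ranking. For one feature with patient
# values x_p (label -1) and control values x_c (label +1), only the m x n
# patient-control pairs are considered: a pair is concordant when the sign
# of the x-difference matches the sign of the label difference, discordant
# when opposite, and neither when the x-difference is zero. Then
# tau = (n_c - n_d) / (m n), so tau > 0 means the feature tends to be lower
# in patients.

#' Cross-group Kendall tau of one feature
#'
#' @param values numeric feature values, one per subject
#' @param labels group labels, -1 (patient) or +1 (control)
#' @return tau in \[-1, 1\]
#' @export
kendallTauCrossGroup <- function(values, labels) {
  stopifnot(length(values) == length(labels),
            all(labels %in% c(-1, 1)))
  xp <- values[labels == -1]
  xc <- values[labels == 1]
  if (length(xp) == 0 || length(xc) == 0)
    stop("both groups must be present")
  sum(sign(outer(xc, xp, "-"))) / (length(xp) * length(xc))
}

# Vectorized tau over all columns of X (N x D). Loops over the smaller
# group; each iteration is a vectorized sign-sum over the other group.
.tauMatrix <- function(X, labels) {
  Xp <- X[labels == -1, , drop = FALSE]
  Xc <- X[labels == 1, , drop = FALSE]
  m <- nrow(Xp); n <- nrow(Xc)
  if (m == 0 || n == 0) stop("both groups must be present")
  s <- numeric(ncol(X))
  if (m <= n) {
    for (p in seq_len(m))
      s <- s + colSums(sign(Xc - rep(Xp[p, ], each = n)))
  } else {
    for (q in seq_len(n))
      s <- s - colSums(sign(Xp - rep(Xc[q, ], each = m)))
  }
  s / (m * n)
}

#' Rank all edge features by cross-group Kendall tau
#'
#' Computes tau per feature and orders features by decreasing `|tau|`,
#' breaking ties by ascending edge index (a fixed rule, required so that
#' fold-wise selections and consensus sets are reproducible).
#'
#' @param x an [FcDataset-class], or an N x D numeric matrix
#' @param labels group labels (ignored when `x` is an FcDataset)
#' @return list of class `"fcRanking"` with elements `tau` (length D) and
#'   `order` (feature indices, most discriminative first)
#' @export
rankFeatures <- function(x, labels = NULL) {
  if (is(x, "FcDataset")) {
    labels <- groupLabels(x)
    x <- featureMatrix(x)
  }
  stopifnot(is.matrix(x), length(labels) == nrow(x))
  tau <- .tauMatrix(x, labels)
  structure(list(tau = tau, order = order(-abs(tau), seq_along(tau))),
            class = "fcRanking")
}

#' Select the top-k ranked features
#'
#' @param ranking an `"fcRanking"` from [rankFeatures()]
#' @param k number of features to keep, 1 <= k <= D
#' @return integer vector of k feature indices in rank order
#' @export
selectTopK <- function(ranking, k) {
  stopifnot(inherits(ranking, "fcRanking"))
  D <- length(ranking$tau)
  if (k < 1 || k > D)
    stop(sprintf("k must lie in [1, %d]", D))
  ranking$order[seq_len(k)]
}

#' Export the tau ranking as a table
#'
#' @param ranking an `"fcRanking"`
#' @param map edge index map (data.frame with `i`, `j`)
#' @param regionLabels region names
#' @return data.frame: edge index, region names, tau, |tau| rank
#' @export
tauTable <- function(ranking, map, regionLabels) {
  rk <- integer(length(ranking$tau))
  rk[ranking$order] <- seq_along(ranking$order)
  data.frame(
    k = map$k,
    region_a = regionLabels[map$i],
    region_b = regionLabels[map$j],
    tau = ranking$tau,
    rank = rk,
    stringsAsFactors = FALSE
  )
}
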