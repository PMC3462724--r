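# Independent oracles used across the suite. These deliberately use naive
# formulations (explicit pair enumeration, normal equations, explicit
# covariance eigendecomposition) so they stay independent of the package's
# implementation paths.

# Cross-group Kendall tau by brute-force enumeration of the m x n
# patient-control pairs: concordant when sgn(x_j - x_k) = sgn(y_j - y_k),
# discordant when the signs are opposite, neither when the x-difference is
# zero; denominator fixed at m x n.
bruteTau <- function(values, labels) {
  p <- which(labels == -1)
  q <- which(labels == 1)
  nc <- 0L; nd <- 0L
  for (j in p) for (k in q) {
    sx <- sign(values[j] - values[k])
    sy <- sign(-1 - 1)  # patient minus control label
    if (sx == 0) next
    if (sx == sy) nc <- nc + 1L else nd <- nd + 1L
  }
  (nc - nd) / (length(p) * length(q))
}

# Least-squares residuals via the normal equations.
neResiduals <- function(X, Z) {
  beta <- solve(t(Z) %*% Z, t(Z) %*% X)
  X - Z %*% beta
}

# Random matrix with orthonormal columns.
randomOrthonormal <- function(k, d) {
  qr.Q(qr(matrix(rnorm(k * d), k, d)))[, seq_len(d), drop = FALSE]
}

# Small planted-effect cohort used by several integration tests.
makeTestCohort <- function(nPerGroup = 8, nRegions = 12, nTimepoints = 120,
                           delta = -0.5, nEdges = 5, seed = 7) {
  map <- edgeIndexMap(nRegions)
  pe <- map[seq_len(nEdges), c("i", "j")]
  pe$delta <- delta
  cfg <- simConfig(
    nPatients = nPerGroup, nControls = nPerGroup, nRegions = nRegions,
    nTimepoints = nTimepoints, plantedEdges = pe, seed = seed
  )
  simulateCohort(cfg)
}
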