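# The classifier: PCA subspace learned from training data, followed by a
# soft-margin linear SVM on the reduced coordinates. The composition
# Y = w' U'(x - xbar) - b collapses to (Uw)'(x - xbar) - b, the identity
# used by the reconstruction stage.

#' Fit a PCA subspace to training data
#'
#' Centers on the training column means and takes the top-d eigenvectors of
#' the training covariance (via SVD of the centered matrix). Component signs
#' are fixed so each column's largest-magnitude entry is positive, making
#' the basis (and hence back-projected weights) reproducible.
#'
#' @param X n x k training matrix (subjects x features), n >= 2
#' @param d number of components; capped at `min(k, n - 1)` with a warning
#' @return an [FcPca-class]
#' @export
fitPca <- function(X, d) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (n < 2) stop("PCA requires at least 2 training samples")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (all(abs(Xc) < 1e-300)) stop("degenerate training matrix: zero variance")
  dmax <- min(k, n - 1)
  if (d > dmax) {
    warning(sprintf("d = %d exceeds the available rank; capped at %d", d, dmax))
    d <- dmax
  }
  if (d < 1) stop("d must be at least 1")
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / (n - 1)
  ev <- pmax(ev, 0)
  U <- sv$v[, seq_len(d), drop = FALSE]
  for (c in seq_len(d)) {
    i0 <- which.max(abs(U[, c]))
    if (U[i0, c] < 0) U[, c] <- -U[, c]
  }
  new("FcPca", center = ctr, rotation = U, eigenvalues = ev, d = as.integer(d))
}

#' Project data into a fitted PCA subspace
#'
#' Computes `U'(x - xbar)` for a single vector or for each row of a matrix.
#'
#' @param pca an [FcPca-class]
#' @param x numeric vector of length k, or an n x k matrix
#' @return length-d vector, or n x d matrix
#' @export
projectPca <- function(pca, x) {
  stopifnot(is(pca, "FcPca"))
  k <- length(pca@center)
  if (is.matrix(x)) {
    if (ncol(x) != k) stop("feature dimension mismatch")
    sweep(x, 2, pca@center) %*% pca@rotation
  } else {
    if (length(x) != k) stop("feature dimension mismatch")
    drop(crossprod(pca@rotation, x - pca@center))
  }
}

#' Fit a soft-margin linear SVM
#'
#' Trains the standard C-SVM with a linear kernel (deterministic SMO solver
#' from libsvm via \pkg{e1071}) and extracts the primal weight vector and
#' bias, oriented so the decision score `Y = w' x - b` is positive for the
#' control class (+1).
#'
#' @param X n x d training matrix of reduced coordinates
#' @param labels group labels, -1 or +1, both present
#' @param C cost parameter, > 0
#' @return an [FcSvm-class]
#' @export
fitSvm <- function(X, labels, C) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(labels), all(labels %in% c(-1, 1)), C > 0)
  if (length(unique(labels)) < 2)
    stop("both classes must be present in SVM training data")
  y <- factor(labels, levels = c(-1, 1))
  fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = C,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- fit$rho
  # libsvm's positive decision side is the class it saw first; flip so that
  # positive scores always mean +1 (control).
  dv <- attr(stats::predict(fit, X[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  posClass <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  if (posClass != "1") {
    w <- -w
    b <- -b
  }
  new("FcSvm", w = w, b = b, cost = as.numeric(C))
}

#' Decision score and predicted label
#'
#' Composes the PCA projection and SVM discriminant:
#' `Y = w' U'(x - xbar) - b`. `Y > 0` is classified as control (+1),
#' otherwise (including exactly 0) as patient (-1).
#'
#' @param pca an [FcPca-class]
#' @param svm an [FcSvm-class]
#' @param x feature vector (length k) or n x k matrix
#' @return list with `score` and `label`
#' @export
decisionScore <- function(pca, svm, x) {
  stopifnot(is(svm, "FcSvm"))
  if (length(svm@w) != ncol(pca@rotation))
    stop("SVM dimension does not match the PCA subspace")
  proj <- projectPca(pca, x)
  score <- if (is.matrix(proj)) drop(proj %*% svm@w) - svm@b
           else sum(proj * svm@w) - svm@b
  list(score = score, label = ifelse(score > 0, 1L, -1L))
}
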