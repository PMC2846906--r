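#' Polynomial kernel matrix
#'
#' Entry (i, j) is \eqn{(\langle x_i, z_j \rangle + r)^p} for columns
#' \eqn{x_i} of \code{X} and \eqn{z_j} of \code{Z}. Degree \eqn{p = 1} with
#' offset \eqn{r = 0} gives the linear kernel.
#'
#' @param X,Z numeric matrices with features in rows and samples in
#'   columns; both must have the same number of rows.
#' @param degree polynomial degree p (>= 1, default 3).
#' @param offset additive constant r (>= 0, default 1).
#' @return Numeric matrix of dimension \code{ncol(X) x ncol(Z)}.
#' @examples
#' polynomialKernel(matrix(1:2), matrix(3:4))  # ((1*3 + 2*4) + 1)^3 = 1728
#' @export
polynomialKernel <- function(X, Z = X, degree = 3, offset = 1) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (nrow(X) != nrow(Z))
    stop("kernel inputs must share the feature dimension (",
         nrow(X), " vs ", nrow(Z), ")")
  if (degree < 1) stop("degree must be >= 1")
  if (offset < 0) stop("offset must be >= 0")
  (crossprod(X, Z) + offset)^degree
}

#' Center a training kernel matrix in feature space
#'
#' Applies the double-sided projection
#' \eqn{K_c = (I - \frac{1}{n} 1 1^\top) K (I - \frac{1}{n} 1 1^\top)},
#' equivalent to mean-centering the implicit feature images. Every row and
#' column of the result sums to zero.
#'
#' @param K symmetric n x n kernel matrix.
#' @return The centered kernel matrix.
#' @export
centerTrainKernel <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K) ||
      max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop("training kernel must be symmetric")
  cm <- colMeans(K)
  # (I - J/n) K (I - J/n) expanded: K - 1 cm' - cm 1' + mean(K)
  sweep(sweep(K, 2, cm), 1, cm) + mean(K)
}

#' Center a test kernel block against its training kernel
#'
#' One-sided analogue of \code{\link{centerTrainKernel}} for the
#' \eqn{n_t \times n} block of test-vs-train kernel evaluations:
#' \eqn{K_{t,c} = (K_t - \frac{1}{n} 1_{n_t} 1_n^\top K)
#' (I - \frac{1}{n} 1_n 1_n^\top)}. Every row of the result sums to zero.
#'
#' @param Kt nt x n matrix of kernel evaluations between test and training
#'   points.
#' @param K the UNCENTERED n x n training kernel.
#' @return The centered test kernel block.
#' @export
centerTestKernel <- function(Kt, K) {
  Kt <- as.matrix(Kt); K <- as.matrix(K)
  if (ncol(Kt) != nrow(K) || nrow(K) != ncol(K))
    stop("test kernel columns must match the training kernel dimension")
  M <- sweep(Kt, 2, colMeans(K))
  M - rowMeans(M)
}

#' Fit a kernel partial least squares classifier
#'
#' Computes the polynomial kernel on the training features, centers it in
#' feature space, mean-centers the +1/-1 response, and extracts
#' \code{ncomp} latent components by the kernel NIPALS recursion (for a
#' single response the inner loop closes in one step): each score is
#' \eqn{t \propto K u} normalized to unit length, after which both the
#' kernel and the response are deflated by the projection
#' \eqn{(I - t t^\top)}. Dual regression coefficients are built from the
#' undeflated centered kernel, so prediction is a single matrix product.
#'
#' @param features numeric matrix, rows = features, columns = samples.
#' @param y numeric response vector of +1/-1 class labels.
#' @param degree,offset polynomial kernel parameters (defaults p = 3,
#'   r = 1).
#' @param ncomp number of latent components, in [1, n-1]. If the kernel
#'   rank is exhausted earlier the count is reduced with a warning.
#' @return A \linkS4class{KPLSModel}.
#' @export
kplsFit <- function(features, y, degree = 3, offset = 1, ncomp = 5L) {
  features <- as.matrix(features)
  n <- ncol(features)
  y <- as.numeric(y)
  if (length(y) != n) stop("response length must match sample count")
  if (!all(y %in% c(-1, 1))) stop("y must be coded +1/-1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp >= n)
    stop("ncomp must be in [1, n-1] (n = ", n, ")")
  K0 <- polynomialKernel(features, features, degree, offset)
  Kc <- centerTrainKernel(K0)
  yMean <- mean(y)
  yc <- y - yMean
  K <- Kc
  r <- yc
  Tm <- matrix(0, n, ncomp)
  Um <- matrix(0, n, ncomp)
  kept <- 0L
  for (h in seq_len(ncomp)) {
    t_ <- K %*% r
    # deflation makes t_ orthogonal to earlier scores in exact arithmetic;
    # re-orthogonalize to stop floating-point drift under large kernels
    if (kept > 0L) {
      Tk <- Tm[, seq_len(kept), drop = FALSE]
      t_ <- t_ - Tk %*% crossprod(Tk, t_)
    }
    nt <- sqrt(sum(t_^2))
    if (nt < 1e-10 * max(1, max(abs(Kc)))) {
      warning("kernel rank exhausted after ", kept,
              " components; reducing ncomp")
      break
    }
    t_ <- t_ / nt
    kept <- kept + 1L
    Tm[, kept] <- t_
    Um[, kept] <- r
    P <- diag(n) - tcrossprod(t_)
    K <- P %*% K %*% P
    r <- r - t_ * sum(t_ * r)
  }
  if (kept == 0L) stop("no latent component could be extracted")
  Tm <- Tm[, seq_len(kept), drop = FALSE]
  Um <- Um[, seq_len(kept), drop = FALSE]
  # dual coefficients of the kernel PLS regression solution:
  # alpha = U (T' Kc U)^{-1} T' yc, so that yhat = Kc alpha + yMean
  alpha <- Um %*% solve(crossprod(Tm, Kc %*% Um), crossprod(Tm, yc))
  new("KPLSModel", trainFeatures = features, degree = degree,
      offset = offset, ncomp = kept, scores = Tm,
      dualCoef = as.numeric(alpha), yMean = yMean, trainKernel = K0)
}

#' Predict with a fitted kernel PLS model
#'
#' Evaluates the polynomial kernel between test and training samples,
#' centers it against the training kernel, applies the dual coefficients
#' and restores the training response mean. The class label is +1 when the
#' regression score is >= 0, else -1.
#'
#' @param object a \linkS4class{KPLSModel}.
#' @param features numeric matrix of test samples (rows = features,
#'   columns = samples), same feature dimension as the training data. When
#'   omitted, the training samples are scored.
#' @param ... ignored.
#' @return List with \code{scores} (real regression scores) and
#'   \code{labels} (+1/-1).
#' @export
setMethod("predict", "KPLSModel", function(object, features, ...) {
  if (missing(features)) features <- object@trainFeatures
  features <- as.matrix(features)
  if (nrow(features) != nrow(object@trainFeatures))
    stop("test feature dimension (", nrow(features),
         ") must match training (", nrow(object@trainFeatures), ")")
  Kt <- polynomialKernel(features, object@trainFeatures,
                         object@degree, object@offset)
  Ktc <- centerTestKernel(Kt, object@trainKernel)
  sc <- as.numeric(Ktc %*% object@dualCoef) + object@yMean
  list(scores = sc, labels = ifelse(sc >= 0, 1, -1))
})

# Stratified fold ids: within each class, samples are shuffled and dealt
# round-robin into k folds. Uses the ambient RNG stream.
.stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("class ", cl, " has fewer than ", k,
           " samples; cannot stratify into ", k, " folds")
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Select the number of latent components by inner cross-validation
#'
#' Stratified 5-fold cross-validation on the training data alone; returns
#' the candidate with the highest mean accuracy, ties toward the smaller
#' value. Candidates too large for a training fold are skipped.
#'
#' @param features numeric matrix, rows = features, columns = samples.
#' @param y +1/-1 response vector.
#' @param candidates integer candidates (default 1..10).
#' @param degree,offset polynomial kernel parameters.
#' @param nfolds inner folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @return The selected integer component count.
#' @export
selectComponents <- function(features, y, candidates = 1:10,
                             degree = 3, offset = 1, nfolds = 5L,
                             seed = 1L) {
  features <- as.matrix(features)
  candidates <- sort(unique(as.integer(candidates)))
  set.seed(seed)
  fold <- .stratifiedFolds(y, nfolds)
  acc <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    C <- candidates[i]
    hits <- 0L; tot <- 0L; bad <- FALSE
    for (f in seq_len(nfolds)) {
      tr <- which(fold != f); te <- which(fold == f)
      if (C >= length(tr)) { bad <- TRUE; break }
      fit <- tryCatch(kplsFit(features[, tr, drop = FALSE], y[tr],
                              degree, offset, C),
                      error = function(e) NULL)
      if (is.null(fit)) { bad <- TRUE; break }
      pr <- predict(fit, features[, te, drop = FALSE])
      hits <- hits + sum(pr$labels == y[te]); tot <- tot + length(te)
    }
    if (!bad) acc[i] <- hits / tot
  }
  ok <- which(!is.na(acc))
  if (!length(ok)) stop("every candidate component count was degenerate")
  candidates[ok[which.max(acc[ok])]]  # first max; ascending order breaks ties low
}
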