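# Independent oracles, coded separately from the package implementation.

# Brute-force statistical moments with explicit loops: mean = sum/N,
# population variance, N-denominator S, raw (non-excess) kurtosis.
bruteMoments <- function(y) {
  n <- length(y)
  mu <- 0
  for (v in y) mu <- mu + v
  mu <- mu / n
  m2 <- m3 <- m4 <- 0
  for (v in y) {
    m2 <- m2 + (v - mu)^2
    m3 <- m3 + (v - mu)^3
    m4 <- m4 + (v - mu)^4
  }
  s <- sqrt(m2 / n)
  c(mean = mu,
    variance = m2 / n,
    skewness = if (s > 0) m3 / (n * s^3) else 0,
    kurtosis = if (s > 0) m4 / (n * s^4) else 0)
}

# Classical primal NIPALS PLS1 regression (single response), operating on
# the explicit feature matrix. X: n x d (samples in rows), y: length n.
# Returns a prediction function for new samples (rows).
primalPLS1 <- function(X, y, ncomp) {
  X <- as.matrix(X)
  xMean <- colMeans(X)
  yMean <- mean(y)
  E <- sweep(X, 2, xMean)
  f <- y - yMean
  n <- nrow(E); d <- ncol(E)
  W <- matrix(0, d, ncomp); P <- matrix(0, d, ncomp)
  Q <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    w <- crossprod(E, f)            # d x 1
    t_ <- E %*% w                   # n x 1
    t_ <- t_ / sqrt(sum(t_^2))      # normalized score, as in the dual form
    p <- crossprod(E, t_)
    q <- sum(f * t_)
    W[, h] <- w; P[, h] <- p; Q[h] <- q
    E <- E - t_ %*% t(p)
    f <- f - t_ * q
  }
  B <- W %*% solve(crossprod(P, W), Q)
  function(Xnew) as.numeric(sweep(as.matrix(Xnew), 2, xMean) %*% B) + yMean
}

# Explicit feature-space centering for a linear kernel: given explicit
# features (columns = samples), center the features and form the Gram
# matrix directly.
explicitCenteredGram <- function(X) {
  Xc <- X - rowMeans(X)
  crossprod(Xc)
}

explicitCenteredCrossGram <- function(Xtest, Xtrain) {
  mu <- rowMeans(Xtrain)
  crossprod(Xtest - mu, Xtrain - mu)
}

# Small labeled RefinedSpectra with a controllable class signal, for
# validation-scheme tests: informative rows get a mean shift in class +1.
makeToyRefined <- function(nPerClass = 10, m = 120, nInformative = 30,
                           shift = 4, seed = 42) {
  set.seed(seed)
  n <- 2 * nPerClass
  labels <- rep(c(-1, 1), each = nPerClass)
  intens <- matrix(rnorm(m * n, mean = 50, sd = 1), m, n)
  if (nInformative > 0) {
    rows <- seq_len(nInformative)
    intens[rows, labels == 1] <- intens[rows, labels == 1] + shift
  }
  spectrumSet(seq_len(m), intens, sprintf("s%02d", seq_len(n)), labels)
}
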