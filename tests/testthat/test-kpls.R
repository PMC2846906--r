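test_that("the polynomial kernel evaluates the defining formula", {
  expect_equal(polynomialKernel(matrix(c(1, 0)), matrix(c(0, 1)),
                                degree = 3, offset = 1)[1, 1], 1)
  expect_equal(polynomialKernel(matrix(0, 4, 1), matrix(0, 4, 1),
                                degree = 5, offset = 1)[1, 1], 1)
  expect_equal(polynomialKernel(matrix(c(1, 2)), matrix(c(3, 4)),
                                degree = 3, offset = 1)[1, 1], (11 + 1)^3)
  expect_error(polynomialKernel(matrix(1, 2, 1), matrix(1, 3, 1)),
               "feature dimension")
})

test_that("training-kernel centering has zero row/column sums and matches
           explicit feature-space centering", {
  expect_equal(centerTrainKernel(matrix(1, 4, 4)), matrix(0, 4, 4))
  Kc <- centerTrainKernel(diag(3))
  expect_equal(rowSums(Kc), rep(0, 3), tolerance = 1e-12)
  expect_equal(colSums(Kc), rep(0, 3), tolerance = 1e-12)
  expect_equal(Kc, t(Kc))

  set.seed(31)
  for (i in 1:10) {
    X <- matrix(rnorm(5 * 6), 5, 6)          # explicit features, 6 samples
    K <- crossprod(X)                        # linear-kernel Gram matrix
    expect_equal(centerTrainKernel(K), explicitCenteredGram(X),
                 tolerance = 1e-10)
  }
  expect_error(centerTrainKernel(matrix(1:9, 3, 3)), "symmetric")
})

test_that("test-kernel centering has zero row sums, agrees with the
           explicit-feature oracle and with training centering", {
  set.seed(32)
  X <- matrix(rnorm(4 * 8), 4, 8)
  Z <- matrix(rnorm(4 * 5), 4, 5)
  K <- crossprod(X)
  Kt <- crossprod(Z, X)
  Ktc <- centerTestKernel(Kt, K)
  expect_equal(rowSums(Ktc), rep(0, 5), tolerance = 1e-10)
  expect_equal(Ktc, explicitCenteredCrossGram(Z, X), tolerance = 1e-10)

  # test points identical to training points reproduce training rows
  expect_equal(centerTestKernel(K, K), centerTrainKernel(K),
               tolerance = 1e-10)
  # a constant kernel (train and test alike) centers to zero
  expect_equal(centerTestKernel(matrix(1, 3, 8), matrix(1, 8, 8)),
               matrix(0, 3, 8), tolerance = 1e-12)
  expect_error(centerTestKernel(matrix(1, 3, 7), K), "dimension")
})

test_that("well-separated Gaussian classes are fit perfectly", {
  set.seed(33)
  n <- 20
  y <- rep(c(-1, 1), each = n / 2)
  X <- rbind(rnorm(n, mean = ifelse(y > 0, 5, -5)), rnorm(n))
  fit <- kplsFit(X, y, degree = 1, offset = 0, ncomp = 2)
  expect_equal(predict(fit)$labels, y)
  expect_equal(predict(fit, X)$labels, y)  # explicit test set = train set
})

test_that("score columns are orthonormal after every fit", {
  set.seed(34)
  for (i in 1:8) {
    n <- sample(8:24, 1)
    d <- sample(2:6, 1)
    y <- rep_len(c(-1, 1), n)
    X <- matrix(rnorm(d * n), d, n) + 0.5 * outer(rep(1, d), y)
    C <- sample(1:5, 1)
    fit <- kplsFit(X, y, degree = sample(1:3, 1), offset = runif(1),
                   ncomp = C)
    G <- crossprod(fit@scores)
    expect_lt(max(abs(G - diag(fit@ncomp))), 1e-8)
  }
})

test_that("linear-kernel KPLS equals classical primal PLS1 predictions", {
  set.seed(35)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    d <- sample(2:10, 1)
    nt <- sample(3:8, 1)
    C <- sample(1:min(4, d), 1)
    y <- rep_len(c(-1, 1), n)[sample(n)]
    X <- matrix(rnorm(d * n), d, n) + outer(rnorm(d), y)
    Xtest <- matrix(rnorm(d * nt), d, nt)
    fit <- kplsFit(X, y, degree = 1, offset = 0, ncomp = C)
    oracle <- primalPLS1(t(X), y, C)
    expect_equal(predict(fit, Xtest)$scores, oracle(t(Xtest)),
                 tolerance = 1e-6)
    expect_equal(predict(fit)$scores, oracle(t(X)), tolerance = 1e-6)
  }
})

test_that("full-rank linear KPLS reproduces least squares on centered data", {
  set.seed(36)
  d <- 4; n <- 12
  y <- rep_len(c(-1, 1), n)
  X <- matrix(rnorm(d * n), d, n)
  fit <- kplsFit(X, y, degree = 1, offset = 0, ncomp = d)
  Xc <- t(X - rowMeans(X))
  beta <- qr.solve(Xc, y - mean(y))
  ols <- as.numeric(Xc %*% beta) + mean(y)
  expect_equal(predict(fit)$scores, ols, tolerance = 1e-6)
})

test_that("an interpolating fit scores a duplicated training point alike", {
  set.seed(37)
  d <- 3; n <- 10
  y <- rep_len(c(-1, 1), n)
  X <- matrix(rnorm(d * n), d, n)
  fit <- kplsFit(X, y, degree = 2, offset = 1, ncomp = n - 1)
  trainScores <- predict(fit)$scores
  single <- predict(fit, X[, 4, drop = FALSE])$scores
  expect_equal(single, trainScores[4], tolerance = 1e-6)
})

test_that("predictions are invariant under training-sample reordering", {
  set.seed(38)
  d <- 5; n <- 16
  y <- rep_len(c(-1, 1), n)
  X <- matrix(rnorm(d * n), d, n) + 0.8 * outer(rep(1, d), y)
  Xtest <- matrix(rnorm(d * 6), d, 6)
  perm <- sample(n)
  f1 <- kplsFit(X, y, ncomp = 3)
  f2 <- kplsFit(X[, perm], y[perm], ncomp = 3)
  expect_equal(predict(f1, Xtest)$scores, predict(f2, Xtest)$scores,
               tolerance = 1e-8)
})

test_that("rank exhaustion reduces the component count with a warning", {
  # rank-1 feature matrix: only one latent direction exists
  X <- outer(c(1, 2), c(-2, -1, 1, 2))
  y <- c(-1, -1, 1, 1)
  expect_warning(fit <- kplsFit(X, y, degree = 1, offset = 0, ncomp = 3),
                 "rank exhausted")
  expect_equal(fit@ncomp, 1L)
  expect_error(kplsFit(X, y, ncomp = 4), "ncomp must be in")
  expect_error(kplsFit(X, c(1, 1, 1, 1), ncomp = 1), "both classes")
})

test_that("component selection finds low-rank signal and breaks ties low", {
  set.seed(39)
  n <- 40; d <- 6
  y <- rep_len(c(-1, 1), n)[sample(n)]
  X <- matrix(rnorm(d * n, sd = 0.3), d, n)
  X[1, ] <- X[1, ] + 3 * y            # signal lives in one direction
  C <- selectComponents(X, y, 1:6, degree = 1, offset = 0, seed = 3)
  expect_lte(C, 3L)
  expect_equal(selectComponents(X, y, candidates = 4, seed = 3), 4L)
  # both candidates reach identical (perfect) accuracy: tie goes small
  expect_equal(selectComponents(X, y, c(2, 3), degree = 1, offset = 0,
                                seed = 3), 2L)
})
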