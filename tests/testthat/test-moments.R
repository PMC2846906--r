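test_that("window plans tile the row axis with a retained partial tail", {
  p <- planWindows(10, 10)
  expect_equal(nWindows(p), 1L)
  expect_equal(p@starts, 1L)
  expect_equal(p@ends, 10L)

  p <- planWindows(39905, 40)
  expect_equal(nWindows(p), 998L)   # hence 998 * 4 = 3992 features
  p <- planWindows(24545, 50)
  expect_equal(nWindows(p), 491L)   # hence 1964 features

  # property: count = ceiling(m / width), full coverage, no overlap
  set.seed(21)
  for (i in 1:25) {
    m <- sample(2:5000, 1)
    w <- sample(2:min(m + 5, 200), 1)
    p <- planWindows(m, w)
    expect_equal(nWindows(p), ceiling(m / w))
    expect_equal(unlist(Map(seq.int, p@starts, p@ends)), seq_len(m))
  }
  expect_error(planWindows(10, 1), "width must be >= 2")
})

test_that("window moments match the brute-force formula oracle", {
  expect_equal(windowMoments(c(5, 5, 5, 5)),
               c(mean = 5, variance = 0, skewness = 0, kurtosis = 0))
  m <- windowMoments(c(-1, 1))
  expect_equal(m[["mean"]], 0)
  expect_equal(m[["variance"]], 1)
  expect_equal(m[["skewness"]], 0)

  expect_equal(windowMoments(c(1, 2, 3, 4, 10)),
               bruteMoments(c(1, 2, 3, 4, 10)), tolerance = 1e-13)
  set.seed(22)
  for (i in 1:20) {
    y <- rnorm(sample(1:30, 1), sd = runif(1, 0.1, 10))
    expect_equal(windowMoments(y), bruteMoments(y), tolerance = 1e-12)
  }
  expect_error(windowMoments(numeric()), "empty")
})

test_that("the transform reproduces the printed dimension identities", {
  set.seed(23)
  a <- matrix(rnorm(39905 * 3), 39905, 3)
  expect_equal(nrow(featureMatrix(momentTransform(a, 40))), 3992L)
  b <- matrix(rnorm(24545 * 3), 24545, 3)
  expect_equal(nrow(featureMatrix(momentTransform(b, 50))), 1964L)
})

test_that("feature rows are window-major, moment-minor and slice-consistent", {
  set.seed(24)
  intens <- matrix(rnorm(23 * 4), 23, 4)
  mf <- momentTransform(intens, width = 10)
  fm <- featureMatrix(mf)
  expect_equal(nrow(fm), 4 * 3)  # 3 windows (last partial), 4 moments
  # transform restricted to one window equals windowMoments on that slice
  for (w in 1:3) {
    rows <- (10 * (w - 1) + 1):min(10 * w, 23)
    for (j in 1:4) {
      expect_equal(unname(fm[(w - 1) * 4 + (1:4), j]),
                   unname(windowMoments(intens[rows, j])),
                   tolerance = 1e-12)
    }
  }
  expect_equal(rownames(fm)[1:5],
               c("w1.mean", "w1.variance", "w1.skewness", "w1.kurtosis",
                 "w2.mean"))
})

test_that("moment subsets and constant input behave as documented", {
  ones <- matrix(1, 30, 5)
  mf <- momentTransform(ones, width = 10, moments = "mean")
  expect_true(all(featureMatrix(mf) == 1))
  expect_equal(nrow(mf), 3L)
  mf2 <- momentTransform(ones, width = 10,
                         moments = c("variance", "kurtosis"))
  expect_true(all(featureMatrix(mf2) == 0))  # zero-variance convention
})

test_that("feature count identity holds over random sizes and subsets", {
  set.seed(25)
  for (i in 1:20) {
    m <- sample(5:400, 1)
    w <- sample(2:60, 1)
    k <- sample(1:4, 1)
    moms <- sample(c("mean", "variance", "skewness", "kurtosis"), k)
    # match.arg reorders to the canonical order; count is what matters
    mf <- momentTransform(matrix(rnorm(m * 3), m, 3), w, moms)
    expect_equal(nrow(mf), length(momentNames(mf)) * ceiling(m / w))
  }
})

test_that("moments transform equivariantly under affine intensity scaling", {
  set.seed(26)
  intens <- matrix(rnorm(80 * 6, 10, 3), 80, 6)
  a <- 2.7; b <- -4
  f1 <- featureMatrix(momentTransform(intens, 9))
  f2 <- featureMatrix(momentTransform(a * intens + b, 9))
  moms <- rep(c("mean", "variance", "skewness", "kurtosis"),
              ceiling(80 / 9))
  expect_equal(f2[moms == "mean", ], a * f1[moms == "mean", ] + b,
               tolerance = 1e-10)
  expect_equal(f2[moms == "variance", ], a^2 * f1[moms == "variance", ],
               tolerance = 1e-10)
  expect_equal(f2[moms == "skewness", ], f1[moms == "skewness", ],
               tolerance = 1e-9)
  expect_equal(f2[moms == "kurtosis", ], f1[moms == "kurtosis", ],
               tolerance = 1e-9)
})

test_that("width selection prefers signal-preserving widths, ties go small", {
  # rows 1-4 shifted +6 in class +1, rows 5-8 shifted -6: a width-4 mean
  # window isolates each block (perfect separation) while a width-8 window
  # spans both and the shifts cancel, destroying the signal. alpha close to
  # 1 keeps (virtually) every row so window positions are stable.
  set.seed(27)
  n <- 20
  labels <- rep(c(-1, 1), each = 10)
  intens <- matrix(rnorm(120 * n), 120, n)
  intens[1:4, labels == 1] <- intens[1:4, labels == 1] + 6
  intens[5:8, labels == 1] <- intens[5:8, labels == 1] - 6
  x <- spectrumSet(1:120, intens, labels = labels)
  cfg <- pipelineConfig(alpha = 0.9999, width = 4, moments = "mean",
                        ncomp = 2)
  sel <- selectWindowWidth(x, c(4, 8), cfg, repeats = 3, seed = 5)
  expect_equal(sel$width, 4L)
  expect_gt(sel$table$meanAc[sel$table$width == 4],
            sel$table$meanAc[sel$table$width == 8] + 0.2)

  # single candidate short-circuits
  expect_equal(selectWindowWidth(x, 40, cfg, repeats = 2, seed = 5)$width,
               40L)

  # numerically identical accuracies break toward the smaller width: a
  # same-sign block signal this strong is perfectly separated either way
  intens2 <- matrix(rnorm(120 * n), 120, n)
  intens2[1:12, labels == 1] <- intens2[1:12, labels == 1] + 8
  x2 <- spectrumSet(1:120, intens2, labels = labels)
  sel2 <- selectWindowWidth(x2, c(3, 6), cfg, repeats = 3, seed = 5)
  expect_equal(sel2$table$meanAc[1], sel2$table$meanAc[2])
  expect_equal(sel2$width, 3L)
})
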