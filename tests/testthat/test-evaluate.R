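test_that("confusion counts match a brute-force tally", {
  expect_equal(confusionCounts(c(1, 1, -1), c(1, 1, -1)),
               c(TP = 2L, FN = 0L, TN = 1L, FP = 0L))
  set.seed(41)
  yt <- sample(c(-1, 1), 200, replace = TRUE)
  yp <- sample(c(-1, 1), 200, replace = TRUE)
  tally <- c(TP = 0L, FN = 0L, TN = 0L, FP = 0L)
  for (i in 1:200) {
    key <- if (yt[i] == 1 && yp[i] == 1) "TP"
           else if (yt[i] == 1) "FN"
           else if (yp[i] == -1) "TN" else "FP"
    tally[key] <- tally[key] + 1L
  }
  expect_equal(confusionCounts(yt, yp), tally)
  # flipping all predictions swaps TP<->FN and TN<->FP
  flipped <- confusionCounts(yt, -yp)
  orig <- confusionCounts(yt, yp)
  expect_equal(flipped[["TP"]], orig[["FN"]])
  expect_equal(flipped[["TN"]], orig[["FP"]])
  expect_error(confusionCounts(c(1, -1), c(1)), "equal length")
})

test_that("metric formulas reproduce the published worked example", {
  # 121 cancers all correct, 94 of 95 controls correct
  m <- classificationMetrics(c(TP = 121, FN = 0, TN = 94, FP = 1))
  expect_equal(round(m[["Ac"]], 4), 0.9954)
  expect_equal(round(m[["CC"]], 4), 0.9906)
  expect_equal(round(m[["Sn"]], 4), 1.0000)
  expect_equal(round(m[["Sp"]], 4), 0.9895)

  perfect <- classificationMetrics(c(TP = 10, FN = 0, TN = 5, FP = 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1))
})

test_that("metrics match an independent formula evaluation on random counts", {
  set.seed(42)
  for (i in 1:25) {
    tp <- sample(0:50, 1); fn <- sample(0:50, 1)
    tn <- sample(0:50, 1); fp <- sample(0:50, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    m <- classificationMetrics(c(TP = tp, FN = fn, TN = tn, FP = fp))
    expect_equal(m[["Ac"]], (tp + tn) / (tp + fn + tn + fp))
    expect_equal(m[["Sn"]], tp / (tp + fn))
    expect_equal(m[["Sp"]], tn / (tn + fp))
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    expect_equal(m[["CC"]],
                 if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den))
    # accuracy is the prevalence-weighted mean of Sn and Sp
    expect_equal(m[["Ac"]],
                 (m[["Sn"]] * (tp + fn) + m[["Sp"]] * (tn + fp)) /
                   (tp + fn + tn + fp))
    # CC = 1 iff no errors (both classes present)
    expect_equal(m[["CC"]] == 1, fp == 0 && fn == 0)
  }
})

test_that("metric edge cases follow the documented conventions", {
  # all predictions positive: CC factor (TN+FN) = 0 -> CC defined 0
  m <- classificationMetrics(c(TP = 5, FN = 0, TN = 0, FP = 5))
  expect_equal(m[["CC"]], 0)
  expect_error(classificationMetrics(c(TP = 0, FN = 0, TN = 3, FP = 1)),
               "no positive samples")
})

test_that("five-fold CV is stratified, pooled per repeat and seed-stable", {
  x <- makeToyRefined(nPerClass = 10, m = 100, nInformative = 30,
                      shift = 5, seed = 43)
  cfg <- pipelineConfig(width = 5, ncomp = 3, alpha = 0.05)
  r1 <- fiveFoldCV(x, cfg, repeats = 4, seed = 7)
  r2 <- fiveFoldCV(x, cfg, repeats = 4, seed = 7)
  expect_identical(r1@perRepeat, r2@perRepeat)  # bitwise determinism
  expect_identical(r1@summary, r2@summary)
  expect_equal(r1@nRepeats, 4L)
  # strong signal: essentially perfect accuracy
  expect_gte(r1@summary$mean[r1@summary$metric == "Ac"], 0.95)

  tiny <- makeToyRefined(nPerClass = 4, m = 30)
  expect_error(fiveFoldCV(tiny, cfg), ">= 5 samples per class")
})

test_that("a null dataset yields chance-level CC under five-fold CV", {
  x <- generateNullMatrix(150, 10, seed = 44)
  cfg <- pipelineConfig(width = 5, ncomp = 2, alpha = 0.2)
  rep_ <- fiveFoldCV(x, cfg, repeats = 5, seed = 9)
  expect_lt(abs(rep_@summary$mean[rep_@summary$metric == "CC"]), 0.35)
})

test_that("proportional validation splits each class by the train fraction", {
  x <- makeToyRefined(nPerClass = 10, m = 60, nInformative = 20,
                      shift = 5, seed = 45)
  cfg <- pipelineConfig(width = 5, ncomp = 3, alpha = 0.05)
  r1 <- proportionalValidation(x, cfg, trainFraction = 0.8, repeats = 3,
                               seed = 11)
  r2 <- proportionalValidation(x, cfg, trainFraction = 0.8, repeats = 3,
                               seed = 11)
  expect_identical(r1@perRepeat, r2@perRepeat)
  # 10 + 10 samples at 0.8 -> every repeat tests on exactly 2 + 2, so all
  # attainable metric values are multiples of 1/4 on 4 test samples
  expect_true(all(r1@perRepeat$Ac %in% c(0, 0.25, 0.5, 0.75, 1)))
  expect_gte(r1@summary$mean[r1@summary$metric == "Ac"], 0.9)
  expect_error(proportionalValidation(x, cfg, trainFraction = 0.99),
               "without training or test")
})

test_that("leave-one-out pools n held-out predictions deterministically", {
  x <- makeToyRefined(nPerClass = 8, m = 60, nInformative = 20, shift = 5,
                      seed = 46)
  cfg <- pipelineConfig(width = 5, ncomp = 3, alpha = 0.05)
  l1 <- loocv(x, cfg)
  l2 <- loocv(x, cfg)
  expect_identical(l1, l2)
  expect_equal(sum(l1$counts), 16)       # counts sum to n
  expect_equal(nrow(l1$predictions), 16)
  expect_equal(l1$metrics[["Ac"]], 1)    # separable construction
})

test_that("held-out predictions cannot be read off the held-out label", {
  # a constant-column dataset carries no information about any sample's own
  # label, so every leave-one-out prediction is the same either way
  intens <- matrix(rep(c(1, 2, 3), each = 6), 3, 6, byrow = TRUE)
  intens <- intens + matrix(rnorm(18, sd = 0.01), 3, 6)
  x <- spectrumSet(1:3, intens, labels = c(-1, -1, -1, 1, 1, 1))
  cfg <- pipelineConfig(width = 2, ncomp = 1, alpha = 0.9999,
                        moments = "mean")
  out <- loocv(x, cfg)
  # predictions exist for every sample and are labels, not echoes
  expect_true(all(out$predictions$predicted %in% c(-1, 1)))
  expect_false(all(out$predictions$predicted == out$predictions$label))
})

test_that("paper-mode global filtering changes only the preprocessing site", {
  x <- makeToyRefined(nPerClass = 8, m = 80, nInformative = 25, shift = 4,
                      seed = 47)
  leakFree <- pipelineConfig(width = 5, ncomp = 2, alpha = 0.05)
  global <- pipelineConfig(width = 5, ncomp = 2, alpha = 0.05,
                           paperMode = TRUE)
  a <- fiveFoldCV(x, leakFree, repeats = 2, seed = 13)
  b <- fiveFoldCV(x, global, repeats = 2, seed = 13)
  expect_s4_class(b, "ValidationReport")
  # both run to completion on the same folds; with this strong a signal
  # both are near-perfect
  expect_gte(b@summary$mean[b@summary$metric == "Ac"], 0.9)
  expect_gte(a@summary$mean[a@summary$metric == "Ac"], 0.9)
})
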