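#' Confusion counts for a binary +1/-1 classification
#'
#' The positive class is cancer (+1).
#'
#' @param yTrue,yPred numeric +1/-1 vectors of equal length.
#' @return Named integer vector with elements TP, FN, TN, FP.
#' @examples
#' confusionCounts(c(1, 1, -1), c(1, 1, -1))  # TP=2 FN=0 TN=1 FP=0
#' @export
confusionCounts <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  if (!all(yTrue %in% c(-1, 1)) || !all(yPred %in% c(-1, 1)))
    stop("labels must be coded +1/-1")
  c(TP = sum(yTrue == 1 & yPred == 1),
    FN = sum(yTrue == 1 & yPred == -1),
    TN = sum(yTrue == -1 & yPred == -1),
    FP = sum(yTrue == -1 & yPred == 1))
}

#' Sensitivity, specificity, accuracy and Matthews correlation
#'
#' \deqn{Ac = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{Sn = TP/(TP+FN), \quad Sp = TN/(TN+FP)}
#' \deqn{CC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' CC is defined as 0 when any factor under the root is 0. Sn and Sp
#' require at least one sample of the corresponding class: every validation
#' fold here contains both classes by construction, so an empty class is an
#' error rather than a silent 0.
#'
#' @param counts named vector with TP, FN, TN, FP (see
#'   \code{\link{confusionCounts}}).
#' @return Named numeric vector with elements Ac, CC, Sn, Sp.
#' @examples
#' metrics <- classificationMetrics(c(TP = 121, FN = 0, TN = 94, FP = 1))
#' round(metrics, 4)  # Ac 0.9954, CC 0.9906, Sn 1.0000, Sp 0.9895
#' @export
classificationMetrics <- function(counts) {
  counts <- counts[c("TP", "FN", "TN", "FP")]
  if (anyNA(counts) || any(counts < 0))
    stop("counts must contain nonnegative TP, FN, TN, FP")
  tp <- counts[["TP"]]; fn <- counts[["FN"]]
  tn <- counts[["TN"]]; fp <- counts[["FP"]]
  n <- tp + fn + tn + fp
  if (n == 0) stop("at least one sample is required")
  if (tp + fn == 0) stop("sensitivity undefined: no positive samples")
  if (tn + fp == 0) stop("specificity undefined: no negative samples")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  cc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  c(Ac = (tp + tn) / n, CC = cc, Sn = tp / (tp + fn), Sp = tn / (tn + fp))
}

# One train/predict pass of the configured pipeline on a column split of a
# labeled RefinedSpectra. Leak-free by default: the t-filter is fit on the
# training columns only and its kept rows applied to the test columns.
# With paperMode the caller has already filtered globally and alpha is
# skipped here (prefiltered = TRUE).
.trainPredictFold <- function(x, trainIdx, testIdx, config,
                              prefiltered = FALSE) {
  intens <- intensityMatrix(x)
  labels <- sampleLabels(x)
  trainM <- intens[, trainIdx, drop = FALSE]
  yTr <- labels[trainIdx]
  if (prefiltered) {
    keep <- seq_len(nrow(intens))
  } else {
    p <- .rowTTest(trainM, yTr, config@tTest)
    keep <- which(p < config@alpha)
    if (!length(keep))
      stop("t-test filter retained no rows in a training fold")
  }
  ftr <- momentTransform(trainM[keep, , drop = FALSE], config@width,
                         config@moments)
  fte <- momentTransform(intens[keep, testIdx, drop = FALSE], config@width,
                         config@moments)
  ncomp <- config@ncomp
  if (is.na(ncomp))
    ncomp <- selectComponents(featureMatrix(ftr), yTr,
                              config@ncompCandidates,
                              config@degree, config@offset)
  ncomp <- min(ncomp, length(trainIdx) - 1L)
  fit <- kplsFit(featureMatrix(ftr), yTr, config@degree, config@offset,
                 ncomp)
  predict(fit, featureMatrix(fte))
}

.checkLabeled <- function(x) {
  labels <- sampleLabels(x)
  if (anyNA(labels)) stop("validation requires labels on all samples")
  labels
}

.reportFromRepeats <- function(scheme, perRepeat, seed) {
  metrics <- c("Ac", "CC", "Sn", "Sp")
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(perRepeat[[m]]), 0),
    sd = vapply(metrics, function(m) stats::sd(perRepeat[[m]]), 0))
  new("ValidationReport", scheme = scheme,
      nRepeats = nrow(perRepeat), perRepeat = perRepeat,
      summary = summ, seed = as.integer(seed))
}

.maybePrefilter <- function(x, config) {
  if (config@paperMode) list(x = tFilter(x, config@alpha, config@tTest)$refined,
                             prefiltered = TRUE)
  else list(x = x, prefiltered = FALSE)
}

#' Repeated stratified five-fold cross-validation
#'
#' Per repeat: samples are partitioned into 5 stratified folds; the full
#' pipeline (t-filter, moment transform, kernel PLS) is fit on 4 folds and
#' predicts the held-out fold; all held-out predictions of the repeat are
#' pooled into one confusion matrix, yielding one metric set per repeat.
#' Mean and SD (N-1) over repeats are reported. By default preprocessing is
#' refit inside each training fold; \code{paperMode} filters once globally
#' instead.
#'
#' @param x a labeled \linkS4class{RefinedSpectra}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param repeats number of independent repeats (default 100).
#' @param seed integer RNG seed; reports are bitwise-reproducible from it.
#' @return A \linkS4class{ValidationReport}.
#' @export
fiveFoldCV <- function(x, config = pipelineConfig(), repeats = 100L,
                       seed = 1L) {
  labels <- .checkLabeled(x)
  if (min(table(labels)) < 5L)
    stop("five-fold stratification needs >= 5 samples per class")
  pf <- .maybePrefilter(x, config)
  set.seed(seed)
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- .stratifiedFolds(labels, 5L)
    pred <- numeric(length(labels))
    for (f in 1:5) {
      te <- which(fold == f)
      pr <- .trainPredictFold(pf$x, which(fold != f), te, config,
                              pf$prefiltered)
      pred[te] <- pr$labels
    }
    rows[[r]] <- as.list(classificationMetrics(confusionCounts(labels, pred)))
  }
  .reportFromRepeats("fivefold", do.call(rbind.data.frame, rows), seed)
}

#' Repeated per-class proportional hold-out validation
#'
#' Per repeat, a random fraction (default 80 percent) of each class is
#' drawn as the training set and the classifier is tested on the remaining
#' samples; one confusion matrix (hence one metric set) per repeat.
#'
#' @param x a labeled \linkS4class{RefinedSpectra}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param trainFraction per-class training fraction in (0, 1).
#' @param repeats number of repeats (default 100).
#' @param seed integer RNG seed.
#' @return A \linkS4class{ValidationReport}.
#' @export
proportionalValidation <- function(x, config = pipelineConfig(),
                                   trainFraction = 0.8, repeats = 100L,
                                   seed = 1L) {
  labels <- .checkLabeled(x)
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  nTrain <- vapply(split(seq_along(labels), labels),
                   function(i) round(trainFraction * length(i)), 0)
  if (any(nTrain < 2L) || any(nTrain >= table(labels)[names(nTrain)]))
    stop("trainFraction leaves a class without training or test samples")
  pf <- .maybePrefilter(x, config)
  set.seed(seed)
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    tr <- unlist(lapply(split(seq_along(labels), labels), function(i)
      sample(i, round(trainFraction * length(i)))))
    te <- setdiff(seq_along(labels), tr)
    pr <- .trainPredictFold(pf$x, tr, te, config, pf$prefiltered)
    rows[[r]] <- as.list(classificationMetrics(
      confusionCounts(labels[te], pr$labels)))
  }
  .reportFromRepeats("proportional", do.call(rbind.data.frame, rows), seed)
}

#' Leave-one-out cross-validation
#'
#' Fits the pipeline n times, each holding out one sample; the n held-out
#' predictions are pooled into one confusion matrix. Deterministic: there
#' is no randomness beyond any fixed component selection, so repeated calls
#' return identical output.
#'
#' @param x a labeled \linkS4class{RefinedSpectra} with n >= 3 and both
#'   classes present.
#' @param config a \linkS4class{PipelineConfig}.
#' @return List with \code{metrics} (named Ac/CC/Sn/Sp vector),
#'   \code{counts} (TP/FN/TN/FP), and \code{predictions} (per-sample
#'   data.frame: sample, label, score, predicted).
#' @export
loocv <- function(x, config = pipelineConfig()) {
  labels <- .checkLabeled(x)
  n <- length(labels)
  if (n < 3L || length(unique(labels)) < 2L)
    stop("leave-one-out needs n >= 3 with both classes present")
  pf <- .maybePrefilter(x, config)
  pred <- numeric(n); score <- numeric(n)
  for (i in seq_len(n)) {
    pr <- tryCatch(
      .trainPredictFold(pf$x, setdiff(seq_len(n), i), i, config,
                        pf$prefiltered),
      error = function(e) stop("pipeline failed on leave-one-out fold ", i,
                               ": ", conditionMessage(e)))
    pred[i] <- pr$labels; score[i] <- pr$scores
  }
  counts <- confusionCounts(labels, pred)
  list(metrics = classificationMetrics(counts), counts = counts,
       predictions = data.frame(sample = colnames(x), label = labels,
                                score = score, predicted = pred))
}
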