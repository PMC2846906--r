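#' Partition the row axis into fixed-width windows
#'
#' Consecutive half-open intervals of \code{width} m/z points; the trailing
#' partial window is retained, so a matrix of \code{m} rows yields
#' \code{ceiling(m / width)} windows. Width counts grid points, not
#' Daltons.
#'
#' @param m number of rows to partition (>= 1).
#' @param width window width in points (>= 2).
#' @return A \linkS4class{WindowPlan}.
#' @examples
#' nWindows(planWindows(39905, 40))  # 998 windows -> 3992 four-moment rows
#' @export
planWindows <- function(m, width) {
  m <- as.integer(m); width <- as.integer(width)
  if (is.na(m) || m < 1L) stop("m must be a positive row count")
  if (is.na(width) || width < 2L)
    stop("width must be >= 2 (moments beyond the mean need >= 2 points)")
  starts <- seq.int(1L, m, by = width)
  ends <- pmin(starts + width - 1L, m)
  new("WindowPlan", width = width, starts = starts, ends = ends, nrows = m)
}

#' Four statistical moments of one window
#'
#' Population (N-denominator) conventions throughout: mean
#' \eqn{\bar Y = \sum Y / N}; variance \eqn{\sum (Y-\bar Y)^2 / N};
#' skewness \eqn{\sum (Y-\bar Y)^3 / (N S^3)}; kurtosis (raw, not excess)
#' \eqn{\sum (Y-\bar Y)^4 / (N S^4)}, with \eqn{S} the N-denominator
#' standard deviation. When \eqn{S = 0} the skewness and kurtosis are
#' defined as 0 so that constant windows do not propagate non-finite
#' features into the kernel.
#'
#' @param values numeric vector of at least one finite intensity.
#' @return Named numeric vector (mean, variance, skewness, kurtosis).
#' @examples
#' windowMoments(c(5, 5, 5, 5))  # (5, 0, 0, 0)
#' @export
windowMoments <- function(values) {
  if (!length(values)) stop("empty window")
  if (!all(is.finite(values))) stop("window values must be finite")
  n <- length(values)
  mu <- sum(values) / n
  d <- values - mu
  v <- sum(d^2) / n
  s <- sqrt(v)
  if (s > 0) {
    sk <- sum(d^3) / (n * s^3)
    ku <- sum(d^4) / (n * s^4)
  } else sk <- ku <- 0
  c(mean = mu, variance = v, skewness = sk, kurtosis = ku)
}

.momentChoices <- c("mean", "variance", "skewness", "kurtosis")

# Windowed moments of a rows-by-samples matrix, vectorized across windows
# via rowsum() on the window index. Returns a list of W x n matrices.
.windowedMoments <- function(intens, plan) {
  g <- rep.int(seq_along(plan@starts), plan@ends - plan@starts + 1L)
  N <- as.numeric(plan@ends - plan@starts + 1L)
  mu <- rowsum(intens, g, reorder = FALSE) / N
  d <- intens - mu[g, , drop = FALSE]
  m2 <- rowsum(d * d, g, reorder = FALSE) / N
  m3 <- rowsum(d^3, g, reorder = FALSE) / N
  m4 <- rowsum(d^4, g, reorder = FALSE) / N
  s <- sqrt(m2)
  pos <- s > 0
  sk <- matrix(0, nrow(m3), ncol(m3))
  ku <- matrix(0, nrow(m4), ncol(m4))
  sk[pos] <- m3[pos] / s[pos]^3
  ku[pos] <- m4[pos] / s[pos]^4
  list(mean = mu, variance = m2, skewness = sk, kurtosis = ku)
}

#' Windowed statistical-moment transform
#'
#' Replaces each window of consecutive m/z rows by the selected moments of
#' each sample's intensities within it, reducing \code{m} rows to
#' \code{k * ceiling(m / width)} feature rows. Output rows are ordered
#' window-major, moment-minor (window 1 mean, window 1 variance, ...,
#' window 2 mean, ...).
#'
#' @param x a \linkS4class{RefinedSpectra}, or a complete numeric matrix
#'   (rows = m/z points, columns = samples).
#' @param width window width in m/z points.
#' @param moments ordered subset of
#'   \code{c("mean", "variance", "skewness", "kurtosis")}; default all four.
#' @param labels optional labels when \code{x} is a bare matrix.
#' @return A \linkS4class{MomentFeatures}.
#' @examples
#' m <- matrix(rnorm(400), 100, 4)
#' dim(featureMatrix(momentTransform(m, width = 40)))  # 12 x 4
#' @export
momentTransform <- function(x, width,
                            moments = .momentChoices, labels = NULL) {
  moments <- match.arg(moments, .momentChoices, several.ok = TRUE)
  if (!length(moments)) stop("at least one moment must be selected")
  if (is(x, "SpectrumSet")) {
    intens <- intensityMatrix(x)
    labels <- sampleLabels(x)
    ids <- colnames(x)
  } else {
    intens <- as.matrix(x)
    ids <- colnames(intens)
    if (is.null(ids)) ids <- paste0("sample", seq_len(ncol(intens)))
    if (is.null(labels)) labels <- rep(NA_real_, ncol(intens))
  }
  if (anyNA(intens)) stop("moment transform requires a complete matrix")
  plan <- planWindows(nrow(intens), width)
  mom <- .windowedMoments(intens, plan)[moments]
  k <- length(moments)
  W <- nWindows(plan)
  out <- matrix(NA_real_, k * W, ncol(intens))
  for (j in seq_len(k))
    out[seq.int(j, by = k, length.out = W), ] <- mom[[j]]
  rownames(out) <- paste0("w", rep(seq_len(W), each = k), ".",
                          rep(moments, W))
  colnames(out) <- ids
  se <- SummarizedExperiment(
    assays = list(features = out),
    rowData = DataFrame(window = rep(seq_len(W), each = k),
                        moment = rep(moments, W)),
    colData = DataFrame(label = as.numeric(labels), row.names = ids))
  md <- metadata(se)
  md$plan <- plan
  md$momentNames <- moments
  metadata(se) <- md
  new("MomentFeatures", se)
}

#' Select the window width by cross-validated accuracy
#'
#' Runs the supplied evaluation protocol (repeated stratified five-fold
#' cross-validation of the full moment + kernel-PLS pipeline) once per
#' candidate width and returns the candidate with the highest mean
#' accuracy; ties break toward the smaller width. Candidates whose
#' evaluation degenerates (e.g. a fold losing a class) are skipped and
#' reported in the returned table.
#'
#' @param x a labeled \linkS4class{RefinedSpectra}.
#' @param candidates integer vector of at least 2 candidate widths (or 1,
#'   which is returned immediately).
#' @param config a \linkS4class{PipelineConfig}; its width is overridden by
#'   each candidate in turn.
#' @param repeats cross-validation repeats per candidate.
#' @param seed RNG seed (same folds across candidates).
#' @return List with \code{width} (the selected width) and \code{table}
#'   (data.frame of width, meanAc, meanCC, error).
#' @export
selectWindowWidth <- function(x, candidates, config = pipelineConfig(),
                              repeats = 5L, seed = 1L) {
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) < 1L) stop("at least one candidate width required")
  tab <- data.frame(width = candidates, meanAc = NA_real_,
                    meanCC = NA_real_, error = NA_character_)
  for (i in seq_along(candidates)) {
    cfg <- config
    cfg@width <- candidates[i]
    rep_ <- tryCatch(fiveFoldCV(x, cfg, repeats = repeats, seed = seed),
                     error = function(e) e)
    if (inherits(rep_, "error")) {
      tab$error[i] <- conditionMessage(rep_)
    } else {
      tab$meanAc[i] <- rep_@summary$mean[rep_@summary$metric == "Ac"]
      tab$meanCC[i] <- rep_@summary$mean[rep_@summary$metric == "CC"]
    }
  }
  ok <- which(!is.na(tab$meanAc))
  if (!length(ok)) stop("every candidate width failed evaluation")
  best <- ok[which.max(tab$meanAc[ok])]  # which.max takes the first maximum;
  # candidates are sorted ascending, so ties already break to smaller width
  list(width = candidates[best], table = tab)
}
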