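#' Align spectra on the sorted union of m/z values
#'
#' Builds the union m/z axis of all spectra and places each sample's
#' intensities on it; grid points a sample did not record become \code{NA}.
#' Two m/z values are the same axis point only when they are exactly equal
#' (no tolerance merging).
#'
#' @param spectra list of \linkS4class{RawSpectrum} (at least 2).
#' @param labels numeric vector of +1/-1 class labels (NA allowed),
#'   one per spectrum.
#' @return A \linkS4class{SpectrumSet} (a \linkS4class{RefinedSpectra} when
#'   no cell is missing).
#' @examples
#' a <- rawSpectrum("a", 1:3, c(1, 2, 3))
#' b <- rawSpectrum("b", 2:4, c(5, 6, 7))
#' alignUnion(list(a, b), c(1, -1))
#' @export
alignUnion <- function(spectra, labels = rep(NA_real_, length(spectra))) {
  if (length(spectra) < 2L)
    stop("alignment needs at least 2 spectra")
  stopifnot(all(vapply(spectra, is, TRUE, "RawSpectrum")),
            length(labels) == length(spectra))
  axis <- sort(unique(unlist(lapply(spectra, function(s) s@mz))))
  intens <- matrix(NA_real_, length(axis), length(spectra))
  for (j in seq_along(spectra)) {
    idx <- match(spectra[[j]]@mz, axis)
    intens[idx, j] <- spectra[[j]]@intensity
  }
  ids <- vapply(spectra, function(s) s@sampleId, "")
  spectrumSet(axis, intens, ids, labels)
}

#' Drop m/z rows with any missing intensity
#'
#' Keeps exactly the rows observed in every sample; row and sample order
#' are preserved. Raises an error (with a diagnostic on the least-missing
#' row) when no row is complete.
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @return A \linkS4class{RefinedSpectra}.
#' @export
refineSpectra <- function(x) {
  stopifnot(is(x, "SpectrumSet"))
  intens <- intensityMatrix(x)
  nmiss <- rowSums(is.na(intens))
  keep <- nmiss == 0L
  if (!any(keep))
    stop("refining removed every m/z row: least-missing row still has ",
         min(nmiss), " of ", ncol(intens), " samples missing")
  spectrumSet(mz(x)[keep], intens[keep, , drop = FALSE],
              colnames(x), sampleLabels(x))
}

# Vectorized two-sided two-sample t-test over matrix rows.
# Returns p-values; rows where both groups have zero variance get p = 1.
.rowTTest <- function(intens, labels, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  g1 <- which(labels == 1)
  g0 <- which(labels == -1)
  n1 <- length(g1); n0 <- length(g0)
  if (n1 < 2L || n0 < 2L)
    stop("t-test requires at least 2 samples in each class (got ",
         n1, " cancer, ", n0, " control)")
  x1 <- intens[, g1, drop = FALSE]; x0 <- intens[, g0, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep.int(n1 + n0 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  tstat <- (m1 - m0) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se == 0] <- 1  # no within- or between-group variation: carries no signal
  p
}

#' Per-row t-test feature filter
#'
#' For each m/z row, a two-sided two-sample t-test compares cancer (+1) and
#' non-cancer (-1) intensities; rows with \code{p < alpha} are retained in
#' their original order. No multiple-testing correction is applied: the
#' filter operates at the raw significance level. A row with zero variance
#' in both groups is assigned \code{p = 1} and dropped.
#'
#' @param x a \linkS4class{RefinedSpectra} with both classes labeled.
#' @param alpha significance level in (0, 1); default 0.01.
#' @param variant \code{"pooled"} (Student, default) or \code{"welch"}.
#' @return List with \code{refined} (the filtered
#'   \linkS4class{RefinedSpectra}) and \code{filter} (a
#'   \linkS4class{FilterResult} holding all p-values).
#' @export
tFilter <- function(x, alpha = 0.01, variant = c("pooled", "welch")) {
  stopifnot(is(x, "RefinedSpectra"))
  variant <- match.arg(variant)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  labels <- sampleLabels(x)
  if (anyNA(labels)) stop("t-test filtering requires labels on all samples")
  p <- .rowTTest(intensityMatrix(x), labels, variant)
  kept <- which(p < alpha)
  fr <- new("FilterResult", pValues = p, keptIndices = as.integer(kept),
            alpha = alpha, variant = variant)
  if (!length(kept))
    stop("t-test filter retained no rows at alpha = ", alpha,
         " (minimum p = ", format(min(p), digits = 4), ")")
  filtered <- spectrumSet(mz(x)[kept],
                          intensityMatrix(x)[kept, , drop = FALSE],
                          colnames(x), labels)
  list(refined = filtered, filter = fr)
}
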