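#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.validLabels <- function(label) {
  ok <- is.na(label) | label %in% c(-1, 1)
  all(ok)
}

#' Single raw mass spectrum
#'
#' One spectrum as recorded for one sample: a strictly increasing m/z axis
#' (Da) and one intensity value (arbitrary ion-abundance units) per m/z
#' point.
#'
#' @slot sampleId single character identifier.
#' @slot mz numeric vector, strictly increasing.
#' @slot intensity numeric vector, finite, same length as \code{mz}.
#'
#' @export
setClass("RawSpectrum",
  representation(sampleId = "character", mz = "numeric",
                 intensity = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@sampleId) != 1L || is.na(object@sampleId))
      msg <- c(msg, "sampleId must be a single non-NA string")
    if (length(object@mz) != length(object@intensity))
      msg <- c(msg, "mz and intensity lengths differ")
    if (length(object@mz) && any(diff(object@mz) <= 0))
      msg <- c(msg, "mz must be strictly increasing")
    if (length(object@intensity) && !all(is.finite(object@intensity)))
      msg <- c(msg, "intensities must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Aligned spectra with explicit missingness
#'
#' A \linkS4class{SummarizedExperiment} holding spectra aligned on the
#' sorted union of all observed m/z values. Rows are m/z points (the
#' \code{mz} column of \code{rowData}), columns are samples. The single
#' assay \code{"intensity"} uses \code{NA} to mark grid points a sample did
#' not record. \code{colData$label} codes the class: \code{+1} cancer,
#' \code{-1} non-cancer (\code{NA} allowed for unlabeled data).
#'
#' @export
setClass("SpectrumSet", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    if (!"intensity" %in% assayNames(object))
      msg <- c(msg, "assay 'intensity' is required")
    if (!"mz" %in% colnames(rowData(object)))
      msg <- c(msg, "rowData column 'mz' is required")
    else {
      mzv <- rowData(object)$mz
      if (!is.numeric(mzv) || anyNA(mzv))
        msg <- c(msg, "mz must be numeric and non-NA")
      else if (length(mzv) > 1L && any(diff(mzv) <= 0))
        msg <- c(msg, "mz must be strictly increasing (no duplicates)")
    }
    if (!"label" %in% colnames(colData(object)))
      msg <- c(msg, "colData column 'label' is required")
    else if (!.validLabels(colData(object)$label))
      msg <- c(msg, "labels must be +1 (cancer), -1 (non-cancer) or NA")
    if (is.null(msg)) TRUE else msg
  })

#' Complete (refined) intensity matrix
#'
#' A \linkS4class{SpectrumSet} whose intensity matrix contains no missing
#' values: every retained m/z row was observed in every sample. Produced by
#' \code{\link{refineSpectra}}.
#'
#' @export
setClass("RefinedSpectra", contains = "SpectrumSet",
  validity = function(object) {
    if (anyNA(assay(object, "intensity")))
      "intensity matrix must be complete (no NA)" else TRUE
  })

#' Fixed-width window partition of the m/z row axis
#'
#' Half-open, consecutive, non-overlapping intervals of equal width (the
#' last may be shorter) covering all \code{nrows} rows. Width counts m/z
#' POINTS, not Daltons; the trailing partial window is retained, so the
#' number of windows is \code{ceiling(nrows / width)}.
#'
#' @slot width integer window width in m/z points.
#' @slot starts,ends integer vectors of 1-based inclusive row bounds.
#' @slot nrows total number of rows partitioned.
#'
#' @export
setClass("WindowPlan",
  representation(width = "integer", starts = "integer", ends = "integer",
                 nrows = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@width < 2L) msg <- c(msg, "width must be >= 2")
    if (length(object@starts) != length(object@ends))
      msg <- c(msg, "starts/ends length mismatch")
    else {
      if (object@starts[1L] != 1L ||
          object@ends[length(object@ends)] != object@nrows)
        msg <- c(msg, "windows must cover rows 1..nrows")
      if (length(object@starts) > 1L &&
          any(object@starts[-1L] != object@ends[-length(object@ends)] + 1L))
        msg <- c(msg, "windows must be consecutive and non-overlapping")
      len <- object@ends - object@starts + 1L
      if (any(len[-length(len)] != object@width))
        msg <- c(msg, "all windows but the last must have length width")
      if (length(object@starts) != ceiling(object@nrows / object@width))
        msg <- c(msg, "window count must be ceiling(nrows/width)")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Windowed statistical-moment features
#'
#' A \linkS4class{SummarizedExperiment} with assay \code{"features"}:
#' rows are (window, moment) pairs in window-major, moment-minor order
#' (window 1 mean, window 1 variance, ..., window 2 mean, ...), columns are
#' samples. \code{metadata()} stores the \linkS4class{WindowPlan} under
#' \code{"plan"} and the ordered moment names under \code{"momentNames"}.
#'
#' @export
setClass("MomentFeatures", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    if (!"features" %in% assayNames(object))
      msg <- c(msg, "assay 'features' is required")
    md <- metadata(object)
    if (!is(md$plan, "WindowPlan"))
      msg <- c(msg, "metadata 'plan' must be a WindowPlan")
    mm <- md$momentNames
    if (is.null(mm) ||
        !all(mm %in% c("mean", "variance", "skewness", "kurtosis")))
      msg <- c(msg, "metadata 'momentNames' must name known moments")
    else if (is(md$plan, "WindowPlan") &&
             nrow(object) != length(mm) * length(md$plan@starts))
      msg <- c(msg, "feature row count must equal k * number of windows")
    if ("label" %in% colnames(colData(object)) &&
        !.validLabels(colData(object)$label))
      msg <- c(msg, "labels must be +1, -1 or NA")
    if (is.null(msg)) TRUE else msg
  })

#' Per-row t-test filter result
#'
#' Records, for every m/z row tested, the two-sided two-sample t-test
#' p-value comparing cancer (+1) and non-cancer (-1) intensities, the
#' significance level, and the indices of rows retained (\code{p < alpha}).
#'
#' @slot pValues numeric vector of two-sided p-values, one per input row.
#' @slot keptIndices integer indices (into the input rows) with p < alpha.
#' @slot alpha significance level in (0, 1).
#' @slot variant \code{"pooled"} or \code{"welch"}.
#'
#' @export
setClass("FilterResult",
  representation(pValues = "numeric", keptIndices = "integer",
                 alpha = "numeric", variant = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@alpha <= 0 || object@alpha >= 1)
      msg <- c(msg, "alpha must be in (0, 1)")
    expect <- which(object@pValues < object@alpha)
    if (!identical(as.integer(expect), object@keptIndices))
      msg <- c(msg, "keptIndices must be exactly the rows with p < alpha")
    if (is.null(msg)) TRUE else msg
  })

#' Fitted kernel partial least squares model
#'
#' Stores everything prediction needs: the training features (for test
#' kernel evaluation), the polynomial kernel parameters, the uncentered
#' training Gram matrix (for one-sided test centering), the orthonormal
#' latent score matrix T, and the dual regression coefficients built from
#' the undeflated centered kernel.
#'
#' @slot trainFeatures numeric matrix, rows = features, columns = samples.
#' @slot degree,offset polynomial kernel parameters p and r.
#' @slot ncomp number of latent components actually extracted.
#' @slot scores n x ncomp matrix T with orthonormal columns.
#' @slot dualCoef length-n dual coefficient vector.
#' @slot yMean training response mean, restored at prediction.
#' @slot trainKernel uncentered n x n training kernel.
#'
#' @export
setClass("KPLSModel",
  representation(trainFeatures = "matrix", degree = "numeric",
                 offset = "numeric", ncomp = "integer", scores = "matrix",
                 dualCoef = "numeric", yMean = "numeric",
                 trainKernel = "matrix"),
  validity = function(object) {
    msg <- NULL
    n <- ncol(object@trainFeatures)
    if (object@ncomp < 1L || object@ncomp > n - 1L)
      msg <- c(msg, "ncomp must be in [1, n-1]")
    G <- crossprod(object@scores)
    if (max(abs(G - diag(nrow(G)))) > 1e-8)
      msg <- c(msg, "score columns must be orthonormal (T'T = I)")
    if (is.null(msg)) TRUE else msg
  })

#' Validation report for one scheme
#'
#' Per-repeat sensitivity (Sn), specificity (Sp), accuracy (Ac) and
#' Matthews correlation (CC), plus their mean and standard deviation
#' (sample SD, N-1 denominator) over repeats.
#'
#' @slot scheme scheme name ("fivefold", "proportional" or "loocv").
#' @slot nRepeats number of repeats.
#' @slot perRepeat data.frame with one row per repeat: Ac, CC, Sn, Sp.
#' @slot summary data.frame with columns metric, mean, sd.
#' @slot seed integer seed the report was generated from (NA for loocv).
#'
#' @export
setClass("ValidationReport",
  representation(scheme = "character", nRepeats = "integer",
                 perRepeat = "data.frame", summary = "data.frame",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@perRepeat) != object@nRepeats)
      msg <- c(msg, "perRepeat must have one row per repeat")
    if (!all(c("Ac", "CC", "Sn", "Sp") %in% colnames(object@perRepeat)))
      msg <- c(msg, "perRepeat must contain Ac, CC, Sn, Sp")
    if (is.null(msg)) TRUE else msg
  })

#' End-to-end pipeline configuration
#'
#' Bundles every tunable of the preprocessing + transform + classification
#' pipeline. Validated against the owning steps' preconditions at
#' construction time; see \code{\link{pipelineConfig}}.
#'
#' @slot alpha t-test significance level.
#' @slot width window width in m/z points.
#' @slot moments ordered subset of mean/variance/skewness/kurtosis.
#' @slot degree,offset polynomial kernel parameters.
#' @slot ncomp fixed number of latent components, or NA for inner-CV
#'   selection over \code{ncompCandidates}.
#' @slot ncompCandidates candidate components for automatic selection.
#' @slot tTest "pooled" or "welch".
#' @slot paperMode if TRUE, the t-filter is applied once to the full data
#'   before validation (global preprocessing); if FALSE (default) it is
#'   refit inside each training fold so held-out samples never influence
#'   filtering.
#'
#' @export
setClass("PipelineConfig",
  representation(alpha = "numeric", width = "integer", moments = "character",
                 degree = "numeric", offset = "numeric", ncomp = "integer",
                 ncompCandidates = "integer", tTest = "character",
                 paperMode = "logical"))

#' Synthetic SELDI-like data configuration
#'
#' Parameters of the synthetic spectrum generator: a shared fine m/z grid,
#' an exponentially decaying baseline, Gaussian peaks at locations shared
#' across samples, class-dependent amplitude shifts at a subset of peaks,
#' additive Gaussian noise, and per-sample random dropout of grid points.
#'
#' @slot nControl,nCancer sample counts per class.
#' @slot mzMin,mzMax grid range in Da.
#' @slot nPoints number of grid points.
#' @slot nPeaks number of Gaussian peaks (locations shared by all samples).
#' @slot peakWidth Gaussian peak sigma in Da.
#' @slot nInformativePeaks peaks whose amplitude differs between classes.
#' @slot effectSize amplitude shift at informative peaks, in units of the
#'   within-class amplitude SD.
#' @slot amplitudeSd within-class SD of peak amplitudes (intensity units).
#' @slot noiseSd additive Gaussian noise SD (intensity units).
#' @slot dropoutRate probability a grid point is missing in a given sample.
#' @slot seed integer RNG seed.
#'
#' @export
setClass("SynthConfig",
  representation(nControl = "integer", nCancer = "integer",
                 mzMin = "numeric", mzMax = "numeric", nPoints = "integer",
                 nPeaks = "integer", peakWidth = "numeric",
                 nInformativePeaks = "integer", effectSize = "numeric",
                 amplitudeSd = "numeric", noiseSd = "numeric",
                 dropoutRate = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
      msg <- c(msg, "dropoutRate must be in [0, 1)")
    if (object@nInformativePeaks > object@nPeaks)
      msg <- c(msg, "nInformativePeaks must be <= nPeaks")
    if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
    if (object@mzMax <= object@mzMin) msg <- c(msg, "mzMax must exceed mzMin")
    if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
    if (is.null(msg)) TRUE else msg
  })
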