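#' Construct a RawSpectrum
#'
#' Rows are sorted by m/z; duplicate m/z values within one spectrum are an
#' error (the union alignment relies on exact, unique m/z points).
#'
#' @param sampleId single character identifier.
#' @param mz numeric m/z values in Da.
#' @param intensity numeric intensities, same length as \code{mz}.
#' @return A \linkS4class{RawSpectrum}.
#' @examples
#' rawSpectrum("s1", c(100, 200, 300), c(1.2, 5.1, 0.4))
#' @export
rawSpectrum <- function(sampleId, mz, intensity) {
  if (anyDuplicated(mz))
    stop("duplicate m/z values in spectrum '", sampleId, "'")
  o <- order(mz)
  new("RawSpectrum", sampleId = as.character(sampleId),
      mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]))
}

#' Construct a SpectrumSet or RefinedSpectra
#'
#' @param mz strictly increasing numeric m/z axis (Da).
#' @param intensities numeric matrix, rows = m/z points, columns = samples;
#'   \code{NA} marks a grid point not observed for that sample.
#' @param sampleIds character sample identifiers (column names).
#' @param labels numeric vector of class labels, +1 = cancer,
#'   -1 = non-cancer; \code{NA} allowed for unlabeled samples.
#' @return A \linkS4class{SpectrumSet}, or a \linkS4class{RefinedSpectra}
#'   when \code{intensities} is complete.
#' @examples
#' ss <- spectrumSet(1:4, matrix(rnorm(8), 4, 2), c("a", "b"), c(1, -1))
#' @export
spectrumSet <- function(mz, intensities,
                        sampleIds = colnames(intensities),
                        labels = rep(NA_real_, ncol(intensities))) {
  intensities <- as.matrix(intensities)
  if (is.null(sampleIds))
    sampleIds <- paste0("sample", seq_len(ncol(intensities)))
  if (length(sampleIds) != ncol(intensities) ||
      length(labels) != ncol(intensities))
    stop("sampleIds and labels must match the number of intensity columns")
  dimnames(intensities) <- list(NULL, sampleIds)
  se <- SummarizedExperiment(
    assays = list(intensity = intensities),
    rowData = DataFrame(mz = as.numeric(mz)),
    colData = DataFrame(label = as.numeric(labels), row.names = sampleIds))
  cls <- if (anyNA(intensities)) "SpectrumSet" else "RefinedSpectra"
  new(cls, se)
}

#' m/z axis accessor
#'
#' The m/z values (Da) of an aligned spectrum set's rows, or of a single
#' raw spectrum's points.
#'
#' @param x a \linkS4class{SpectrumSet} or \linkS4class{RawSpectrum}.
#' @return Numeric vector of m/z values.
#' @export
setGeneric("mz", function(x) standardGeneric("mz"))

#' @rdname mz
#' @export
setMethod("mz", "SpectrumSet", function(x) rowData(x)$mz)

#' @rdname mz
#' @export
setMethod("mz", "RawSpectrum", function(x) x@mz)

#' Intensity matrix accessor
#'
#' The aligned intensity matrix, rows = m/z points, columns = samples;
#' \code{NA} marks missing observations.
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @return Numeric matrix.
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname intensityMatrix
#' @export
setMethod("intensityMatrix", "SpectrumSet",
          function(x) assay(x, "intensity"))

#' Class label accessor (+1 cancer, -1 non-cancer)
#'
#' @param x a \linkS4class{SpectrumSet} or \linkS4class{MomentFeatures}.
#' @return Numeric vector of labels, possibly with \code{NA}.
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname sampleLabels
#' @export
setMethod("sampleLabels", "SummarizedExperiment",
          function(x) colData(x)$label)

#' Moment feature matrix accessor
#'
#' Rows are (window, moment) pairs in window-major, moment-minor order;
#' columns are samples.
#'
#' @param x a \linkS4class{MomentFeatures}.
#' @return Numeric matrix.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "MomentFeatures",
          function(x) assay(x, "features"))

#' Window plan accessor
#'
#' @param x a \linkS4class{MomentFeatures}.
#' @return The \linkS4class{WindowPlan} used by the transform.
#' @export
setGeneric("windowPlan", function(x) standardGeneric("windowPlan"))

#' @rdname windowPlan
#' @export
setMethod("windowPlan", "MomentFeatures", function(x) metadata(x)$plan)

#' Ordered moment names accessor
#'
#' @param x a \linkS4class{MomentFeatures}.
#' @return Character vector, subset of mean/variance/skewness/kurtosis.
#' @export
setGeneric("momentNames", function(x) standardGeneric("momentNames"))

#' @rdname momentNames
#' @export
setMethod("momentNames", "MomentFeatures",
          function(x) metadata(x)$momentNames)

#' Number of windows in a plan
#'
#' @param x a \linkS4class{WindowPlan}.
#' @return Integer count of windows (\code{ceiling(nrows / width)}).
#' @export
nWindows <- function(x) {
  stopifnot(is(x, "WindowPlan"))
  length(x@starts)
}

setMethod("show", "RawSpectrum", function(object) {
  cat("RawSpectrum '", object@sampleId, "': ", length(object@mz),
      " points, m/z ", format(min(object@mz)), "-", format(max(object@mz)),
      "\n", sep = "")
})

setMethod("show", "WindowPlan", function(object) {
  lastLen <- object@ends[length(object@ends)] -
    object@starts[length(object@starts)] + 1L
  cat("WindowPlan: ", length(object@starts), " windows of width ",
      object@width, " over ", object@nrows, " rows",
      if (lastLen < object@width) " (last window partial)", "\n", sep = "")
})

setMethod("show", "FilterResult", function(object) {
  cat("FilterResult (", object@variant, " t-test): ",
      length(object@keptIndices), "/", length(object@pValues),
      " rows retained at alpha = ", object@alpha, "\n", sep = "")
})

setMethod("show", "KPLSModel", function(object) {
  cat("KPLSModel: polynomial kernel (degree ", object@degree, ", offset ",
      object@offset, "), ", object@ncomp, " latent components, ",
      ncol(object@trainFeatures), " training samples x ",
      nrow(object@trainFeatures), " features\n", sep = "")
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport: scheme '", object@scheme, "', ", object@nRepeats,
      " repeat(s)\n", sep = "")
  print(object@summary, row.names = FALSE, digits = 4)
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig: ", object@nControl, " controls + ", object@nCancer,
      " cancers; grid ", object@nPoints, " points over ",
      object@mzMin, "-", object@mzMax, " Da; ", object@nPeaks, " peaks (",
      object@nInformativePeaks, " informative, effect size ",
      object@effectSize, " SD); dropout ", object@dropoutRate, "\n",
      sep = "")
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig: alpha=", object@alpha, ", width=", object@width,
      ", moments={", paste(object@moments, collapse = ","), "}, kernel (p=",
      object@degree, ", r=", object@offset, "), ncomp=",
      if (is.na(object@ncomp)) "auto" else object@ncomp,
      ", t-test=", object@tTest,
      ", preprocessing=", if (object@paperMode) "global" else "in-fold",
      "\n", sep = "")
})
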