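#' Synthetic data generator configuration
#'
#' Defaults describe the regime the pipeline targets: many more m/z points
#' than samples, a smooth decaying baseline, tens of shared Gaussian peaks
#' of which a minority carry class signal as an amplitude shift, mild
#' additive noise and a small per-sample dropout rate that exercises the
#' union alignment and refining steps.
#'
#' @param nControl,nCancer samples per class (defaults 30 and 30).
#' @param mzMin,mzMax grid range in Da (defaults 2000 and 20000).
#' @param nPoints shared grid size (default 2000).
#' @param nPeaks Gaussian peaks with locations shared across samples
#'   (default 40).
#' @param peakWidth peak sigma in Da (default 60).
#' @param nInformativePeaks peaks whose mean amplitude differs between
#'   classes (default 10).
#' @param effectSize class shift at informative peaks in within-class
#'   amplitude SD units (default 5).
#' @param amplitudeSd within-class SD of peak amplitudes (default 5).
#' @param noiseSd additive Gaussian noise SD (default 1).
#' @param dropoutRate probability a grid point is missing in a given sample
#'   (default 0.01, which at realistic sample counts reproduces the order
#'   of row loss that union alignment plus refining shows on real
#'   high-resolution SELDI data).
#' @param seed integer RNG seed (default 1).
#' @return A \linkS4class{SynthConfig}.
#' @export
synthConfig <- function(nControl = 30L, nCancer = 30L, mzMin = 2000,
                        mzMax = 20000, nPoints = 2000L, nPeaks = 40L,
                        peakWidth = 60, nInformativePeaks = 10L,
                        effectSize = 5, amplitudeSd = 5, noiseSd = 1,
                        dropoutRate = 0.01, seed = 1L) {
  new("SynthConfig", nControl = as.integer(nControl),
      nCancer = as.integer(nCancer), mzMin = mzMin, mzMax = mzMax,
      nPoints = as.integer(nPoints), nPeaks = as.integer(nPeaks),
      peakWidth = peakWidth,
      nInformativePeaks = as.integer(nInformativePeaks),
      effectSize = effectSize, amplitudeSd = amplitudeSd,
      noiseSd = noiseSd, dropoutRate = dropoutRate, seed = as.integer(seed))
}

#' Generate synthetic SELDI-like spectra
#'
#' Each sample's intensity over the shared grid is an exponentially
#' decaying baseline plus Gaussian peaks at locations shared across all
#' samples plus i.i.d. Gaussian noise, truncated at zero. Peak amplitudes
#' vary per sample around a per-peak base level; in the cancer class (+1)
#' the informative peaks' base amplitude is shifted by
#' \code{effectSize * amplitudeSd}. Finally each grid point is dropped
#' independently with probability \code{dropoutRate}, so different samples
#' record different subsets of the grid. Fully reproducible from the
#' config's seed.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @return List with \code{spectra} (list of \linkS4class{RawSpectrum}),
#'   \code{labels} (+1/-1 vector, controls first), and \code{truth}
#'   (peak locations and informative-peak indices, for diagnostics).
#' @export
generateSpectra <- function(config = synthConfig()) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  set.seed(config@seed)
  grid <- seq(config@mzMin, config@mzMax, length.out = config@nPoints)
  span <- config@mzMax - config@mzMin
  centers <- sort(stats::runif(config@nPeaks,
                               config@mzMin + 0.02 * span,
                               config@mzMax - 0.02 * span))
  baseAmp <- stats::runif(config@nPeaks, 20, 100)
  informative <- if (config@nInformativePeaks > 0L)
    sort(sample.int(config@nPeaks, config@nInformativePeaks)) else integer()
  # precompute the unit peak shapes over the grid (nPoints x nPeaks)
  shapes <- vapply(centers, function(ctr)
    exp(-0.5 * ((grid - ctr) / config@peakWidth)^2), numeric(length(grid)))
  baseline <- 20 * exp(-(grid - config@mzMin) / (span / 3))
  n <- config@nControl + config@nCancer
  labels <- c(rep(-1, config@nControl), rep(1, config@nCancer))
  shift <- config@effectSize * config@amplitudeSd
  spectra <- vector("list", n)
  for (j in seq_len(n)) {
    amp <- stats::rnorm(config@nPeaks, baseAmp, config@amplitudeSd)
    if (labels[j] == 1 && length(informative))
      amp[informative] <- amp[informative] + shift
    y <- baseline + as.numeric(shapes %*% amp) +
      stats::rnorm(length(grid), 0, config@noiseSd)
    y <- pmax(y, 0)
    keep <- stats::runif(length(grid)) >= config@dropoutRate
    if (!any(keep)) keep[sample.int(length(grid), 1L)] <- TRUE
    spectra[[j]] <- rawSpectrum(
      sprintf("%s%03d", if (labels[j] == 1) "cancer" else "control", j),
      grid[keep], y[keep])
  }
  list(spectra = spectra, labels = labels,
       truth = list(centers = centers, informative = informative,
                    baseAmp = baseAmp))
}

#' Generate a null intensity matrix (no class signal)
#'
#' Every row is i.i.d. Gaussian with the same mean and SD in both classes;
#' used to calibrate the type-I error of the t-test filter.
#'
#' @param m number of rows.
#' @param nPerClass samples per class.
#' @param mean,sd distribution parameters shared by both classes.
#' @param seed integer RNG seed.
#' @return A labeled, complete \linkS4class{RefinedSpectra} with
#'   \code{nPerClass} controls followed by \code{nPerClass} cancers.
#' @export
generateNullMatrix <- function(m, nPerClass, mean = 0, sd = 1, seed = 1L) {
  m <- as.integer(m); nPerClass <- as.integer(nPerClass)
  stopifnot(m >= 1L, nPerClass >= 2L, sd > 0)
  set.seed(seed)
  n <- 2L * nPerClass
  intens <- matrix(stats::rnorm(m * n, mean, sd), m, n)
  spectrumSet(seq_len(m), intens,
              sprintf("s%03d", seq_len(n)),
              c(rep(-1, nPerClass), rep(1, nPerClass)))
}
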