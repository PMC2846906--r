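#' Construct a pipeline configuration
#'
#' Validates every tunable against the preconditions of the step that owns
#' it before any computation runs.
#'
#' @param alpha t-test significance level in (0, 1); default 0.01.
#' @param width window width in m/z points (>= 2); default 40.
#' @param moments ordered subset of
#'   \code{c("mean", "variance", "skewness", "kurtosis")}; default all
#'   four.
#' @param degree polynomial kernel degree p (default 3).
#' @param offset polynomial kernel offset r (default 1).
#' @param ncomp latent components: a fixed integer (default 5) or
#'   \code{"auto"} for inner-CV selection over \code{ncompCandidates}.
#' @param ncompCandidates candidates for automatic component selection.
#' @param tTest \code{"pooled"} (default) or \code{"welch"}.
#' @param paperMode if TRUE the t-filter runs once on the full data before
#'   validation (global preprocessing); default FALSE (leak-free in-fold
#'   preprocessing).
#' @return A \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(alpha = 0.01, width = 40L,
                           moments = c("mean", "variance", "skewness",
                                       "kurtosis"),
                           degree = 3, offset = 1, ncomp = 5L,
                           ncompCandidates = 1:10,
                           tTest = c("pooled", "welch"),
                           paperMode = FALSE) {
  tTest <- match.arg(tTest)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  width <- as.integer(width)
  if (is.na(width) || width < 2L) stop("width must be >= 2")
  moments <- match.arg(moments, .momentChoices, several.ok = TRUE)
  if (degree < 1) stop("degree must be >= 1")
  if (offset < 0) stop("offset must be >= 0")
  auto <- identical(ncomp, "auto")
  if (!auto) {
    ncomp <- as.integer(ncomp)
    if (is.na(ncomp) || ncomp < 1L) stop("ncomp must be >= 1 or \"auto\"")
  }
  ncompCandidates <- as.integer(ncompCandidates)
  if (!length(ncompCandidates) || any(ncompCandidates < 1L))
    stop("ncompCandidates must be positive integers")
  new("PipelineConfig", alpha = alpha, width = width, moments = moments,
      degree = degree, offset = offset,
      ncomp = if (auto) NA_integer_ else ncomp,
      ncompCandidates = ncompCandidates, tTest = tTest,
      paperMode = paperMode)
}

#' Run the full pipeline end to end
#'
#' Align (if raw spectra are given), refine, t-filter, transform to moment
#' features, validate with the requested scheme, and write the refined
#' matrix, p-values, features, validation report and a reproducibility
#' manifest to \code{outDir}. The manifest records the configuration, the
#' seed, MD5 checksums of every written file and the stage-by-stage
#' dimensions (union m/z rows, refined rows, filtered rows, feature rows).
#'
#' @param input a \linkS4class{SpectrumSet}/\linkS4class{RefinedSpectra},
#'   or a list with \code{spectra} and \code{labels} as returned by
#'   \code{\link{readSpectrumDir}} or \code{\link{generateSpectra}}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param outDir output directory (created if needed).
#' @param scheme validation scheme: \code{"fivefold"},
#'   \code{"proportional"} or \code{"loocv"}.
#' @param repeats repeats for the repeated schemes (default 100).
#' @param seed integer RNG seed.
#' @return Invisibly, a list with the manifest, the validation result and
#'   the written file paths.
#' @export
runPipeline <- function(input, config = pipelineConfig(),
                        outDir = ".", scheme = c("fivefold", "proportional",
                                                 "loocv"),
                        repeats = 100L, seed = 1L) {
  scheme <- match.arg(scheme)
  stage <- "align"
  result <- tryCatch({
    if (is.list(input) && !is(input, "SpectrumSet"))
      input <- alignUnion(input$spectra, input$labels)
    nUnion <- nrow(input)
    stage <- "refine"
    refined <- if (is(input, "RefinedSpectra")) input
               else refineSpectra(input)
    stage <- "t-filter"
    flt <- tFilter(refined, config@alpha, config@tTest)
    stage <- "transform"
    feats <- momentTransform(flt$refined, config@width, config@moments)
    stage <- "validate"
    val <- switch(scheme,
      fivefold = fiveFoldCV(refined, config, repeats, seed),
      proportional = proportionalValidation(refined, config,
                                            repeats = repeats, seed = seed),
      loocv = loocv(refined, config))
    list(refined = refined, flt = flt, feats = feats, val = val,
         nUnion = nUnion)
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outDir, c(refined = "refined.tsv",
                               pvalues = "pvalues.tsv",
                               features = "features.tsv",
                               report = "report.json",
                               manifest = "manifest.json"))
  names(paths) <- c("refined", "pvalues", "features", "report", "manifest")
  writeIntensityMatrix(result$refined, paths[["refined"]])
  utils::write.table(
    data.frame(mz = mz(result$refined), p = result$flt$filter@pValues),
    paths[["pvalues"]], sep = "\t", quote = FALSE, row.names = FALSE)
  writeFeatures(result$feats, paths[["features"]])
  if (is(result$val, "ValidationReport")) {
    writeValidationReport(result$val, paths[["report"]])
  } else {
    jsonlite::write_json(
      list(scheme = "loocv", metrics = as.list(result$val$metrics),
           counts = as.list(result$val$counts),
           predictions = result$val$predictions),
      paths[["report"]], auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  dims <- list(union_mz_rows = result$nUnion,
               refined_rows = nrow(result$refined),
               filtered_rows = nrow(result$flt$refined),
               feature_rows = nrow(result$feats))
  manifest <- list(
    config = list(alpha = config@alpha, width = config@width,
                  moments = config@moments, degree = config@degree,
                  offset = config@offset,
                  ncomp = if (is.na(config@ncomp)) "auto" else config@ncomp,
                  tTest = config@tTest, paperMode = config@paperMode),
    scheme = scheme, repeats = repeats, seed = seed, dimensions = dims,
    checksums = as.list(tools::md5sum(paths[names(paths) != "manifest"])))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(list(manifest = manifest, validation = result$val,
                 paths = paths))
}
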