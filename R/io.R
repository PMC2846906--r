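.detectSep <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

.splitFields <- function(line, sep) {
  if (sep == "") strsplit(trimws(line), "[[:space:]]+")[[1]]
  else trimws(strsplit(line, sep, fixed = TRUE)[[1]])
}

# Map a raw label token to +1/-1; aliases "cancer"/"control" accepted.
.parseLabel <- function(token, context = "") {
  tok <- tolower(trimws(as.character(token)))
  out <- switch(tok,
    "1" = 1, "+1" = 1, "cancer" = 1,
    "-1" = -1, "control" = -1, "non-cancer" = -1, "noncancer" = -1,
    NA_real_)
  if (is.na(out))
    stop("labeling error", context, ": unrecognized label '", token,
         "' (expected +1/-1 or cancer/control)")
  out
}

#' Read a label table
#'
#' Two delimited columns (sample id, label), header optional. Labels may be
#' \code{+1}/\code{-1} or the aliases \code{"cancer"}/\code{"control"}.
#'
#' @param path path to the label file.
#' @return Named numeric vector of +1/-1, names = sample ids.
#' @export
readLabelTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("labeling error: empty label table '", path, "'")
  sep <- .detectSep(lines[1L])
  rows <- lapply(lines, .splitFields, sep = sep)
  # drop a header line whose second field is not a parseable label
  first <- tolower(trimws(rows[[1L]][2L]))
  if (!first %in% c("1", "+1", "-1", "cancer", "control", "non-cancer",
                    "noncancer"))
    rows <- rows[-1L]
  if (!length(rows)) stop("labeling error: no label rows in '", path, "'")
  ids <- vapply(rows, `[`, "", 1L)
  labs <- vapply(seq_along(rows), function(i)
    .parseLabel(rows[[i]][2L], paste0(" in '", path, "' line ", i)), 0)
  if (anyDuplicated(ids))
    stop("labeling error: duplicate sample ids in '", path, "'")
  stats::setNames(labs, ids)
}

.readTwoColumnSpectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("input-format error: empty spectrum file '", path, "'")
  sep <- .detectSep(lines[1L])
  start <- 1L
  f1 <- .splitFields(lines[1L], sep)
  if (length(f1) >= 2L && (is.na(suppressWarnings(as.numeric(f1[1L]))) ||
                           is.na(suppressWarnings(as.numeric(f1[2L])))))
    start <- 2L  # header line
  n <- length(lines) - start + 1L
  if (n < 1L) stop("input-format error: no data rows in '", path, "'")
  mzv <- numeric(n); iv <- numeric(n)
  for (k in seq_len(n)) {
    ln <- start + k - 1L
    f <- .splitFields(lines[ln], sep)
    if (length(f) < 2L)
      stop("input-format error in '", path, "' line ", ln,
           ": expected two fields (mz, intensity)")
    vals <- suppressWarnings(as.numeric(f[1:2]))
    if (anyNA(vals))
      stop("input-format error in '", path, "' line ", ln,
           ": non-numeric value '", f[which(is.na(vals))[1L]], "'")
    mzv[k] <- vals[1L]; iv[k] <- vals[2L]
  }
  list(mz = mzv, intensity = iv)
}

#' Read a directory of per-sample spectra
#'
#' Each file holds one spectrum as two delimited columns (m/z, intensity);
#' comma, tab or whitespace separation is auto-detected and a header line is
#' optional. The sample id is the file name without extension and must
#' appear in the label table. Rows are returned sorted by m/z; a duplicate
#' m/z within one file is an error.
#'
#' @param path directory of spectrum files.
#' @param labelFile path to the label table (see
#'   \code{\link{readLabelTable}}).
#' @param pattern regular expression selecting spectrum files.
#' @return List with \code{spectra} (list of \linkS4class{RawSpectrum}) and
#'   \code{labels} (numeric +1/-1 vector, one per spectrum).
#' @export
readSpectrumDir <- function(path, labelFile,
                            pattern = "\\.(csv|tsv|txt)$") {
  files <- sort(list.files(path, pattern = pattern, full.names = TRUE))
  if (file.exists(labelFile))  # the label table may live in the same dir
    files <- files[normalizePath(files) != normalizePath(labelFile)]
  if (!length(files)) stop("input-format error: no spectrum files in '", path, "'")
  labels <- readLabelTable(labelFile)
  ids <- sub("\\.[^.]*$", "", basename(files))
  missing <- setdiff(ids, names(labels))
  if (length(missing))
    stop("labeling error: sample(s) missing from label table: ",
         paste(missing, collapse = ", "))
  spectra <- vector("list", length(files))
  for (i in seq_along(files)) {
    cols <- .readTwoColumnSpectrum(files[i])
    spectra[[i]] <- rawSpectrum(ids[i], cols$mz, cols$intensity)
  }
  list(spectra = spectra, labels = unname(labels[ids]))
}

#' Read an aligned intensity matrix
#'
#' Delimited text with a header; by default the first column is \code{mz}
#' and each remaining column is one sample. A configurable token (default
#' \code{"NA"}) and empty fields mark missing values.
#'
#' @param path path to the delimited file (tab or comma, auto-detected).
#' @param missingToken string marking a missing intensity.
#' @param samplesInRows if TRUE the file is transposed (rows = samples,
#'   first row = mz axis).
#' @param labels optional numeric label vector (+1/-1, by sample order) or
#'   path to a label table matched by sample id.
#' @return A \linkS4class{RefinedSpectra} when the matrix is complete,
#'   otherwise a \linkS4class{SpectrumSet}.
#' @export
readIntensityMatrix <- function(path, missingToken = "NA",
                                samplesInRows = FALSE, labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("format error: matrix file '", path,
                               "' needs a header and at least one row")
  sep <- .detectSep(lines[1L])
  rows <- lapply(lines, .splitFields, sep = sep)
  nf <- lengths(rows)
  if (length(unique(nf)) != 1L)
    stop("format error: ragged rows in '", path, "' (fields ",
         paste(unique(nf), collapse = "/"), ")")
  header <- rows[[1L]]
  body <- rows[-1L]
  cells <- matrix(unlist(body), nrow = length(body), byrow = TRUE)
  valcells <- cells[, -1L, drop = FALSE]
  valcells[valcells == missingToken | valcells == ""] <- NA_character_
  num <- suppressWarnings(matrix(as.numeric(valcells), nrow = nrow(valcells)))
  bad <- which(is.na(num) & !is.na(valcells), arr.ind = TRUE)
  if (nrow(bad))
    stop("format error in '", path, "' row ", bad[1L, 1L] + 1L,
         ": non-numeric value '", valcells[bad[1L, , drop = FALSE]], "'")
  if (samplesInRows) {
    # rows = samples: first header field is a corner label, remaining
    # header fields are the mz axis; first column holds sample ids
    mzv <- suppressWarnings(as.numeric(header[-1L]))
    sampleIds <- cells[, 1L]
    intens <- t(num)
  } else {
    mzv <- suppressWarnings(as.numeric(cells[, 1L]))
    intens <- num
    sampleIds <- header[-1L]
  }
  if (anyNA(mzv)) stop("format error: non-numeric mz values in '", path, "'")
  if (anyDuplicated(mzv))
    stop("format error: duplicate mz rows in '", path, "'")
  o <- order(mzv)
  mzv <- mzv[o]; intens <- intens[o, , drop = FALSE]
  labv <- rep(NA_real_, length(sampleIds))
  if (!is.null(labels)) {
    if (is.character(labels) && length(labels) == 1L) {
      tab <- readLabelTable(labels)
      miss <- setdiff(sampleIds, names(tab))
      if (length(miss))
        stop("labeling error: sample(s) missing from label table: ",
             paste(miss, collapse = ", "))
      labv <- unname(tab[sampleIds])
    } else labv <- vapply(labels, .parseLabel, 0)
  }
  spectrumSet(mzv, intens, sampleIds, labv)
}

#' Write an aligned intensity matrix
#'
#' Tab-delimited, first column \code{mz}, one column per sample, \code{NA}
#' for missing cells. Values are written at full precision so that a
#' write/read round trip is exact.
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeIntensityMatrix <- function(x, path) {
  stopifnot(is(x, "SpectrumSet"))
  df <- data.frame(mz = format(mz(x), digits = 17, trim = TRUE),
                   format(intensityMatrix(x), digits = 17, trim = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("mz", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a moment feature matrix
#'
#' Tab-delimited, first column \code{feature} (window index and moment
#' name), one column per sample, full precision.
#'
#' @param x a \linkS4class{MomentFeatures}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatures <- function(x, path) {
  stopifnot(is(x, "MomentFeatures"))
  fm <- featureMatrix(x)
  df <- data.frame(feature = rownames(fm),
                   format(fm, digits = 17, trim = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("feature", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by \code{writeFeatures}
#'
#' @param path path to the tab-delimited feature file.
#' @return Numeric matrix, rows = features (named), columns = samples.
#' @export
readFeatureMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write a validation report
#'
#' Machine-parseable JSON holding the scheme name, repeat count, seed,
#' per-metric mean and SD, and the per-repeat metric table.
#'
#' @param report a \linkS4class{ValidationReport}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeValidationReport <- function(report, path) {
  stopifnot(is(report, "ValidationReport"))
  if (report@nRepeats < 1L)
    stop("refusing to write an empty report (0 repeats)")
  obj <- list(
    scheme = report@scheme,
    n_repeats = report@nRepeats,
    seed = if (is.na(report@seed)) NULL else report@seed,
    summary = lapply(split(report@summary, report@summary$metric),
                     function(r) list(mean = r$mean, sd = r$sd)),
    per_repeat = report@perRepeat)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
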