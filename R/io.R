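#' Read a mass spectrum from disk
#'
#' Supports single-spectrum mzML files (via the \pkg{mzR} proteowizard
#' bindings) and two-column delimited text.  The text dialect is
#' deliberately permissive towards lab exports: comma, tab or whitespace
#' delimiters are auto-detected, and lines starting with `#` are comments.
#' Unsorted input is sorted by m/z; duplicate m/z values are merged by
#' summing their intensities; negative intensities are clipped to zero and
#' the clipping is recorded in the metadata.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"mzml"`, `"txt"`.  `"auto"` decides by
#'   file extension (`.mzml` vs anything else).
#' @return A [mass_spectrum()].
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, format = c("auto", "mzml", "txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("spectrum file not found: '%s'", path), call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "txt"
  }
  switch(format,
         mzml = read_spectrum_mzml(path),
         txt  = read_spectrum_txt(path))
}

read_spectrum_txt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop(sprintf("empty spectrum: no data rows in '%s'", path), call. = FALSE)
  }
  # normalize delimiters (comma / tab / runs of spaces) to single spaces
  norm <- gsub("[,\t ]+", " ", lines)
  parts <- strsplit(trimws(norm), " ", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 2L
  if (any(bad)) {
    stop(sprintf("non-numeric or malformed row in '%s' (line starting '%s')",
                 path, substr(lines[which(bad)[1]], 1, 30)), call. = FALSE)
  }
  mz <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(mz) || anyNA(it)) {
    i <- which(is.na(mz) | is.na(it))[1]
    stop(sprintf("non-numeric row in '%s' (line starting '%s')",
                 path, substr(lines[i], 1, 30)), call. = FALSE)
  }
  spectrum_from_points(mz, it, meta = list(source = path, format = "txt"))
}

read_spectrum_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML support requires the 'mzR' package", call. = FALSE)
  }
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) stop(sprintf(
                       "unreadable mzML file '%s': %s", path, conditionMessage(e)),
                       call. = FALSE))
  on.exit(mzR::close(handle))
  if (length(handle) < 1L) {
    stop(sprintf("empty spectrum: no spectra in '%s'", path), call. = FALSE)
  }
  pk <- mzR::peaks(handle, 1L)
  if (NROW(pk) == 0L) {
    stop(sprintf("empty spectrum: no data points in '%s'", path), call. = FALSE)
  }
  spectrum_from_points(pk[, 1], pk[, 2],
                       meta = list(source = path, format = "mzml"))
}

#' Write a mass spectrum to disk
#'
#' The text format writes `# key: value` metadata comment lines followed by
#' tab-separated `m/z<TAB>intensity` rows at full double precision, so a
#' read/write round trip preserves the arrays to within float formatting
#' tolerance.  The mzML format is written through \pkg{mzR} (64-bit float
#' arrays) and round-trips exactly.
#'
#' @param spectrum a [mass_spectrum()].
#' @param path output file path.
#' @param format `"txt"` or `"mzml"`.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spectrum, path, format = c("txt", "mzml")) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  format <- match.arg(format)
  if (format == "txt") {
    header <- "# m/z\tintensity"
    meta <- spectrum$meta
    meta_lines <- if (length(meta)) {
      vapply(names(meta), function(k) sprintf("# %s: %s", k,
             paste(format(meta[[k]]), collapse = " ")), "")
    } else character(0)
    body <- sprintf("%.17g\t%.17g", spectrum$mz, spectrum$intensity)
    ok <- tryCatch({
      writeLines(c(meta_lines, header, body), path)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(path)) {
      stop(sprintf("cannot write spectrum to '%s'", path), call. = FALSE)
    }
  } else {
    write_spectrum_mzml(spectrum, path)
  }
  invisible(path)
}

write_spectrum_mzml <- function(spectrum, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML support requires the 'mzR' package", call. = FALSE)
  }
  mz <- spectrum$mz
  it <- spectrum$intensity
  n <- length(mz)
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = n, totIonCurrent = sum(it), retentionTime = 0,
    basePeakMZ = mz[which.max(it)], basePeakIntensity = max(it),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(mz), highMZ = max(mz),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = "spectrum=1", centroided = FALSE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = min(mz), scanWindowUpperLimit = max(mz),
    stringsAsFactors = FALSE)
  tryCatch(
    mzR::writeMSData(list(cbind(mz, it)), file = path, header = hdr,
                     outformat = "mzml"),
    error = function(e) stop(sprintf("cannot write mzML to '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  if (!file.exists(path)) {
    stop(sprintf("cannot write mzML to '%s'", path), call. = FALSE)
  }
  invisible(path)
}
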