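#' Construct a mass spectrum
#'
#' The central data container of the package: a pair of parallel numeric
#' vectors holding the m/z axis (Th, strictly increasing) and the measured
#' intensity (arbitrary units, non-negative), plus free-form acquisition
#' metadata.
#'
#' @param mz numeric vector of m/z values; must be finite, positive and
#'   strictly increasing.
#' @param intensity numeric vector of intensities, same length as `mz`;
#'   must be finite and non-negative.
#' @param meta named list of acquisition metadata (instrument, number of
#'   laser events, calibration status, ...).
#' @return An object of class `mass_spectrum`: a list with elements `mz`,
#'   `intensity` and `meta`.
#' @examples
#' s <- mass_spectrum(c(100, 200, 300), c(1, 5, 2))
#' length(s$mz)
#' @export
mass_spectrum <- function(mz, intensity, meta = list()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) == 0L) {
    stop("empty spectrum: no data points", call. = FALSE)
  }
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length", call. = FALSE)
  }
  if (anyNA(mz) || any(!is.finite(mz))) {
    stop("mz contains NA or non-finite values", call. = FALSE)
  }
  if (any(mz <= 0)) {
    stop("mz values must be positive", call. = FALSE)
  }
  if (is.unsorted(mz, strictly = TRUE)) {
    stop("mz must be strictly increasing (use spectrum_from_points() to sort/merge raw data)",
         call. = FALSE)
  }
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    stop("intensity contains NA or non-finite values", call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("intensity must be non-negative", call. = FALSE)
  }
  structure(list(mz = mz, intensity = intensity, meta = as.list(meta)),
            class = "mass_spectrum")
}

#' Build a spectrum from possibly unsorted raw points
#'
#' Sorts by m/z, merges duplicate m/z values by summing their intensities
#' (conserving total ion count), and clips negative intensities to zero,
#' recording in the metadata that clipping occurred.
#'
#' @inheritParams mass_spectrum
#' @return A `mass_spectrum`.
#' @export
spectrum_from_points <- function(mz, intensity, meta = list()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) == 0L) stop("empty spectrum: no data points", call. = FALSE)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length", call. = FALSE)
  }
  ord <- order(mz)
  mz <- mz[ord]
  intensity <- intensity[ord]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
    meta$merged_duplicates <- TRUE
  }
  if (any(intensity < 0, na.rm = TRUE)) {
    intensity[intensity < 0] <- 0
    meta$clipped_negative <- TRUE
  }
  mass_spectrum(mz, intensity, meta)
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum: %d points, m/z %.2f..%.2f, max intensity %.4g>\n",
              length(x$mz), min(x$mz), max(x$mz), max(x$intensity)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.mass_spectrum <- function(x) length(x$mz)

#' @export
as.data.frame.mass_spectrum <- function(x, ...) {
  data.frame(mz = x$mz, intensity = x$intensity)
}

#' Restrict a spectrum to an m/z window
#'
#' @param spectrum a `mass_spectrum`.
#' @param low,high window bounds (Th), inclusive.
#' @return A `mass_spectrum` containing only points with `low <= mz <= high`.
#' @export
crop_spectrum <- function(spectrum, low, high) {
  stopifnot(inherits(spectrum, "mass_spectrum"), low < high)
  keep <- spectrum$mz >= low & spectrum$mz <= high
  if (!any(keep)) stop("no data points in the requested m/z window", call. = FALSE)
  mass_spectrum(spectrum$mz[keep], spectrum$intensity[keep], spectrum$meta)
}

# run expr with a private RNG state so package internals never disturb the
# caller's random stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
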