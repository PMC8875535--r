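#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing of the intensity trace (the
#' m/z axis is untouched).  The filter reproduces any polynomial of degree
#' at most `polyorder` exactly; edges are handled by evaluating the fit of
#' the first/last full window at the boundary points, so no padding
#' artifacts are introduced.  Backed by \code{signal::sgolayfilt}.
#'
#' @param spectrum a [mass_spectrum()].
#' @param window odd integer filter length in points; must exceed
#'   `polyorder` and not exceed the spectrum length.
#' @param polyorder integer polynomial order, `< window`.
#' @return A smoothed `mass_spectrum` (negative smoothed values are kept;
#'   clip downstream if needed).
#' @export
savitzky_golay <- function(spectrum, window = 11L, polyorder = 3L) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be smaller than window", call. = FALSE)
  n <- length(spectrum$mz)
  if (n < window) stop("window larger than the spectrum", call. = FALSE)
  d <- diff(spectrum$mz)
  if ((max(d) - min(d)) / stats::median(d) > 0.10) {
    warning("m/z spacing varies by more than 10%; Savitzky-Golay assumes a uniform grid")
  }
  sm <- signal::sgolayfilt(spectrum$intensity, p = polyorder, n = window)
  out <- spectrum
  out$intensity <- sm
  out$meta$savitzky_golay <- c(window = window, polyorder = polyorder)
  # bypass the non-negativity check of the constructor: SG may undershoot
  class(out) <- "mass_spectrum"
  out
}

#' SNIP baseline estimation
#'
#' Statistics-sensitive nonlinear iterative peak clipping.  For clipping
#' half-window m = 1..`iterations` (classic increasing order; set
#' `decreasing = TRUE` for the reverse schedule), each interior point is
#' replaced by the minimum of itself and the mean of its two neighbours at
#' distance m:
#' \deqn{y_i \leftarrow \min\{y_i, (y_{i-m} + y_{i+m})/2\}.}
#' Endpoints are held fixed.  With `lls = TRUE` the clipping runs in
#' log-log-square-root compressed space (`log(log(sqrt(y+1)+1)+1)`),
#' which de-emphasizes tall peaks; the transform is inverted before
#' returning.  The returned baseline never exceeds the input anywhere.
#'
#' @param spectrum a [mass_spectrum()].
#' @param iterations maximum clipping half-window in points (>= 1); the
#'   spectrum must be longer than `2 * iterations`.
#' @param lls apply the LLS compression (default `FALSE`: linear space, in
#'   which the baseline of a straight line is the line itself).
#' @param decreasing run m from `iterations` down to 1 instead of up.
#' @return A `mass_spectrum` holding the estimated baseline.
#' @seealso [subtract_baseline()], [snip_iterations_for_fwhm()]
#' @export
snip_baseline <- function(spectrum, iterations, lls = FALSE, decreasing = FALSE) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  n <- length(spectrum$mz)
  if (n <= 2L * iterations) {
    stop("iterations too large for the spectrum length", call. = FALSE)
  }
  y <- spectrum$intensity
  if (lls) y <- log(log(sqrt(y + 1) + 1) + 1)
  ms <- seq_len(iterations)
  if (decreasing) ms <- rev(ms)
  for (m in ms) {
    idx <- (m + 1L):(n - m)
    y[idx] <- pmin(y[idx], (y[idx - m] + y[idx + m]) / 2)
  }
  if (lls) y <- (exp(exp(y) - 1) - 1)^2 - 1
  # guard against round-off pushing the transform inverse above the input
  y <- pmin(y, spectrum$intensity)
  out <- spectrum
  out$intensity <- y
  out$meta$snip <- c(iterations = iterations, lls = lls, decreasing = decreasing)
  out
}

#' Pick a SNIP clipping width from an expected peak width
#'
#' Rule of thumb: the clipping half-window should comfortably exceed the
#' peak half-width, so `iterations = round(2 * fwhm_points)` (i.e. half of
#' four full widths).
#'
#' @param fwhm_points expected peak FWHM in grid points.
#' @return Integer iteration count, at least 1.
#' @export
snip_iterations_for_fwhm <- function(fwhm_points) {
  max(1L, as.integer(round(0.5 * fwhm_points * 4)))
}

#' Subtract a baseline from a spectrum
#'
#' @param spectrum a [mass_spectrum()].
#' @param baseline a `mass_spectrum` on the identical m/z grid (e.g. from
#'   [snip_baseline()]).
#' @param clip_negative clip the difference at zero (default `TRUE`).
#' @return The baseline-subtracted `mass_spectrum`.
#' @export
subtract_baseline <- function(spectrum, baseline, clip_negative = TRUE) {
  stopifnot(inherits(spectrum, "mass_spectrum"), inherits(baseline, "mass_spectrum"))
  if (length(spectrum$mz) != length(baseline$mz) ||
      any(spectrum$mz != baseline$mz)) {
    stop("spectrum and baseline must share an identical m/z grid", call. = FALSE)
  }
  y <- spectrum$intensity - baseline$intensity
  if (clip_negative) y[y < 0] <- 0
  out <- spectrum
  out$intensity <- y
  out$meta$baseline_subtracted <- TRUE
  class(out) <- "mass_spectrum"
  out
}

#' Smooth and baseline-correct a spectrum in one call
#'
#' Convenience wrapper chaining [savitzky_golay()], [snip_baseline()] and
#' [subtract_baseline()].  If `snip_iterations` is `NULL` it is derived
#' from the FWHM (in points) of the tallest peak of the smoothed spectrum
#' via [snip_iterations_for_fwhm()], capped so SNIP stays applicable.
#'
#' @param spectrum a [mass_spectrum()].
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param snip_iterations SNIP clipping width in points, or `NULL` to
#'   derive from the data.
#' @param snip_lls run SNIP in LLS-compressed space.
#' @param clip_negative clip negative intensities after subtraction.
#' @return The preprocessed `mass_spectrum`; the estimated baseline is
#'   attached as attribute `"baseline"`.
#' @export
preprocess_spectrum <- function(spectrum, sg_window = 11L, sg_polyorder = 3L,
                                snip_iterations = NULL, snip_lls = FALSE,
                                clip_negative = TRUE) {
  sm <- savitzky_golay(spectrum, sg_window, sg_polyorder)
  smc <- sm
  smc$intensity <- pmax(smc$intensity, 0)
  if (is.null(snip_iterations)) {
    w_pts <- tryCatch({
      w <- fwhm(smc$mz, smc$intensity)
      w / stats::median(diff(smc$mz))
    }, error = function(e) 10)
    snip_iterations <- snip_iterations_for_fwhm(w_pts)
  }
  snip_iterations <- min(as.integer(snip_iterations),
                         (length(spectrum$mz) - 1L) %/% 2L)
  bl <- snip_baseline(smc, snip_iterations, lls = snip_lls)
  out <- subtract_baseline(smc, bl, clip_negative = clip_negative)
  attr(out, "baseline") <- bl
  out
}
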