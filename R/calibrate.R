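#' Mass of a proton in Da (charge adduction; average-mass regime)
#' @export
PROTON_MASS <- 1.007276

#' Theoretical m/z of a charged species
#'
#' @param mass neutral (average) mass in Da.
#' @param z positive integer charge.
#' @return `(mass + z * 1.007276) / z` in Th.
#' @export
mz_of <- function(mass, z) {
  stopifnot(all(z >= 1))
  (mass + z * PROTON_MASS) / z
}

#' Polynomial mass calibration against reference species
#'
#' Fits a degree-1 or degree-2 polynomial mapping observed m/z positions to
#' the theoretical m/z of reference calibrants (e.g. BSA and its
#' multiply-charged ions spanning the mass range of interest) by ordinary
#' least squares, and applies it to the spectrum's m/z axis.  Reference m/z
#' values are computed as `(M + z * 1.007276) / z` from the supplied neutral
#' masses and charges.
#'
#' @param spectrum a [mass_spectrum()].
#' @param observed_peaks numeric vector of observed calibrant peak
#'   positions (Th).
#' @param reference_masses a data frame (or 2-column matrix) with columns
#'   `mass` (neutral Da) and `z` (charge), one row per calibrant, in the
#'   same order as `observed_peaks`.
#' @param degree polynomial degree, 1 or 2.  Needs at least `degree + 1`
#'   calibrants.
#' @return A list with `spectrum` (corrected m/z axis; metadata gains
#'   `calibrated = TRUE`) and `model` (class `calibration_model`: `degree`,
#'   `coefficients` in increasing power order, `residuals` per calibrant in
#'   Th, `reference_mz`, `observed_mz`).
#' @export
calibrate <- function(spectrum, observed_peaks, reference_masses, degree = 1) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2", call. = FALSE)
  ref <- as.data.frame(reference_masses)
  if (ncol(ref) < 2) stop("reference_masses needs columns mass and z", call. = FALSE)
  names(ref)[1:2] <- c("mass", "z")
  obs <- as.numeric(observed_peaks)
  if (length(obs) != nrow(ref)) {
    stop("observed_peaks and reference_masses must have the same length",
         call. = FALSE)
  }
  if (length(obs) < degree + 1) {
    stop(sprintf("need at least %d calibrants for degree %d", degree + 1, degree),
         call. = FALSE)
  }
  if (anyDuplicated(obs)) {
    stop("degenerate calibration: duplicate observed calibrant positions",
         call. = FALSE)
  }
  ref_mz <- mz_of(ref$mass, ref$z)
  fit <- stats::lm(ref_mz ~ stats::poly(obs, degree, raw = TRUE))
  coefs <- unname(stats::coef(fit))
  model <- structure(list(degree = degree,
                          coefficients = coefs,
                          residuals = unname(stats::residuals(fit)),
                          reference_mz = ref_mz,
                          observed_mz = obs),
                     class = "calibration_model")
  corrected <- apply_calibration(model, spectrum$mz)
  meta <- spectrum$meta
  meta$calibrated <- TRUE
  list(spectrum = mass_spectrum(corrected, spectrum$intensity, meta),
       model = model)
}

#' Apply a calibration model to m/z values
#'
#' @param model a `calibration_model` from [calibrate()].
#' @param mz numeric vector of observed m/z values.
#' @return Corrected m/z values.
#' @export
apply_calibration <- function(model, mz) {
  stopifnot(inherits(model, "calibration_model"))
  drop(outer(mz, seq_len(model$degree + 1) - 1, `^`) %*% model$coefficients)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model: degree %d, %d calibrants, max |residual| %.4g Th>\n",
              x$degree, length(x$residuals), max(abs(x$residuals))))
  invisible(x)
}

#' Full width at half maximum of a single peak
#'
#' Generic peak-width measure usable on mass peaks and chromatographic
#' (e.g. SEC) traces alike.  The half height is taken at
#' `base + (max - base) / 2` where `base` is the lower of the two endpoint
#' values; the two crossings flanking the global maximum are located by
#' linear interpolation.
#'
#' @param x numeric vector of positions (strictly increasing).
#' @param y numeric vector of heights, same length; must attain a unique
#'   interior global maximum strictly above both endpoints.
#' @return The width at half maximum, in the units of `x`.
#' @examples
#' x <- seq(-5, 5, length.out = 2001)
#' fwhm(x, exp(-x^2 / 2))  # 2.3548 for a sigma = 1 Gaussian
#' @export
fwhm <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (is.unsorted(x, strictly = TRUE)) stop("x must be strictly increasing", call. = FALSE)
  imax <- which.max(y)
  n <- length(y)
  if (imax == 1L || imax == n || y[imax] <= max(y[1], y[n])) {
    stop("no interior maximum: curve has no well-defined peak", call. = FALSE)
  }
  base <- min(y[1], y[n])
  half <- base + (y[imax] - base) / 2
  # left crossing: last index before the peak with y <= half
  left_idx <- which(y[1:(imax - 1)] <= half)
  right_idx <- which(y[(imax + 1):n] <= half)
  if (length(left_idx) == 0L || length(right_idx) == 0L) {
    stop("half-maximum level not crossed on both sides of the peak", call. = FALSE)
  }
  i <- max(left_idx)                       # y[i] <= half < y[i+1]
  xl <- x[i] + (half - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
  j <- imax + min(right_idx)               # y[j-1] > half >= y[j]
  xr <- x[j - 1] + (half - y[j - 1]) / (y[j] - y[j - 1]) * (x[j] - x[j - 1])
  xr - xl
}
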