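# shared builders for synthetic test spectra

gaussian_trace <- function(x, center, sigma, amplitude = 1) {
  amplitude * exp(-(x - center)^2 / (2 * sigma^2))
}

# spectrum made of explicit Gaussians on a uniform grid (no noise)
multi_gaussian_spectrum <- function(lo, hi, n, centers, sigmas, amplitudes,
                                    baseline = 0) {
  x <- seq(lo, hi, length.out = n)
  y <- rep(baseline, n)
  for (k in seq_along(centers)) {
    y <- y + gaussian_trace(x, centers[k], sigmas[k], amplitudes[k])
  }
  mass_spectrum(x, y)
}

# independent brute-force SNIP (double loop, no vectorization tricks)
snip_bruteforce <- function(y, iterations) {
  n <- length(y)
  for (m in seq_len(iterations)) {
    z <- y
    for (i in (m + 1):(n - m)) {
      z[i] <- min(y[i], (y[i - m] + y[i + m]) / 2)
    }
    y <- z
  }
  y
}

expect_spectra_equal <- function(a, b, tol = 1e-6) {
  expect_equal(a$mz, b$mz, tolerance = tol)
  expect_equal(a$intensity, b$intensity, tolerance = tol)
}
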