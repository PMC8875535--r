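#' Describe the expected conjugate ion ladder
#'
#' A carrier protein bearing 0..n copies of a peptide appears, at charge
#' `z`, as a series of peaks spaced `delta / z` apart.  This object
#' parameterizes that series for deconvolution.
#'
#' @param M0 neutral mass (Da) of the load-0 species (carrier including any
#'   activation/capping adducts).  Not refit; residual inaccuracy is
#'   absorbed by the bounded global shift during fitting.
#' @param delta neutral mass increment (Da) per additionally conjugated
#'   peptide — see [ladder_spacing()] and [predict_species_masses()].
#' @param z charge state of the fitted series (doubly charged by default,
#'   the dominant series in linear MALDI of ~60 kDa conjugates).
#' @param n_min,n_max integer peptide-load range covered by the fit.
#' @return An object of class `conjugate_ladder`.
#' @export
conjugate_ladder <- function(M0, delta, z = 2L, n_min = 0L, n_max = 10L) {
  stopifnot(M0 > 0, delta > 0, z >= 1, n_min >= 0, n_max >= n_min)
  structure(list(M0 = M0, delta = delta, z = as.integer(z),
                 n_min = as.integer(n_min), n_max = as.integer(n_max),
                 global_shift = 0),
            class = "conjugate_ladder")
}

#' @export
print.conjugate_ladder <- function(x, ...) {
  cat(sprintf("<conjugate_ladder: M0 %.1f Da, delta %.2f Da, z %d, loads %d..%d>\n",
              x$M0, x$delta, x$z, x$n_min, x$n_max))
  invisible(x)
}

#' Predicted m/z centers of a conjugate ladder
#'
#' `center(n) = (M0 + n * delta + z * 1.007276) / z`, so consecutive
#' centers are exactly `delta / z` apart.
#'
#' @param M0,delta,z as in [conjugate_ladder()]; alternatively pass a
#'   `conjugate_ladder` as `M0`.
#' @param n_range integer vector `c(n_min, n_max)`.
#' @return A data frame with columns `load` and `center` (Th).
#' @export
predict_ladder <- function(M0, delta = NULL, z = NULL, n_range = NULL) {
  if (inherits(M0, "conjugate_ladder")) {
    l <- M0
    if (is.null(n_range)) n_range <- c(l$n_min, l$n_max)
    M0 <- l$M0; delta <- l$delta; z <- l$z
  }
  stopifnot(delta > 0, z >= 1, length(n_range) == 2, n_range[1] <= n_range[2],
            n_range[1] >= 0)
  n <- seq.int(n_range[1], n_range[2])
  data.frame(load = n, center = mz_of(M0 + n * delta, z))
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2) * (N - 1) / (N - n_params - 1)` with
#' `R^2 = 1 - SS_res / SS_tot`; the cumulative-fit quality measure used to
#' judge a ladder deconvolution.
#'
#' @param observed,fitted numeric vectors of equal length `N`.
#' @param n_params number of free model parameters; must satisfy
#'   `N > n_params + 1`.
#' @return A value in `(-Inf, 1]`.
#' @export
adjusted_r2 <- function(observed, fitted, n_params) {
  observed <- as.numeric(observed); fitted <- as.numeric(fitted)
  N <- length(observed)
  stopifnot(length(fitted) == N, N > n_params + 1)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("zero total variance: observed data are constant", call. = FALSE)
  r2 <- 1 - sum((observed - fitted)^2) / ss_tot
  1 - (1 - r2) * (N - 1) / (N - n_params - 1)
}

#' Options controlling the ladder fit
#'
#' @param width_model `"shared"` (one Gaussian sigma for the whole series,
#'   the default: linear-TOF resolution varies slowly over one ladder's
#'   span) or `"linear"` (sigma is an affine function of m/z).
#' @param shift_bound bound (Th) on the fitted global center shift common
#'   to all peaks; default `0.2 * delta / z`, absorbing calibration error
#'   while keeping load assignment unambiguous.
#' @param jitter_bound bound (Th) on the per-peak center jitter; default
#'   `0.05 * delta / z`.  Set to 0 to pin centers to the shifted ladder.
#' @param prune_threshold fraction of the maximum fitted amplitude below
#'   which leading/trailing species are dropped (followed by one refit);
#'   pruning works inward from the range ends so surviving loads stay
#'   contiguous.
#' @param snr_prune detection-limit multiplier: end species whose fitted
#'   amplitude is below `snr_prune` times the residual RMS of the first
#'   fit are also pruned (the classic S/N >= 3 limit of detection).  Set
#'   to 0 to disable.
#' @param background `"constant"` (default) adds one flat background term
#'   to the Gaussian series, absorbing the small positive offset that SNIP
#'   subtraction leaves under noise; `"none"` fits the bare series.
#' @param sigma_init initial Gaussian sigma (Th), or `NULL` to estimate
#'   from the tallest peak's FWHM.
#' @param window_pad fit-window margin on each side of the outermost
#'   predicted centers, in multiples of the initial sigma.
#' @param max_restarts maximum number of perturbed-initialization restarts
#'   on non-convergence.
#' @param seed integer seed driving restart perturbations (the fit is
#'   otherwise deterministic).
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(width_model = c("shared", "linear"),
                        shift_bound = NULL, jitter_bound = NULL,
                        prune_threshold = 0.01, snr_prune = 3,
                        background = c("constant", "none"),
                        sigma_init = NULL,
                        window_pad = 5, max_restarts = 3, seed = 1L) {
  structure(list(width_model = match.arg(width_model),
                 shift_bound = shift_bound, jitter_bound = jitter_bound,
                 prune_threshold = prune_threshold, snr_prune = snr_prune,
                 background = match.arg(background),
                 sigma_init = sigma_init,
                 window_pad = window_pad, max_restarts = max_restarts,
                 seed = as.integer(seed)),
            class = "fit_control")
}

# model and analytic Jacobian of the Gaussian series ------------------------

ladder_model_eval <- function(par, x, K, centers0, xmid, width_model,
                              background) {
  A <- par[1:K]
  shift <- par[K + 1]
  jit <- par[(K + 2):(2 * K + 1)]
  cn <- centers0 + shift + jit
  n_sig <- if (width_model == "shared") 1L else 2L
  sig <- if (width_model == "shared") rep(par[2 * K + 2], length(x))
         else par[2 * K + 2] + par[2 * K + 3] * (x - xmid)
  y <- numeric(length(x))
  G <- matrix(0, length(x), K)
  for (k in seq_len(K)) {
    G[, k] <- exp(-(x - cn[k])^2 / (2 * sig^2))
    y <- y + A[k] * G[, k]
  }
  if (background == "constant") y <- y + par[2 * K + 1 + n_sig + 1]
  list(y = y, G = G, cn = cn, sig = sig)
}

ladder_residual <- function(par, x, yobs, K, centers0, xmid, width_model,
                            background) {
  yobs - ladder_model_eval(par, x, K, centers0, xmid, width_model, background)$y
}

ladder_jacobian <- function(par, x, yobs, K, centers0, xmid, width_model,
                            background) {
  ev <- ladder_model_eval(par, x, K, centers0, xmid, width_model, background)
  A <- par[1:K]
  sig <- ev$sig
  npar <- length(par)
  J <- matrix(0, length(x), npar)
  dshift <- numeric(length(x))
  dsig_common <- numeric(length(x))
  for (k in seq_len(K)) {
    dx <- x - ev$cn[k]
    gk <- ev$G[, k]
    J[, k] <- -gk                                  # d r / d A_k
    dcdk <- -A[k] * gk * dx / sig^2                # d r / d c_k  (r = y - model)
    J[, K + 1 + k] <- dcdk                         # jitter_k
    dshift <- dshift + dcdk
    dsig_common <- dsig_common - A[k] * gk * dx^2 / sig^3
  }
  J[, K + 1] <- dshift
  n_sig <- if (width_model == "shared") 1L else 2L
  J[, 2 * K + 2] <- dsig_common
  if (width_model == "linear") J[, 2 * K + 3] <- dsig_common * (x - xmid)
  if (background == "constant") J[, 2 * K + 1 + n_sig + 1] <- -1
  J
}

#' Fit a conjugate ion ladder as a constrained Gaussian series
#'
#' Nonlinear (bounded Levenberg-Marquardt) least squares of
#' \deqn{y(x) = \sum_n A_n \exp\{-(x - c_n)^2 / (2\sigma_n^2)\}}
#' over the m/z window spanned by the predicted ladder, with non-negative
#' amplitudes, centers `c_n = predicted(n) + shift + jitter_n` constrained
#' by bounded global shift and per-peak jitter, and either one shared width
#' or a width linear in m/z.  Amplitudes are initialized from the local
#' maxima nearest the predicted centers; on non-convergence the fit is
#' restarted (up to `max_restarts` times) from perturbed initializations
#' drawn from a seeded private RNG.  Species at the range ends whose fitted
#' amplitude falls below `prune_threshold` times the maximum amplitude are
#' removed and the reduced model refit once.
#'
#' The input is expected to be smoothed and baseline-subtracted
#' (see [preprocess_spectrum()]).
#'
#' @param spectrum a preprocessed [mass_spectrum()].
#' @param ladder a [conjugate_ladder()].
#' @param control a [fit_control()].
#' @return An object of class `deconvolution_result`: `peaks` (data frame
#'   with `load`, `center`, `sigma`, `amplitude`, `area
#'   = amplitude * sigma * sqrt(2*pi)`, ordered by load), `adj_r2`,
#'   `residual_rms`, `ladder` (with the fitted `global_shift`),
#'   `fit_window`, `converged`, `n_params`, and the windowed `mz`/
#'   `observed`/`fitted` traces for diagnostics.
#' @export
fit_ladder <- function(spectrum, ladder, control = fit_control()) {
  stopifnot(inherits(spectrum, "mass_spectrum"),
            inherits(ladder, "conjugate_ladder"),
            inherits(control, "fit_control"))
  if (all(spectrum$intensity == 0)) {
    stop("all-zero spectrum: nothing to fit", call. = FALSE)
  }
  spacing <- ladder$delta / ladder$z
  pred <- predict_ladder(ladder)
  shift_bound <- if (is.null(control$shift_bound)) 0.2 * spacing else control$shift_bound
  jitter_bound <- if (is.null(control$jitter_bound)) 0.05 * spacing else control$jitter_bound

  fit_once <- function(loads) {
    centers0 <- mz_of(ladder$M0 + loads * ladder$delta, ladder$z)
    K <- length(loads)
    sigma0 <- control$sigma_init
    if (!is.null(control$fixed_window)) {
      lo_w <- control$fixed_window[1]; hi_w <- control$fixed_window[2]
    } else {
      pad <- max(spacing / 2, control$window_pad * (sigma0 %||% spacing / 8))
      lo_w <- min(centers0) - pad
      hi_w <- max(centers0) + pad
    }
    win <- tryCatch(crop_spectrum(spectrum, lo_w, hi_w),
                    error = function(e) stop("empty fit window", call. = FALSE))
    x <- win$mz; yobs <- win$intensity
    if (all(yobs == 0)) stop("all-zero spectrum in the fit window", call. = FALSE)
    step <- stats::median(diff(x))
    if (is.null(sigma0)) {
      sigma0 <- tryCatch(fwhm(x, yobs) / (2 * sqrt(2 * log(2))),
                         error = function(e) spacing / 8)
      sigma0 <- min(max(sigma0, 2 * step), spacing)
    }
    # amplitude init: local maximum near each predicted center
    slack <- shift_bound + jitter_bound + sigma0
    A0 <- vapply(centers0, function(c0) {
      sel <- x >= c0 - slack & x <= c0 + slack
      if (!any(sel)) 0 else max(yobs[sel], 0)
    }, 0)
    xmid <- mean(range(x))
    n_sig_par <- if (control$width_model == "shared") 1L else 2L
    bmax <- max(abs(yobs)) / 2
    par0 <- c(A0, 0, rep(0, K),
              if (n_sig_par == 1L) sigma0 else c(sigma0, 0),
              if (control$background == "constant") 0)
    lower <- c(rep(0, K), -shift_bound, rep(-jitter_bound, K),
               if (n_sig_par == 1L) max(step, sigma0 / 20)
               else c(max(step, sigma0 / 20), -sigma0 / diff(range(x))),
               if (control$background == "constant") -bmax)
    # amplitudes cannot meaningfully exceed the data maximum; the cap also
    # pins species whose centers fall outside the recorded m/z range
    upper <- c(rep(1.5 * max(yobs), K), shift_bound, rep(jitter_bound, K),
               if (n_sig_par == 1L) 2 * spacing
               else c(2 * spacing, sigma0 / diff(range(x))),
               if (control$background == "constant") bmax)
    if (jitter_bound == 0) {
      lower[(K + 2):(2 * K + 1)] <- 0
      upper[(K + 2):(2 * K + 1)] <- 0
    }

    run_lm <- function(p0) {
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = ladder_residual, jac = ladder_jacobian,
                         x = x, yobs = yobs, K = K, centers0 = centers0,
                         xmid = xmid, width_model = control$width_model,
                         background = control$background,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12))
    }
    fit <- run_lm(par0)
    tries <- 0
    while (!(fit$info %in% 1:4) && tries < control$max_restarts) {
      tries <- tries + 1
      pert <- with_local_seed(control$seed + tries,
                              stats::runif(length(par0), 0.8, 1.2))
      p0 <- pmin(pmax(par0 * pert, lower), upper)
      fit <- run_lm(p0)
    }
    list(fit = fit, x = x, yobs = yobs, K = K, centers0 = centers0,
         xmid = xmid, loads = loads, window = c(lo_w, hi_w),
         converged = fit$info %in% 1:4)
  }

  loads <- pred$load
  res <- fit_once(loads)

  # prune weak species from the range ends, keeping loads contiguous
  amp <- res$fit$par[1:res$K]
  ev0 <- ladder_model_eval(res$fit$par, res$x, res$K, res$centers0, res$xmid,
                           control$width_model, control$background)
  rms0 <- sqrt(mean((res$yobs - ev0$y)^2))
  thr <- max(control$prune_threshold * max(amp), control$snr_prune * rms0)
  keep <- amp >= thr
  if (any(keep)) {
    lo <- min(which(keep)); hi <- max(which(keep))
    if (lo > 1 || hi < res$K) {
      res <- fit_once(loads[lo:hi])
    }
  }

  par <- res$fit$par
  K <- res$K
  ev <- ladder_model_eval(par, res$x, K, res$centers0, res$xmid,
                          control$width_model, control$background)
  sig_at <- if (control$width_model == "shared") rep(par[2 * K + 2], K)
            else par[2 * K + 2] + par[2 * K + 3] * (ev$cn - res$xmid)
  peaks <- data.frame(load = res$loads,
                      center = ev$cn,
                      sigma = sig_at,
                      amplitude = par[1:K],
                      area = par[1:K] * sig_at * sqrt(2 * pi))
  n_params <- length(par) - if (all(par[(K + 2):(2 * K + 1)] == 0) &&
                                 jitter_bound == 0) K else 0
  out_ladder <- ladder
  out_ladder$global_shift <- par[K + 1] * ladder$z   # report shift in Da
  out_ladder$n_min <- min(res$loads); out_ladder$n_max <- max(res$loads)
  structure(list(peaks = peaks,
                 adj_r2 = adjusted_r2(res$yobs, ev$y, n_params),
                 residual_rms = sqrt(mean((res$yobs - ev$y)^2)),
                 ladder = out_ladder,
                 fit_window = res$window,
                 converged = res$converged,
                 n_params = n_params,
                 mz = res$x, observed = res$yobs, fitted = ev$y),
            class = "deconvolution_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("<deconvolution_result: loads %d..%d, adj R2 %.4f, rms %.4g>\n",
              min(x$peaks$load), max(x$peaks$load), x$adj_r2, x$residual_rms))
  print(x$peaks, digits = 5)
  invisible(x)
}

#' @export
as.data.frame.deconvolution_result <- function(x, ...) x$peaks

#' Choose the peptide-load range supported by the data
#'
#' Fits the full candidate range of the ladder, then trims species at the
#' range ends that the data do not support, either by amplitude (species
#' whose fitted amplitude is below `threshold` times the maximum) or by a
#' greedy BIC descent (an end species is dropped while doing so lowers
#' `N log(RSS/N) + k log N`).
#'
#' @param spectrum a preprocessed [mass_spectrum()].
#' @param ladder a [conjugate_ladder()] over the candidate superset range.
#' @param criterion `"bic"` or `"amplitude_threshold"`.
#' @param threshold amplitude fraction for `"amplitude_threshold"`.
#' @param control a [fit_control()].
#' @return Integer vector `c(n_min, n_max)`.
#' @export
select_load_range <- function(spectrum, ladder,
                              criterion = c("bic", "amplitude_threshold"),
                              threshold = 0.01, control = fit_control()) {
  criterion <- match.arg(criterion)
  if (all(spectrum$intensity == 0)) {
    stop("flat spectrum: load range undecidable", call. = FALSE)
  }
  ctl <- control
  ctl$prune_threshold <- 0          # keep the full range for inspection
  ctl$snr_prune <- 0
  full <- fit_ladder(spectrum, ladder, ctl)
  amp <- full$peaks$amplitude
  if (max(amp) == 0) stop("flat spectrum: load range undecidable", call. = FALSE)
  if (criterion == "amplitude_threshold") {
    keep <- which(amp >= threshold * max(amp))
    return(c(full$peaks$load[min(keep)], full$peaks$load[max(keep)]))
  }
  bic_of <- function(res) {
    N <- length(res$observed)
    rss <- sum((res$observed - res$fitted)^2)
    N * log(rss / N) + res$n_params * log(N)
  }
  # candidates must be compared on the same data: pin the fit window
  ctl$fixed_window <- full$fit_window
  cur_lo <- ladder$n_min; cur_hi <- ladder$n_max
  cur <- full; cur_bic <- bic_of(full)
  repeat {
    if (cur_hi == cur_lo) break
    improved <- FALSE
    for (side in c("hi", "lo")) {
      lo <- cur_lo + (side == "lo"); hi <- cur_hi - (side == "hi")
      cand_ladder <- ladder; cand_ladder$n_min <- lo; cand_ladder$n_max <- hi
      cand <- tryCatch(fit_ladder(spectrum, cand_ladder, ctl),
                       error = function(e) NULL)
      if (!is.null(cand) && bic_of(cand) < cur_bic) {
        cur <- cand; cur_bic <- bic_of(cand); cur_lo <- lo; cur_hi <- hi
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  c(cur_lo, cur_hi)
}
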