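#' Configure a synthetic conjugate-spectrum simulation
#'
#' Describes a linear-MALDI spectrum of a carrier protein bearing
#' 0..n copies of a peptide: a species load distribution, the mass ladder,
#' the observed charge states, instrument resolution, a smooth decaying
#' baseline and additive detector noise.  Defaults emulate a ~58 kDa
#' carrier with ~20 activatable sites conjugated to a ~1.7 kDa
#' single-epitope peptide via a thioether crosslinker (capped unreacted
#' sites), observed as doubly charged ions.
#'
#' @param load_model species load distribution: `list(type = "binomial",
#'   size, prob)` (independent occupancy of `size` sites), `list(type =
#'   "poisson", lambda)`, or `list(type = "table", load, fraction)`.
#' @param carrier_mass bare carrier neutral mass (Da).
#' @param design,chem peptide design and conjugation chemistry defining
#'   the mass ladder (defaults: mouse single-epitope design, SBAP
#'   chemistry over 20 sites, all unconjugated sites capped).
#' @param charge_states data frame with columns `z` and `weight`
#'   (relative total-area weight per charge series).
#' @param resolution peak FWHM as a fraction of m/z (dimensionless);
#'   0.002 is a realistic linear-MALDI figure at ~30 kTh.
#' @param baseline_amplitude exponential baseline height at the low edge
#'   of the grid, as a fraction of the maximum clean signal.
#' @param baseline_rate baseline decay rate per Th.
#' @param noise_sd additive Gaussian noise SD as a fraction of the
#'   maximum clean signal (so SNR = 1 / noise_sd).
#' @param signal_max intensity of the tallest clean peak (arbitrary
#'   units).
#' @param grid `c(mz_low, mz_high, n_points)`, or `NULL` to cover all
#'   predicted centers +/- 5 FWHM with `grid_points` points.
#' @param grid_points grid size used when `grid` is `NULL`.
#' @param seed integer RNG seed; a fixed seed makes the rendered spectrum
#'   bitwise reproducible.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(load_model = list(type = "binomial", size = 20,
                                                prob = 0.1),
                              carrier_mass = 58408,
                              design = iris_design("mIRIS1"),
                              chem = sbap_chemistry(20),
                              charge_states = data.frame(z = 2, weight = 1),
                              resolution = 0.002,
                              baseline_amplitude = 0.2,
                              baseline_rate = 2e-4,
                              noise_sd = 0.01,
                              signal_max = 1000,
                              grid = NULL, grid_points = 4000L,
                              seed = 1L) {
  charge_states <- as.data.frame(charge_states)
  stopifnot(all(c("z", "weight") %in% names(charge_states)),
            all(charge_states$z >= 1), all(charge_states$weight >= 0),
            resolution > 0, noise_sd >= 0, baseline_amplitude >= 0,
            grid_points >= 100)
  structure(list(load_model = load_model, carrier_mass = carrier_mass,
                 design = design, chem = chem, charge_states = charge_states,
                 resolution = resolution,
                 baseline_amplitude = baseline_amplitude,
                 baseline_rate = baseline_rate, noise_sd = noise_sd,
                 signal_max = signal_max, grid = grid,
                 grid_points = as.integer(grid_points),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Analytic species distribution of a simulation
#'
#' Computes the exact molar fractions of the conjugate species from the
#' configured load model (no Monte-Carlo sampling), truncates loads with
#' fraction below 1e-6, renormalizes, and reports the ground-truth mean
#' load and its standard deviation from the truncated distribution.
#'
#' @param config a [simulation_config()].
#' @return A list of class `simulated_truth`: `species` (data frame
#'   `load`, `fraction`), `true_hd`, `true_sigma`.
#' @export
sample_loads <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  lm_ <- config$load_model
  tab <- switch(lm_$type,
    binomial = {
      stopifnot(lm_$prob >= 0, lm_$prob <= 1)
      data.frame(load = 0:lm_$size,
                 fraction = stats::dbinom(0:lm_$size, lm_$size, lm_$prob))
    },
    poisson = {
      nmax <- max(1L, stats::qpois(1 - 1e-9, lm_$lambda))
      data.frame(load = 0:nmax,
                 fraction = stats::dpois(0:nmax, lm_$lambda))
    },
    table = data.frame(load = as.integer(lm_$load),
                       fraction = lm_$fraction / sum(lm_$fraction)),
    stop(sprintf("unknown load model '%s'", lm_$type), call. = FALSE))
  tab <- tab[tab$fraction >= 1e-6, , drop = FALSE]
  if (nrow(tab) == 0) stop("degenerate load model: no species retained", call. = FALSE)
  tab$fraction <- tab$fraction / sum(tab$fraction)
  hd <- sum(tab$fraction * tab$load)
  sg <- sqrt(sum(tab$fraction * (tab$load - hd)^2))
  structure(list(species = tab, true_hd = hd, true_sigma = sg),
            class = "simulated_truth")
}

#' @export
print.simulated_truth <- function(x, ...) {
  cat(sprintf("<simulated_truth: %d species, true HD %.3f, true sigma %.3f>\n",
              nrow(x$species), x$true_hd, x$true_sigma))
  invisible(x)
}

#' Render a synthetic spectrum from a species distribution
#'
#' Sums, over species and charge states, Gaussian peaks centered at the
#' ladder-predicted m/z with width `sigma = resolution * center / 2.3548`.
#' Per-species peak areas are proportional to molar fraction times the
#' charge-state weight (equal ionization/transmission efficiency across
#' loads).  An exponentially decaying baseline and seeded additive
#' Gaussian noise are added and the result clipped at zero.
#'
#' @param truth a [sample_loads()] result.
#' @param config the same [simulation_config()].
#' @return A [mass_spectrum()]; the clean (noise- and baseline-free)
#'   trace is attached as attribute `"clean"`.
#' @export
render_spectrum <- function(truth, config) {
  stopifnot(inherits(truth, "simulated_truth"),
            inherits(config, "simulation_config"))
  ladder <- design_ladder(config$carrier_mass, config$design, config$chem,
                          z = 1L, n_range = c(0L, max(truth$species$load)))
  fw <- 2 * sqrt(2 * log(2))
  peak_params <- do.call(rbind, lapply(seq_len(nrow(config$charge_states)),
    function(i) {
      z <- config$charge_states$z[i]
      w <- config$charge_states$weight[i]
      centers <- mz_of(ladder$M0 + truth$species$load * ladder$delta, z)
      sigma <- config$resolution * centers / fw
      data.frame(load = truth$species$load, z = z,
                 center = centers, sigma = sigma,
                 area = truth$species$fraction * w)
    }))
  if (is.null(config$grid)) {
    pad <- 5 * config$resolution * peak_params$center
    lo <- min(peak_params$center - pad)
    hi <- max(peak_params$center + pad)
    n <- config$grid_points
  } else {
    lo <- config$grid[1]; hi <- config$grid[2]; n <- as.integer(config$grid[3])
    need_lo <- min(peak_params$center - 5 * peak_params$sigma * fw)
    need_hi <- max(peak_params$center + 5 * peak_params$sigma * fw)
    if (lo > need_lo || hi < need_hi) {
      stop("grid too narrow: does not cover all predicted centers +/- 5 FWHM",
           call. = FALSE)
    }
  }
  x <- seq(lo, hi, length.out = n)
  clean <- numeric(n)
  for (i in seq_len(nrow(peak_params))) {
    p <- peak_params[i, ]
    amp <- p$area / (p$sigma * sqrt(2 * pi))
    clean <- clean + amp * exp(-(x - p$center)^2 / (2 * p$sigma^2))
  }
  clean <- clean * (config$signal_max / max(clean))
  base <- config$baseline_amplitude * config$signal_max *
    exp(-config$baseline_rate * (x - lo))
  y <- clean + base
  if (config$noise_sd > 0) {
    y <- y + with_local_seed(config$seed,
           stats::rnorm(n, sd = config$noise_sd * config$signal_max))
  }
  y[y < 0] <- 0
  out <- mass_spectrum(x, y, meta = list(simulated = TRUE, seed = config$seed,
                                         true_hd = truth$true_hd))
  attr(out, "clean") <- clean
  attr(out, "peak_params") <- peak_params
  out
}

#' Simulate a conjugate spectrum with known ground truth
#'
#' @param config a [simulation_config()].
#' @return A list with `spectrum`, `truth` and the fit-ready `ladder`
#'   (charge state of the first configured series).
#' @export
simulate_conjugate_spectrum <- function(config) {
  truth <- sample_loads(config)
  spectrum <- render_spectrum(truth, config)
  ladder <- design_ladder(config$carrier_mass, config$design, config$chem,
                          z = as.integer(config$charge_states$z[1]),
                          n_range = c(0L, max(truth$species$load)))
  list(spectrum = spectrum, truth = truth, ladder = ladder)
}

#' Write a batch of simulated fixtures with a manifest
#'
#' Renders each configuration, writes the spectrum as two-column text (and
#' mzML when \pkg{mzR} is available), and writes a JSON manifest pairing
#' each file with its ground truth.
#'
#' @param configs list of [simulation_config()] objects.
#' @param out_dir output directory (created if needed).
#' @param formats subset of `c("txt", "mzml")`.
#' @return Invisibly, the manifest (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
generate_batch <- function(configs, out_dir, formats = "txt") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create '%s'", out_dir), call. = FALSE)
  manifest <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    stopifnot(inherits(cfg, "simulation_config"))
    sim <- simulate_conjugate_spectrum(cfg)
    stem <- sprintf("sim_%02d", i)
    files <- character(0)
    if ("txt" %in% formats) {
      f <- file.path(out_dir, paste0(stem, ".txt"))
      write_spectrum(sim$spectrum, f, "txt")
      files <- c(files, basename(f))
    }
    if ("mzml" %in% formats) {
      f <- file.path(out_dir, paste0(stem, ".mzML"))
      write_spectrum(sim$spectrum, f, "mzml")
      files <- c(files, basename(f))
    }
    manifest[[i]] <- list(
      files = files, seed = cfg$seed,
      true_hd = sim$truth$true_hd, true_sigma = sim$truth$true_sigma,
      species = sim$truth$species,
      ladder = list(M0 = sim$ladder$M0, delta = sim$ladder$delta,
                    z = sim$ladder$z),
      load_model = cfg$load_model)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
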