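test_that("ladder centers follow the charge-reduced arithmetic", {
  pr <- predict_ladder(60000, 2000, 2, c(0, 2))
  expect_equal(pr$center, c(30001.007276, 31001.007276, 32001.007276),
               tolerance = 1e-3)
  # z = 1: spacing equals delta exactly
  pr1 <- predict_ladder(50000, 1723.9, 1, c(0, 5))
  expect_equal(diff(pr1$center), rep(1723.9, 5))
  # property: z = 2 spacing is delta / 2 for random (M0, delta)
  withr::with_seed(11, {
    for (i in 1:20) {
      M0 <- runif(1, 2e4, 8e4); delta <- runif(1, 500, 4000)
      pr2 <- predict_ladder(M0, delta, 2, c(0, 8))
      expect_equal(diff(pr2$center), rep(delta / 2, 8), tolerance = 1e-9)
      # brute-force arithmetic oracle for the absolute positions
      expect_equal(pr2$center, (M0 + (0:8) * delta + 2 * 1.007276) / 2)
    }
  })
})

test_that("adjusted R-square matches its defining formula", {
  expect_equal(adjusted_r2(c(1, 2, 3, 4), c(1, 2, 3, 4), 1), 1.0)
  y <- c(1, 2, 3, 4, 5)
  expect_equal(adjusted_r2(y, rep(mean(y), 5), 0), 0.0)
  # independent spreadsheet-style computation on random data
  withr::with_seed(5, {
    obs <- rnorm(40); fit <- obs + rnorm(40, sd = 0.3); k <- 7
    r2 <- 1 - sum((obs - fit)^2) / sum((obs - mean(obs))^2)
    manual <- 1 - (1 - r2) * (40 - 1) / (40 - k - 1)
    expect_equal(adjusted_r2(obs, fit, k), manual)
  })
  expect_error(adjusted_r2(rep(2, 10), rep(2, 10), 1), "zero total variance")
})

test_that("a noise-free Gaussian series is recovered to numerical precision", {
  lad <- conjugate_ladder(60000, 2000, z = 2, n_min = 0, n_max = 3)
  pr <- predict_ladder(lad)
  A <- c(5, 10, 7, 2); sg <- 40
  s <- multi_gaussian_spectrum(29500, 34500, 3000, pr$center,
                               rep(sg, 4), A)
  fit <- fit_ladder(s, lad)
  expect_true(fit$converged)
  expect_equal(fit$peaks$area, A * sg * sqrt(2 * pi), tolerance = 1e-3)
  expect_equal(fit$peaks$sigma, rep(sg, 4), tolerance = 1e-3)
  expect_gte(fit$adj_r2, 0.9999)
  # deterministic: identical inputs give identical results
  fit2 <- fit_ladder(s, lad)
  expect_identical(fit$peaks, fit2$peaks)
})

test_that("areas survive additive noise at high SNR", {
  lad <- conjugate_ladder(60000, 2000, z = 2, n_min = 0, n_max = 3)
  pr <- predict_ladder(lad)
  A <- c(5, 10, 7, 2); sg <- 40
  x <- seq(29500, 34500, length.out = 3000)
  clean <- Reduce(`+`, lapply(1:4, function(k)
    gaussian_trace(x, pr$center[k], sg, A[k])))
  noisy <- withr::with_seed(9, clean + rnorm(3000, sd = max(clean) / 100))
  fit <- fit_ladder(mass_spectrum(x, pmax(noisy, 0)), lad)
  expect_equal(fit$peaks$area, A * sg * sqrt(2 * pi), tolerance = 0.05)
})

test_that("absent species are pruned from the range ends", {
  lad <- conjugate_ladder(60000, 2000, z = 2, n_min = 0, n_max = 5)
  ctr0 <- predict_ladder(lad)$center[1]
  s <- multi_gaussian_spectrum(29000, 37000, 3000, ctr0, 40, 10)
  fit <- fit_ladder(s, lad)
  expect_equal(fit$peaks$load, 0)
  expect_equal(fit$peaks$area, 10 * 40 * sqrt(2 * pi), tolerance = 1e-3)
})

test_that("degenerate inputs are rejected", {
  lad <- conjugate_ladder(60000, 2000, z = 2, n_min = 0, n_max = 3)
  s0 <- mass_spectrum(seq(29500, 34500, length.out = 500), rep(0, 500))
  expect_error(fit_ladder(s0, lad), "all-zero")
  far <- mass_spectrum(seq(100, 200, length.out = 500), rep(1, 500))
  expect_error(fit_ladder(far, lad), "window")
})

test_that("load-range selection finds the supported species range", {
  lad_true <- conjugate_ladder(60000, 2000, z = 2, n_min = 3, n_max = 5)
  pr <- predict_ladder(lad_true)
  x <- seq(29000, 42000, length.out = 4000)
  clean <- Reduce(`+`, lapply(1:3, function(k)
    gaussian_trace(x, pr$center[k], 40, c(5, 8, 4)[k])))
  noisy <- withr::with_seed(2, clean + rnorm(4000, sd = 0.02))
  s <- mass_spectrum(x, pmax(noisy, 0))
  cand <- conjugate_ladder(60000, 2000, z = 2, n_min = 0, n_max = 10)
  expect_equal(select_load_range(s, cand, "amplitude_threshold"), c(3, 5))
  expect_equal(select_load_range(s, cand, "bic"), c(3, 5))
  # single species
  s1 <- multi_gaussian_spectrum(29000, 42000, 4000, pr$center[2], 40, 8)
  expect_equal(select_load_range(s1, cand, "amplitude_threshold"), c(4, 4))
  # flat spectrum is undecidable
  flat <- mass_spectrum(x, rep(0, 4000))
  expect_error(select_load_range(flat, cand), "flat|all-zero")
})

test_that("simulated ladders are recovered species by species", {
  # 50 seeded conjugate simulations at SNR 50, mean load in [1, 8]:
  # every species holding >= 5% of the area is recovered within 5%,
  # and the fitted curve never shoots above the data
  set.seed(7)
  ps <- runif(50, 0.05, 0.40)
  ctl <- fit_control(width_model = "linear")  # simulator width grows with m/z
  for (i in seq_along(ps)) {
    cfg <- simulation_config(load_model = list(type = "binomial", size = 20,
                                               prob = ps[i]),
                             noise_sd = 0.02, seed = 100 + i)
    sim <- simulate_conjugate_spectrum(cfg)
    rep <- estimate_hapten_density(sim$spectrum, sim$ladder, control = ctl)
    m <- merge(rep$abundances, sim$truth$species, by = "load")
    fx <- m$area / sum(m$area)
    fy <- m$fraction.y / sum(m$fraction.y)
    keep <- fy >= 0.05
    expect_lt(max(abs(fx[keep] / fy[keep] - 1)), 0.05)
    fit <- attr(rep, "fit")
    expect_lt(max(fit$fitted), 1.1 * max(sim$spectrum$intensity))
  }
})
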