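test_that("analytic load distributions match closed forms and pmf sums", {
  cfg0 <- simulation_config(load_model = list(type = "binomial", size = 20,
                                              prob = 0))
  t0 <- sample_loads(cfg0)
  expect_equal(t0$species$load, 0)
  expect_equal(t0$true_hd, 0)

  cfg <- simulation_config(load_model = list(type = "binomial", size = 20,
                                             prob = 0.1))
  tr <- sample_loads(cfg)
  expect_equal(tr$true_hd, 20 * 0.1, tolerance = 1e-4)
  expect_equal(tr$true_sigma, sqrt(20 * 0.1 * 0.9), tolerance = 1e-4)
  expect_equal(sum(tr$species$fraction), 1, tolerance = 1e-12)

  # Poisson fractions against brute-force pmf arithmetic
  lam <- 3.5
  cfgp <- simulation_config(load_model = list(type = "poisson", lambda = lam))
  trp <- sample_loads(cfgp)
  manual <- exp(-lam) * lam^trp$species$load / factorial(trp$species$load)
  expect_equal(trp$species$fraction, manual / sum(manual), tolerance = 1e-9)

  # explicit table passes through renormalized
  cfgt <- simulation_config(load_model = list(type = "table",
                                              load = c(2, 3), fraction = c(2, 6)))
  trt <- sample_loads(cfgt)
  expect_equal(trt$species$fraction, c(0.25, 0.75))
  expect_equal(trt$true_hd, 2.75)
})

test_that("rendered peaks have the configured width and are reproducible", {
  cfg <- simulation_config(load_model = list(type = "table", load = 3,
                                             fraction = 1),
                           noise_sd = 0, baseline_amplitude = 0,
                           resolution = 0.002, seed = 4)
  tr <- sample_loads(cfg)
  sp <- render_spectrum(tr, cfg)
  w <- fwhm(sp$mz, sp$intensity)
  ctr <- sp$mz[which.max(sp$intensity)]
  expect_equal(w, 0.002 * ctr, tolerance = 0.01)

  # fixed seed implies bitwise-identical output
  cfg2 <- simulation_config(load_model = list(type = "binomial", size = 20,
                                              prob = 0.2), seed = 99)
  a <- render_spectrum(sample_loads(cfg2), cfg2)
  b <- render_spectrum(sample_loads(cfg2), cfg2)
  expect_identical(a$mz, b$mz)
  expect_identical(a$intensity, b$intensity)
})

test_that("integrated species areas are proportional to molar fractions", {
  cfg <- simulation_config(load_model = list(type = "table", load = c(1, 3, 5),
                                             fraction = c(0.2, 0.5, 0.3)),
                           noise_sd = 0, baseline_amplitude = 0,
                           grid_points = 20000L)
  tr <- sample_loads(cfg)
  sp <- render_spectrum(tr, cfg)
  step <- diff(sp$mz)[1]
  pp <- attr(sp, "peak_params")
  areas <- vapply(seq_len(nrow(pp)), function(k) {
    sel <- abs(sp$mz - pp$center[k]) < 4 * pp$sigma[k]
    sum(sp$intensity[sel]) * step
  }, 0)
  expect_equal(areas / sum(areas), c(0.2, 0.5, 0.3), tolerance = 0.005)
})

test_that("a too-narrow explicit grid is rejected", {
  cfg <- simulation_config(load_model = list(type = "table", load = c(0, 5),
                                             fraction = c(0.5, 0.5)),
                           grid = c(31000, 32000, 1000))
  expect_error(render_spectrum(sample_loads(cfg), cfg), "grid too narrow")
})

test_that("batch generation writes fixtures with a faithful manifest", {
  out <- withr::local_tempdir()
  configs <- lapply(seq_along(c(0.1, 0.2, 0.35)), function(i) {
    simulation_config(load_model = list(type = "binomial", size = 20,
                                        prob = c(0.1, 0.2, 0.35)[i]),
                      seed = 10 + i, grid_points = 1500L)
  })
  man <- generate_batch(configs, out)
  expect_length(man, 3)
  hds <- vapply(man, `[[`, 0, "true_hd")
  expect_true(all(diff(hds) > 0))  # molar-excess series: increasing HD
  files <- vapply(man, function(m) m$files[[1]], "")
  expect_true(all(file.exists(file.path(out, files))))
  expect_true(file.exists(file.path(out, "manifest.json")))
  # re-running with the same seeds reproduces the fixtures byte for byte
  out2 <- withr::local_tempdir()
  generate_batch(configs, out2)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(out, f))),
                     unname(tools::md5sum(file.path(out2, f))))
  }
  # an empty config list yields an empty manifest and no fixtures
  out3 <- withr::local_tempdir()
  man0 <- generate_batch(list(), out3)
  expect_length(man0, 0)
  expect_identical(setdiff(list.files(out3), "manifest.json"), character(0))
})
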