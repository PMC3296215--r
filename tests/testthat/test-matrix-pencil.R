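test_that("noise-free damped sinusoids are recovered exactly", {
  e <- make_echo(spectral_components(10, 100, 0.5, 20, 0), 2000, 256)
  dec <- pencil_decompose(e, pencil_config(sv_threshold = 1e-3))
  expect_equal(dec$order, 1L)
  expect_equal(dec$components$amplitude, 10, tolerance = 1e-8)
  expect_equal(dec$components$frequency, 100, tolerance = 1e-8)
  expect_equal(dec$components$lorentz_decay, 20, tolerance = 1e-8)
  expect_equal(dec$components$phase, 0.5, tolerance = 1e-8)
})

test_that("Hankel rank equals the component count on noise-free data", {
  comp <- separated_triplet()
  dec <- pencil_decompose(make_echo(comp, 2000, 256),
                          pencil_config(sv_threshold = 1e-3))
  d <- dec$singular_values
  expect_identical(sum(d > 1e-3 * d[1]), 3L)
  expect_equal(dec$order, 3L)
})

test_that("two components 50 Hz apart are resolved to well under 0.01 Hz", {
  comp <- spectral_components(c(5, 4), c(-25, 25), c(0.2, -1),
                              fwhm_to_decay(10, "lorentzian"), 0)
  dec <- pencil_decompose(make_echo(comp, 2000, 256),
                          pencil_config(sv_threshold = 1e-3))
  expect_equal(sort(dec$components$frequency), c(-25, 25), tolerance = 1e-4)
})

test_that("reconstruction plus residual reproduces the input", {
  set.seed(7)
  comp <- separated_triplet()
  e <- make_echo(comp, 2000, 256, noise_sd = 0.5, seed = 7)
  dec <- pencil_decompose(e)
  expect_lt(max(Mod(dec$reconstruction + dec$residual - e$samples)),
            1e-12 * max(Mod(e$samples)))
})

test_that("known-order noise-free decompositions equal the generator (K <= 5)", {
  set.seed(42)
  for (K in c(2L, 4L, 5L)) {
    comp <- spectral_components(
      amplitude = runif(K, 5, 50),
      frequency = seq(-600, 500, length.out = K) + runif(K, -10, 10),
      phase = runif(K, -3, 3),
      lorentz_decay = runif(K, 10, 50), gauss_decay = 0)
    dec <- pencil_decompose(make_echo(comp, 2000, 256),
                            pencil_config(sv_threshold = 1e-3))
    got <- dec$components[order(dec$components$frequency), ]
    want <- comp[order(comp$frequency), ]
    expect_equal(got$amplitude, want$amplitude, tolerance = 1e-6)
    expect_equal(got$frequency, want$frequency, tolerance = 1e-6)
    expect_equal(got$lorentz_decay, want$lorentz_decay, tolerance = 1e-5)
  }
})

test_that("water removal clears >= 98% of water-band energy, metabolites intact", {
  metab <- metabolite_singlets("lorentzian")
  echo_clean <- make_echo(metab, 2000, 256)
  echo <- make_echo(dplyr::bind_rows(metab, water_components()), 2000, 256)
  wr <- remove_water(echo, pencil_config(water_band = 60))
  expect_gte(wr$removed_fraction, 0.98)
  expect_gte(wr$n_water_components, 1L)
  # metabolite amplitudes re-fit after removal differ < 2% from the
  # water-free fit
  fit_clean <- fit_time_domain(echo_clean, "lorentzian",
                               initialize_params(echo_clean, n_peaks = 3))
  fit_after <- fit_time_domain(wr$echo, "lorentzian",
                               initialize_params(wr$echo, n_peaks = 3))
  a0 <- mrsipipe:::match_components(fit_clean$components, metab)$amplitude
  a1 <- mrsipipe:::match_components(fit_after$components, metab)$amplitude
  expect_lt(max(abs(a1 - a0) / a0), 0.02)
})

test_that("water removal is a no-op without water-band content, and idempotent", {
  metab <- metabolite_singlets("lorentzian")
  e <- make_echo(metab, 2000, 256)
  wr <- remove_water(e, pencil_config(sv_threshold = 1e-3, water_band = 60))
  expect_lt(max(Mod(wr$echo$samples - e$samples)), 1e-6 * max(Mod(e$samples)))

  echo <- make_echo(dplyr::bind_rows(metab, water_components()), 2000, 256)
  once <- remove_water(echo, pencil_config(water_band = 60))
  twice <- remove_water(once$echo, pencil_config(water_band = 60))
  change1 <- sqrt(sum(Mod(once$echo$samples - echo$samples)^2))
  change2 <- sqrt(sum(Mod(twice$echo$samples - once$echo$samples)^2))
  expect_lt(change2, 0.01 * change1)
})

test_that("empty water band warns and returns the input", {
  e <- make_echo(metabolite_singlets(), 2000, 256)
  expect_warning(out <- remove_water(e, pencil_config(water_band = 0)),
                 "empty water band")
  expect_identical(out$echo$samples, e$samples)
  expect_identical(out$removed_fraction, 0)
})

test_that("corrupted leading points are restored from the pencil model", {
  e <- make_echo(metabolite_singlets("lorentzian"), 2000, 256)
  bad <- e
  bad$samples[1:6] <- 100 * bad$samples[1:6]
  fixed <- repair_corrupted_points(bad, n_bad = 6,
                                   pencil_config(sv_threshold = 1e-3))
  expect_lt(max(Mod(fixed$samples[1:6] - e$samples[1:6]) / Mod(e$samples[1:6])),
            1e-6)
  expect_identical(fixed$samples[7:256], bad$samples[7:256])
  # n_bad = 0 is the identity
  expect_identical(repair_corrupted_points(e, 0), e)
})

test_that("pencil configuration errors are raised", {
  e <- make_echo(metabolite_singlets(), 2000, 256)
  expect_error(repair_corrupted_points(e, 64), "N/4")
  expect_error(pencil_decompose(e, pencil_config(L = 40, order = 41)),
               "order K")
  bad <- e
  bad$samples[10] <- NaN * 1i
  expect_error(pencil_decompose(bad), "non-finite")
})
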