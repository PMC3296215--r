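test_that("initialization finds peaks, frequencies and the global phase", {
  # single noise-free peak: frequency within the 4096-point grid resolution
  e <- make_echo(spectral_components(10, 200, 0.8, fwhm_to_decay(10, "lorentzian"), 0),
                 2000, 256)
  init <- initialize_params(e, "lorentzian", n_peaks = 1)
  expect_equal(nrow(init), 1L)
  expect_lt(abs(init$frequency - 200), 2000 / 4096)
  top <- which.max(Mod(e$samples))
  expect_identical(attr(init, "global_phase"), Arg(e$samples[top]))
  expect_equal(init$phase, Arg(e$samples[top]))
  # three well-separated singlets: exactly 3 peaks
  e3 <- make_echo(separated_triplet(), 2000, 256)
  expect_identical(nrow(initialize_params(e3, "lorentzian")), 3L)
  expect_error(initialize_params(echo_signal(rep(0 + 0i, 64), 2000)),
               "identically zero")
})

test_that("noise-free truncated echoes are recovered exactly in the time domain", {
  for (kind in c("lorentzian", "gaussian", "voigt")) {
    comp <- metabolite_singlets(kind)
    e <- make_echo(comp, 2000, 256)
    fit <- fit_time_domain(e, kind, initialize_params(e, kind, n_peaks = 3))
    expect_true(fit$converged)
    expect_lt(max_amp_error(fit, comp), 1e-4)
    expect_lt(fit$residual_norm, 1e-8 * sqrt(sum(Mod(e$samples)^2)))
  }
})

test_that("fitting a model's own exact evaluation is a fixed point", {
  comp <- metabolite_singlets("lorentzian")
  e <- make_echo(comp, 2000, 256)
  fit <- fit_time_domain(e, "lorentzian", comp)
  expect_lt(max(abs(fit$components$amplitude - comp$amplitude)), 1e-10)
  expect_lt(max(abs(fit$components$frequency - comp$frequency)), 1e-10)
})

test_that("overparameterized models are rejected", {
  e <- make_echo(metabolite_singlets(), 2000, 64)
  init <- spectral_components(rep(1, 5), seq(-600, 600, length.out = 5), 0, 30, 0)
  expect_error(fit_time_domain(e, "lorentzian", init), "overparameterized")
})

test_that("frequency-domain fitting of non-truncated data recovers amplitudes", {
  for (kind in c("lorentzian", "gaussian", "voigt")) {
    comp <- metabolite_singlets(kind)
    e <- make_echo(comp, 2000, 1024)
    fit <- fit_frequency_domain(e, kind, initialize_params(e, kind, n_peaks = 3))
    expect_lt(max_amp_error(fit, comp), 5e-4)
  }
})

test_that("truncation penalizes the frequency domain but not the time domain", {
  for (kind in c("lorentzian", "gaussian", "voigt")) {
    comp <- metabolite_singlets(kind)
    e <- make_echo(comp, 2000, 256)
    init <- initialize_params(e, kind, n_peaks = 3)
    err_td <- max_amp_error(fit_time_domain(e, kind, init), comp)
    err_fd <- max_amp_error(
      suppressWarnings(fit_frequency_domain(e, kind, init)), comp)
    err_pad <- max_amp_error(
      suppressWarnings(fit_frequency_domain(e, kind, init, n_spectrum = 1024)),
      comp)
    expect_gt(err_fd, err_td)
    expect_gt(err_pad, err_td)
    expect_gt(err_fd, 1e-3)   # a genuinely non-zero truncation penalty
  }
})

test_that("zero-filling leaves frequency-domain errors of the same order", {
  # well-separated Lorentzian triplet: padding neither cures nor explodes
  # the truncation error
  comp <- separated_triplet("lorentzian")
  e <- make_echo(comp, 2000, 256)
  err_fd <- max_amp_error(
    suppressWarnings(fit_frequency_domain(e, "lorentzian", comp)), comp)
  err_pad <- max_amp_error(
    suppressWarnings(fit_frequency_domain(e, "lorentzian", comp,
                                          n_spectrum = 1024)), comp)
  expect_lt(max(err_fd, err_pad) / min(err_fd, err_pad), 3)
})

test_that("Monte-Carlo summaries are seeded, unbiased and near the CRLB", {
  g <- echo_grid(2000, 256)
  comp <- metabolite_singlets("lorentzian")
  mc1 <- run_monte_carlo(comp, "lorentzian", g, noise_sd = 0.8,
                         n_realizations = 60, seed = 99)
  mc2 <- run_monte_carlo(comp, "lorentzian", g, noise_sd = 0.8,
                         n_realizations = 60, seed = 99)
  expect_identical(mc1$estimates, mc2$estimates)
  # unbiased within 3 standard errors, efficiency near 1 at this SNR
  se <- mc1$summary$sd / sqrt(nrow(mc1$estimates))
  expect_true(all(abs(mc1$summary$mean - mc1$summary$true_amplitude) <= 3 * se))
  expect_true(all(mc1$summary$sd_over_crlb > 0.7 &
                    mc1$summary$sd_over_crlb < 1.4))
  # vanishing noise: estimates collapse onto the truth
  mc0 <- run_monte_carlo(comp, "lorentzian", g, noise_sd = 1e-6,
                         n_realizations = 5, seed = 1)
  expect_lt(max(abs(mc0$summary$mean - comp$amplitude)), 1e-4)
  expect_lt(max(mc0$summary$sd), 1e-4)
  expect_error(run_monte_carlo(comp, "lorentzian", g, 0.5, 10), "seed")
})

test_that("amplitude bias stays within 3 SE across two orders of noise magnitude", {
  g <- echo_grid(2000, 256)
  comp <- metabolite_singlets("lorentzian")
  for (sdn in c(0.05, 0.5, 5)) {
    mc <- run_monte_carlo(comp, "lorentzian", g, noise_sd = sdn,
                          n_realizations = 40, seed = 1234,
                          init_from = "truth")
    se <- mc$summary$sd / sqrt(nrow(mc$estimates))
    expect_true(all(abs(mc$summary$mean - mc$summary$true_amplitude) <= 3 * se))
  }
})

test_that("the scaled complex error function matches independent references", {
  # small |z|: direct formula through pracma's complex erf
  zs <- c(0.3 + 0i, 1 + 0.5i, 0.2 - 2i, 2 + 1i)
  ref <- exp(zs^2) * (1 - pracma::erfz(zs))
  expect_lt(max(Mod(mrsipipe:::erfcx_cplx(zs) - ref) / Mod(ref)), 1e-12)
  # large |z|: asymptotic limit z*sqrt(pi)*erfcx(z) -> 1
  zl <- c(50 + 10i, 20 - 300i, 500 + 0i)
  expect_lt(max(Mod(zl * sqrt(pi) * mrsipipe:::erfcx_cplx(zl) - 1)), 1e-3)
  # the Voigt profile it feeds integrates the two-sided envelope: at df = 0
  # it must equal the numeric integral of exp(-a|t| - b t^2)
  a <- fwhm_to_decay(2.5, "lorentzian")
  b <- fwhm_to_decay(7.5, "gaussian")
  tt <- seq(-2, 2, by = 1e-4)
  expect_equal(mrsipipe:::lineshape_profile(0, a, b),
               sum(exp(-a * abs(tt) - b * tt^2)) * 1e-4, tolerance = 1e-6)
})

test_that("tidy and glance expose fit results as tables", {
  e <- make_echo(metabolite_singlets(), 2000, 256)
  fit <- fit_time_domain(e, "lorentzian", initialize_params(e, n_peaks = 3))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_identical(nrow(glance(fit)), 1L)
  expect_true(glance(fit)$converged)
})
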