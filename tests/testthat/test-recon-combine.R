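make_kvol <- function(arr) kspace_volume(arr, sw = 2000)

test_that("the Hamming window peaks at the k-space centre and is 0.08 at the edge", {
  w <- mrsipipe:::hamming_window(16)
  expect_equal(w[9], 1.0, tolerance = 1e-12)        # 0-based index 8 = centre
  expect_equal(w[1], 0.08, tolerance = 1e-12)
  kv <- make_kvol(array(1 + 0i, c(1, 1, 16, 16, 4)))
  filt <- spatial_filter(kv, "hamming")
  expect_equal(Re(filt$data[1, 1, 9, 9, 1]), 1.0, tolerance = 1e-12)
  expect_equal(Re(filt$data[1, 1, 1, 1, 1]), 0.08^2, tolerance = 1e-12)
  # "none" is the identity; unknown window errors
  expect_identical(spatial_filter(kv, "none")$data, kv$data)
  expect_error(spatial_filter(kv, "hann"), "unknown window")
})

test_that("a DC-only k-space maps to a uniform image and transforms round-trip", {
  arr <- array(0 + 0i, c(2, 3, 16, 16, 2))
  arr[, , 9, 9, ] <- 5 + 1i
  img <- kspace_to_image(make_kvol(arr))
  expect_lt(max(Mod(sweep(img$data, c(1, 2, 5), array(5 + 1i, c(2, 3, 2)), "-"))),
            1e-12)
  set.seed(11)
  arr2 <- array(complex(real = rnorm(2 * 3 * 16 * 16 * 2),
                        imaginary = rnorm(2 * 3 * 16 * 16 * 2)),
                c(2, 3, 16, 16, 2))
  kv <- make_kvol(arr2)
  back <- image_to_kspace(kspace_to_image(kv))
  expect_lt(max(Mod(back$data - kv$data)) / max(Mod(kv$data)), 1e-12)
})

test_that("a single-voxel phantom reconstructs its generating echo", {
  comp <- metabolite_singlets()
  g <- echo_grid(2000, 64)
  echo <- evaluate_model(comp, g)
  img <- array(0 + 0i, c(1, 1, 8, 8, 64))
  img[1, 1, 3, 6, ] <- echo
  ivol <- structure(list(data = img, sw = 2000, dt = g$dt, t = g$t),
                    class = "image_volume")
  rec <- kspace_to_image(image_to_kspace(ivol))
  expect_lt(max(Mod(rec$data[1, 1, 3, 6, ] - echo)) / max(Mod(echo)), 1e-12)
  other <- rec$data[1, 1, -3, , ]
  expect_lt(max(Mod(other)), 1e-10 * max(Mod(echo)))
})

test_that("Hamming filtering tames the point-spread sidelobes", {
  # PSF of a 16x16 acquisition, oversampled 4x by embedding the sampled
  # window in a zero-filled 64x64 k-space
  psf_of <- function(window) {
    arr16 <- array(1 + 0i, c(1, 1, 16, 16, 2))
    w <- spatial_filter(make_kvol(arr16), window)$data[1, 1, , , 1]
    big <- array(0 + 0i, c(1, 1, 64, 64, 2))
    big[1, 1, 25:40, 25:40, 1] <- w
    big[1, 1, 25:40, 25:40, 2] <- w
    p <- Mod(kspace_to_image(make_kvol(big))$data[1, 1, , 33, 1])
    p / max(p)
  }
  unfilt <- psf_of("none")
  filt <- psf_of("hamming")
  # sidelobe = largest magnitude more than 4 nominal voxels (16 oversampled
  # points) from the mainlobe at index 33. The DFT-even (periodic) Hamming
  # window centred on sample n/2 has a theoretical peak sidelobe of 1.04%;
  # the unwindowed rect PSF rings at tens of percent.
  sidelobe <- function(p) max(p[c(1:16, 50:64)])
  expect_gte(sidelobe(unfilt), 0.05)
  expect_lte(sidelobe(filt), 0.0105)
})

test_that("apodization leaves t=0 untouched and sets the programmed linewidth", {
  e <- make_echo(spectral_components(10, -200), 2000, 1024)
  expect_identical(apodize(e, 0), e)
  ap <- apodize(e, 10)
  expect_equal(ap$samples[513], e$samples[513])
  sp <- echo_spectrum(ap, 16384)
  ms <- Mod(sp$spectrum)
  i <- which.max(ms)
  half <- ms[i] / 2
  l <- max(which(ms[1:i] < half))
  r <- i + min(which(ms[(i + 1):length(ms)] < half))
  expect_lt(abs((sp$frequency[r] - sp$frequency[l]) - 10), 0.5)
  expect_error(apodize(e, -1), "invalid parameter")
})

test_that("noise estimation recovers the programmed SD and scales linearly", {
  set.seed(5)
  n <- 512
  sigma <- 0.8
  spec <- complex(real = rnorm(n, 0, sigma), imaginary = rnorm(n, 0, sigma))
  est <- estimate_noise(spec, 1:128)
  expect_lt(abs(est - sigma) / sigma, 0.15)
  expect_equal(estimate_noise(3 * spec, 1:128), 3 * est, tolerance = 1e-12)
  expect_lt(estimate_noise(rep(0 + 0i, 64), 1:64), 1e-10)
  expect_error(estimate_noise(spec, 1:16), "at least 32")
  expect_error(estimate_noise(spec, 1:64, peak_bands = list(60:70)),
               "overlaps")
})

test_that("phase alignment makes echo tops real and coherent", {
  e <- make_echo(metabolite_singlets(), 2000, 256)
  rot <- echo_signal(e$samples * exp(1i * pi / 2), 2000)
  al <- align_phase(list(e, rot))
  expect_equal(al[[1]]$samples, al[[2]]$samples, tolerance = 1e-12)
  top <- which.max(Mod(al[[1]]$samples))
  expect_lt(abs(Im(al[[1]]$samples[top])), 1e-12 * Mod(al[[1]]$samples[top]))
  expect_gte(Re(al[[1]]$samples[top]), 0)
  # coherent summation at the echo top
  s0 <- abs(sum(vapply(al, function(x) Re(x$samples[top]), 1)))
  expect_equal(s0, sum(vapply(al, function(x) Mod(x$samples[top]), 1)),
               tolerance = 1e-10)
  expect_warning(align_phase(list(e, echo_signal(rep(0 + 0i, 256), 2000))),
                 "all-zero")
})

test_that("identical channels combine to a single channel; zero weight at infinite noise", {
  e <- make_echo(metabolite_singlets(), 2000, 256)
  out <- combine_channels(list(e, e, e), rep(0.5, 3))
  expect_equal(out$echo$samples, e$samples, tolerance = 1e-12)
  out2 <- combine_channels(list(e, e), c(0.5, Inf))
  expect_equal(out2$weights$weight[2], 0)
  expect_equal(out2$echo$samples, e$samples, tolerance = 1e-12)
  expect_error(combine_channels(list(e), 0), "positive")
})

test_that("combined noise variance follows the weights and SNR beats every channel", {
  for (seed in c(3, 17, 91)) {
    fx <- multichannel_fixture(seed)
    al <- align_phase(fx$echoes)
    out <- combine_channels(al, fx$noise_sd)
    snr_single <- vapply(fx$echoes, spectral_snr, 1)
    expect_gte(spectral_snr(out$echo), max(snr_single))
    # combined noise variance = sum w_i^2 sigma_i^2 (within estimation error)
    pred_sd <- sqrt(sum(out$weights$weight^2 * fx$noise_sd^2))
    sp <- echo_spectrum(out$echo)
    reg <- sp$frequency >= 300 & sp$frequency <= 900
    expect_lt(abs(stats::sd(Re(sp$spectrum[reg])) / sqrt(out$echo$n) - pred_sd) /
                pred_sd, 0.25)
  }
})

test_that("the default weights maximize SNR over random weightings", {
  fx <- multichannel_fixture(29)
  a <- fx$gains * max(Mod(fx$base))
  sig <- fx$noise_sd
  snr_of <- function(w) sum(w * a) / sqrt(sum(w^2 * sig^2))
  w_star <- a / sig^2
  set.seed(1)
  for (i in 1:1000) {
    w <- runif(length(a))
    expect_lte(snr_of(w), snr_of(w_star) * (1 + 1e-12))
  }
})

test_that("the k-space container round-trips exactly", {
  set.seed(23)
  arr <- array(complex(real = rnorm(2 * 2 * 4 * 4 * 8),
                       imaginary = rnorm(2 * 2 * 4 * 4 * 8)),
               c(2, 2, 4, 4, 8))
  kv <- kspace_volume(arr, sw = 2000, te = 144, tr = 2300,
                      slice_thickness = 10, slice_spacing = 4)
  stem <- file.path(tempdir(), "kvol-test")
  write_kspace(kv, stem)
  back <- read_kspace(stem)
  expect_identical(back$data, kv$data)
  expect_equal(back$sw, 2000)
  expect_equal(back$te, 144)
  expect_equal(back$slice_spacing, 4)
  unlink(paste0(stem, c(".json", ".bin")))
})
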