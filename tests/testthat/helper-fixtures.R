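# Shared fixtures built in code.

default_grid <- function(n = 256) echo_grid(2000, n)

# A well-separated three-singlet model (used where peak proximity is not the
# property under test).
separated_triplet <- function(kind = "lorentzian", fwhm = 10) {
  comp <- spectral_components(c(48, 36, 24), c(-300, 0, 300), 0, 0, 0,
                              label = c("a", "b", "c"))
  if (kind == "lorentzian") {
    comp$lorentz_decay <- fwhm_to_decay(fwhm, "lorentzian")
  } else if (kind == "gaussian") {
    comp$gauss_decay <- fwhm_to_decay(fwhm, "gaussian")
  } else {
    comp$lorentz_decay <- fwhm_to_decay(2.5, "lorentzian")
    comp$gauss_decay <- fwhm_to_decay(7.5, "gaussian")
  }
  comp
}

# Residual-water components: two peaks near the carrier whose summed
# amplitude is `ratio` times the largest metabolite amplitude.
water_components <- function(a_max = 48, ratio = 10) {
  spectral_components(
    amplitude = ratio * a_max * c(0.625, 0.375),
    frequency = c(-6, 9), phase = c(0.4, -0.7),
    lorentz_decay = fwhm_to_decay(c(14, 9), "lorentzian"),
    gauss_decay = 0, label = c("water1", "water2"))
}

# Max relative amplitude error of a fit against the generating components,
# matching fitted to true components by nearest frequency.
max_amp_error <- function(fit, truth) {
  idx <- vapply(truth$frequency, function(f)
    which.min(abs(fit$components$frequency - f)), 1L)
  max(abs(fit$components$amplitude[idx] - truth$amplitude) / truth$amplitude)
}

# Spectral SNR: peak magnitude over the SD of the real part in a signal-free
# frequency band.
spectral_snr <- function(echo, signal_band = c(-500, -100),
                         noise_band = c(300, 900)) {
  sp <- echo_spectrum(echo)
  pk <- max(Mod(sp$spectrum[sp$frequency >= signal_band[1] &
                              sp$frequency <= signal_band[2]]))
  ns <- stats::sd(Re(sp$spectrum[sp$frequency >= noise_band[1] &
                                   sp$frequency <= noise_band[2]]))
  pk / ns
}

# Multichannel fixture: one underlying metabolite echo seen through C
# channels with gains/phases plus independent noise.
multichannel_fixture <- function(seed, n_channels = 8, noise_sd = NULL,
                                 n = 256) {
  set.seed(seed)
  comp <- metabolite_singlets("lorentzian")
  base <- evaluate_model(comp, echo_grid(2000, n))
  gains <- runif(n_channels, 0.4, 1.2)
  phases <- runif(n_channels, -pi, pi)
  if (is.null(noise_sd)) noise_sd <- runif(n_channels, 0.3, 1.5)
  echoes <- lapply(seq_len(n_channels), function(i)
    echo_signal(gains[i] * exp(1i * phases[i]) * base +
                  complex(real = rnorm(n, 0, noise_sd[i]),
                          imaginary = rnorm(n, 0, noise_sd[i])), 2000))
  list(echoes = echoes, gains = gains, phases = phases,
       noise_sd = noise_sd, base = base)
}
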