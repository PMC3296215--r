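#' Gaussian apodization of an echo
#'
#' Multiplies the echo by \eqn{G(t) = e^{-\beta t^2}} with \eqn{\beta} set so
#' that the window alone has a spectral FWHM of `line_broadening` Hz
#' (\eqn{\beta = \pi^2 LB^2 / (4\ln 2)}, see [fwhm_to_decay()]). The echo-top
#' sample (t = 0) is unchanged. Suppresses late-echo noise and baseline
#' distortion at the cost of line broadening; 10 Hz suits phantom-style data
#' and 4 Hz in-vivo-style data.
#'
#' @param echo An [echo_signal()].
#' @param line_broadening Gaussian line broadening in Hz, >= 0.
#' @return The apodized [echo_signal()].
#' @export
apodize <- function(echo, line_broadening) {
  stopifnot(inherits(echo, "echo_signal"))
  if (!is.numeric(line_broadening) || line_broadening < 0)
    stop("invalid parameter: `line_broadening` must be >= 0", call. = FALSE)
  if (line_broadening == 0) return(echo)
  be <- fwhm_to_decay(line_broadening, "gaussian")
  echo_signal(echo$samples * exp(-be * echo$t^2), echo$sw)
}

#' Noise SD from a signal-free spectral region
#'
#' Standard deviation of the real part of the spectrum over a signal-free
#' index range, the per-channel noise measure used to weight the channel
#' combination.
#'
#' @param spectrum Complex spectrum (vector).
#' @param signal_free_region Integer indices of the signal-free region,
#'   at least 32 points.
#' @param peak_bands Optional list of integer index vectors declaring peak
#'   regions; overlap with the region is a configuration error.
#' @return Estimated noise SD (per real channel).
#' @export
estimate_noise <- function(spectrum, signal_free_region, peak_bands = NULL) {
  region <- as.integer(signal_free_region)
  if (length(region) < 32L)
    stop("signal-free region must contain at least 32 points", call. = FALSE)
  if (any(region < 1L) || any(region > length(spectrum)))
    stop("signal-free region outside the spectrum", call. = FALSE)
  if (!is.null(peak_bands) &&
      any(region %in% unlist(peak_bands)))
    stop("signal-free region overlaps a declared peak band", call. = FALSE)
  stats::sd(Re(spectrum[region]))
}

#' Align per-channel echo phases at the echo top
#'
#' Rotates each channel's echo by \eqn{e^{-i\theta_i}}, where \eqn{\theta_i}
#' is the phase of that channel's maximum-magnitude sample (ties broken toward
#' the earlier index). After alignment the echo-top sample is real and
#' non-negative in every channel, so the channels sum coherently.
#'
#' @param echoes List of [echo_signal()] on a common grid.
#' @return List of phase-aligned [echo_signal()], with the removed phases in
#'   attribute `"phases"`.
#' @export
align_phase <- function(echoes) {
  stopifnot(length(echoes) >= 1L, all(vapply(echoes, inherits, TRUE, "echo_signal")))
  n <- unique(vapply(echoes, function(e) e$n, 1L))
  sw <- unique(vapply(echoes, function(e) e$sw, 1))
  if (length(n) != 1L || length(sw) != 1L)
    stop("all echoes must share one sampling grid", call. = FALSE)
  phases <- numeric(length(echoes))
  out <- vector("list", length(echoes))
  for (i in seq_along(echoes)) {
    s <- echoes[[i]]$samples
    if (all(s == 0)) {
      warning(sprintf("channel %d is all-zero; skipped in phase alignment", i))
      out[[i]] <- echoes[[i]]
      next
    }
    top <- which.max(Mod(s))
    phases[i] <- Arg(s[top])
    out[[i]] <- echo_signal(s * exp(-1i * phases[i]), echoes[[i]]$sw)
  }
  attr(out, "phases") <- phases
  out
}

#' Weighted combination of phase-aligned multichannel echoes
#'
#' Sums phase-aligned channel echoes with weights proportional to the echo-top
#' amplitude and inversely proportional to the channel noise level:
#' \eqn{w_i \propto a_i / \sigma_i^2} under the default (SNR-optimal,
#' matched-filter) rule, or \eqn{w_i \propto a_i / \sigma_i} when
#' `weighting = "amp_over_sd"`. Weights are scaled so that
#' \eqn{\sum_i w_i a_i = \max_i a_i}: the combined echo keeps the amplitude
#' scale of the strongest channel, so C identical channels combine to exactly
#' one of them, and a channel with diverging noise receives vanishing weight.
#'
#' @param echoes List of phase-aligned [echo_signal()] (see [align_phase()]).
#' @param noise_sds Numeric vector, one noise SD per channel, all > 0.
#' @param weighting `"amp_over_var"` (default) or `"amp_over_sd"`.
#' @return List with `echo` (the combined [echo_signal()]) and `weights`
#'   (tibble: channel, amplitude, noise_sd, weight).
#' @export
combine_channels <- function(echoes, noise_sds,
                             weighting = c("amp_over_var", "amp_over_sd")) {
  weighting <- match.arg(weighting)
  stopifnot(length(echoes) >= 1L, all(vapply(echoes, inherits, TRUE, "echo_signal")))
  if (length(noise_sds) != length(echoes))
    stop("need one noise SD per channel", call. = FALSE)
  if (any(is.na(noise_sds)) || any(noise_sds <= 0))
    stop("noise SDs must be positive", call. = FALSE)
  a <- vapply(echoes, function(e) max(Mod(e$samples)), 1)
  raw <- switch(weighting,
    amp_over_var = a / noise_sds^2,
    amp_over_sd = a / noise_sds)
  denom <- sum(raw * a)
  w <- if (denom > 0) raw * max(a) / denom else rep(0, length(a))
  comb <- complex(echoes[[1L]]$n)
  for (i in seq_along(echoes)) comb <- comb + w[i] * echoes[[i]]$samples
  list(
    echo = echo_signal(comb, echoes[[1L]]$sw),
    weights = tibble::tibble(
      channel = seq_along(echoes), amplitude = a,
      noise_sd = noise_sds, weight = w)
  )
}
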