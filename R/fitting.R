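#' Initial parameter estimates from the zero-filled magnitude spectrum
#'
#' Zero-fills the echo (default to 4096 points), takes the magnitude spectrum
#' and picks local maxima above a prominence threshold. Initial frequencies
#' come from the bin centres, initial amplitudes from the peak heights
#' corrected by the lineshape height-area relation (the on-resonance peak of a
#' unit-amplitude component equals the summed decay envelope), initial decays
#' from the measured FWHM, and the global initial phase from the phase of the
#' echo-top sample.
#'
#' @param echo An [echo_signal()].
#' @param kind Lineshape kind; decides how the measured FWHM maps to decays.
#' @param n_peaks Keep only the `n_peaks` tallest peaks (optional).
#' @param prominence Absolute height threshold; default
#'   `max(5 * mad(|spectrum|), 0.01 * max(|spectrum|))`, i.e. 5x a robust
#'   noise-floor estimate, falling back to 1 percent of the maximum on
#'   noise-free data.
#' @param n_fft Zero-fill length for the initialization spectrum (default 4096).
#' @param detect_broadening Gaussian broadening (Hz) applied to a copy of the
#'   echo for automatic peak counting only (default 15). Severely truncated
#'   echoes carry sinc wiggles whose lobes are genuine local maxima of the
#'   zero-filled spectrum; apodizing the detection copy suppresses them. Peak
#'   positions, heights and widths are still measured on the raw spectrum.
#'   Ignored when `n_peaks` is given.
#' @return Component tibble ready for [fit_time_domain()], with the global
#'   phase in attribute `"global_phase"`.
#' @export
initialize_params <- function(echo, kind = "lorentzian", n_peaks = NULL,
                              prominence = NULL, n_fft = 4096,
                              detect_broadening = 15) {
  kind <- check_kind(kind)
  stopifnot(inherits(echo, "echo_signal"))
  if (all(echo$samples == 0)) stop("echo is identically zero", call. = FALSE)
  n_fft <- max(n_fft, echo$n)
  sp <- echo_spectrum(echo, n_fft = n_fft)
  ms <- Mod(sp$spectrum)
  n <- length(ms)
  local_max <- function(v)
    c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  if (!is.null(n_peaks)) {
    # known model order: the n_peaks tallest maxima of the raw spectrum
    idx <- which(local_max(ms))
    if (length(idx) > n_peaks)
      idx <- sort(idx[order(ms[idx], decreasing = TRUE)][seq_len(n_peaks)])
  } else {
    # unknown order: count peaks on an apodized copy (wiggle-free), then
    # refine each position to the raw-spectrum maximum nearby
    det <- Mod(echo_spectrum(apodize(echo, detect_broadening), n_fft)$spectrum)
    thr <- if (is.null(prominence))
      max(5 * stats::mad(det), 0.01 * max(det)) else prominence
    cand <- which(local_max(det) & det > thr)
    halfwin <- max(1L, as.integer(round(8 / (echo$sw / n_fft))))   # +/- 8 Hz
    idx <- sort(unique(vapply(cand, function(i) {
      lo <- max(1L, i - halfwin)
      hi <- min(n, i + halfwin)
      lo + which.max(ms[lo:hi]) - 1L
    }, 1L)))
  }
  if (length(idx) == 0L)
    stop("no spectral peak above the prominence threshold", call. = FALSE)

  global_phase <- Arg(echo$samples[which.max(Mod(echo$samples))])
  fwhm <- vapply(idx, function(i) measure_fwhm(sp$frequency, ms, i), 1)
  fwhm[!is.finite(fwhm) | fwhm <= 0] <- 2 * echo$sw / n

  al <- be <- numeric(length(idx))
  if (kind == "lorentzian") al <- fwhm_to_decay(fwhm, "lorentzian")
  if (kind == "gaussian") be <- fwhm_to_decay(fwhm, "gaussian")
  if (kind == "voigt") {
    al <- fwhm_to_decay(fwhm / 2, "lorentzian")
    be <- rep(fwhm_to_decay(mean(fwhm) / 2, "gaussian"), length(idx))
  }
  # height-area relation on this grid: unit component peaks at sum(envelope)
  amp <- vapply(seq_along(idx), function(j) {
    env <- sum(exp(-al[j] * abs(echo$t) - be[j] * echo$t^2))
    ms[idx[j]] / env
  }, 1)
  comp <- spectral_components(amp, sp$frequency[idx], global_phase, al, be)
  attr(comp, "global_phase") <- global_phase
  comp
}

# FWHM of the peak at index i by linear interpolation of the half-max
# crossings on each side.
measure_fwhm <- function(freq, ms, i) {
  half <- ms[i] / 2
  l <- i
  while (l > 1L && ms[l] > half) l <- l - 1L
  r <- i
  n <- length(ms)
  while (r < n && ms[r] > half) r <- r + 1L
  if (ms[l] > half || ms[r] > half) return(NA_real_)
  fl <- freq[l] + (half - ms[l]) / (ms[l + 1L] - ms[l]) * (freq[l + 1L] - freq[l])
  fr <- freq[r - 1L] + (half - ms[r - 1L]) / (ms[r] - ms[r - 1L]) *
    (freq[r] - freq[r - 1L])
  fr - fl
}

new_fit_result <- function(components, kind, residual_norm, n_iterations,
                           converged, domain) {
  structure(
    list(components = components, kind = kind, residual_norm = residual_norm,
         n_iterations = n_iterations, converged = converged, domain = domain),
    class = "mrsi_fit"
  )
}

#' @export
print.mrsi_fit <- function(x, ...) {
  cat(sprintf("<mrsi_fit> %s-domain %s fit, %d components, residual %.4g, %s\n",
              x$domain, x$kind, nrow(x$components), x$residual_norm,
              if (x$converged) sprintf("converged in %d iterations", x$n_iterations)
              else "NOT converged"))
  print(x$components)
  invisible(x)
}

#' Tidy a spectral fit
#' @param x An `mrsi_fit`.
#' @param ... Unused.
#' @return Tibble of fitted components.
#' @export
tidy.mrsi_fit <- function(x, ...) x$components

#' One-row fit summary
#' @param x An `mrsi_fit`.
#' @param ... Unused.
#' @export
glance.mrsi_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, domain = x$domain,
                 n_components = nrow(x$components),
                 residual_norm = x$residual_norm,
                 n_iterations = x$n_iterations, converged = x$converged)
}

#' Turn a fitted object into a tidy tibble
#' @param x Object.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of a fitted object
#' @param x Object.
#' @param ... Method arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")

wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  ifelse(out == -pi, pi, out)
}

fit_bounds <- function(kind, M) {
  lo <- rep(-Inf, 4L * M)
  lo[seq(1L, 4L * M, by = 4L)] <- 0   # amplitudes
  lo[seq(4L, 4L * M, by = 4L)] <- 0   # decays
  if (kind == "voigt") lo <- c(lo, 0)
  lo
}

#' Nonlinear least-squares fit of a full echo in the time domain
#'
#' Minimizes \eqn{\sum_n |S_{model}(t_n) - s(t_n)|^2} by Levenberg-Marquardt
#' on the concatenated real/imaginary residual, with the analytic Jacobian.
#' The lineshape kind fixes the constraint pattern (\eqn{\beta = 0} /
#' \eqn{\alpha = 0} / shared \eqn{\beta}); amplitudes and decays are bounded
#' below by zero. Hitting the iteration cap sets `converged = FALSE` rather
#' than raising.
#'
#' @param echo An [echo_signal()].
#' @param kind Lineshape kind.
#' @param init Initial component tibble (e.g. from [initialize_params()]).
#' @param max_iter Iteration cap (default 500).
#' @return An `mrsi_fit` (see [tidy.mrsi_fit()]).
#' @export
fit_time_domain <- function(echo, kind = "lorentzian", init,
                            max_iter = 500) {
  kind <- check_kind(kind)
  stopifnot(inherits(echo, "echo_signal"))
  validate_components(init)
  M <- nrow(init)
  if (4L * M + (kind == "voigt") >= echo$n / 4)
    stop("overparameterized model: too many components for this echo length",
         call. = FALSE)
  p0 <- param_pack(init, kind)
  y <- echo$samples
  t <- echo$t
  fn <- function(p) {
    r <- model_eval_p(p, t, kind, M) - y
    c(Re(r), Im(r))
  }
  jac <- function(p) {
    J <- model_jacobian(p, t, kind, M)
    rbind(Re(J), Im(J))
  }
  fit <- minpack.lm::nls.lm(
    par = p0, lower = fit_bounds(kind, M), fn = fn, jac = jac,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-12, ptol = 1e-12, gtol = 0))
  comp <- param_unpack(fit$par, kind, M, init$label)
  comp$phase <- wrap_phase(comp$phase)
  new_fit_result(comp, kind,
                 residual_norm = sqrt(fit$deviance),
                 n_iterations = fit$niter,
                 converged = fit$info %in% 1:3,
                 domain = "time")
}

# Scaled complementary error function erfcx(z) = exp(z^2) erfc(z) for
# complex z with Re(z) >= 0, via the Faddeeva function w(iz) evaluated with
# Weideman's rational approximation (uniformly accurate on the closed upper
# half plane; N = 36 terms gives ~1e-14). Coefficients are cached.
weideman_env <- new.env(parent = emptyenv())

weideman_coefs <- function(N = 36L) {
  key <- as.character(N)
  if (!is.null(weideman_env[[key]])) return(weideman_env[[key]])
  M <- 2L * N
  M2 <- 2L * M
  k <- (-M + 1L):(M - 1L)
  L <- sqrt(N / sqrt(2))
  t <- L * tan(k * pi / M / 2)
  f <- c(0, exp(-t^2) * (L^2 + t^2))
  a <- Re(stats::fft(fftshift_vec(f))) / M2
  a <- rev(a[2:(N + 1L)])
  res <- list(a = a, L = L)
  weideman_env[[key]] <- res
  res
}

# Faddeeva w(z) = exp(-z^2) erfc(-iz) for Im(z) >= 0.
faddeeva_upper <- function(z) {
  cf <- weideman_coefs()
  L <- cf$L
  iZ <- (L + 1i * z) / (L - 1i * z)
  p <- rep(0 + 0i, length(z))
  for (ak in cf$a) p <- p * iZ + ak
  2 * p / (L - 1i * z)^2 + (1 / sqrt(pi)) / (L - 1i * z)
}

erfcx_cplx <- function(z) {
  out <- faddeeva_upper(1i * z)
  big <- Mod(z) > 1e7    # avoid roundoff in the Mobius transform far out
  if (any(big)) out[big] <- 1 / (z[big] * sqrt(pi))
  out
}

# Analytic (non-truncated) lineshape spectrum of one component at frequency
# offsets df, scaled to the discrete spectrum convention (1/dt).
# Lorentzian: 2a/(a^2 + 4 pi^2 df^2); Gaussian: sqrt(pi/b) exp(-pi^2 df^2 / b);
# Voigt via the scaled complex error function.
lineshape_profile <- function(df, alpha, beta) {
  if (is.na(alpha) || is.na(beta)) return(rep(NA_real_, length(df)))
  if (beta <= 1e-12) {
    2 * alpha / (alpha^2 + 4 * pi^2 * df^2)
  } else if (alpha <= 1e-12) {
    sqrt(pi / beta) * exp(-pi^2 * df^2 / beta)
  } else {
    z <- complex(real = alpha, imaginary = 2 * pi * df) / (2 * sqrt(beta))
    Re(sqrt(pi / beta) * erfcx_cplx(z))
  }
}

# Profile and its partial derivatives wrt frequency offset and the decays.
# For the Voigt branch: with w = erfcx(z), w'(z) = 2 z w - 2/sqrt(pi).
lineshape_profile_grad <- function(df, alpha, beta) {
  if (beta <= 1e-12) {
    u <- 2 * pi * df
    den <- (alpha^2 + u^2)
    list(prof = 2 * alpha / den,
         d_df = -8 * pi * alpha * u / den^2,
         d_alpha = 2 * (u^2 - alpha^2) / den^2,
         d_beta = rep(0, length(df)))
  } else if (alpha <= 1e-12) {
    prof <- sqrt(pi / beta) * exp(-pi^2 * df^2 / beta)
    list(prof = prof,
         d_df = prof * (-2 * pi^2 * df / beta),
         d_alpha = rep(0, length(df)),
         d_beta = prof * (-1 / (2 * beta) + pi^2 * df^2 / beta^2))
  } else {
    sb <- sqrt(beta)
    z <- complex(real = alpha, imaginary = 2 * pi * df) / (2 * sb)
    w <- erfcx_cplx(z)
    wp <- 2 * z * w - 2 / sqrt(pi)
    list(prof = Re(sqrt(pi) / sb * w),
         d_df = Re(1i * pi^1.5 * wp / beta),
         d_alpha = Re(sqrt(pi) * wp / (2 * beta)),
         d_beta = Re(-0.5 * sqrt(pi) * beta^-1.5 * w -
                       sqrt(pi) / sb * wp * z / (2 * beta)))
  }
}

model_spectrum <- function(p, freq, kind, M, dt) {
  comp <- param_unpack(p, kind, M)
  s <- complex(length(freq))
  for (m in seq_len(M)) {
    prof <- lineshape_profile(freq - comp$frequency[m],
                              comp$lorentz_decay[m], comp$gauss_decay[m])
    s <- s + comp$amplitude[m] * exp(1i * comp$phase[m]) * prof
  }
  s / dt
}

# Complex Jacobian of model_spectrum wrt the packed parameters; rows = freq.
spectrum_jacobian <- function(p, freq, kind, M, dt) {
  comp <- param_unpack(p, kind, M)
  np <- length(p)
  J <- matrix(0 + 0i, length(freq), np)
  dbe_acc <- complex(length(freq))
  for (m in seq_len(M)) {
    pg <- lineshape_profile_grad(freq - comp$frequency[m],
                                 comp$lorentz_decay[m], comp$gauss_decay[m])
    ph <- exp(1i * comp$phase[m])
    A <- comp$amplitude[m]
    J[, 4L * (m - 1L) + 1L] <- ph * pg$prof
    J[, 4L * (m - 1L) + 2L] <- -A * ph * pg$d_df
    J[, 4L * (m - 1L) + 3L] <- 1i * A * ph * pg$prof
    J[, 4L * (m - 1L) + 4L] <- A * ph *
      (if (kind == "gaussian") pg$d_beta else pg$d_alpha)
    if (kind == "voigt") dbe_acc <- dbe_acc + A * ph * pg$d_beta
  }
  if (kind == "voigt") J[, np] <- dbe_acc
  J / dt
}

#' Least-squares fit of the spectrum in the frequency domain
#'
#' Fourier-transforms the (optionally zero-filled) echo and fits the analytic
#' continuous-lineshape spectrum, sampled at the grid frequencies, to the
#' complex data spectrum. This is the comparison method: with truncated
#' echoes the data spectrum carries truncation/wiggle artifacts that the
#' continuous model cannot represent, producing the characteristic
#' frequency-domain amplitude errors.
#'
#' @inheritParams fit_time_domain
#' @param n_spectrum Spectrum length: the echo length (no padding) or a larger
#'   zero-fill length.
#' @return An `mrsi_fit` with `domain = "frequency"`.
#' @export
fit_frequency_domain <- function(echo, kind = "lorentzian", init,
                                 n_spectrum = NULL, max_iter = 500) {
  kind <- check_kind(kind)
  stopifnot(inherits(echo, "echo_signal"))
  validate_components(init)
  M <- nrow(init)
  if (4L * M + (kind == "voigt") >= echo$n / 4)
    stop("overparameterized model: too many components for this echo length",
         call. = FALSE)
  if (is.null(n_spectrum)) n_spectrum <- echo$n
  if (n_spectrum < echo$n)
    stop("`n_spectrum` must be the echo length or a zero-fill length >= it",
         call. = FALSE)
  sp <- echo_spectrum(echo, n_fft = n_spectrum)
  y <- sp$spectrum
  freq <- sp$frequency
  dt <- echo$dt
  p0 <- param_pack(init, kind)
  fn <- function(p) {
    r <- model_spectrum(p, freq, kind, M, dt) - y
    c(Re(r), Im(r))
  }
  jac <- function(p) {
    J <- spectrum_jacobian(p, freq, kind, M, dt)
    rbind(Re(J), Im(J))
  }
  fit <- minpack.lm::nls.lm(
    par = p0, lower = fit_bounds(kind, M), fn = fn, jac = jac,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-12, ptol = 1e-12, gtol = 0))
  comp <- param_unpack(fit$par, kind, M, init$label)
  comp$phase <- wrap_phase(comp$phase)
  new_fit_result(comp, kind,
                 residual_norm = sqrt(fit$deviance),
                 n_iterations = fit$niter,
                 converged = fit$info %in% 1:3,
                 domain = "frequency")
}

# Match fitted components to reference components by nearest frequency.
match_components <- function(fitted, reference) {
  idx <- vapply(reference$frequency, function(f)
    which.min(abs(fitted$frequency - f)), 1L)
  fitted[idx, , drop = FALSE]
}
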