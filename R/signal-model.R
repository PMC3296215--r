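#' Spectral components of the echo model
#'
#' The package models a full echo as a sum of M damped complex sinusoids,
#' \deqn{S(t) = \sum_{m=1}^{M} A_m e^{i(2\pi f_m t + \phi_m)}
#'             e^{-\alpha_m |t| - \beta_m t^2},}
#' with two-sided decay about the echo top. `amplitude` \eqn{A_m \ge 0} is in
#' signal units, `frequency` \eqn{f_m} the Hz offset from the carrier, `phase`
#' \eqn{\phi_m} in radians in \eqn{(-\pi, \pi]}, `lorentz_decay`
#' \eqn{\alpha_m \ge 0} in 1/s and `gauss_decay` \eqn{\beta_m \ge 0} in 1/s^2.
#'
#' Lineshape kinds constrain the decays: `"lorentzian"` fixes \eqn{\beta_m = 0},
#' `"gaussian"` fixes \eqn{\alpha_m = 0}, and `"voigt"` keeps both with a single
#' \eqn{\beta} shared by all M components.
#'
#' @param amplitude,frequency,phase,lorentz_decay,gauss_decay Numeric vectors,
#'   recycled to a common length.
#' @param label Optional component labels (e.g. metabolite names).
#' @return A tibble with one row per component.
#' @export
spectral_components <- function(amplitude, frequency, phase = 0,
                                lorentz_decay = 0, gauss_decay = 0,
                                label = NULL) {
  comp <- tibble::tibble(
    amplitude = as.numeric(amplitude),
    frequency = as.numeric(frequency),
    phase = as.numeric(phase),
    lorentz_decay = as.numeric(lorentz_decay),
    gauss_decay = as.numeric(gauss_decay)
  )
  comp$label <- if (is.null(label)) paste0("c", seq_len(nrow(comp))) else
    as.character(label)
  validate_components(comp)
  comp
}

validate_components <- function(comp) {
  need <- c("amplitude", "frequency", "phase", "lorentz_decay", "gauss_decay")
  if (!all(need %in% names(comp)))
    stop("components need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(comp) < 1L) stop("at least one spectral component required", call. = FALSE)
  if (any(!is.finite(as.matrix(comp[need]))))
    stop("component parameters must be finite", call. = FALSE)
  if (any(comp$amplitude < 0))
    stop("invalid parameter: negative amplitude", call. = FALSE)
  if (any(comp$lorentz_decay < 0) || any(comp$gauss_decay < 0))
    stop("invalid parameter: negative decay constant", call. = FALSE)
  invisible(comp)
}

lineshape_kinds <- c("lorentzian", "gaussian", "voigt")

check_kind <- function(kind) {
  match.arg(kind, lineshape_kinds)
}

#' Evaluate the echo model on a sampling grid
#'
#' @param components Component table from [spectral_components()].
#' @param grid An [echo_grid()] or [echo_signal()] supplying the time axis.
#' @return Complex vector of model samples \eqn{S(t_n)}.
#' @examples
#' g <- echo_grid(2000, 256)
#' s <- evaluate_model(spectral_components(48, 0), g)
#' all(s == 48 + 0i)
#' @export
evaluate_model <- function(components, grid) {
  validate_components(components)
  g <- as_echo_grid(grid)
  model_eval_t(components, g$t)
}

model_eval_t <- function(comp, t) {
  s <- complex(length(t))
  for (m in seq_len(nrow(comp))) {
    s <- s + comp$amplitude[m] *
      exp(1i * (2 * pi * comp$frequency[m] * t + comp$phase[m])) *
      exp(-comp$lorentz_decay[m] * abs(t) - comp$gauss_decay[m] * t^2)
  }
  s
}

#' Convert a spectral FWHM linewidth to a time-domain decay constant
#'
#' For a Lorentzian envelope \eqn{e^{-\alpha|t|}} the magnitude-spectrum full
#' width at half maximum is \eqn{\alpha/\pi}, so \eqn{\alpha = \pi\,\mathrm{FWHM}}.
#' For a Gaussian envelope \eqn{e^{-\beta t^2}} the spectrum is Gaussian with
#' \eqn{\mathrm{FWHM} = 2\sqrt{\beta \ln 2}/\pi}, so
#' \eqn{\beta = \pi^2 \mathrm{FWHM}^2 / (4 \ln 2)}.
#'
#' @param fwhm Linewidth in Hz (full width at half maximum), >= 0.
#' @param kind `"lorentzian"` or `"gaussian"`.
#' @return Decay constant: \eqn{\alpha} (1/s) or \eqn{\beta} (1/s^2).
#' @export
fwhm_to_decay <- function(fwhm, kind = c("lorentzian", "gaussian")) {
  kind <- match.arg(kind)
  if (any(!is.finite(fwhm)) || any(fwhm < 0))
    stop("invalid parameter: `fwhm` must be >= 0", call. = FALSE)
  switch(kind,
    lorentzian = pi * fwhm,
    gaussian = pi^2 * fwhm^2 / (4 * log(2))
  )
}

#' Inverse of [fwhm_to_decay()]
#' @param decay Decay constant (1/s for Lorentzian, 1/s^2 for Gaussian).
#' @param kind Lineshape kind.
#' @return FWHM in Hz.
#' @export
decay_to_fwhm <- function(decay, kind = c("lorentzian", "gaussian")) {
  kind <- match.arg(kind)
  if (any(decay < 0)) stop("invalid parameter: negative decay", call. = FALSE)
  switch(kind,
    lorentzian = decay / pi,
    gaussian = 2 * sqrt(decay * log(2)) / pi
  )
}

#' Default brain metabolite singlet model
#'
#' Three singlets for NAA, Cr and Cho at 2.01, 3.03 and 3.22 ppm, expressed as
#' Hz offsets from the water carrier at 4.70 ppm. Default amplitude ratios are
#' 48:36:24 (a.u.) and the default linewidth is 10 Hz FWHM. For the Voigt kind
#' the linewidth splits into a 2.5 Hz Lorentzian and a 7.5 Hz Gaussian FWHM
#' contribution, the Gaussian decay shared across components.
#'
#' @param kind Lineshape kind.
#' @param amplitudes Named amplitudes for NAA, Cr, Cho.
#' @param fwhm Linewidth in Hz FWHM (scalar) for the pure lineshapes.
#' @param voigt_fwhm Length-2 vector: Lorentzian and Gaussian FWHM contributions
#'   used when `kind = "voigt"`.
#' @param field_mhz Proton resonance frequency in MHz (default 127.74, 3 T).
#' @param phase Common phase in radians.
#' @return Component tibble (see [spectral_components()]).
#' @export
metabolite_singlets <- function(kind = c("lorentzian", "gaussian", "voigt"),
                                amplitudes = c(NAA = 48, Cr = 36, Cho = 24),
                                fwhm = 10, voigt_fwhm = c(2.5, 7.5),
                                field_mhz = 127.74, phase = 0) {
  kind <- match.arg(kind)
  ppm <- c(NAA = 2.01, Cr = 3.03, Cho = 3.22)
  nm <- names(amplitudes)
  if (is.null(nm)) nm <- names(ppm)[seq_along(amplitudes)]
  freq <- (ppm[nm] - 4.70) * field_mhz
  al <- switch(kind,
    lorentzian = fwhm_to_decay(fwhm, "lorentzian"),
    gaussian = 0,
    voigt = fwhm_to_decay(voigt_fwhm[1L], "lorentzian"))
  be <- switch(kind,
    lorentzian = 0,
    gaussian = fwhm_to_decay(fwhm, "gaussian"),
    voigt = fwhm_to_decay(voigt_fwhm[2L], "gaussian"))
  spectral_components(unname(amplitudes), unname(freq), phase, al, be, label = nm)
}

# ---- Fisher information / CRLB ------------------------------------------------

# Free-parameter layout for a lineshape kind: per component A, f, phi plus the
# kind's decay (alpha for lorentzian/voigt, beta for gaussian), and for voigt
# one trailing shared beta.
param_pack <- function(comp, kind) {
  M <- nrow(comp)
  per <- switch(kind,
    lorentzian = comp$lorentz_decay,
    gaussian = comp$gauss_decay,
    voigt = comp$lorentz_decay)
  p <- as.vector(rbind(comp$amplitude, comp$frequency, comp$phase, per))
  if (kind == "voigt") p <- c(p, comp$gauss_decay[1L])
  p
}

param_unpack <- function(p, kind, M, labels = NULL) {
  q <- matrix(p[seq_len(4L * M)], nrow = 4L)
  al <- switch(kind, lorentzian = q[4L, ], gaussian = rep(0, M), voigt = q[4L, ])
  be <- switch(kind, lorentzian = rep(0, M), gaussian = q[4L, ],
               voigt = rep(p[4L * M + 1L], M))
  tibble::tibble(
    amplitude = q[1L, ], frequency = q[2L, ], phase = q[3L, ],
    lorentz_decay = al, gauss_decay = be,
    label = if (is.null(labels)) paste0("c", seq_len(M)) else labels
  )
}

param_names <- function(kind, M, labels = NULL) {
  if (is.null(labels)) labels <- paste0("c", seq_len(M))
  decay <- switch(kind, lorentzian = "alpha", gaussian = "beta", voigt = "alpha")
  nm <- as.vector(vapply(labels, function(l)
    paste0(c("A_", "f_", "phi_", paste0(decay, "_")), l), character(4L)))
  if (kind == "voigt") nm <- c(nm, "beta_shared")
  nm
}

# Complex Jacobian of the model wrt the packed free parameters; rows = t.
model_jacobian <- function(p, t, kind, M) {
  np <- length(p)
  J <- matrix(0 + 0i, length(t), np)
  be_sh <- if (kind == "voigt") p[4L * M + 1L] else 0
  dbe_acc <- complex(length(t))
  for (m in seq_len(M)) {
    q <- p[(4L * (m - 1L) + 1L):(4L * m)]
    al <- switch(kind, lorentzian = q[4L], gaussian = 0, voigt = q[4L])
    be <- switch(kind, lorentzian = 0, gaussian = q[4L], voigt = be_sh)
    base <- exp(1i * (2 * pi * q[2L] * t + q[3L])) * exp(-al * abs(t) - be * t^2)
    sm <- q[1L] * base
    J[, 4L * (m - 1L) + 1L] <- base
    J[, 4L * (m - 1L) + 2L] <- 1i * 2 * pi * t * sm
    J[, 4L * (m - 1L) + 3L] <- 1i * sm
    J[, 4L * (m - 1L) + 4L] <- if (kind == "gaussian") -t^2 * sm else -abs(t) * sm
    if (kind == "voigt") dbe_acc <- dbe_acc - t^2 * sm
  }
  if (kind == "voigt") J[, np] <- dbe_acc
  J
}

model_eval_p <- function(p, t, kind, M) {
  model_eval_t(param_unpack(p, kind, M), t)
}

#' Cramer-Rao lower bounds for the echo model parameters
#'
#' Fisher information of the free parameters (per-component amplitude,
#' frequency, phase and decay; one shared Gaussian decay under the Voigt kind)
#' for the concatenated real/imaginary observation model with i.i.d. Gaussian
#' noise of SD `noise_sd` per real channel:
#' \eqn{I = \sigma^{-2}\,\mathrm{Re}(J^H J)}. Bounds are the square roots of
#' the diagonal of \eqn{I^{-1}}; they scale linearly in `noise_sd`.
#'
#' @param components Component table (true parameter values).
#' @param kind Lineshape kind; fixes which decays are free.
#' @param grid [echo_grid()] or [echo_signal()].
#' @param noise_sd Noise SD per real channel, > 0.
#' @param free_parameters `"all"` (default: every parameter the lineshape kind
#'   leaves free) or `"amplitude"` (amplitudes only, all other parameters
#'   treated as known).
#' @return Object of class `crlb_result`: list with `bounds` (tibble:
#'   `parameter`, `value`, `bound`), `noise_sd`, `fisher_condition`.
#' @export
compute_crlb <- function(components, kind = "lorentzian", grid, noise_sd,
                         free_parameters = c("all", "amplitude")) {
  kind <- check_kind(kind)
  free_parameters <- match.arg(free_parameters)
  validate_components(components)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0)
    stop("`noise_sd` must be a positive scalar", call. = FALSE)
  g <- as_echo_grid(grid)
  M <- nrow(components)
  p <- param_pack(components, kind)
  J <- model_jacobian(p, g$t, kind, M)
  if (free_parameters == "amplitude") {
    sel <- seq(1L, 4L * M, by = 4L)
    J <- J[, sel, drop = FALSE]
    p <- p[sel]
  }
  fim <- Re(Conj(t(J)) %*% J) / noise_sd^2
  ev <- eigen(fim, symmetric = TRUE, only.values = TRUE)$values
  cond <- max(ev) / max(min(ev), 0)
  if (!is.finite(cond) || min(ev) <= max(ev) * .Machine$double.eps * 1e3) {
    gaps <- abs(outer(components$frequency, components$frequency, "-"))
    diag(gaps) <- Inf
    close <- which(gaps == min(gaps), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "model not identifiable: singular Fisher matrix (components '%s' and '%s' collide at %.4g Hz apart)",
      components$label[close[1L]], components$label[close[2L]],
      min(gaps)), call. = FALSE)
  }
  bounds <- sqrt(diag(solve(fim)))
  nm <- param_names(kind, M, components$label)
  if (free_parameters == "amplitude") nm <- nm[grepl("^A_", nm)]
  structure(
    list(
      bounds = tibble::tibble(parameter = nm, value = p, bound = bounds),
      noise_sd = noise_sd,
      fisher_condition = cond
    ),
    class = "crlb_result"
  )
}

#' @export
print.crlb_result <- function(x, ...) {
  cat(sprintf("<crlb_result> noise_sd %.4g, Fisher condition %.3g\n",
              x$noise_sd, x$fisher_condition))
  print(x$bounds, n = nrow(x$bounds))
  invisible(x)
}

#' Amplitude CRLBs only
#' @param crlb A `crlb_result`.
#' @return Named numeric vector of amplitude bounds, one per component.
#' @export
amplitude_crlb <- function(crlb) {
  stopifnot(inherits(crlb, "crlb_result"))
  b <- crlb$bounds
  sel <- grepl("^A_", b$parameter)
  stats::setNames(b$bound[sel], sub("^A_", "", b$parameter[sel]))
}
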