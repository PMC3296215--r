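#' Sampling grid of a full echo
#'
#' A full echo is sampled symmetrically about its top: with dwell time
#' \eqn{dt = 1/SW}, the time axis is \eqn{t_n = (n - N/2)\,dt} for
#' \eqn{n = 0, \dots, N-1}, running from \eqn{-dt\,N/2} to \eqn{dt\,(N/2-1)}.
#' The echo top (\eqn{t = 0}) sits at 0-based index \eqn{N/2}.
#'
#' @param sw Spectral width in Hz (sampling rate).
#' @param n Number of complex points, at least 2.
#' @return An object of class `echo_grid`: a list with `sw`, `n`, `dt` and the
#'   time axis `t` (seconds).
#' @examples
#' g <- echo_grid(2000, 256)
#' range(g$t)   # -0.064 to 0.0635
#' @export
echo_grid <- function(sw, n) {
  if (!is.numeric(sw) || length(sw) != 1L || sw <= 0)
    stop("`sw` must be a positive spectral width in Hz", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("`n` must be an integer number of points >= 2", call. = FALSE)
  n <- as.integer(n)
  dt <- 1 / sw
  structure(
    list(sw = sw, n = n, dt = dt, t = ((0:(n - 1L)) - n / 2) * dt),
    class = "echo_grid"
  )
}

#' A sampled complex full echo
#'
#' @param samples Complex vector of length >= 2, sampled on the symmetric grid
#'   of [echo_grid()].
#' @param sw Spectral width in Hz.
#' @return An object of class `echo_signal`: list with `samples`, `sw`, `dt`,
#'   `n` and time axis `t`.
#' @export
echo_signal <- function(samples, sw) {
  if (!is.numeric(samples) && !is.complex(samples))
    stop("`samples` must be a numeric or complex vector", call. = FALSE)
  g <- echo_grid(sw, length(samples))
  structure(
    list(samples = as.complex(samples), sw = sw, dt = g$dt, n = g$n, t = g$t),
    class = "echo_signal"
  )
}

as_echo_grid <- function(x) {
  if (inherits(x, "echo_grid")) return(x)
  if (inherits(x, "echo_signal")) return(echo_grid(x$sw, x$n))
  stop("expected an `echo_grid` or `echo_signal`", call. = FALSE)
}

#' @export
print.echo_signal <- function(x, ...) {
  cat(sprintf("<echo_signal> %d complex points, SW %.6g Hz, t in [%.6g, %.6g] s\n",
              x$n, x$sw, x$t[1L], x$t[x$n]))
  invisible(x)
}

#' @export
print.echo_grid <- function(x, ...) {
  cat(sprintf("<echo_grid> %d points, SW %.6g Hz, dt %.6g s\n", x$n, x$sw, x$dt))
  invisible(x)
}

# Zero-extend a full echo symmetrically in time to `n_out` points.
# The original samples keep their time coordinates; the axis grows on both
# sides so that t = 0 stays at 0-based index n_out/2.
pad_echo <- function(echo, n_out) {
  stopifnot(inherits(echo, "echo_signal"))
  n_out <- as.integer(n_out)
  if (n_out < echo$n) stop("`n_out` must be >= the echo length", call. = FALSE)
  if (n_out == echo$n) return(echo)
  out <- complex(n_out)
  offset <- floor(n_out / 2) - floor(echo$n / 2)
  out[(offset + 1L):(offset + echo$n)] <- echo$samples
  echo_signal(out, echo$sw)
}

#' Spectrum of a full echo
#'
#' Discrete Fourier transform honouring the symmetric time axis:
#' \eqn{S(f_k) = \sum_n s(t_n) e^{-i 2\pi f_k t_n}} on the frequency grid
#' \eqn{f_k = (k - n/2)\,SW/n}. Optionally zero-fills the echo first.
#'
#' @param echo An [echo_signal()].
#' @param n_fft Output length (>= echo length); the echo is zero-extended
#'   symmetrically in time. Default: the echo length.
#' @return List with `frequency` (Hz, ascending) and complex `spectrum`.
#' @export
echo_spectrum <- function(echo, n_fft = NULL) {
  stopifnot(inherits(echo, "echo_signal"))
  if (!is.null(n_fft)) echo <- pad_echo(echo, n_fft)
  sp <- fftshift_vec(stats::fft(ifftshift_vec(echo$samples)))
  list(frequency = freq_axis(echo$n, echo$sw), spectrum = sp)
}
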