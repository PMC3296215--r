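# FFT bookkeeping shared across the package.
#
# Convention: the k-space / frequency origin sits at index floor(n/2) (0-based),
# i.e. the centre of even-length grids, so that fftshift() moves the origin of a
# raw DFT to the grid centre and ifftshift() undoes it (they differ for odd n).

fftshift_vec <- function(x) {
  n <- length(x)
  if (n < 2L) return(x)
  s <- floor(n / 2)
  c(x[(n - s + 1L):n], x[1L:(n - s)])
}

ifftshift_vec <- function(x) {
  n <- length(x)
  if (n < 2L) return(x)
  s <- ceiling(n / 2)
  c(x[(n - s + 1L):n], x[1L:(n - s)])
}

shift_index <- function(n, inverse = FALSE) {
  s <- if (inverse) ceiling(n / 2) else floor(n / 2)
  c((n - s + 1L):n, seq_len(n - s))
}

# Apply fftshift/ifftshift along the first two dims of an array.
shift2 <- function(x, inverse = FALSE) {
  d <- dim(x)
  idx <- c(list(shift_index(d[1L], inverse), shift_index(d[2L], inverse)),
           lapply(d[-(1:2)], seq_len))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Batched 2D DFT over the first two dims of an n-dimensional array, via two
# passes of stats::mvfft. Unnormalized, like stats::fft.
fft2_batch <- function(x, inverse = FALSE) {
  d <- dim(x)
  stopifnot(length(d) >= 2L)
  xm <- matrix(x, d[1L], prod(d[-1L]))
  xm <- stats::mvfft(xm, inverse = inverse)
  x <- array(xm, d)
  perm <- c(2L, 1L, seq_along(d)[-(1:2)])
  x <- aperm(x, perm)
  d2 <- dim(x)
  xm <- matrix(x, d2[1L], prod(d2[-1L]))
  xm <- stats::mvfft(xm, inverse = inverse)
  aperm(array(xm, d2), perm)
}

# Frequency axis matching the shifted DFT: f_k = (k - floor(n/2)) * sw / n.
freq_axis <- function(n, sw) {
  (seq_len(n) - 1L - floor(n / 2)) * sw / n
}

# Seeded complex circular Gaussian noise, SD `sd` per real channel.
complex_noise <- function(n, sd) {
  complex(real = stats::rnorm(n, 0, sd), imaginary = stats::rnorm(n, 0, sd))
}
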