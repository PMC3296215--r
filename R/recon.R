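#' Multichannel, multislice phase-encoded echo array
#'
#' Container for raw k-space MRSI data: a 5-D complex array with dimensions
#' (channel, slice, ky, kx, time) plus acquisition metadata. Slices are
#' numbered inferior to superior; voxel (1, 1) of a reconstructed slice is the
#' anterior-left corner; the k-space origin sits at 0-based index `n/2` of
#' each even phase-encoding axis.
#'
#' @param data Complex 5-D array, dims (channel, slice, ky, kx, time).
#' @param sw Spectral width in Hz.
#' @param te,tr Echo and repetition time in ms (metadata, optional).
#' @param slice_thickness,slice_spacing Slice geometry in mm (optional).
#' @return Object of class `kspace_volume`.
#' @export
kspace_volume <- function(data, sw, te = NA_real_, tr = NA_real_,
                          slice_thickness = NA_real_, slice_spacing = NA_real_) {
  if (!is.array(data) || length(dim(data)) != 5L)
    stop("`data` must be a 5-D array (channel, slice, ky, kx, time)",
         call. = FALSE)
  if (!is.complex(data)) storage.mode(data) <- "complex"
  g <- echo_grid(sw, dim(data)[5L])
  structure(
    list(data = data, sw = sw, dt = g$dt, t = g$t, te = te, tr = tr,
         slice_thickness = slice_thickness, slice_spacing = slice_spacing),
    class = "kspace_volume"
  )
}

#' @export
print.kspace_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<kspace_volume> %d channels x %d slices x %dx%d encodings x %d points, SW %.6g Hz\n",
    d[1L], d[2L], d[3L], d[4L], d[5L], x$sw))
  invisible(x)
}

# Hamming window with peak 1 at 0-based index floor(n/2) and value
# 0.54 - 0.46 = 0.08 at index 0 (even n): standard coefficients, centred on
# the k-space origin.
hamming_window <- function(n) {
  k <- seq_len(n) - 1L
  0.54 + 0.46 * cos(pi * (k - floor(n / 2)) / (n / 2))
}

#' Spatial k-space filtering
#'
#' Multiplies each (ky, kx) plane by a separable 2D window centred on the
#' k-space origin; channel, slice and time axes are untouched. Hamming
#' filtering suppresses the point-spread sidelobes (Gibbs ringing) of the
#' finite phase-encoding grid at the cost of spatial-resolution broadening.
#'
#' @param kvol A [kspace_volume()].
#' @param window `"hamming"` or `"none"`.
#' @return The filtered [kspace_volume()].
#' @export
spatial_filter <- function(kvol, window = c("hamming", "none")) {
  stopifnot(inherits(kvol, "kspace_volume"))
  if (!is.character(window) || !window[1L] %in% c("hamming", "none"))
    stop("unknown window name: ", window[1L], call. = FALSE)
  window <- window[1L]
  if (window == "none") return(kvol)
  d <- dim(kvol$data)
  w2 <- outer(hamming_window(d[3L]), hamming_window(d[4L]))
  warr <- aperm(array(w2, c(d[3L], d[4L], d[1L], d[2L], d[5L])),
                c(3L, 4L, 1L, 2L, 5L))
  kvol$data <- kvol$data * warr
  kvol
}

# Centered 2D DFT pair over the ky/kx dims of a 5-D (ch, slice, ky, kx, time)
# array. Forward (image -> kspace) divides by Ny*Nx so a uniform unit object
# gives a unit DC sample; inverse is the exact round trip.
centered_fft2 <- function(arr5, inverse = FALSE) {
  d <- dim(arr5)
  x <- aperm(arr5, c(3L, 4L, 1L, 2L, 5L))
  x <- shift2(x, inverse = TRUE)            # origin to index 0
  x <- fft2_batch(x, inverse = inverse)
  x <- shift2(x, inverse = FALSE)           # origin back to centre
  if (!inverse) x <- x / (d[3L] * d[4L])
  aperm(x, c(3L, 4L, 1L, 2L, 5L))
}

#' Reconstruct voxel echoes from k-space
#'
#' Centered inverse 2D discrete Fourier transform over the phase-encoding
#' dims, per channel, slice and time point. Normalization: a uniform object of
#' unit signal yields unit voxel amplitude (equivalently, a k-space array with
#' a single unit DC sample maps to a uniform unit image).
#'
#' @param kvol A [kspace_volume()].
#' @return Object of class `image_volume`: same shape (channel, slice, y, x,
#'   time) with the acquisition metadata carried over.
#' @export
kspace_to_image <- function(kvol) {
  stopifnot(inherits(kvol, "kspace_volume"))
  out <- kvol
  out$data <- centered_fft2(kvol$data, inverse = TRUE)
  class(out) <- "image_volume"
  out
}

#' Forward projection of voxel echoes to k-space
#'
#' Inverse of [kspace_to_image()] (exact round trip).
#'
#' @param ivol An `image_volume`.
#' @return A [kspace_volume()].
#' @export
image_to_kspace <- function(ivol) {
  stopifnot(inherits(ivol, "image_volume"))
  out <- ivol
  out$data <- centered_fft2(ivol$data, inverse = FALSE)
  class(out) <- "kspace_volume"
  out
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_volume> %d channels x %d slices x %dx%d voxels x %d points\n",
    d[1L], d[2L], d[3L], d[4L], d[5L]))
  invisible(x)
}

#' Extract one voxel's multichannel echoes
#'
#' @param ivol An `image_volume`.
#' @param slice,y,x Voxel indices (1-based).
#' @return List of [echo_signal()], one per channel.
#' @export
voxel_echoes <- function(ivol, slice, y, x) {
  stopifnot(inherits(ivol, "image_volume"))
  d <- dim(ivol$data)
  lapply(seq_len(d[1L]), function(ch)
    echo_signal(ivol$data[ch, slice, y, x, ], ivol$sw))
}

# ---- Raw-data container -------------------------------------------------------

#' Write / read the raw k-space container
#'
#' The package's raw-data entry point is a two-file container: `<path>.json`
#' holds the metadata (dims in order channel, slice, ky, kx, time; SW, dt, TE,
#' TR, slice geometry; element type and byte order) and `<path>.bin` holds the
#' samples as little-endian float64 pairs (real, imaginary), in R column-major
#' order of the declared dims (channel fastest).
#'
#' @param kvol A [kspace_volume()].
#' @param path Path stem (without extension).
#' @return `write_kspace` returns `path` invisibly; `read_kspace` returns the
#'   [kspace_volume()].
#' @export
write_kspace <- function(kvol, path) {
  stopifnot(inherits(kvol, "kspace_volume"))
  meta <- list(
    format = "mrsipipe-kspace-v1",
    dims = dim(kvol$data),
    dim_order = c("channel", "slice", "ky", "kx", "time"),
    dtype = "complex128", byte_order = "little",
    sw_hz = kvol$sw, dwell_s = kvol$dt, te_ms = kvol$te, tr_ms = kvol$tr,
    slice_thickness_mm = kvol$slice_thickness,
    slice_spacing_mm = kvol$slice_spacing
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  v <- as.vector(kvol$data)
  inter <- as.vector(rbind(Re(v), Im(v)))
  writeBin(inter, con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "mrsipipe-kspace-v1"))
    stop("not a recognised k-space container: ", path, call. = FALSE)
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = 2L * n, size = 8L, endian = "little")
  v <- complex(real = raw[c(TRUE, FALSE)], imaginary = raw[c(FALSE, TRUE)])
  kspace_volume(array(v, dims), sw = meta$sw_hz, te = meta$te_ms,
                tr = meta$tr_ms, slice_thickness = meta$slice_thickness_mm,
                slice_spacing = meta$slice_spacing_mm)
}
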