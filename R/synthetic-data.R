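#' Phantom specification for the synthetic MRSI generator
#'
#' Describes a multislice digital phantom: slice stack geometry, labeled 2D
#' compartments per slice, per-compartment metabolite amplitudes (default
#' NAA:Cr:Cho = 48:36:24), a residual-water amplitude expressed as a multiple
#' of the NAA amplitude, and the lineshape. The default compartment is a
#' centred ellipse covering roughly the inner two thirds of the grid, shared
#' by all slices.
#'
#' @param grid Length-2 phase-encoding grid (ky, kx).
#' @param n_slices Number of slices (default 7).
#' @param thickness,spacing Slice thickness and gap in mm (defaults 10 and 4).
#' @param compartments List of compartments, each a list with `mask` (logical
#'   grid matrix) and `amplitudes` (named numeric, metabolite amplitudes).
#'   Default: one elliptical compartment with the default amplitudes.
#' @param amplitudes Default metabolite amplitudes for the default compartment.
#' @param water_amplitude Residual water amplitude as a multiple of the NAA
#'   amplitude (default 1); the water resonance sits at the carrier.
#' @param kind,fwhm,voigt_fwhm,field_mhz Lineshape options passed to
#'   [metabolite_singlets()].
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid = c(16, 16), n_slices = 7, thickness = 10,
                         spacing = 4, compartments = NULL,
                         amplitudes = c(NAA = 48, Cr = 36, Cho = 24),
                         water_amplitude = 1,
                         kind = "lorentzian", fwhm = 10,
                         voigt_fwhm = c(2.5, 7.5), field_mhz = 127.74) {
  kind <- check_kind(kind)
  if (is.null(compartments)) {
    compartments <- list(list(mask = ellipse_mask(grid), amplitudes = amplitudes))
  }
  for (cp in compartments) {
    if (!is.matrix(cp$mask) || !identical(dim(cp$mask), as.integer(grid)))
      stop("compartment mask does not fit the phase-encoding grid", call. = FALSE)
    if (any(cp$amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  }
  structure(
    list(grid = as.integer(grid), n_slices = as.integer(n_slices),
         thickness = thickness, spacing = spacing,
         compartments = compartments, water_amplitude = water_amplitude,
         kind = kind, fwhm = fwhm, voigt_fwhm = voigt_fwhm,
         field_mhz = field_mhz),
    class = "phantom_spec"
  )
}

#' Elliptical mask helper
#' @param grid Length-2 grid dims.
#' @param semi_axes Semi-axes as a fraction of the half grid (default 0.7).
#' @return Logical matrix.
#' @export
ellipse_mask <- function(grid, semi_axes = c(0.7, 0.7)) {
  cy <- (grid[1L] + 1) / 2
  cx <- (grid[2L] + 1) / 2
  ry <- semi_axes[1L] * grid[1L] / 2
  rx <- semi_axes[2L] * grid[2L] / 2
  outer(seq_len(grid[1L]), seq_len(grid[2L]), function(y, x)
    ((y - cy) / ry)^2 + ((x - cx) / rx)^2 <= 1)
}

#' Phased-array coil profile
#'
#' Smooth per-channel complex sensitivity over the slice grid: channels sit at
#' equal angles around the head with a quadratic amplitude roll-off away from
#' each element and phases in 45-degree increments (8 channels), which
#' produces the inter-channel phase dispersion that phase alignment must
#' remove. Per-channel noise SDs are carried alongside.
#'
#' @param grid Length-2 grid dims.
#' @param n_channels Number of receive channels (default 8).
#' @param noise_sd Per-channel k-space noise SD (scalar recycled, default 0).
#' @param rolloff Amplitude drop from the near to the far edge, in (0, 1).
#' @return A `coil_profile`: list with `sensitivity` (complex array channel x
#'   y x x) and `noise_sd` (vector).
#' @export
coil_profile <- function(grid, n_channels = 8, noise_sd = 0, rolloff = 0.6) {
  grid <- as.integer(grid)
  sens <- array(0 + 0i, c(n_channels, grid[1L], grid[2L]))
  ang <- 2 * pi * (seq_len(n_channels) - 1L) / n_channels
  cy <- (grid[1L] + 1) / 2
  cx <- (grid[2L] + 1) / 2
  for (ch in seq_len(n_channels)) {
    ey <- cy + sin(ang[ch]) * grid[1L] / 2
    ex <- cx + cos(ang[ch]) * grid[2L] / 2
    d2 <- outer(seq_len(grid[1L]), seq_len(grid[2L]), function(y, x)
      ((y - ey)^2 + (x - ex)^2) / (grid[1L]^2 + grid[2L]^2))
    amp <- 1 - rolloff * pmin(d2 / max(d2), 1)
    sens[ch, , ] <- amp * exp(1i * ang[ch])
  }
  structure(
    list(sensitivity = sens,
         noise_sd = rep_len(noise_sd, n_channels),
         n_channels = n_channels, grid = grid),
    class = "coil_profile"
  )
}

#' Adjacent-slice crosstalk model
#'
#' Scalar amplitude attenuation applied to slices that are excited after a
#' spatially adjacent neighbour within the same TR (imperfect slice profiles
#' partially saturate the shared edge). The attenuation interpolates linearly
#' from `gamma0` at 0 mm spacing to 1 at `full_spacing` mm and is therefore
#' monotonically non-decreasing in the spacing.
#'
#' @param gamma0 Attenuation factor at 0 mm spacing, in (0, 1].
#' @param full_spacing Spacing (mm) at and beyond which no attenuation occurs
#'   (default 4).
#' @return A `crosstalk_model` with a `gamma(spacing)` function.
#' @export
crosstalk_model <- function(gamma0 = 1, full_spacing = 4) {
  if (gamma0 <= 0 || gamma0 > 1) stop("`gamma0` must be in (0, 1]", call. = FALSE)
  structure(
    list(gamma0 = gamma0, full_spacing = full_spacing,
         gamma = function(spacing)
           gamma0 + (1 - gamma0) * pmin(pmax(spacing, 0), full_spacing) / full_spacing),
    class = "crosstalk_model"
  )
}

# Interleaved excitation order (odd slices then even, e.g. 1-3-5-7-2-4-6) and
# the per-slice attenuation flags: a slice is attenuated when a spatial
# neighbour was excited earlier in the same TR.
interleaved_order <- function(n_slices) {
  c(seq(1L, n_slices, by = 2L), seq(2L, n_slices, by = 2L))
}

slice_attenuation <- function(n_slices, gamma) {
  ord <- interleaved_order(n_slices)
  pos <- match(seq_len(n_slices), ord)
  vapply(seq_len(n_slices), function(s) {
    nb <- c(s - 1L, s + 1L)
    nb <- nb[nb >= 1L & nb <= n_slices]
    if (any(pos[nb] < pos[s])) gamma else 1
  }, 1)
}

#' Simulate one echo
#'
#' Evaluates the echo model on the symmetric grid and adds seeded circular
#' complex Gaussian noise.
#'
#' @param components Component table.
#' @param sw Spectral width in Hz (default 2000).
#' @param n Number of points (default 256).
#' @param noise_sd Noise SD per real channel (default 0).
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return An [echo_signal()].
#' @export
make_echo <- function(components, sw = 2000, n = 256, noise_sd = 0,
                      seed = NULL) {
  g <- echo_grid(sw, n)
  s <- evaluate_model(components, g)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("`seed` is required when `noise_sd` > 0", call. = FALSE)
    set.seed(as.integer(seed))
    s <- s + complex_noise(n, noise_sd)
  }
  echo_signal(s, sw)
}

# Component table of a compartment: metabolite singlets scaled to the
# compartment amplitudes plus the residual water singlet at the carrier.
compartment_components <- function(phantom, amplitudes) {
  comp <- metabolite_singlets(
    kind = phantom$kind, amplitudes = amplitudes, fwhm = phantom$fwhm,
    voigt_fwhm = phantom$voigt_fwhm, field_mhz = phantom$field_mhz)
  if (phantom$water_amplitude > 0) {
    a_naa <- if ("NAA" %in% names(amplitudes)) amplitudes[["NAA"]] else
      max(amplitudes)
    water <- spectral_components(
      phantom$water_amplitude * a_naa, 0, 0,
      fwhm_to_decay(12, "lorentzian"), 0, label = "water")
    comp <- dplyr::bind_rows(comp, water)
  }
  comp
}

#' Simulate a multichannel multislice MRSI acquisition
#'
#' Builds voxel echoes per slice as compartment model x coil sensitivity x
#' crosstalk attenuation, forward-transforms each slice to k-space (so the
#' object is fully phase-encoded) and adds per-channel complex Gaussian noise
#' in k-space. Slice excitation is interleaved (odd then even); slices excited
#' after a spatial neighbour carry the crosstalk attenuation
#' `crosstalk$gamma(phantom$spacing)`.
#'
#' @param phantom A [phantom_spec()].
#' @param coils A [coil_profile()] on the same grid.
#' @param crosstalk A [crosstalk_model()] or `NULL` for none.
#' @param sw,n Spectral width (Hz) and echo length.
#' @param seed Integer seed; required when any coil noise SD is positive.
#' @return A [kspace_volume()].
#' @export
make_mrsi_dataset <- function(phantom, coils, crosstalk = NULL,
                              sw = 2000, n = 256, seed = NULL) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(coils, "coil_profile"))
  if (!identical(coils$grid, phantom$grid))
    stop("coil profile grid does not match the phantom grid", call. = FALSE)
  g <- echo_grid(sw, n)
  nc <- coils$n_channels
  ns <- phantom$n_slices
  gy <- phantom$grid[1L]
  gx <- phantom$grid[2L]
  att <- if (is.null(crosstalk)) rep(1, ns) else
    slice_attenuation(ns, crosstalk$gamma(phantom$spacing))

  img <- array(0 + 0i, c(nc, ns, gy, gx, n))
  for (cp in phantom$compartments) {
    echo <- evaluate_model(compartment_components(phantom, cp$amplitudes), g)
    msk <- cp$mask
    base <- array(0 + 0i, c(nc, gy, gx))
    for (ch in seq_len(nc)) base[ch, , ] <- coils$sensitivity[ch, , ] * msk
    for (s in seq_len(ns)) {
      acc <- array(img[, s, , , ], c(nc, gy, gx, n))
      img[, s, , , ] <- acc + outer(att[s] * base, echo)
    }
  }
  ivol <- structure(
    list(data = img, sw = sw, dt = g$dt, t = g$t, te = NA_real_, tr = NA_real_,
         slice_thickness = phantom$thickness, slice_spacing = phantom$spacing),
    class = "image_volume")
  kvol <- image_to_kspace(ivol)
  if (any(coils$noise_sd > 0)) {
    if (is.null(seed)) stop("`seed` is required when coil noise is positive",
                            call. = FALSE)
    set.seed(as.integer(seed))
    for (ch in seq_len(nc)) {
      if (coils$noise_sd[ch] > 0) {
        nz <- complex_noise(ns * gy * gx * n, coils$noise_sd[ch])
        kvol$data[ch, , , , ] <- as.vector(kvol$data[ch, , , , ]) + nz
      }
    }
  }
  kvol
}

#' Paired with-/without-spacing crosstalk datasets
#'
#' Generates two acquisitions sharing the phantom geometry, coil profile and
#' noise seed: one with the phantom's nominal spacing (no attenuation under
#' the default crosstalk model) and one with 0 mm spacing, where slices
#' excited after a spatial neighbour are attenuated by `gamma0`. Sharing the
#' seed makes the pair identical when `gamma0 = 1`, so the crosstalk
#' statistic isolates the programmed attenuation.
#'
#' @param phantom A [phantom_spec()] (its `spacing` is used for the
#'   with-spacing member).
#' @param coils A [coil_profile()].
#' @param gamma0 Attenuation at 0 mm spacing, in (0, 1].
#' @param sw,n Acquisition parameters.
#' @param seed Integer seed shared by the pair.
#' @return List with `with_spacing` and `without_spacing` [kspace_volume()]s.
#' @export
make_paired_crosstalk_datasets <- function(phantom, coils, gamma0,
                                           sw = 2000, n = 256, seed = NULL) {
  ct <- crosstalk_model(gamma0)
  ph_with <- phantom
  ph_without <- phantom
  ph_without$spacing <- 0
  list(
    with_spacing = make_mrsi_dataset(ph_with, coils, ct, sw, n, seed),
    without_spacing = make_mrsi_dataset(ph_without, coils, ct, sw, n, seed)
  )
}
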