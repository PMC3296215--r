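---
title: "Multisection MRSI post-processing: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multisection MRSI post-processing: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsipipe)
```

# The problem

Multisection (multislice) proton MR spectroscopic imaging excites and samples
several slices within one repetition time, which buys whole-brain coverage at
the cost of a hard time budget: with `N_sec` slices per TR,
`TR = T_sec * N_sec`, and the per-slice time `T_sec` is dominated by the echo
time plus the acquired half of the echo (`T_acq = N/SW`). Fitting seven
contiguous 10 mm slices into a 2300 ms TR at a 2000 Hz spectral width forces
the echo down to 256 complex points — a *severely truncated* full echo whose
spectrum has poor digital resolution and, after zero-filling, sinc wiggles.
`mrsipipe` implements the post-processing that makes such data quantifiable:
spatial reconstruction, phased-array combination, water removal, and —
centrally — nonlinear least-squares fitting of the truncated echo in the
*time domain*, where truncation does not bias the estimates.

# The signal model

A voxel echo is modelled as a sum of M damped complex sinusoids on the
symmetric time axis `t_n = (n - N/2) / SW`:

$$S(t) = \sum_{m=1}^{M} A_m\, e^{i(2\pi f_m t + \phi_m)}\,
         e^{-\alpha_m |t| - \beta_m t^2}$$

with amplitude `A_m` (a.u., the quantity of clinical interest — it is
proportional to metabolite concentration), frequency offset `f_m` (Hz from
the carrier), phase `phi_m`, Lorentzian decay `alpha_m` (1/s) and Gaussian
decay `beta_m` (1/s²). The two-sided decay `|t|` encodes that a *full echo*
is acquired symmetrically about its top, so magnitude spectra need no phase
correction. Three constraint patterns are supported: pure Lorentzian
(`beta = 0`), pure Gaussian (`alpha = 0`), and Voigt, where each line keeps
its own `alpha` but a single `beta` is shared by all M lines — the Gaussian
contribution models field inhomogeneity, which is common to all resonances
in a voxel, while the Lorentzian part is line-specific relaxation.

Linewidths are stated as spectral full widths at half maximum:
`alpha = pi * FWHM` for a Lorentzian and `beta = pi^2 FWHM^2 / (4 ln 2)` for
a Gaussian (`fwhm_to_decay()`). The default simulated triplet places NAA,
Cr and Cho at 2.01, 3.03 and 3.22 ppm against a 4.70 ppm water carrier at
127.74 MHz (3 T), with amplitudes 48:36:24 and 10 Hz FWHM (2.5 Hz Lorentzian
+ 7.5 Hz Gaussian under the Voigt kind). The frequencies are a modelling
choice — the physically standard chemical shifts — and every
frequency-dependent property in the test suite holds for any well-separated
triplet.

```{r model}
comp <- metabolite_singlets("lorentzian")
comp
echo <- make_echo(comp, sw = 2000, n = 256)
echo
```

# Why the time domain

Time- and frequency-domain representations carry the same information, but a
*truncated* echo does not: its DFT is the true spectrum convolved with a sinc
kernel, while the analytic lineshape model is not. A frequency-domain fit of
truncated data therefore minimizes against a model that cannot represent the
data (model mismatch); a time-domain fit evaluates the model exactly on the
acquired samples and recovers noise-free truncated data to machine precision.
`fit_time_domain()` concatenates real and imaginary parts into one real
residual and runs Levenberg–Marquardt (`minpack.lm::nls.lm`) with the
analytic Jacobian, bounds `A, alpha, beta >= 0`, relative tolerances 1e-12
and a 500-iteration cap (hitting the cap reports `converged = FALSE` rather
than raising). `fit_frequency_domain()` implements the comparison method:
the analytic continuous lineshape sampled at the DFT grid frequencies, fit
to the complex data spectrum, again with an analytic Jacobian.

Two pathologies of the frequency-domain route on 256-point data are worth
naming because the test suite demonstrates both. First, the mismatch error:
amplitude errors at the several-percent level (and far worse when the
Gaussian or Voigt model meets strong truncation wiggles). Second, an
identifiability failure: at a 7.8 Hz grid spacing the fit can park a line
*between* frequency samples and inflate its amplitude almost freely, so the
optimizer may wander without converging — itself a symptom of fitting
low-resolution spectra. Zero-filling to 1024 points interpolates the grid
but adds wiggles, leaving errors of the same order. The acceptance checks
assert the *ordering* (frequency-domain error strictly exceeds time-domain
error for all three lineshapes) rather than specific percentages, because
the mismatch error depends on the exact peak positions relative to the grid.

The Voigt spectrum needs the scaled complex error function
`erfcx(z) = e^{z^2}\mathrm{erfc}(z)`: the package evaluates it through
Weideman's rational approximation of the Faddeeva function (36 terms,
~1e-13 uniform accuracy on `Re(z) >= 0`). A naive
`exp(z^2) * (1 - erf(z))` loses five or more digits once `|Im z|` exceeds a
few units, which is enough to break derivative-based fitting.

## Initialization

Starting values follow the magnitude spectrum of the echo zero-filled to
4096 points: frequencies from bin centres (0.49 Hz granularity), amplitudes
from peak heights via the height–area relation (a unit-amplitude component
peaks at the sum of its decay envelope over the grid), decays from measured
FWHM, and one global phase from the echo-top sample. Peak *counting* on
severely truncated data is deliberately done on a 15 Hz-apodized copy of the
echo: zero-filling makes sinc wiggle lobes genuine local maxima (several
percent of the tallest peak on noise-free fixtures), and apodization removes
the edge discontinuity that creates them. Positions, heights and widths are
then measured on the raw spectrum. When the number of peaks is known — the
usual case in a mapping pipeline — the n tallest raw maxima are used
directly. The automatic prominence threshold is `max(5 * mad(|spectrum|),
0.01 * max)`, i.e. five times a robust noise floor with a 1%-of-maximum
floor for noise-free data.

# Accuracy bounds: CRLB and Monte Carlo

`compute_crlb()` builds the Fisher information of the free parameters from
the analytic model Jacobian under i.i.d. circular complex Gaussian noise
(`I = sigma^{-2} Re(J^H J)` on the concatenated real/imaginary observation);
bounds are `sqrt(diag(I^{-1}))` and scale linearly in the noise SD. For
well-separated singlets of equal width the amplitude bound is nearly
identical across lines and independent of the amplitudes themselves.
`run_monte_carlo()` adds seeded noise to the noise-free echo, re-initializes
and refits each realization, and reports per-metabolite means, SDs and
SD/CRLB ratios; `calibrate_noise_sd()` exploits the linear scaling to set
the noise so a chosen amplitude bound takes a prescribed value. At the
operating point used in the acceptance run (Lorentzian NAA amplitude CRLB
0.1574, echo-top SNR ≈ 80) the time-domain estimator is unbiased within
Monte-Carlo error and its SD sits close to the bound (ratios near 1, safely
below 2), for both the Lorentzian and Voigt models, with 400 realizations.

```{r crlb}
g <- echo_grid(2000, 256)
amplitude_crlb(compute_crlb(comp, "lorentzian", g, noise_sd = 0.83))
```

# Water removal and point repair: the matrix pencil

Residual water dominates metabolite signals even after suppression. The
matrix pencil method estimates damped sinusoids from the generalized
eigenvalues of shifted Hankel matrices built from the *causal half* of the
echo (`t >= 0`): a full echo is not globally a one-sided exponential sum,
but its causal half is, and the reconstruction mirrors the Lorentzian decay
through `e^{-alpha|t|}`. Components with `|f| <= water_band` (default 60 Hz,
about 0.47 ppm at 3 T) are subtracted; the removed fraction is measured as
water-band spectral energy before versus after. The same decomposition
extrapolates the model over corrupted leading samples
(`repair_corrupted_points()`, default 6 points — ADC activation transients),
which never contaminate the causal half because `n_bad < N/4`.

Defaults: pencil parameter `L = floor(M/3)` of the `M = N/2` causal samples;
model order chosen by singular-value threshold — `1e-3 * sigma_max` suits
noise-free data, and the default `"auto"` rule keeps singular values above
three times a noise floor estimated as the median of the lower half of the
singular spectrum. These are engineering defaults, configurable through
`pencil_config()`; no claim is made that they match any particular scanner
implementation.

# Reconstruction and phased-array combination

Phase-encoded k-space is Hamming-filtered (separable window, peak 1 at the
k-space centre sample, 0.08 at the grid edge) and inverse-Fourier-transformed
per channel, slice and time point, normalized so a uniform unit object gives
unit voxel amplitude. One convention note: with the k-space origin fixed at
grid index N/2 of an even grid, the window is the DFT-even ("periodic")
Hamming, whose peak PSF sidelobe is 1.04% — the textbook −42.7 dB figure
belongs to the symmetric window, whose peak would fall between samples. The
unfiltered PSF rings at tens of percent, so the filter still buys an
order-of-magnitude reduction in Gibbs ringing at the usual resolution cost.

Channel combination follows five steps per voxel: water removal, point
repair, Gaussian apodization (`e^{-beta t^2}`, stated as a line-broadening
FWHM: 10 Hz suits phantom-style data, 4 Hz in-vivo-style), phase alignment
by subtracting each channel's echo-top phase (ties broken toward the earlier
sample), and weighted summation with `w_i ∝ a_i / sigma_i^2` — echo-top
amplitude over noise variance, the matched-filter weighting that maximizes
combined SNR for phase-aligned channels (`a_i/sigma_i` is available as an
option). Per-channel noise SDs are measured once, as the SD of the real part
of the spectrum over a signal-free region, and reused across voxels. The
weights are scaled so that `sum(w_i a_i) = max(a_i)`: the combined echo
keeps the amplitude scale of the strongest channel, identical channels
combine to exactly one of them, and a channel with diverging noise gets
vanishing weight. (Weight normalization only rescales all amplitudes by one
constant, so it cancels from the crosstalk statistic and from any
ratio-based quantitation.)

# Slice crosstalk

Interleaved excitation (odd slices then even, e.g. 1-3-5-7-2-4-6) means
even-numbered slices are excited after both spatial neighbours; imperfect
slice profiles then partially saturate their shared edges, attenuating the
signal when the gap between slices is removed. The statistic is the
per-voxel relative difference
`d_m = (A_{m,w.sp} - A_{m,wo.sp}) / A_{m,w.sp}` between amplitudes fitted
with and without slice spacing, summarized as mean ± sample (n−1) SD per
metabolite over a central-slice region of interest (`crosstalk_report()`).

The generator models crosstalk as a scalar attenuation `gamma(spacing)`
applied to slices excited after a spatial neighbour, interpolating linearly
from `gamma0` at 0 mm to 1 at 4 mm. This reproduces the *net amplitude
effect* that the statistic measures; it does not simulate Bloch dynamics,
T1-dependence or the shape of real slice profiles, so `gamma0` is a free
knob for generating test regimes (0.95 yields the ~5% reductions typical of
in-vivo comparisons), never a predicted quantity. Paired datasets share one
noise seed so that `gamma0 = 1` gives bitwise-identical volumes and the
statistic isolates the programmed attenuation.

# The synthetic generator, and what passing tests do not show

`make_mrsi_dataset()` builds voxel echoes as compartment model × coil
sensitivity × crosstalk attenuation, forward-transforms to k-space and adds
per-channel circular complex Gaussian noise there (every output is a pure
function of its seed). The default emulation: 7 slices of 10 mm with 4 or
0 mm spacing, 16×16 or 32×32 encodings, SW 2000 Hz, 256 points, 8 channels
at 45° phase increments with smooth quadratic amplitude roll-off, residual
water at the carrier, NAA:Cr:Cho = 48:36:24. Real data differ in ways the
generator deliberately omits: B0 inhomogeneity and eddy currents, lipid
ring contamination, baseline from macromolecules, J-coupled multiplets,
motion, and true slice profiles. Green tests therefore certify the
*algorithms* — reconstruction conventions, estimator correctness and
efficiency, statistic recovery — not robustness to every in-vivo artifact.

Raw data enter through a documented two-file container (JSON metadata plus
little-endian float64 binary, dimension order channel × slice × ky × kx ×
time; `read_kspace()`/`write_kspace()`).

# Problem sizes and numerical choices

The test suite and the acceptance script are sized for a single CPU: 400
Monte-Carlo realizations per lineshape for the efficiency claims (the full
study design), 60 or fewer for property tests; crosstalk recovery on a
12×12 grid, 7 slices, 8 channels, with a 16-voxel central-slice ROI; the
PSF study on a 16×16 grid oversampled 4×. Tie-breaks and degenerate inputs:
the echo top is the earliest maximum-magnitude sample; an all-zero channel
is skipped with a warning in phase alignment; an empty water band returns
the input unchanged with a warning; colliding component frequencies raise an
identifiability error naming the pair; fitted phases are wrapped to
(−π, π]. TE is taken as the user states it and validated against nothing,
since published protocol descriptions are not always internally consistent
about it.

# Limitations

- Quantitation is relative (amplitudes in arbitrary units); no relaxation
  correction, water referencing or absolute concentration scaling.
- No prior-knowledge basis-set fitting; singlet models only.
- No parallel-imaging reconstruction or coil-sensitivity mapping; the
  combination assumes one echo per channel per voxel.
- The frequency-domain fit is provided as the comparison method; its
  behaviour on strongly truncated data is the pathology under study, not a
  recommended analysis route.
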