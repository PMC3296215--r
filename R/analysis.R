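#' Relative amplitude difference between paired acquisitions
#'
#' The crosstalk statistic for one voxel and metabolite:
#' \deqn{d_m = (A_{m,\mathrm{w.sp}} - A_{m,\mathrm{wo.sp}}) /
#'             A_{m,\mathrm{w.sp}},}
#' the relative signal reduction when slice spacing is removed. Scale
#' invariant: multiplying both amplitudes by c > 0 leaves d unchanged.
#'
#' @param a_with Amplitude with slice spacing, > 0 (vectorized).
#' @param a_without Amplitude without spacing.
#' @return The ratio d.
#' @examples
#' relative_difference(10, 9)  # 0.10
#' @export
relative_difference <- function(a_with, a_without) {
  if (any(!is.finite(a_with)) || any(a_with <= 0))
    stop("invalid input: `a_with` must be > 0", call. = FALSE)
  (a_with - a_without) / a_with
}

#' Per-metabolite crosstalk report from paired fit tables
#'
#' Joins the with-spacing and without-spacing fit tables on
#' (slice, y, x, metabolite), computes the relative difference d per voxel and
#' metabolite, and summarizes mean and sample (n-1) SD per metabolite, the
#' layout in which slice-crosstalk comparisons are reported. Voxels present in
#' only one table are excluded with a message.
#'
#' @param fits_with,fits_without Fit tables (tibbles with columns slice, y, x,
#'   metabolite, amplitude), e.g. the `fits` element of [run_pipeline()].
#' @param roi Optional data frame of voxels (columns slice, y, x) to restrict
#'   to (the central-slice design).
#' @param metabolites Optional metabolite subset.
#' @return Object of class `crosstalk_stat`: tibble with one row per
#'   metabolite (metabolite, n_voxels, mean_d, sd_d) plus the per-voxel `d`
#'   table in attribute `"voxels"`.
#' @export
crosstalk_report <- function(fits_with, fits_without, roi = NULL,
                             metabolites = NULL) {
  keys <- c("slice", "y", "x", "metabolite")
  for (tab in list(fits_with, fits_without))
    if (!all(c(keys, "amplitude") %in% names(tab)))
      stop("fit tables need columns: ", paste(c(keys, "amplitude"), collapse = ", "),
           call. = FALSE)
  if (!is.null(roi))
    fits_with <- dplyr::semi_join(fits_with, roi, by = intersect(names(roi), keys))
  if (!is.null(metabolites)) {
    fits_with <- fits_with[fits_with$metabolite %in% metabolites, ]
    fits_without <- fits_without[fits_without$metabolite %in% metabolites, ]
  }
  joined <- dplyr::inner_join(
    fits_with[, c(keys, "amplitude")],
    fits_without[, c(keys, "amplitude")],
    by = keys, suffix = c("_with", "_without"))
  n_dropped <- nrow(fits_with) - nrow(joined)
  if (n_dropped > 0)
    message(n_dropped, " voxel-metabolite rows present in only one table; excluded")
  if (nrow(joined) == 0L) stop("no shared voxels between the tables", call. = FALSE)
  joined$d <- relative_difference(joined$amplitude_with, joined$amplitude_without)
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$metabolite),
    n_voxels = dplyr::n(),
    mean_d = mean(.data$d),
    sd_d = stats::sd(.data$d),
    .groups = "drop")
  attr(out, "voxels") <- joined
  class(out) <- c("crosstalk_stat", class(out))
  out
}

#' Aligned-text rendering of a crosstalk report
#' @param x A `crosstalk_stat`.
#' @param ... Unused.
#' @return Character vector of report lines (invisibly printed).
#' @export
format.crosstalk_stat <- function(x, ...) {
  lines <- c(sprintf("%-12s %8s %18s", "Metabolite", "n", "mean +/- SD"),
             vapply(seq_len(nrow(x)), function(i)
               sprintf("%-12s %8d %9.2f%% %6.2f%%", x$metabolite[i],
                       x$n_voxels[i], 100 * x$mean_d[i], 100 * x$sd_d[i]),
               character(1L)))
  lines
}

#' @export
print.crosstalk_stat <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Multisection sequence timing budget
#'
#' Assembles the per-slice time budget \eqn{T_{sec}} and the repetition time
#' \eqn{TR = T_{sec} \times N_{sec}} of an interleaved multisection
#' acquisition. When `T_sec` is not given it is assembled as
#' \eqn{T_p + TE + T_{acq}/2 + T_d} (preparation, echo formation, the
#' acquired half-echo after the echo top, and hardware delay). `T_acq` may be
#' given directly or derived as \eqn{N/SW}.
#'
#' @param T_sec Per-slice time in ms, overriding the assembled budget.
#' @param N_sec Number of slices per TR, >= 1.
#' @param TE Echo time in ms.
#' @param T_acq Acquisition window in ms (or give `n` and `sw`).
#' @param T_p,T_d Preparation time and pre-acquisition delay in ms
#'   (hardware constants; default 0).
#' @param n,sw Echo length and spectral width (Hz), used to derive `T_acq`.
#' @return Object of class `sequence_timing`: list with all budget entries
#'   and `TR` in ms.
#' @examples
#' compute_timing(T_sec = 575, N_sec = 4)$TR  # 2300
#' @export
compute_timing <- function(T_sec = NULL, N_sec = 1, TE = NA_real_,
                           T_acq = NULL, T_p = 0, T_d = 0,
                           n = NULL, sw = NULL) {
  if (N_sec < 1 || N_sec != round(N_sec))
    stop("`N_sec` must be a positive integer", call. = FALSE)
  if (is.null(T_acq) && !is.null(n) && !is.null(sw)) T_acq <- 1000 * n / sw
  if (is.null(T_acq)) T_acq <- NA_real_
  if (any(stats::na.omit(c(T_p, T_d, TE, T_acq, T_sec)) < 0))
    stop("times must be >= 0", call. = FALSE)
  if (is.null(T_sec)) {
    if (is.na(TE) || is.na(T_acq))
      stop("give `T_sec` directly, or `TE` plus `T_acq` (or `n` and `sw`)",
           call. = FALSE)
    T_sec <- T_p + TE + T_acq / 2 + T_d
  }
  structure(
    list(T_p = T_p, TE = TE, T_d = T_d, T_acq = T_acq, T_sec = T_sec,
         N_sec = as.integer(N_sec), TR = T_sec * N_sec,
         n = n, sw = sw),
    class = "sequence_timing"
  )
}

#' @export
print.sequence_timing <- function(x, ...) {
  cat(sprintf("<sequence_timing> T_sec %.4g ms x %d slices -> TR %.4g ms (T_acq %.4g ms)\n",
              x$T_sec, x$N_sec, x$TR, x$T_acq))
  invisible(x)
}

#' Total scan duration of a phase-encoded acquisition
#'
#' Number of acquired phase encodings times TR. Under `"circular"` sampling
#' only lattice points within radius `floor(min(grid)/2)` of the k-space
#' origin (DC included) are acquired.
#'
#' @param TR Repetition time in ms.
#' @param grid Length-2 integer vector (ky, kx encodings).
#' @param sampling `"full"` or `"circular"`.
#' @return Scan duration in seconds.
#' @examples
#' scan_duration(2300, c(16, 16))            # 588.8
#' @export
scan_duration <- function(TR, grid, sampling = c("full", "circular")) {
  sampling <- match.arg(sampling)
  if (length(grid) != 2L || any(grid < 1))
    stop("`grid` must be two dims >= 1", call. = FALSE)
  n_pe <- if (sampling == "full") {
    prod(grid)
  } else {
    r <- floor(min(grid) / 2)
    ky <- seq_len(grid[1L]) - 1L - floor(grid[1L] / 2)
    kx <- seq_len(grid[2L]) - 1L - floor(grid[2L] / 2)
    sum(outer(ky^2, kx^2, "+") <= r^2)
  }
  n_pe * TR / 1000
}
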