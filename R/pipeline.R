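#' Pipeline configuration
#'
#' All stage parameters of [run_pipeline()], serializable to YAML/JSON (the
#' round trip through [write_pipeline_config()] / [read_pipeline_config()] is
#' exact).
#'
#' @param window k-space window: `"hamming"` (default) or `"none"`.
#' @param water_removal Run matrix-pencil water removal per channel (default
#'   TRUE).
#' @param water_band Water-band half width in Hz (default 60).
#' @param n_bad Leading corrupted points to repair per channel (default 0;
#'   scanner data typically uses 6).
#' @param line_broadening Gaussian apodization in Hz (default 4,
#'   in-vivo-style; 10 suits phantom-style data).
#' @param kind Lineshape kind for fitting.
#' @param metabolites Metabolite names to map (subset of NAA, Cr, Cho).
#' @param field_mhz Proton frequency in MHz for the expected metabolite
#'   frequencies.
#' @param match_tolerance Max |Hz| between a fitted and an expected frequency
#'   for map assignment (default 20).
#' @param signal_free_band Positive-frequency interval (Hz) used to estimate
#'   per-channel noise (default 300-900; metabolites sit below the carrier).
#' @param roi Optional data frame (slice, y, x) of voxels to fit; default:
#'   all voxels whose combined echo-top magnitude exceeds `mask_threshold`
#'   times the volume maximum.
#' @param mask_threshold Relative support threshold (default 0.2).
#' @param weighting Channel weighting rule, see [combine_channels()].
#' @param seed Provenance seed recorded in outputs (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window = "hamming", water_removal = TRUE,
                            water_band = 60, n_bad = 0, line_broadening = 4,
                            kind = "lorentzian",
                            metabolites = c("NAA", "Cr", "Cho"),
                            field_mhz = 127.74, match_tolerance = 20,
                            signal_free_band = c(300, 900),
                            roi = NULL, mask_threshold = 0.2,
                            weighting = "amp_over_var", seed = NULL) {
  structure(
    list(window = window, water_removal = water_removal,
         water_band = water_band, n_bad = n_bad,
         line_broadening = line_broadening, kind = check_kind(kind),
         metabolites = metabolites, field_mhz = field_mhz,
         match_tolerance = match_tolerance,
         signal_free_band = signal_free_band, roi = roi,
         mask_threshold = mask_threshold, weighting = weighting, seed = seed),
    class = "pipeline_config"
  )
}

#' Serialize / deserialize a pipeline configuration
#'
#' Format chosen by extension: `.yaml`/`.yml` or `.json`.
#'
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$roi)) x$roi <- as.list(as.data.frame(x$roi))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(x$roi)) x$roi <- tibble::as_tibble(x$roi)
  args <- x[intersect(names(x), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# Default ROI: voxels whose combined (sum-of-squares over channels) echo-top
# magnitude exceeds `thr` x the volume maximum.
support_roi <- function(ivol, thr) {
  d <- dim(ivol$data)
  top <- d[5L] / 2 + 1L
  mag <- sqrt(apply(Mod(ivol$data[, , , , top, drop = FALSE])^2, 2:4, sum))
  sel <- which(mag > thr * max(mag), arr.ind = TRUE)
  tibble::tibble(slice = sel[, 1L], y = sel[, 2L], x = sel[, 3L])
}

#' Run the full post-processing pipeline
#'
#' Stages, in order: k-space Hamming filtering; centred inverse 2D Fourier
#' reconstruction; per channel and voxel: matrix-pencil water removal,
#' corrupted-point repair, Gaussian apodization; echo-top phase alignment;
#' noise-weighted channel combination (per-channel noise SDs estimated once
#' from the signal-free spectral region and reused across voxels); time-domain
#' nonlinear least-squares fitting; metabolite-map assembly. Deterministic:
#' identical input and config give identical outputs.
#'
#' @param kvol A [kspace_volume()].
#' @param config A [pipeline_config()].
#' @return Object of class `mrsi_pipeline_result`: list with `maps` (a
#'   `metabolite_maps` object), `fits` (tibble: slice, y, x, metabolite,
#'   amplitude, frequency, phase, lorentz_decay, gauss_decay, residual_norm,
#'   converged), `channel_noise_sd`, `config`, `config_hash` and a `log` of
#'   stage timings.
#' @export
run_pipeline <- function(kvol, config = pipeline_config()) {
  stopifnot(inherits(kvol, "kspace_volume"))
  logline <- character(0)
  tic <- function() proc.time()[[3L]]
  stage <- function(name, t0) {
    msg <- sprintf("[%s] %.2fs", name, tic() - t0)
    logline <<- c(logline, msg)
  }

  t0 <- tic()
  kvol <- spatial_filter(kvol, config$window)
  stage("spatial_filter", t0)

  t0 <- tic()
  ivol <- kspace_to_image(kvol)
  stage("kspace_to_image", t0)

  d <- dim(ivol$data)
  nc <- d[1L]
  roi <- if (is.null(config$roi)) support_roi(ivol, config$mask_threshold) else
    tibble::as_tibble(config$roi)
  if (nrow(roi) == 0L) stop("empty region of interest", call. = FALSE)

  pcfg <- pencil_config(water_band = config$water_band)
  process_channel <- function(echo) {
    if (config$water_removal) echo <- remove_water(echo, pcfg)$echo
    if (config$n_bad > 0) echo <- repair_corrupted_points(echo, config$n_bad, pcfg)
    apodize(echo, config$line_broadening)
  }

  # process all ROI voxels once, keep per-channel echoes
  t0 <- tic()
  processed <- vector("list", nrow(roi))
  for (v in seq_len(nrow(roi))) {
    echoes <- voxel_echoes(ivol, roi$slice[v], roi$y[v], roi$x[v])
    processed[[v]] <- tryCatch(
      lapply(echoes, process_channel),
      error = function(e) stop(sprintf(
        "stage water-removal/apodization failed at voxel (slice %d, y %d, x %d): %s",
        roi$slice[v], roi$y[v], roi$x[v], conditionMessage(e)), call. = FALSE))
  }
  stage("per_channel_processing", t0)

  # per-channel noise SDs, measured once in the signal-free region and reused
  t0 <- tic()
  nv <- min(nrow(roi), 16L)
  sds <- matrix(NA_real_, nv, nc)
  for (v in seq_len(nv)) {
    for (ch in seq_len(nc)) {
      sp <- echo_spectrum(processed[[v]][[ch]])
      region <- which(sp$frequency >= config$signal_free_band[1L] &
                        sp$frequency <= config$signal_free_band[2L])
      sds[v, ch] <- estimate_noise(sp$spectrum, region)
    }
  }
  channel_sd <- apply(sds, 2L, stats::median)
  scale0 <- max(vapply(processed[[1L]], function(e) max(Mod(e$samples)), 1))
  channel_sd <- pmax(channel_sd, 1e-9 * scale0 + 1e-300)
  stage("noise_estimation", t0)

  expected <- metabolite_singlets(kind = config$kind,
                                  field_mhz = config$field_mhz)
  expected <- expected[expected$label %in% config$metabolites, , drop = FALSE]

  t0 <- tic()
  rows <- vector("list", nrow(roi))
  for (v in seq_len(nrow(roi))) {
    combined <- combine_channels(align_phase(processed[[v]]), channel_sd,
                                 weighting = config$weighting)$echo
    fit <- tryCatch({
      init <- initialize_params(combined, config$kind,
                                n_peaks = nrow(expected))
      fit_time_domain(combined, config$kind, init)
    }, error = function(e) NULL)
    if (is.null(fit)) next
    comp <- match_components(fit$components, expected)
    keep <- abs(comp$frequency - expected$frequency) <= config$match_tolerance
    rows[[v]] <- tibble::tibble(
      slice = roi$slice[v], y = roi$y[v], x = roi$x[v],
      metabolite = expected$label[keep],
      amplitude = comp$amplitude[keep], frequency = comp$frequency[keep],
      phase = comp$phase[keep], lorentz_decay = comp$lorentz_decay[keep],
      gauss_decay = comp$gauss_decay[keep],
      residual_norm = fit$residual_norm, converged = fit$converged)
  }
  fits <- dplyr::bind_rows(rows)
  stage("fitting", t0)

  hash <- config_hash(config)
  arrays <- lapply(stats::setNames(nm = config$metabolites), function(met) {
    arr <- array(0, c(d[2L], d[3L], d[4L]))
    sub <- fits[fits$metabolite == met, , drop = FALSE]
    arr[cbind(sub$slice, sub$y, sub$x)] <- pmax(sub$amplitude, 0)
    arr
  })
  maps <- structure(
    list(arrays = arrays, grid = c(d[3L], d[4L]), n_slices = d[2L],
         config_hash = hash),
    class = "metabolite_maps")

  structure(
    list(maps = maps, fits = fits, channel_noise_sd = channel_sd,
         roi = roi, config = config, config_hash = hash, log = logline),
    class = "mrsi_pipeline_result")
}

#' @export
print.mrsi_pipeline_result <- function(x, ...) {
  cat(sprintf("<mrsi_pipeline_result> %d fitted voxels, %d metabolites, config %s\n",
              length(unique(paste(x$fits$slice, x$fits$y, x$fits$x))),
              length(unique(x$fits$metabolite)), substr(x$config_hash, 1, 8)))
  cat(x$log, sep = "\n")
  invisible(x)
}

#' Write a fit table as CSV
#' @param fits Fit tibble (e.g. `run_pipeline()$fits`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE)
  invisible(path)
}

#' Render metabolite maps to PNG
#'
#' One grayscale (or localizer-overlay) image per slice and metabolite. Map
#' intensities are windowed to [0, max] over the whole volume per metabolite;
#' the window is recorded in the PNG text metadata. With a localizer, the map
#' is nearest-neighbour upsampled to the localizer matrix (aspect ratio
#' preserved) and blended as a hot overlay.
#'
#' @param maps A `metabolite_maps` (from [run_pipeline()]).
#' @param dir Output directory (created if needed).
#' @param localizer Optional numeric array (slice, Y, X) of localizer images;
#'   its per-slice matrix must be an integer multiple of the map grid.
#' @return Character vector of files written, invisibly.
#' @export
render_maps <- function(maps, dir, localizer = NULL) {
  stopifnot(inherits(maps, "metabolite_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (met in names(maps$arrays)) {
    arr <- maps$arrays[[met]]
    mx <- max(arr, 1e-300)
    for (s in seq_len(dim(arr)[1L])) {
      plane <- arr[s, , ] / mx
      if (!is.null(localizer)) {
        ldim <- dim(localizer)[2:3]
        fac <- ldim / dim(plane)
        if (any(fac != round(fac)) ||
            !identical(dim(localizer)[1L], dim(arr)[1L]))
          stop(sprintf(
            "localizer geometry (%s) does not match maps (%s)",
            paste(dim(localizer), collapse = "x"),
            paste(dim(arr), collapse = "x")), call. = FALSE)
        up <- plane[rep(seq_len(nrow(plane)), each = fac[1L]),
                    rep(seq_len(ncol(plane)), each = fac[2L])]
        loc <- localizer[s, , ]
        loc <- loc / max(loc, 1e-300)
        img <- array(0, c(ldim, 3L))
        img[, , 1L] <- pmin(1, 0.5 * loc + up)          # hot overlay in red
        img[, , 2L] <- pmin(1, 0.5 * loc + 0.4 * up)
        img[, , 3L] <- 0.5 * loc
      } else {
        img <- plane
      }
      f <- file.path(dir, sprintf("%s_slice%02d.png", met, s))
      png::writePNG(img, f, text = c(
        intensity_window = sprintf("0..%.6g", mx),
        config = maps$config_hash))
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Write metabolite maps as NIfTI volumes
#'
#' One NIfTI file per metabolite, dimensions (x, y, slice).
#'
#' @param maps A `metabolite_maps`.
#' @param path_stem Output stem; files are `<stem>_<metabolite>.nii.gz`.
#' @param voxel_dims Length-3 voxel size in mm (default c(10, 10, 10)).
#' @return Files written, invisibly.
#' @export
write_maps_nifti <- function(maps, path_stem, voxel_dims = c(10, 10, 10)) {
  stopifnot(inherits(maps, "metabolite_maps"))
  files <- character(0)
  for (met in names(maps$arrays)) {
    vol <- aperm(maps$arrays[[met]], c(3L, 2L, 1L))
    f <- paste0(path_stem, "_", met, ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = voxel_dims), f)
    files <- c(files, f)
  }
  invisible(files)
}
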