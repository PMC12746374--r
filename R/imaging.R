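# Voxelwise application of the kinetic models to dynamic image series, and a
# synthetic phantom generator that emulates the in-vivo acquisition: a blood
# voxel carrying the bolus, tumor voxels governed by Model I kinetics under
# snapshot sampling, spatially varying receive sensitivity and additive
# Gaussian noise at a stated peak SNR.

#' Construct a dynamic image series
#'
#' A 4-D stack `(x, y, z, time)` of dynamic magnitude-style signal with its
#' acquisition metadata. Timepoints are uniformly spaced at `TR` starting at
#' `time_origin`.
#'
#' @param data 4-D numeric array `(x, y, z, time)`; finite, time length >= 2.
#' @param TR Repetition time between timepoints, s.
#' @param flip Excitation angle, degrees.
#' @param voxel_size Voxel dimensions, mm (length 3).
#' @param time_origin Time of the first frame, s.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, TR = 1, flip = 20,
                           voxel_size = c(2.5, 2.5, 10), time_origin = 0) {
  if (!is.array(data) || length(dim(data)) != 4) {
    abort("`data` must be a 4-D array (x, y, z, time).")
  }
  if (dim(data)[4] < 2) abort("`data` must have at least 2 timepoints.")
  if (any(!is.finite(data))) abort("`data` must be finite.")
  if (!is.finite(TR) || TR <= 0) abort("`TR` must be > 0.")
  structure(
    list(data = data, TR = TR, flip = flip, voxel_size = voxel_size,
         time_origin = time_origin),
    class = "dynamic_series"
  )
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_series> %d x %d x %d voxels, %d timepoints (TR %g s, flip %g deg)\n",
              d[1], d[2], d[3], d[4], x$TR, x$flip))
  invisible(x)
}

series_times <- function(series) {
  series$time_origin + (seq_len(dim(series$data)[4]) - 1) * series$TR
}

#' Extract a voxel timecourse to use as a measured VIF shape
#'
#' Returns one voxel's dynamic signal as a [signal_curve()]. Used
#' nonparametrically as the vascular input shape for voxelwise fitting (the
#' samples are linearly interpolated onto the quadrature grid); the amplitude
#' is left to the fitted VIF scale factor.
#'
#' @param series A [dynamic_series()].
#' @param voxel Integer voxel index `c(x, y, z)` (1-based).
#' @return A [signal_curve()]. A warning is raised if the voxel shows no
#'   signal (not bolus-like).
#' @export
extract_vif_timecourse <- function(series, voxel) {
  stopifnot(inherits(series, "dynamic_series"))
  d <- dim(series$data)
  if (length(voxel) != 3 || any(voxel < 1) || any(voxel > d[1:3])) {
    abort("`voxel` must be an in-bounds index triple c(x, y, z).")
  }
  values <- series$data[voxel[1], voxel[2], voxel[3], ]
  if (all(values == 0) || max(values) <= 0) {
    warn("VIF voxel timecourse has no positive signal: not bolus-like.")
  }
  signal_curve(series_times(series), values,
               params = list(voxel = as.integer(voxel), role = "vif_shape"))
}

#' Early-window area-under-the-curve map
#'
#' Per-voxel mean signal over the timepoints falling in the half-open window
#' `[t_start, t_end)`, used for display and ROI orientation.
#'
#' @param series A [dynamic_series()].
#' @param window Numeric `c(t_start, t_end)`, s.
#' @return A 3-D array with the spatial dimensions of the series.
#' @export
auc_map <- function(series, window) {
  stopifnot(inherits(series, "dynamic_series"))
  if (length(window) != 2 || window[2] <= window[1]) {
    abort("`window` must be c(t_start, t_end) with t_end > t_start.")
  }
  tt <- series_times(series)
  keep <- which(tt >= window[1] & tt < window[2])
  if (length(keep) == 0) abort("`window` contains no timepoints.")
  apply(series$data[, , , keep, drop = FALSE], 1:3, mean)
}

#' Generate a synthetic dynamic HP urea phantom
#'
#' Builds a small dynamic series standing in for an in-vivo exam: one blood
#' voxel carries the (optionally delayed) gamma-variate bolus, tumor voxels
#' follow Model I kinetics under snapshot spoiled-GRE sampling, and the
#' background holds no agent. The whole stack is multiplied by a receive
#' sensitivity map, and Gaussian noise is added with SD set so that the mean
#' noise-free tumor-voxel peak attains `peak_snr`.
#'
#' Noise is additive and real-valued (not magnitude-rectified), so noisy
#' phantoms can contain small negative values, unlike true magnitude images.
#'
#' @param dim Spatial grid size, length 3 (default `c(16, 16, 1)`).
#' @param vif_voxel Index triple of the blood voxel (must lie outside the
#'   tumor region).
#' @param tumor_mask Logical 3-D array flagging tumor voxels; default is a
#'   6 x 6 block centered in the grid (first slice).
#' @param physio Tumor-voxel physiology ([physio_params()]).
#' @param vif Bolus description ([vif_params()]).
#' @param acq Acquisition ([acq_params()]), default TR 1 s, flip 20 deg, 60 s.
#' @param sensitivity Receive sensitivity: scalar or 3-D array (default 1
#'   everywhere).
#' @param peak_snr Peak SNR of tumor voxels; `Inf` for noise-free.
#' @param vif_delay Extra bolus arrival delay of the blood voxel, s.
#' @param seed Seed for the noise (reproducible series).
#' @return A list of class `hpk_phantom`: `series` (a [dynamic_series()])
#'   and `truth` (generating parameters, masks, sensitivity, noise sigma and
#'   the clean array).
#' @export
generate_phantom <- function(dim = c(16, 16, 1), vif_voxel = c(2, 2, 1),
                             tumor_mask = NULL, physio = physio_params(),
                             vif = vif_params(), acq = acq_params(),
                             sensitivity = 1, peak_snr = Inf,
                             vif_delay = 0, seed = NULL) {
  stopifnot(length(dim) == 3, inherits(physio, "physio_params"),
            inherits(vif, "vif_params"), inherits(acq, "acq_params"))
  if (is.null(tumor_mask)) {
    tumor_mask <- array(FALSE, dim)
    cx <- floor(dim[1] / 2) + (-2:3)
    cy <- floor(dim[2] / 2) + (-2:3)
    tumor_mask[cx[cx >= 1 & cx <= dim[1]], cy[cy >= 1 & cy <= dim[2]], 1] <- TRUE
  }
  if (!all(base::dim(tumor_mask) == dim)) abort("`tumor_mask` shape must match `dim`.")
  if (tumor_mask[vif_voxel[1], vif_voxel[2], vif_voxel[3]]) {
    abort("`vif_voxel` must lie outside the tumor region.")
  }
  if (length(sensitivity) == 1) sensitivity <- array(sensitivity, dim)

  n_t <- n_excitations(acq)
  times <- vif$onset + (seq_len(n_t) - 1) * acq$TR
  sinf <- sin(acq$flip * pi / 180)

  tumor_curve <- simulate_dynamic_signal(physio, acq, vif, model = "I")$signal
  vif_delayed <- vif_params(amplitude = vif$amplitude, shape = vif$shape,
                            timescale = vif$timescale,
                            onset = vif$onset + vif_delay)
  vif_curve <- sinf * vif_concentration(times, vif_delayed)

  clean <- array(0, c(dim, n_t))
  for (idx in which(tumor_mask)) {
    pos <- arrayInd(idx, dim)
    clean[pos[1], pos[2], pos[3], ] <- tumor_curve
  }
  clean[vif_voxel[1], vif_voxel[2], vif_voxel[3], ] <- vif_curve
  clean <- clean * as.vector(sensitivity)  # recycled along time

  sigma <- 0
  data <- clean
  if (is.finite(peak_snr)) {
    if (peak_snr <= 0) abort("`peak_snr` must be > 0.")
    peaks <- vapply(which(tumor_mask), function(idx) {
      pos <- arrayInd(idx, dim)
      max(clean[pos[1], pos[2], pos[3], ])
    }, numeric(1))
    sigma <- mean(peaks) / peak_snr
    noise <- if (is.null(seed)) {
      rnorm(length(clean), 0, sigma)
    } else {
      withr::with_seed(seed, rnorm(length(clean), 0, sigma))
    }
    data <- clean + array(noise, base::dim(clean))
  }

  series <- dynamic_series(data, TR = acq$TR, flip = acq$flip,
                           time_origin = times[1])
  structure(
    list(series = series,
         truth = list(physio = physio, vif = vif, acq = acq,
                      tumor_mask = tumor_mask, vif_voxel = as.integer(vif_voxel),
                      sensitivity = sensitivity, noise_sigma = sigma,
                      vif_delay = vif_delay, clean = clean)),
    class = "hpk_phantom"
  )
}

#' Voxelwise kinetic model fitting of a dynamic series
#'
#' Fits the chosen kinetic model to every masked voxel's timecourse using a
#' measured VIF *shape* (see [extract_vif_timecourse()]) with the VIF scaling
#' factor always included as a fitted parameter — the measured amplitude
#' cannot be trusted across the image when receive sensitivity varies.
#'
#' @param series A [dynamic_series()].
#' @param mask Logical 3-D array of voxels to fit (at least one `TRUE`).
#' @param vif_shape A [signal_curve()] giving the vascular input shape.
#' @param model Kinetic model id.
#' @param options A [fit_options()]; `fit_vif_scale` is forced `TRUE`.
#' @param T1 Assumed relaxation time, s.
#' @return An object of class `parameter_maps`: 3-D maps (`k_ve`, `v_b`,
#'   `v_e`, `vif_scale`, `kve_ve`, `residual_norm`, `converged`) with `NA`
#'   outside the mask, plus the mask and model. Deterministic given inputs.
#' @export
voxelwise_fit <- function(series, mask, vif_shape, model = "I",
                          options = fit_options(fit_vif_scale = TRUE),
                          T1 = 20) {
  stopifnot(inherits(series, "dynamic_series"))
  model <- model_id(model)
  d <- dim(series$data)
  if (!all(base::dim(mask) == d[1:3])) abort("`mask` shape must match the series.")
  if (!any(mask)) abort("`mask` must flag at least one voxel.")
  options$fit_vif_scale <- TRUE
  n_t <- d[4]
  acq <- acq_params(TR = series$TR, flip = series$flip,
                    duration = n_t * series$TR)
  tt <- series_times(series)
  vif_df <- tibble(time_s = vif_shape$time_s, signal = vif_shape$signal)

  map_names <- c("k_ve", "v_b", "v_e", "vif_scale", "kve_ve",
                 "residual_norm", "converged")
  maps <- lapply(map_names, function(nm) array(NA_real_, d[1:3]))
  names(maps) <- map_names

  for (idx in which(mask)) {
    pos <- arrayInd(idx, d[1:3])
    curve <- signal_curve(tt, series$data[pos[1], pos[2], pos[3], ])
    fit <- fit_model(curve, model, acq, vif_df, options = options, T1 = T1)
    maps$k_ve[idx] <- fit$estimates[["k_ve"]]
    maps$v_b[idx] <- fit$v_b
    maps$v_e[idx] <- fit$v_e
    maps$vif_scale[idx] <- fit$vif_scale
    maps$kve_ve[idx] <- fit$ratios[["kve_ve"]]
    maps$residual_norm[idx] <- fit$residual_norm
    maps$converged[idx] <- as.numeric(fit$converged)
  }
  structure(
    list(maps = maps, mask = mask, model = model, voxel_size = series$voxel_size),
    class = "parameter_maps"
  )
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("<parameter_maps> Model %s, %d fitted voxels\n",
              x$model, sum(x$mask)))
  cat("  maps:", paste(names(x$maps), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy voxelwise fitting results
#'
#' @param x A `parameter_maps` object.
#' @param ... Unused.
#' @return A tibble with one row per fitted voxel: `x`, `y`, `z` and every
#'   parameter map value.
#' @export
tidy.parameter_maps <- function(x, ...) {
  idx <- which(x$mask)
  pos <- arrayInd(idx, dim(x$mask))
  out <- tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3])
  for (nm in names(x$maps)) out[[nm]] <- x$maps[[nm]][idx]
  out$converged <- as.logical(out$converged)
  out
}

#' Plot a parameter map slice
#'
#' @param object A `parameter_maps` object.
#' @param parameter Which map to show.
#' @param slice z-slice index.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.parameter_maps <- function(object, parameter = "k_ve", slice = 1, ...) {
  m <- object$maps[[parameter]][, , slice]
  df <- tidyr::expand_grid(x = seq_len(nrow(m)), y = seq_len(ncol(m))) |>
    dplyr::mutate(value = m[cbind(.data$x, .data$y)])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = parameter) +
    ggplot2::theme_minimal()
}

#' Read / write dynamic series and parameter maps as NIfTI
#'
#' Thin wrappers over RNifti for the standard interchange format; the TR is
#' carried in the time-dimension pixdim. Requires the RNifti package.
#'
#' @param series A [dynamic_series()].
#' @param path NIfTI file path (`.nii` / `.nii.gz`).
#' @param flip Excitation angle, degrees (not stored in NIfTI headers).
#' @return `write_dynamic_series()` returns `path` invisibly;
#'   `read_dynamic_series()` returns a [dynamic_series()].
#' @export
write_dynamic_series <- function(series, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) abort("RNifti is required.")
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size, series$TR)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_dynamic_series
#' @export
read_dynamic_series <- function(path, flip = 20) {
  if (!requireNamespace("RNifti", quietly = TRUE)) abort("RNifti is required.")
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  dynamic_series(array(as.numeric(img), dim(img)),
                 TR = if (length(pd) >= 4) pd[4] else 1,
                 flip = flip, voxel_size = pd[1:3])
}

#' Write parameter maps to NIfTI files plus a per-voxel CSV table
#'
#' @param maps A `parameter_maps` object.
#' @param dir Output directory (created if missing); one
#'   `<parameter>.nii.gz` per map and a `voxel_fits.csv` table.
#' @return `dir`, invisibly.
#' @export
write_parameter_maps <- function(maps, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) abort("RNifti is required.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(maps$maps)) {
    RNifti::writeNifti(RNifti::asNifti(maps$maps[[nm]]),
                       file.path(dir, paste0(nm, ".nii.gz")))
  }
  readr::write_csv(tidy(maps), file.path(dir, "voxel_fits.csv"))
  invisible(dir)
}
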