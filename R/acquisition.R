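#' Construct a dynamic signal curve
#'
#' A `signal_curve` is a tibble with columns `time_s` (strictly increasing
#' excitation timestamps) and `signal` (observed value per excitation,
#' arbitrary units), carrying the noise standard deviation and generating
#' parameters as attributes.
#'
#' @param time_s Excitation timestamps, s, strictly increasing.
#' @param signal Observed signal per excitation; finite.
#' @param noise_sigma SD of added noise (0 if noise-free).
#' @param params Optional named list of generating parameters, kept as an
#'   attribute for provenance.
#' @return A tibble of class `signal_curve`.
#' @export
signal_curve <- function(time_s, signal, noise_sigma = 0, params = list()) {
  if (length(time_s) != length(signal)) abort("`time_s` and `signal` lengths differ.")
  if (any(!is.finite(time_s)) || any(!is.finite(signal))) {
    abort("`time_s` and `signal` must be finite.")
  }
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    abort("`time_s` must be strictly increasing.")
  }
  if (!is.finite(noise_sigma) || noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  out <- tibble(time_s = as.numeric(time_s), signal = as.numeric(signal))
  attr(out, "noise_sigma") <- noise_sigma
  attr(out, "params") <- params
  class(out) <- c("signal_curve", class(out))
  out
}

#' @export
#' @rdname signal_curve
#' @param curve A `signal_curve`.
noise_sigma <- function(curve) attr(curve, "noise_sigma") %||% 0

# Precompute everything about (vif, acquisition) that candidate kinetic
# parameters do not change: pulse times, the fine quadrature grid and the VIF
# sampled on it. Because the grid offsets within each TR interval are
# identical, the inter-pulse convolution integrals for any decay rate reduce
# to one matrix-vector product.
sim_context <- function(vif, acq, onset = NULL, step = 0.01) {
  stopifnot(inherits(acq, "acq_params"))
  f <- vif_function(vif)
  if (is.null(onset)) {
    onset <- if (inherits(vif, "vif_params")) vif$onset else 0
  }
  n <- n_excitations(acq)
  times <- onset + (seq_len(n) - 1) * acq$TR
  m <- max(2L, as.integer(round(acq$TR / step)))
  dt <- acq$TR / m
  if (n > 1) {
    fine <- onset + (0:((n - 1L) * m)) * dt
    cb_fine <- f(fine)
    idx <- outer(0:m, (seq_len(n - 1L) - 1L) * m, "+") + 1L  # (m+1) x (n-1)
    cmat <- matrix(cb_fine[idx], nrow = m + 1L)
    cb_pulse <- cb_fine[1L + (seq_len(n) - 1L) * m]
  } else {
    cmat <- NULL
    cb_pulse <- f(times)
  }
  list(times = times, cmat = cmat, cb_pulse = cb_pulse,
       m = m, dt = dt, TR = acq$TR, n = n, flip = acq$flip, onset = onset)
}

# Quadrature weights for int_0^{m*dt} Cb(tau) exp(-alpha*(end - tau)) dtau
# with Cb piecewise linear on the grid: each segment integrates in closed
# form against the exponential kernel, so the error comes from the linear
# interpolation of Cb only and is independent of alpha (which can be large
# when k_ve/v_e is). Returns weights for the m+1 grid values of Cb.
conv_weights <- function(alpha, dt, m) {
  x <- alpha * dt
  if (x < 1e-4) {
    g1 <- dt * (0.5 - x / 6 + x^2 / 24)
    g0 <- dt * (0.5 - x / 3 + x^2 / 8)
  } else {
    em <- -expm1(-x)          # 1 - exp(-alpha*dt)
    g1 <- (dt / x) * (1 - em / x)
    g0 <- dt * em / x - g1
  }
  e <- exp(-alpha * dt * ((m - 1):0))
  c(g0 * e, 0) + c(0, g1 * e)
}

# Snapshot spoiled-GRE recursion over the pulse train. Between pulses the EES
# concentration follows the closed-form solution of the mass balance; at each
# pulse the extravascular longitudinal magnetization is reduced by cos(flip)
# while blood is fully replenished (no excitation losses on the VIF).
sim_from_context <- function(ctx, k_ve, v_b, v_e, T1, Ce0 = 0, vif_scale = 1) {
  sinf <- sin(ctx$flip * pi / 180)
  cosf <- cos(ctx$flip * pi / 180)
  rate <- if (k_ve == 0) 0 else k_ve / max(v_e, 1e-12)
  a <- rate + 1 / T1
  ce <- numeric(ctx$n)
  ce[1] <- Ce0
  if (ctx$n > 1) {
    w <- conv_weights(a, ctx$dt, ctx$m)
    ints <- as.numeric(crossprod(ctx$cmat, w)) * vif_scale
    decay <- exp(-a * ctx$TR)
    for (i in 2:ctx$n) {
      ce[i] <- cosf * ce[i - 1] * decay + rate * ints[i - 1]
    }
  }
  sinf * (v_b * ctx$cb_pulse * vif_scale + v_e * ce)
}

#' Simulate a dynamic snapshot spoiled-GRE signal curve
#'
#' Simulates the observed HP urea signal over a train of RF excitations. The
#' first excitation coincides with the VIF onset (negligible initial HP
#' signal); each excitation reads out
#' `sin(flip) * (v_b * C_b(t) + v_e * C_e(t))` and instantaneously reduces the
#' extravascular longitudinal magnetization by `cos(flip)`. Blood within the
#' voxel is assumed fully replaced between excitations, so the vascular term
#' is never attenuated by prior pulses. The output is noise-free; use
#' [add_noise()] to add measurement noise.
#'
#' @param physio A [physio_params()] object.
#' @param acq An [acq_params()] object.
#' @param vif VIF as accepted by [vif_concentration()].
#' @param model Kinetic model id (see [model_id()]).
#' @param Ce0 EES concentration at the first excitation (default 0).
#' @param step Internal quadrature step, s.
#' @return A [signal_curve()] with one row per excitation.
#' @examples
#' curve <- simulate_dynamic_signal(physio_params(), acq_params(), vif_params())
#' head(curve)
#' @export
simulate_dynamic_signal <- function(physio, acq, vif, model = "I",
                                    Ce0 = 0, step = 0.01) {
  model <- model_id(model)
  stopifnot(inherits(physio, "physio_params"))
  eff <- effective_volumes(model, physio)
  ctx <- sim_context(vif, acq, step = step)
  values <- sim_from_context(ctx, physio$k_ve, eff$v_b, eff$v_e, physio$T1,
                             Ce0 = Ce0)
  signal_curve(ctx$times, values, noise_sigma = 0,
               params = list(model = model, physio = unclass(physio),
                             acq = unclass(acq),
                             vif = if (inherits(vif, "vif_params")) unclass(vif) else "sampled"))
}

#' Calibrate the noise standard deviation for a reference peak SNR
#'
#' To compare noisy-fit performance consistently while physiological or
#' acquisition parameters vary, a *reference SNR* fixes the noise SD at the
#' value that produces that peak SNR for the **default** model and acquisition
#' parameters: `sigma = max(default noise-free curve) / reference_snr`. The
#' same sigma is then reused across all varied conditions of an experiment.
#'
#' @param reference_snr Target peak SNR (> 0) at the default settings.
#' @param physio,acq,vif,model Settings defining the reference curve; default
#'   to the package defaults.
#' @return Noise SD (scalar).
#' @export
calibrate_noise_sigma <- function(reference_snr, physio = physio_params(),
                                  acq = acq_params(), vif = vif_params(),
                                  model = "I") {
  if (!is.numeric(reference_snr) || !is.finite(reference_snr) || reference_snr <= 0) {
    abort("`reference_snr` must be > 0.")
  }
  peak <- max(simulate_dynamic_signal(physio, acq, vif, model = model)$signal)
  peak / reference_snr
}

#' Add Gaussian measurement noise to a signal curve
#'
#' Adds independent zero-mean Gaussian deviates of SD `sigma` to each sample
#' (real-valued additive model; no magnitude rectification). Deterministic
#' when `seed` is given.
#'
#' @param curve A [signal_curve()] (or any data frame with a `signal` column).
#' @param sigma Noise SD; >= 0.
#' @param seed Optional integer seed for reproducibility.
#' @return The curve with noisy `signal` and `noise_sigma` recorded.
#' @export
add_noise <- function(curve, sigma, seed = NULL) {
  if (!is.numeric(sigma) || !is.finite(sigma) || sigma < 0) {
    abort("`sigma` must be finite and >= 0.")
  }
  if (sigma == 0) {
    attr(curve, "noise_sigma") <- 0
    return(curve)
  }
  noise <- if (is.null(seed)) {
    rnorm(nrow(curve), 0, sigma)
  } else {
    withr::with_seed(seed, rnorm(nrow(curve), 0, sigma))
  }
  curve$signal <- curve$signal + noise
  attr(curve, "noise_sigma") <- sigma
  curve
}

#' Write / read a signal curve as CSV plus a JSON sidecar
#'
#' The curve is stored as a two-column CSV `(time_s, signal)` with header;
#' `noise_sigma` and the generating parameters go to `<path>.json`.
#'
#' @param curve A [signal_curve()].
#' @param path CSV file path.
#' @return `write_signal_curve()` returns `path` invisibly;
#'   `read_signal_curve()` returns a [signal_curve()].
#' @export
write_signal_curve <- function(curve, path) {
  readr::write_csv(tibble(time_s = curve$time_s, signal = curve$signal), path)
  meta <- list(noise_sigma = noise_sigma(curve), params = attr(curve, "params"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_signal_curve
#' @export
read_signal_curve <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  signal_curve(df$time_s, df$signal,
               noise_sigma = meta$noise_sigma %||% 0,
               params = meta$params %||% list())
}
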