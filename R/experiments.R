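# Monte-Carlo studies of acquisition settings, model-misspecification bias
# and noise. All studies generate data from Model I; the noise SD is
# calibrated once per study at the default settings (never per grid point)
# and recorded in every result row.

# Independent per-condition seeds derived from one master seed, so results
# are invariant to iteration order.
derive_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

aggregate_draws <- function(draws, truths) {
  draws |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      mean_estimate = mean(.data$estimate),
      cov_pct = if (dplyr::n() >= 2) coefficient_of_variation_pct(.data$estimate) else NA_real_,
      convergence_rate = mean(.data$converged),
      .groups = "drop"
    ) |>
    dplyr::left_join(truths, by = "parameter") |>
    dplyr::mutate(mean_error_pct = 100 * (.data$mean_estimate - .data$truth) / .data$truth)
}

fit_draw_row <- function(fit) {
  tibble(
    parameter = c("k_ve", "v_b", "v_e", "vif_scale", "kve_ve"),
    estimate = c(fit$estimates[["k_ve"]], fit$v_b, fit$v_e, fit$vif_scale,
                 fit$ratios[["kve_ve"]]),
    converged = fit$converged
  ) |>
    dplyr::filter(is.finite(.data$estimate))
}

#' Acquisition-setting sweep for Model I parameter recovery
#'
#' For each (TR, flip) grid point, a noise-free Model I curve is simulated at
#' the reference physiology, Gaussian noise with the SD calibrated for
#' `reference_snr` at the *default* acquisition (TR 1 s, flip 20 deg) is
#' added `n_reps` times, and Model I is refit with the accurate VIF each
#' time. Accuracy and reproducibility are summarized as percent mean error
#' and coefficient of variation per parameter.
#'
#' @param tr_grid TR values, s.
#' @param flip_grid Excitation angles, degrees.
#' @param reference_snr Reference peak SNR calibrating the (fixed) noise SD.
#' @param n_reps Noise repetitions per grid point.
#' @param seed Master seed; per-repetition seeds are derived from it.
#' @param physio,vif Generating physiology and VIF (defaults as in
#'   [physio_params()] / [vif_params()]).
#' @param duration Acquisition duration, s.
#' @return A tibble of class `hpk_sweep`: one row per grid point x parameter
#'   with `mean_error_pct`, `cov_pct`, `convergence_rate`, `noise_sigma`.
#' @export
run_acquisition_sweep <- function(tr_grid, flip_grid, reference_snr = 25,
                                  n_reps = 100, seed = 1,
                                  physio = physio_params(), vif = vif_params(),
                                  duration = 60) {
  if (length(tr_grid) < 1 || length(flip_grid) < 1) abort("grids must be non-empty.")
  sigma <- if (is.finite(reference_snr)) {
    calibrate_noise_sigma(reference_snr, physio = physio,
                          acq = acq_params(duration = duration), vif = vif)
  } else 0
  grid <- tidyr::expand_grid(TR = tr_grid, flip = flip_grid)
  seeds <- matrix(derive_seeds(seed, nrow(grid) * n_reps), nrow = nrow(grid))
  truths <- tibble(parameter = c("k_ve", "v_b", "v_e"),
                   truth = c(physio$k_ve, physio$v_b, physio$v_ee))

  res <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    acq <- acq_params(TR = grid$TR[g], flip = grid$flip[g], duration = duration)
    clean <- simulate_dynamic_signal(physio, acq, vif, model = "I")
    draws <- purrr::map_dfr(seq_len(n_reps), function(r) {
      noisy <- add_noise(clean, sigma, seed = seeds[g, r])
      fit_draw_row(fit_model(noisy, "I", acq, vif))
    })
    aggregate_draws(dplyr::filter(draws, .data$parameter %in% truths$parameter),
                    truths) |>
      dplyr::mutate(TR = grid$TR[g], flip = grid$flip[g], .before = 1)
  })
  out <- res |>
    dplyr::mutate(n_reps = n_reps, reference_snr = reference_snr,
                  noise_sigma = sigma)
  attr(out, "seed") <- seed
  class(out) <- c("hpk_sweep", class(out))
  out
}

#' Sensitivity of the simplified models to the parameters driving Model I
#'
#' Noise-free Model I data are generated while one physiological parameter
#' sweeps through a grid (the other two held at their reference values), and
#' each requested model is fit with the accurate VIF. The fitted values trace
#' the bias of Models II and III against underlying changes in the tissue
#' state; Model I serves as the control.
#'
#' @param param_name One of `"k_ve"`, `"v_b"`, `"v_ee"`.
#' @param value_grid Values the driving parameter sweeps through.
#' @param models Models to fit.
#' @param physio,vif,acq Reference settings.
#' @return A tibble of class `hpk_sensitivity`: one row per grid value x
#'   model with fitted `k_ve`, `v_b`, `v_e` and the `kve_ve` ratio.
#' @export
run_sensitivity_sweep <- function(param_name, value_grid,
                                  models = c("I", "II", "III"),
                                  physio = physio_params(), vif = vif_params(),
                                  acq = acq_params()) {
  if (!param_name %in% c("k_ve", "v_b", "v_ee")) {
    abort('`param_name` must be one of "k_ve", "v_b", "v_ee".')
  }
  if (length(value_grid) < 1) abort("`value_grid` must be non-empty.")
  models <- vapply(models, model_id, character(1))
  out <- purrr::map_dfr(value_grid, function(val) {
    args <- unclass(physio)
    args[[param_name]] <- val
    p <- do.call(physio_params, args)
    clean <- simulate_dynamic_signal(p, acq, vif, model = "I")
    purrr::map_dfr(models, function(mod) {
      fit <- fit_model(clean, mod, acq, vif)
      tibble(param = param_name, true_value = val, model = mod,
             k_ve = fit$estimates[["k_ve"]], v_b = fit$v_b, v_e = fit$v_e,
             kve_ve = fit$ratios[["kve_ve"]], converged = fit$converged)
    })
  })
  class(out) <- c("hpk_sensitivity", class(out))
  out
}

#' Monte-Carlo noise study across models and VIF-fitting modes
#'
#' Data are always generated from Model I at the reference physiology. At
#' each reference SNR, `n_reps` noisy realizations are fit with every
#' requested model, both with the accurate VIF held fixed
#' (`"accurate_vif"`) and with the VIF amplitude as an additional fitted
#' parameter (`"fitted_vif_scale"`). Each noisy realization is shared across
#' models and modes so comparisons see identical noise. Aggregates cover
#' `k_ve`, the volume fractions, the VIF scale and the `k_ve/v_e` ratio.
#'
#' @param snr_grid Reference SNR values (default 10 to 50 in steps of 5).
#' @param n_reps Noise repetitions per SNR (>= 2).
#' @param seed Master seed.
#' @param models Models to fit.
#' @param modes VIF handling modes, subset of
#'   `c("accurate_vif", "fitted_vif_scale")`.
#' @param physio,vif,acq Generating settings.
#' @return A tibble of class `hpk_noise_study`: one row per SNR x model x
#'   mode x parameter, with raw per-repetition estimates in the `"draws"`
#'   attribute.
#' @export
run_noise_study <- function(snr_grid = seq(10, 50, by = 5), n_reps = 100,
                            seed = 1, models = c("I", "II", "III"),
                            modes = c("accurate_vif", "fitted_vif_scale"),
                            physio = physio_params(), vif = vif_params(),
                            acq = acq_params()) {
  if (n_reps < 2) abort("`n_reps` must be >= 2.")
  if (length(snr_grid) < 1) abort("`snr_grid` must be non-empty.")
  if (!all(modes %in% c("accurate_vif", "fitted_vif_scale"))) {
    abort('`modes` must be a subset of c("accurate_vif", "fitted_vif_scale").')
  }
  models <- vapply(models, model_id, character(1))
  clean <- simulate_dynamic_signal(physio, acq, vif, model = "I")
  peak <- max(clean$signal)
  seeds <- matrix(derive_seeds(seed, length(snr_grid) * n_reps),
                  nrow = length(snr_grid))
  truths <- tibble(
    parameter = c("k_ve", "v_b", "v_e", "vif_scale", "kve_ve"),
    truth = c(physio$k_ve, physio$v_b, physio$v_ee, 1,
              physio$k_ve / physio$v_ee)
  )
  opts <- list(accurate_vif = fit_options(fit_vif_scale = FALSE),
               fitted_vif_scale = fit_options(fit_vif_scale = TRUE))

  res <- purrr::map_dfr(seq_along(snr_grid), function(s) {
    sigma <- peak / snr_grid[s]
    draws <- purrr::map_dfr(seq_len(n_reps), function(r) {
      noisy <- add_noise(clean, sigma, seed = seeds[s, r])
      purrr::map_dfr(modes, function(mode) {
        purrr::map_dfr(models, function(mod) {
          fit_draw_row(fit_model(noisy, mod, acq, vif, options = opts[[mode]])) |>
            dplyr::mutate(model = mod, vif_mode = mode, rep = r)
        })
      })
    })
    draws |>
      dplyr::group_by(.data$model, .data$vif_mode) |>
      dplyr::group_modify(~ aggregate_draws(.x, truths)) |>
      dplyr::ungroup() |>
      dplyr::mutate(reference_snr = snr_grid[s], noise_sigma = sigma,
                    n_reps = n_reps, .before = 1) |>
      dplyr::mutate(raw = list(dplyr::mutate(draws, reference_snr = snr_grid[s])))
  })
  raw <- dplyr::bind_rows(unique(res$raw))
  res$raw <- NULL
  attr(res, "draws") <- raw
  attr(res, "seed") <- seed
  class(res) <- c("hpk_noise_study", class(res))
  res
}

#' @export
#' @rdname run_noise_study
#' @param study An `hpk_noise_study` object.
noise_study_draws <- function(study) attr(study, "draws")

# 3x3 mean filter used only when displaying sweep maps (edge cells average
# over available neighbors); stored metrics are never smoothed.
mean_filter_3x3 <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- mat
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- mean(mat[max(1, i - 1):min(nr, i + 1),
                            max(1, j - 1):min(nc, j + 1)])
    }
  }
  out
}

#' Plot an acquisition sweep as accuracy / reproducibility maps
#'
#' @param object An `hpk_sweep` tibble.
#' @param metric `"mean_error_pct"` or `"cov_pct"`.
#' @param smooth Apply a 3x3 mean filter for display (display only; the
#'   stored metrics are untouched).
#' @param ... Unused.
#' @return A ggplot, faceted by parameter.
#' @export
autoplot.hpk_sweep <- function(object, metric = c("mean_error_pct", "cov_pct"),
                               smooth = FALSE, ...) {
  metric <- match.arg(metric)
  df <- as_tibble(object)[, c("TR", "flip", "parameter", metric)]
  if (smooth) {
    df <- df |>
      dplyr::group_by(.data$parameter) |>
      dplyr::arrange(.data$TR, .data$flip, .by_group = TRUE) |>
      dplyr::group_modify(function(d, key) {
        m <- matrix(d[[metric]], nrow = dplyr::n_distinct(d$TR), byrow = TRUE)
        d[[metric]] <- as.vector(t(mean_filter_3x3(m)))
        d
      }) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flip, y = .data$TR,
                                   fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Excitation angle (deg)", y = "TR (s)", fill = metric) +
    ggplot2::theme_minimal()
}

#' Plot sensitivity-sweep fitted values against the driving parameter
#'
#' @param object An `hpk_sensitivity` tibble.
#' @param parameter Fitted quantity to display (default `"k_ve"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hpk_sensitivity <- function(object, parameter = "k_ve", ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$true_value, y = .data[[parameter]],
                               color = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = sprintf("True %s", object$param[1]),
                  y = sprintf("Fitted %s", parameter), color = "Model") +
    ggplot2::theme_minimal()
}

#' Plot noise-study reproducibility against reference SNR
#'
#' @param object An `hpk_noise_study` tibble.
#' @param parameter Parameter to display (default `"k_ve"`).
#' @param metric `"cov_pct"` or `"mean_error_pct"`.
#' @param ... Unused.
#' @return A ggplot, faceted by VIF mode.
#' @export
autoplot.hpk_noise_study <- function(object, parameter = "k_ve",
                                     metric = c("cov_pct", "mean_error_pct"),
                                     ...) {
  metric <- match.arg(metric)
  df <- dplyr::filter(as_tibble(object), .data$parameter == !!parameter)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference_snr,
                                   y = .data[[metric]], color = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~vif_mode) +
    ggplot2::labs(x = "Reference SNR", y = metric, color = "Model") +
    ggplot2::theme_minimal()
}

#' Write study results as tidy CSV plus a JSON summary
#'
#' @param result A study result tibble (`hpk_sweep`, `hpk_sensitivity` or
#'   `hpk_noise_study`).
#' @param path Output CSV path; a `<path>.json` summary (seed, noise sigma,
#'   convergence) is written alongside.
#' @return `path`, invisibly.
#' @export
write_study_result <- function(result, path) {
  readr::write_csv(as_tibble(result), path)
  summ <- list(
    class = class(result)[1],
    seed = attr(result, "seed"),
    noise_sigma = if ("noise_sigma" %in% names(result)) unique(result$noise_sigma),
    convergence_rate = if ("convergence_rate" %in% names(result)) {
      mean(result$convergence_rate)
    }
  )
  jsonlite::write_json(summ, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
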