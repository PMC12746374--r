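#' Fit a kinetic model to a dynamic signal curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box constraints)
#' of a kinetic model to an observed snapshot spoiled-GRE signal curve. The
#' forward model is [simulate_dynamic_signal()] with candidate parameters;
#' the free parameters are `k_ve` plus the volume fraction(s) of the chosen
#' model, optionally with a VIF amplitude scaling factor (`vif_scale`) when
#' the VIF amplitude is unreliable (e.g. unknown coil sensitivity). `T1` and
#' the acquisition settings are treated as known and held fixed.
#'
#' For Model I the physical constraint `v_b + v_ee <= 1` is enforced by a
#' smooth penalty residual that is zero inside the feasible region.
#'
#' Non-convergence is reported through `converged = FALSE` in the result,
#' never as an error.
#'
#' @param curve A [signal_curve()] (or data frame with `time_s`, `signal`).
#' @param model Kinetic model id (see [model_id()]).
#' @param acq The [acq_params()] used for the acquisition.
#' @param vif VIF *shape*: a [vif_params()] object, function, or sampled
#'   curve (see [vif_concentration()]). With `fit_vif_scale = TRUE` its
#'   amplitude is multiplied by the fitted scale factor.
#' @param options A [fit_options()] object.
#' @param T1 Longitudinal relaxation time assumed during fitting, s.
#' @param step Internal quadrature step, s.
#' @return An object of class `hpk_fit` with elements `model`, `estimates`
#'   (named vector of fitted parameters), `ratios` (`kve_ve`, and `kve_vb`
#'   where `v_b` is a parameter), `residual_norm`, `converged`, `iterations`,
#'   `fitted`, and the inputs. Ratios are recomputed from the estimates.
#' @examples
#' curve <- simulate_dynamic_signal(physio_params(), acq_params(), vif_params())
#' fit <- fit_model(curve, "I", acq_params(), vif_params())
#' tidy(fit)
#' glance(fit)
#' @export
fit_model <- function(curve, model, acq, vif, options = fit_options(),
                      T1 = 20, step = 0.01) {
  model <- model_id(model)
  stopifnot(inherits(acq, "acq_params"), inherits(options, "fit_options"))
  if (!all(c("time_s", "signal") %in% names(curve))) {
    abort("`curve` must have columns `time_s` and `signal`.")
  }
  free <- switch(model,
    I   = c("k_ve", "v_b", "v_e"),
    II  = c("k_ve", "v_e"),
    III = c("k_ve", "v_b")
  )
  if (options$fit_vif_scale) free <- c(free, "vif_scale")
  if (nrow(curve) < length(free) + 1) {
    abort("`curve` must have at least one more sample than free parameters.")
  }

  defaults_init  <- c(k_ve = 0.05, v_b = 0.1, v_e = 0.3, vif_scale = 1)
  defaults_lower <- c(k_ve = 0, v_b = 0, v_e = 0, vif_scale = 0.01)
  defaults_upper <- c(k_ve = 1, v_b = 1, v_e = 1, vif_scale = 100)
  take <- function(user, def) {
    out <- def[free]
    if (!is.null(user)) out[intersect(names(user), free)] <- user[intersect(names(user), free)]
    out
  }
  start <- take(options$initial_guess, defaults_init)
  lower <- take(options$lower, defaults_lower)
  upper <- take(options$upper, defaults_upper)
  if (any(start < lower | start > upper)) {
    abort("`initial_guess` must lie within the bounds.")
  }

  ctx <- sim_context(vif, acq, onset = curve$time_s[1], step = step)
  n_use <- min(ctx$n, nrow(curve))
  obs <- curve$signal[seq_len(n_use)]
  peak <- max(abs(obs), 1e-12)

  predict_free <- function(par) {
    vb <- switch(model, I = par[["v_b"]], II = 0, III = par[["v_b"]])
    ve <- switch(model, I = par[["v_e"]], II = par[["v_e"]], III = 1 - par[["v_b"]])
    sc <- if (options$fit_vif_scale) par[["vif_scale"]] else 1
    sim_from_context(ctx, par[["k_ve"]], vb, ve, T1, vif_scale = sc)[seq_len(n_use)]
  }
  residual_fn <- function(par) {
    r <- obs - predict_free(par)
    if (model == "I") {
      excess <- max(0, par[["v_b"]] + par[["v_e"]] - 1)
      r <- c(r, 1e4 * peak * excess)
    }
    r
  }

  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper, fn = residual_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = options$max_iterations,
        ftol = options$tolerance, ptol = options$tolerance
      )
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    est <- start
    converged <- FALSE
    iterations <- 0L
    info <- -1L
    msg <- "optimizer error"
  } else {
    est <- setNames(fit$par, free)
    converged <- fit$info %in% 1:4
    iterations <- fit$niter
    info <- fit$info
    msg <- fit$message
  }

  pred <- predict_free(est)
  resid <- obs - pred
  vb_hat <- switch(model, I = est[["v_b"]], II = NA_real_, III = est[["v_b"]])
  ve_hat <- switch(model, I = est[["v_e"]], II = est[["v_e"]], III = 1 - est[["v_b"]])
  ratios <- c(kve_ve = unname(est[["k_ve"]] / ve_hat))
  if (model %in% c("I", "III")) {
    ratios <- c(ratios, kve_vb = unname(est[["k_ve"]] / vb_hat))
  }

  structure(
    list(
      model = model,
      estimates = est,
      v_b = vb_hat, v_e = ve_hat,
      vif_scale = if (options$fit_vif_scale) est[["vif_scale"]] else NA_real_,
      ratios = ratios,
      residual_norm = sum(resid^2),
      converged = converged,
      iterations = iterations,
      info = info,
      message = msg,
      fitted = pred,
      curve = curve[seq_len(n_use), , drop = FALSE],
      options = options,
      T1 = T1,
      acq = acq
    ),
    class = "hpk_fit"
  )
}

#' @export
print.hpk_fit <- function(x, ...) {
  cat(sprintf("<hpk_fit> Model %s (%s)\n", x$model,
              if (x$converged) "converged" else "NOT converged"))
  cat("  estimates:", paste(sprintf("%s = %.5g", names(x$estimates), x$estimates),
                            collapse = ", "), "\n")
  cat("  ratios:   ", paste(sprintf("%s = %.5g", names(x$ratios), x$ratios),
                            collapse = ", "), "\n")
  cat(sprintf("  residual_norm: %.4g over %d samples\n", x$residual_norm,
              nrow(x$curve)))
  invisible(x)
}

#' Tidy a fitted kinetic model
#'
#' @param x An `hpk_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per fitted or derived quantity: `term`,
#'   `estimate`, and `kind` (`"fitted"`, `"derived"`).
#' @export
tidy.hpk_fit <- function(x, ...) {
  fitted_tbl <- tibble(term = names(x$estimates),
                       estimate = unname(x$estimates), kind = "fitted")
  derived <- c(if (x$model == "III") c(v_e = x$v_e), x$ratios)
  dplyr::bind_rows(
    fitted_tbl,
    tibble(term = names(derived), estimate = unname(derived), kind = "derived")
  )
}

#' Glance at a fitted kinetic model
#'
#' @param x An `hpk_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `residual_norm`, `converged`,
#'   `iterations`, `n`.
#' @export
glance.hpk_fit <- function(x, ...) {
  tibble(model = x$model, residual_norm = x$residual_norm,
         converged = x$converged, iterations = x$iterations,
         n = nrow(x$curve))
}

#' @export
fitted.hpk_fit <- function(object, ...) object$fitted

#' Plot a fitted kinetic model over the data
#'
#' @param object An `hpk_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hpk_fit <- function(object, ...) {
  df <- tibble(time_s = object$curve$time_s,
               observed = object$curve$signal,
               fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "firebrick") +
    ggplot2::labs(x = "Time (s)", y = "Signal (a.u.)",
                  title = sprintf("Model %s fit", object$model),
                  subtitle = paste(sprintf("%s = %.4g", names(object$estimates),
                                           object$estimates), collapse = "   ")) +
    ggplot2::theme_minimal()
}

#' Percent mean error of a set of estimates
#'
#' `100 * (mean(estimates) - truth) / truth`, the accuracy metric of the
#' Monte-Carlo studies.
#'
#' @param estimates Numeric vector of fitted values (non-empty).
#' @param truth True parameter value (non-zero).
#' @return Percent mean error (scalar).
#' @export
mean_error_pct <- function(estimates, truth) {
  if (length(estimates) < 1) abort("`estimates` must be non-empty.")
  if (!is.finite(truth) || truth == 0) abort("`truth` must be non-zero.")
  100 * (mean(estimates) - truth) / truth
}

#' Percent coefficient of variation of a set of estimates
#'
#' `100 * sd(estimates) / mean(estimates)` with the sample (n - 1) SD, the
#' reproducibility metric of the Monte-Carlo studies.
#'
#' @param estimates Numeric vector of fitted values (length >= 2, non-zero mean).
#' @return Percent CoV (scalar).
#' @export
coefficient_of_variation_pct <- function(estimates) {
  if (length(estimates) < 2) abort("`estimates` must have at least 2 values.")
  m <- mean(estimates)
  if (m == 0) abort("`estimates` must have non-zero mean.")
  100 * sd(estimates) / m
}
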