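#' Evaluate the vascular input function
#'
#' Concentration of HP urea in blood at time `t` for a gamma-variate VIF:
#' zero before onset, then
#' `amplitude * ((t - t0) / (shape * timescale))^shape * exp(shape - (t - t0) / timescale)`,
#' which peaks at exactly `amplitude` when `t = t0 + shape * timescale`.
#'
#' @param t Time(s), s. Vectorized.
#' @param vif A [vif_params()] object, a function of time, or a two-column
#'   data frame `(time_s, signal)` of a sampled VIF (linearly interpolated,
#'   zero outside its support).
#' @return Concentration(s), arbitrary units.
#' @export
vif_concentration <- function(t, vif) {
  if (!is.numeric(t) || any(!is.finite(t))) abort("`t` must be finite numeric.")
  f <- vif_function(vif)
  f(t)
}

# Normalize any accepted VIF representation to a vectorized function of time.
vif_function <- function(vif) {
  if (inherits(vif, "vif_params")) {
    force(vif)
    function(t) {
      u <- (t - vif$onset) / vif$timescale
      out <- numeric(length(t))
      pos <- u > 0
      out[pos] <- vif$amplitude *
        (u[pos] / vif$shape)^vif$shape * exp(vif$shape - u[pos])
      out
    }
  } else if (is.function(vif)) {
    vif
  } else if (is.data.frame(vif)) {
    if (ncol(vif) < 2) abort("A sampled VIF needs columns (time_s, signal).")
    tt <- vif[[1]]
    yy <- vif[[2]]
    function(t) approx(tt, yy, xout = t, yleft = 0, yright = 0, rule = 1)$y |>
      (\(y) ifelse(is.na(y), 0, y))()
  } else {
    abort("`vif` must be vif_params, a function of time, or a sampled curve.")
  }
}

#' Concentration of HP urea in the extravascular/extracellular space
#'
#' Solves the EES mass balance
#' \deqn{dC_e/dt = (k_{ve}/v_{ee}) C_b(t) - \alpha C_e(t), \quad
#'       \alpha = k_{ve}/v_{ee} + 1/T_1}
#' forward from an initial condition `Ce0` at `t0`:
#' \deqn{C_e(t) = C_{e0} e^{-\alpha (t - t_0)} +
#'       \frac{k_{ve}}{v_{ee}} \int_{t_0}^{t} C_b(\tau) e^{-\alpha (t - \tau)} d\tau.}
#' The convolution integral is evaluated on a fine internal grid (default
#' step 0.01 s) by product quadrature: the VIF is taken piecewise linear
#' between grid points and each segment is integrated exactly against the
#' exponential kernel, so accuracy does not degrade when the washout rate
#' `alpha` is large.
#'
#' @param t Evaluation time(s), s; all must be >= `t0`.
#' @param physio A [physio_params()] object. For Models II/III pass the
#'   model's distribution volume as `v_ee`.
#' @param vif VIF as accepted by [vif_concentration()].
#' @param t0 Start of propagation, s.
#' @param Ce0 EES concentration at `t0`.
#' @param step Quadrature grid step, s.
#' @return EES concentration(s) at `t`.
#' @export
ees_concentration <- function(t, physio, vif, t0 = 0, Ce0 = 0, step = 0.01) {
  stopifnot(inherits(physio, "physio_params"))
  if (!is.numeric(t) || any(!is.finite(t))) abort("`t` must be finite numeric.")
  if (any(t < t0)) abort("`t` must be >= t0.")
  if (physio$v_ee == 0 && physio$k_ve > 0) {
    abort("EES rate undefined: v_ee = 0 with k_ve > 0.")
  }
  a <- alpha_decay(physio)
  rate <- if (physio$k_ve == 0) 0 else physio$k_ve / physio$v_ee
  f <- vif_function(vif)
  vapply(t, function(ti) {
    hom <- Ce0 * exp(-a * (ti - t0))
    if (rate == 0 || ti == t0) return(hom)
    m <- max(2L, as.integer(ceiling((ti - t0) / step)))
    tau <- seq(t0, ti, length.out = m + 1L)
    hom + rate * sum(f(tau) * conv_weights(a, (ti - t0) / m, m))
  }, numeric(1))
}

#' Relaxation-only longitudinal signal of a kinetic model
#'
#' The longitudinal magnetization (up to a proportionality constant) in the
#' absence of RF excitation:
#' * Model I:   `v_b * C_b(t) + v_ee * C_e(t)`
#' * Model II:  `v_ec * C_e(t)` (vascular term neglected)
#' * Model III: `v_b * C_b(t) + (1 - v_b) * C_e(t)`
#'
#' with `C_e` propagated from `(t0, Ce0)` by [ees_concentration()]. For Model
#' II the `v_ee` slot of `physio` is read as `v_ec`; for Model III the
#' distribution volume is `v_ev = 1 - v_b` regardless of `v_ee`.
#'
#' @inheritParams ees_concentration
#' @param model Model id, see [model_id()].
#' @return Longitudinal signal(s), arbitrary units.
#' @export
model_signal <- function(t, model, physio, vif, t0 = 0, Ce0 = 0, step = 0.01) {
  model <- model_id(model)
  stopifnot(inherits(physio, "physio_params"))
  eff <- effective_volumes(model, physio)
  p_eff <- physio_params(k_ve = physio$k_ve, v_b = eff$v_b, v_ee = eff$v_e,
                         T1 = physio$T1)
  ce <- ees_concentration(t, p_eff, vif, t0 = t0, Ce0 = Ce0, step = step)
  cb <- vif_function(vif)(t)
  eff$v_b * cb + eff$v_e * ce
}

# Map a physio_params object to the vascular / distribution volumes a model
# actually uses. Model II: v_b -> 0, v_e = v_ec (stored in v_ee). Model III:
# v_e = 1 - v_b, whatever v_ee holds.
effective_volumes <- function(model, physio) {
  switch(model,
    I   = list(v_b = physio$v_b, v_e = physio$v_ee),
    II  = list(v_b = 0,          v_e = physio$v_ee),
    III = list(v_b = physio$v_b, v_e = 1 - physio$v_b)
  )
}
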