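#' Physiological parameters of one tissue voxel
#'
#' Bundles the physiological state driving HP urea kinetics in a voxel: the
#' trans-capillary transfer rate constant `k_ve` (blood to
#' extravascular/extracellular space, EES), the blood and EES volume fractions
#' `v_b` and `v_ee`, and the longitudinal relaxation time `T1` of the
#' hyperpolarized agent. The cellular fraction `v_c = 1 - v_b - v_ee` is
#' implied (the agent does not enter cells on the imaging timescale) and must
#' be non-negative.
#'
#' Defaults correspond to values measured in preclinical solid-tumor imaging:
#' `k_ve` = 0.02 s^-1, `v_b` = 0.09, `v_ee` = 0.30, `T1` = 20 s.
#'
#' @param k_ve Trans-capillary transfer rate constant, s^-1. Must be >= 0.
#' @param v_b Blood volume fraction in `[0, 1]`.
#' @param v_ee Extravascular/extracellular volume fraction in `[0, 1]`;
#'   `v_b + v_ee` must not exceed 1.
#' @param T1 Longitudinal relaxation time of HP urea, s. Must be > 0.
#'
#' @return An object of class `physio_params`.
#' @seealso [alpha_decay()], [v_c()], [vif_params()], [acq_params()]
#' @examples
#' p <- physio_params()
#' alpha_decay(p)  # k_ve / v_ee + 1 / T1
#' v_c(p)          # implied cellular fraction
#' @export
physio_params <- function(k_ve = 0.02, v_b = 0.09, v_ee = 0.30, T1 = 20) {
  stopifnot(is.numeric(k_ve), is.numeric(v_b), is.numeric(v_ee), is.numeric(T1))
  if (!is.finite(k_ve) || k_ve < 0) abort("`k_ve` must be finite and >= 0.")
  if (!is.finite(v_b) || v_b < 0 || v_b > 1) abort("`v_b` must be in [0, 1].")
  if (!is.finite(v_ee) || v_ee < 0 || v_ee > 1) abort("`v_ee` must be in [0, 1].")
  if (v_b + v_ee > 1 + 1e-12) {
    abort("`v_b + v_ee` must not exceed 1 (the cellular fraction v_c = 1 - v_b - v_ee is negative).")
  }
  if (!is.finite(T1) || T1 <= 0) abort("`T1` must be finite and > 0.")
  structure(
    list(k_ve = k_ve, v_b = v_b, v_ee = v_ee, T1 = T1),
    class = "physio_params"
  )
}

#' Aggregate EES decay rate
#'
#' The rate `alpha = k_ve / v_ee + 1 / T1` at which EES concentration decays
#' through the combination of physiological washout and T1 relaxation.
#'
#' @param p A [physio_params()] object.
#' @return Decay rate in s^-1.
#' @export
alpha_decay <- function(p) {
  stopifnot(inherits(p, "physio_params"))
  if (p$v_ee == 0 && p$k_ve > 0) {
    abort("`alpha` is undefined: v_ee = 0 with k_ve > 0.")
  }
  washout <- if (p$k_ve == 0) 0 else p$k_ve / p$v_ee
  washout + 1 / p$T1
}

#' Implied cellular volume fraction
#'
#' @param p A [physio_params()] object.
#' @return `1 - v_b - v_ee`, the fraction of the voxel inaccessible to the agent.
#' @export
v_c <- function(p) {
  stopifnot(inherits(p, "physio_params"))
  1 - p$v_b - p$v_ee
}

#' @export
print.physio_params <- function(x, ...) {
  cat("<physio_params>\n")
  cat(sprintf("  k_ve: %g s^-1   v_b: %g   v_ee: %g   (v_c: %g)   T1: %g s\n",
              x$k_ve, x$v_b, x$v_ee, v_c(x), x$T1))
  invisible(x)
}

#' Gamma-variate vascular input function parameters
#'
#' The vascular input function (VIF) is the time course of agent concentration
#' in blood, modeled as an amplitude-normalized gamma variate
#' \deqn{C_b(t) = A \left(\frac{t - t_0}{a b}\right)^{a} e^{\,a - (t - t_0)/b}}
#' for `t >= t0` (0 before), with shape `a`, timescale `b` (s) and onset `t0`.
#' The normalization makes the curve peak exactly at `A` when
#' `t = t0 + a * b`.
#'
#' Defaults (shape 2.5, timescale 2.5 s, onset 0, amplitude 1) give a bolus
#' peaking about 6.25 s after onset, plausible for a murine tail-vein
#' injection; all four are exposed so values measured in a specific exam can
#' be substituted.
#'
#' @param amplitude Peak concentration, arbitrary units; >= 0.
#' @param shape Dimensionless gamma-variate shape exponent; > 0.
#' @param timescale Gamma-variate time constant, s; > 0.
#' @param onset Bolus arrival time t0, s.
#'
#' @return An object of class `vif_params`.
#' @examples
#' v <- vif_params()
#' vif_concentration(v$onset + v$shape * v$timescale, v)  # the peak: amplitude
#' @export
vif_params <- function(amplitude = 1, shape = 2.5, timescale = 2.5, onset = 0) {
  stopifnot(is.numeric(amplitude), is.numeric(shape), is.numeric(timescale),
            is.numeric(onset))
  if (!is.finite(amplitude) || amplitude < 0) abort("`amplitude` must be >= 0.")
  if (!is.finite(shape) || shape <= 0) abort("`shape` must be > 0.")
  if (!is.finite(timescale) || timescale <= 0) abort("`timescale` must be > 0.")
  if (!is.finite(onset)) abort("`onset` must be finite.")
  structure(
    list(amplitude = amplitude, shape = shape, timescale = timescale, onset = onset),
    class = "vif_params"
  )
}

#' @export
print.vif_params <- function(x, ...) {
  cat("<vif_params>\n")
  cat(sprintf("  amplitude: %g   shape: %g   timescale: %g s   onset: %g s (peak at %g s)\n",
              x$amplitude, x$shape, x$timescale, x$onset,
              x$onset + x$shape * x$timescale))
  invisible(x)
}

#' Snapshot spoiled-gradient-echo acquisition parameters
#'
#' One full image is acquired per RF excitation of constant flip angle at
#' interval `TR`; residual transverse magnetization is spoiled between
#' excitations. Defaults match a 1-s TR, 20-degree, 60-s dynamic acquisition.
#'
#' @param TR Repetition time between excitations, s; > 0.
#' @param flip Excitation angle, degrees, in `[0, 90]`.
#' @param duration Total acquisition time, s; >= TR. The number of samples is
#'   `floor(duration / TR)`.
#'
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(TR = 1, flip = 20, duration = 60) {
  stopifnot(is.numeric(TR), is.numeric(flip), is.numeric(duration))
  if (!is.finite(TR) || TR <= 0) abort("`TR` must be > 0.")
  if (!is.finite(flip) || flip < 0 || flip > 90) abort("`flip` must be in [0, 90] degrees.")
  if (!is.finite(duration) || duration < TR) abort("`duration` must be >= TR.")
  structure(
    list(TR = TR, flip = flip, duration = duration),
    class = "acq_params"
  )
}

#' @export
print.acq_params <- function(x, ...) {
  cat("<acq_params>\n")
  cat(sprintf("  TR: %g s   flip: %g deg   duration: %g s (%d excitations)\n",
              x$TR, x$flip, x$duration, n_excitations(x)))
  invisible(x)
}

n_excitations <- function(acq) as.integer(floor(acq$duration / acq$TR + 1e-9))

#' Kinetic model identifiers
#'
#' Three nested models describe the HP urea signal in a voxel:
#' * **Model I** (extended-Tofts-like): parameters `k_ve`, `v_b`, `v_ee`;
#'   signal is `v_b * C_b(t) + v_ee * C_e(t)`.
#' * **Model II** (Tofts-like): vascular signal neglected (`v_b = 0`);
#'   parameters `k_ve` and the extracellular fraction `v_ec`.
#' * **Model III**: cellular space neglected (`v_c = 0`), so the extravascular
#'   fraction is `v_ev = 1 - v_b`; parameters `k_ve`, `v_b`.
#'
#' When distribution-volume fractions are compared across models
#' (`v_ee`, `v_ec`, `v_ev`) the generic name `v_e` is used.
#'
#' @param model Model id: `"I"`, `"II"` or `"III"` (numeric 1:3 also accepted).
#' @return The canonical model id string.
#' @export
model_id <- function(model) {
  if (is.numeric(model) && length(model) == 1 && model %in% 1:3) {
    return(c("I", "II", "III")[model])
  }
  model <- as.character(model)
  if (length(model) != 1 || !model %in% c("I", "II", "III")) {
    abort('`model` must be one of "I", "II", "III".')
  }
  model
}

#' Options controlling nonlinear least-squares model fitting
#'
#' @param fit_vif_scale If `TRUE`, a VIF amplitude scaling factor is estimated
#'   jointly with the kinetic parameters (needed when coil sensitivity makes
#'   the measured VIF amplitude unreliable).
#' @param initial_guess Named numeric vector of starting values; any of
#'   `k_ve`, `v_b`, `v_e`, `vif_scale`. Defaults: k_ve 0.05 s^-1, v_b 0.1,
#'   v_e 0.3, vif_scale 1.
#' @param lower,upper Named numeric vectors of box constraints overriding the
#'   defaults (k_ve in `[0, 1]` s^-1, volume fractions in `[0, 1]`, vif_scale
#'   in `[0.01, 100]`).
#' @param max_iterations Maximum optimizer iterations.
#' @param tolerance Convergence tolerance on cost and step (passed to the
#'   Levenberg-Marquardt controls `ftol`/`ptol`).
#'
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(fit_vif_scale = FALSE, initial_guess = NULL,
                        lower = NULL, upper = NULL,
                        max_iterations = 200, tolerance = 1e-10) {
  stopifnot(is.logical(fit_vif_scale), length(fit_vif_scale) == 1)
  if (!is.finite(tolerance) || tolerance <= 0) abort("`tolerance` must be > 0.")
  if (!is.finite(max_iterations) || max_iterations < 1) abort("`max_iterations` must be >= 1.")
  chk_named <- function(x, nm) {
    if (!is.null(x) && (is.null(names(x)) || !all(names(x) %in% c("k_ve", "v_b", "v_e", "vif_scale")))) {
      abort(sprintf("`%s` must be a named vector over k_ve, v_b, v_e, vif_scale.", nm))
    }
  }
  chk_named(initial_guess, "initial_guess")
  chk_named(lower, "lower")
  chk_named(upper, "upper")
  structure(
    list(fit_vif_scale = fit_vif_scale, initial_guess = initial_guess,
         lower = lower, upper = upper,
         max_iterations = as.integer(max_iterations), tolerance = tolerance),
    class = "fit_options"
  )
}
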