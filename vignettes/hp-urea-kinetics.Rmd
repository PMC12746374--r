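---
title: "Kinetic modeling of dynamic hyperpolarized urea MRI: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modeling of dynamic hyperpolarized urea MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpurea)
library(dplyr)
```

## The physical problem

Hyperpolarized (HP) ¹³C urea is an endogenous perfusion agent: after a
bolus injection its MR signal reports where blood delivers the agent and how
readily it crosses the capillary wall. Unlike gadolinium contrast in
DCE-MRI, the HP signal is non-renewable — it decays by T1 relaxation and is
consumed by every RF excitation — so kinetic modeling must describe the
acquisition as much as the physiology.

`hpurea` implements three nested compartmental models of the urea signal in
a tissue voxel, a forward simulator of dynamic snapshot spoiled-gradient-echo
(GRE) sampling, bounded least-squares estimation, Monte-Carlo studies of
acquisition settings, model misspecification and noise, and a voxelwise
pipeline for dynamic image series.

## The three models

A voxel is partitioned into blood ($v_b$), extravascular/extracellular space
(EES, $v_{ee}$) and cells ($v_c = 1 - v_b - v_{ee}$). Urea barely enters
cells on the imaging timescale (urea transporters are scarce outside
erythrocytes), so the cellular compartment carries no agent. The EES
concentration $C_e$ obeys

$$\frac{dC_e}{dt} = \frac{k_{ve}}{v_{ee}} C_b(t) - \alpha C_e(t),
\qquad \alpha = \frac{k_{ve}}{v_{ee}} + \frac{1}{T_1},$$

driven by the vascular input function (VIF) $C_b(t)$; $k_{ve}$ (s⁻¹) is the
trans-capillary transfer rate and $\alpha$ aggregates washout and
relaxation. No hematocrit correction is applied to $v_b$ because
erythrocytes are permeable to urea. The observable longitudinal signal is

* **Model I** (extended-Tofts-like): $M_z \propto v_b C_b + v_{ee} C_e$,
  parameters $k_{ve}, v_b, v_{ee}$;
* **Model II** (Tofts-like): vascular signal neglected,
  $M_z \propto v_{ec} C_e$, parameters $k_{ve}, v_{ec}$;
* **Model III**: cellular space neglected,
  $M_z \propto v_b C_b + (1 - v_b) C_e$, parameters $k_{ve}, v_b$.

Model II is Model I with $v_b = 0$ and Model III is Model I with
$v_{ee} = 1 - v_b$; both identities are verified numerically in the test
suite. When distribution volumes are compared across models the generic
symbol $v_e$ is used.

## Defaults and what they emulate

Defaults mirror preclinical solid-tumor imaging: $k_{ve} = 0.02$ s⁻¹,
$v_b = 0.09$, $v_{ee} = 0.30$, $T_1 = 20$ s; TR 1 s, 20° excitation, 60-s
acquisition. The VIF is an amplitude-normalized gamma variate
$C_b(t) = A\,(u/a)^a e^{a-u}$ with $u = (t - t_0)/b$, which peaks at exactly
$A$ when $t = t_0 + ab$. The shape terms measured in small-animal exams are
not available to us, so we adopt shape $a = 2.5$ and timescale $b = 2.5$ s —
a bolus peaking ≈ 6.25 s after arrival, plausible for a murine tail-vein
injection — and expose all four VIF parameters in `vif_params()` so measured
values can be substituted. Quantities that depend on the exact bolus shape
(for example the small biases of Model I estimates at the default
acquisition point, or the direction of Model III's weak response to the
underlying blood volume) should be read with that uncertainty in mind;
identifiable structure (orderings of reproducibility across models, gauge
invariance of ratios) is robust to it.

Concentrations and signals are in arbitrary units throughout — HP signal is
not absolutely quantified — so only rate constants and ratios of volumes are
physically interpretable.

## Acquisition model

Snapshot spoiled GRE is modeled as a train of instantaneous excitations at
interval TR with constant flip angle $\theta$: each excitation reads
$\sin\theta \,(v_b C_b + v_e C_e)$ and multiplies the *extravascular*
longitudinal magnetization by $\cos\theta$; transverse magnetization is
assumed fully spoiled, and TE decay is not modeled. Blood within the voxel
is taken as fully replaced between excitations, so the vascular term never
carries excitation losses. The first excitation coincides with bolus onset,
where the signal is exactly zero.

Between pulses the EES state is propagated by the closed-form solution of
the mass balance; the simulator therefore consists of a per-interval
convolution integral plus the $\cos\theta$ pulse operator, and is exact up
to quadrature error (below).

```{r simulate}
curve <- simulate_dynamic_signal(physio_params(), acq_params(), vif_params())
head(curve, 3)
```

## Noise model and the reference SNR

Noise is zero-mean additive Gaussian on the simulated signal, applied after
simulation and never propagated through the kinetics; magnitude
rectification is *not* applied. A **reference SNR** pins the noise SD once
per study: `calibrate_noise_sigma(snr)` divides the peak of the
default-settings noise-free curve by the requested SNR, and that same sigma
is reused while acquisition or physiological parameters vary, so
"reference SNR 25" labels a noise level rather than a per-condition SNR. The
sigma actually used is recorded in every study result row.

## Fitting

`fit_model()` minimizes the sum of squared residuals between an observed
curve and the forward simulator with candidate parameters, using
box-constrained Levenberg–Marquardt (`minpack.lm::nls.lm`). $T_1$ and the
acquisition settings are treated as known. Choices that the problem does not
pin down, and our settings:

* **Initial guesses**: $k_{ve} = 0.05$ s⁻¹, $v_b = 0.1$, $v_e = 0.3$,
  VIF scale 1 — inside the simulated ranges, where the fits are locally
  well behaved.
* **Bounds**: $k_{ve} \in [0, 1]$ s⁻¹, volume fractions $\in [0, 1]$,
  VIF scale $\in [0.01, 100]$.
* **Model I feasibility** ($v_b + v_{ee} \le 1$) is enforced by a penalty
  residual, zero inside the feasible region and steeply increasing outside;
  we preferred this to reparameterization because it leaves the reported
  parameters in their natural units and the constraint is inactive at
  physiologic optima.
* **Convergence tolerance** $10^{-10}$ on cost and step, 200 iterations
  maximum. Non-convergence is reported as a flag, never an exception, and
  non-converged fits are retained in Monte-Carlo aggregates (a convergence
  rate is reported alongside).
* The coefficient of variation uses the sample ($n-1$) SD; at 100
  repetitions the distinction from the population SD is below 1%.

### Joint VIF-amplitude fitting and gauge degeneracy

When receive-coil sensitivity varies across the image, a measured VIF is
reliable only up to scale, and the amplitude must be co-estimated
(`fit_options(fit_vif_scale = TRUE)`). This makes every model exactly
scale-degenerate: multiplying the VIF amplitude by $s$ and dividing
$k_{ve}$ and all volume fractions by $s$ leaves the predicted curve
unchanged. Individual parameters are then defined only up to this gauge
orbit, and where a bounded optimizer lands on the orbit is a property of the
optimizer, not of the data. The ratios $k_{ve}/v_e$ and $k_{ve}/v_b$ are
gauge-invariant and remain identifiable; the package recomputes them from
the estimates of every fit, and the voxelwise pipeline reports a
$k_{ve}/v_e$ map for exactly this reason. Consequences worth knowing:

* noise-free "recovery" of individual parameters under joint scale fitting
  is not a meaningful target — only ratios are;
* Monte-Carlo CoVs of individual parameters under joint scale fitting mix
  estimator noise with optimizer behavior along the flat direction, and are
  therefore implementation-sensitive in a way the ratio CoVs are not.

```{r gauge}
acq <- acq_params()
opts <- fit_options(fit_vif_scale = TRUE)
fit <- fit_model(curve, "I", acq, vif_params(amplitude = 2), options = opts)
tidy(fit)  # estimates land on the gauge orbit; kve_ve is invariant
```

## The Monte-Carlo studies

Three study drivers regenerate the package's headline results; data are
always generated from Model I.

* `run_acquisition_sweep()` — Model I refit over a (TR, flip) grid with the
  accurate VIF, noise fixed by the reference SNR at the default settings.
  Accurate, reproducible recovery occurs at moderate flip angles (roughly
  10–40°), widening as TR grows.
* `run_sensitivity_sweep()` — noise-free Model I data with one parameter
  swept ($k_{ve}$ 0.002–0.5 s⁻¹, $v_b$ and $v_{ee}$ 2–50%), fit with Models
  II and III. Model II overestimates and Model III underestimates $k_{ve}$
  throughout, both approaching truth as the true $v_{ee}$ grows.
* `run_noise_study()` — reference SNRs 10–50 (step 5), each model fit with
  an accurate VIF and with joint VIF-scale estimation; 100 noise repetitions
  by default, with each noisy realization shared across models and modes so
  comparisons see identical noise. Aggregates cover every parameter and the
  $k_{ve}/v_e$ ratio.

Determinism: every study derives independent per-condition seeds from one
master seed, so results are exactly reproducible and invariant to iteration
order.

Problem sizes used by the shipped tests and the acceptance script: the
noise study at a single reference SNR of 25 with 100 repetitions (600 fits),
the single default acquisition grid point with 100 repetitions, 8-point
sensitivity grids, and a 16×16 single-slice phantom. These sizes put the
Monte-Carlo error of a CoV estimate near $\text{CoV}/\sqrt{2n} \approx 7\%$
relative, small against the between-model differences under study; the full
15×30 acquisition grid of `run_acquisition_sweep()` remains available for
exploratory use.

## The phantom and the voxelwise pipeline

`generate_phantom()` builds a small dynamic series that stands in for an
in-vivo exam: a designated blood voxel carries the (optionally delayed)
bolus, a tumor region follows Model I under snapshot sampling, the
background holds no agent, a receive-sensitivity map multiplies the stack,
and Gaussian noise is added at a stated tumor peak SNR (13 by default in
examples, matching murine exam conditions). The full ground truth is
returned for testing. Because the noise is additive and unrectified, noisy
phantoms can contain small negative values, unlike true magnitude images —
one of several respects in which passing phantom tests does not certify
behavior on real data (no partial-volume mixing by default, no B1
inhomogeneity, no EPI reconstruction artifacts, a noiseless VIF shape in
the noise-free case).

`voxelwise_fit()` applies `fit_model()` to every masked voxel using a
measured VIF *shape* taken nonparametrically from a chosen voxel
(`extract_vif_timecourse()`, linearly interpolated to the quadrature grid,
zero outside its support — deliberately not refit to a gamma variate), with
the VIF scale always fitted. Unfitted voxels carry `NA`, never zero. Voxel
indices are 1-based throughout, following R convention. `auc_map()`
provides the early-window mean-signal image used for orientation.

```{r phantom}
ph <- generate_phantom(peak_snr = Inf)
vifc <- extract_vif_timecourse(ph$series, ph$truth$vif_voxel)
maps <- voxelwise_fit(ph$series, ph$truth$tumor_mask, vifc, model = "I")
summarise(tidy(maps), kve_ve = mean(kve_ve), converged = all(converged))
```

## Numerical choices

* **Convolution quadrature.** The inter-pulse convolution
  $\int C_b(\tau) e^{-\alpha(t-\tau)} d\tau$ is evaluated on a fine grid
  (step 0.01 s, exposed) by product quadrature: $C_b$ is taken piecewise
  linear between grid points and each segment is integrated exactly against
  the exponential kernel. The error is then set by the linear interpolation
  of $C_b$ alone and does not degrade when $\alpha$ is large (at the sweep
  extremes $\alpha$ exceeds 16 s⁻¹, where a plain trapezoid loses three
  orders of magnitude of accuracy). Against an adaptive ODE oracle the
  relative error stays below $10^{-6}$ across the simulated parameter
  ranges; an independent 1-ms fine-step simulator agrees with the pulse-train
  recursion to better than $10^{-4}$ at every sample.
* **Uniform-TR structure.** Within one acquisition all inter-pulse
  intervals share the same grid offsets, so the convolution for any
  $\alpha$ reduces to a single matrix–vector product over a precomputed
  VIF matrix; this is what makes thousands of Monte-Carlo fits cheap.
* **Degenerate inputs.** $v_{ee} = 0$ with $k_{ve} > 0$ is rejected (the
  transfer rate is undefined); a zero flip angle yields an all-zero curve;
  an all-zero VIF voxel is usable but flagged as not bolus-like; fits to
  curves shorter than the parameter count error out, while any other fitting
  failure returns `converged = FALSE`.

## Known limitations

Confounds deliberately not modeled: errors in assumed $T_1$, flip angle or
VIF timing; B1 inhomogeneity and slice-profile effects; variable-flip
schedules, SSFP/FSE acquisitions; Rician noise floor in magnitude data;
intravascular-restricted (DSC-style) kinetics for tissues with tight
endothelium. Model II should be read as suited to poorly vascularized
tissue and Model III to tissue where the agent fills the extravascular
space; when their simplifying assumptions fail, their $k_{ve}$ estimates
carry the systematic biases quantified by `run_sensitivity_sweep()`.
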