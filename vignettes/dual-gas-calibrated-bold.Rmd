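---
title: "Dual-gas calibrated BOLD: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-gas calibrated BOLD: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoxcal)
```

## The problem

Classical calibrated BOLD converts a task BOLD response and an ASL flow
measurement into a relative change in oxygen metabolism (rCMRO2), but it
needs the venous blood volume response, which it usually obtains from an
assumed power-law coupling between blood volume and blood flow (a Grubb
exponent).  That coupling is poorly characterised in humans, refers to
total rather than venous blood volume, and may vary regionally and in
disease.

`hoxcal` implements the alternative: perform the *same task twice*, once
breathing air and once breathing oxygen-enriched gas at constant end-tidal
CO2 (isocapnic hyperoxia).  Hyperoxia raises venous oxygenation by a
computable amount while (by assumption) leaving flow and metabolism alone.
The two task repetitions then provide enough information to measure the
venous blood volume change directly, so no coupling law is needed.

## Signal model

In the static dephasing regime around randomly oriented vessels, with the
exponent linking relaxation to deoxyhaemoglobin content fixed at 1
(appropriate at high field, e.g. 7 T), tissue transverse relaxation is

    R2* = k V Q + R2,0*,

with `V` the venous blood volume fraction, `Q = 1 - Yv` the venous
deoxyhaemoglobin fraction and `k` a field/haemoglobin constant.  Writing
`Q = Q0 (1 + q_h)` under hyperoxia and adding a task term `q_act`,

    rest:   R2* = k V0 Q0 (1 + q_h) + R2,0*
    active: R2* = k (V0 + dV) Q0 (1 + q_h + q_act) + R2,0*

Plotted against the abscissa `x = 1 + q_h`, the rest and active lines have
slopes `k V0 Q0` and `k (V0 + dV) Q0`.  Converted to percent-signal units
by `100 * TE * slope` these are the calibration parameters `M` and `M'`:
the BOLD signal change that full venous oxygenation would produce, at rest
and during the task.  Then

* `rvCBV = M'/M - 1` (slope ratio; `k`, `Q0` and `B0` all cancel), and
* `q_act = (intercept_act - intercept_rest) / slope_act`, with intercepts
  taken at abscissa zero.

With an ASL measurement of `rCBF`, Fick's principle gives
`1 + rCMRO2 = (1 + q_act)(1 + rCBF)`.

**Why the abscissa is `1 + q_h` and not `q_h`.**  The intercept-difference
identity for `q_act` holds at `x = 0`, i.e. at extrapolated zero venous
deoxyhaemoglobin.  Fitting against `q_h` and differencing intercepts at
`q_h = 0` would add an `(M' - M)`-proportional term to the numerator and
bias `q_act` by `1 - M/M'` (about +0.25 at the default operating point).
This is unit-tested.

## From gas traces to q_h

End-tidal PO2 is taken as arterial PO2 — a stated model assumption, not a
configuration knob; with sequential gas delivery the end-tidal-to-arterial
gradient is negligible for this purpose.  The chain is:

1. `sa_o2()`: Severinghaus-form dissociation curve at 310 K, pH 7.4,
   evaluated in double precision (no lookup tables).
2. `ca_o2()`: arterial O2 content `phi [Hb] SaO2 + epsilon PaO2`
   (defaults `phi = 1.34` ml/g, `[Hb] = 15` g/dl, `epsilon = 0.0031`
   ml/(dl·mm Hg)).
3. `venous_state()`: absolute oxygen extraction fixed at its normoxic
   value, dissolved O2 neglected on the venous side, giving `Yv` and `Q`.

The absolute hyperoxic change `dQ_h` is independent of the assumed resting
extraction fraction; the relative change `q_h = dQ_h / Q0` scales as
`1/Q0`.  Per gas block, PaO2 is the mean end-tidal PO2 over the block's
final 120 s (configurable); the same 2-minute steady-state convention is
used by the phase analysis.  Normoxic blocks get `q_h = 0` by
construction.

A 110 → 440 mm Hg step (the 330 mm Hg transition typical of a 60% O2
challenge) raises venous saturation by 0.068 at OEF 0.4, i.e.
`q_h = -0.17`; these are the package's simulation defaults.

## Preprocessing conventions

* **Baseline** = normoxic timepoints not during, and not within 30 s
  after, any stimulation window.
* **Detrending** is a linear fit to baseline samples only, subtracted
  everywhere with the baseline mean added back; a high-pass filter would
  not respect the long gas cycles.
* **Normalisation** divides by the baseline mean (percent change).
* **Trial averaging**: the active level is the mean over the stimulation
  window excluding its first 6 s (about 2–3 TRs of haemodynamic rise);
  the rest level is the mean over the following OFF period excluding its
  first 6 s of decay, clamped to the trial's gas block.  The margins are
  configurable; the source experiment specifies the windows only as
  "rest" and "active", so the 6 s values are this package's choice.  The
  clamp matters for variant-B hyperoxia trials, whose 60 s OFF period
  crosses the transition out of hyperoxia.
* **CO2 QC**: trials containing any end-tidal PCO2 excursion beyond
  1 mm Hg from the normocapnic reference (the baseline-timepoint mean)
  are discarded; CO2 is vasoactive and would contaminate the fit.
* **ASL**: interleaved tag/control streams are each linearly interpolated
  onto the single-image grid (edges clamped), subtracted, normalised to
  the mean over the last half of all rest periods, and averaged over
  stimulation windows.  Samples within one tag/control pair period of a
  flow transition are excluded, because their interpolation anchors
  straddle the transition; with that margin a noiseless boxcar is
  recovered exactly.

## Paradigms

Variant A (15 min, TR 2.4 s): normoxia–hyperoxia alternation in 3-minute
blocks with a final recovery block; two 30 s ON / 30 s OFF trials sit in
the last two minutes of each of the first four blocks, ending exactly at
the gas transition — 8 trials, 4 per gas level.  Variant B (14 min):
2 min normoxia, then two repeats of 2 min hyperoxia + 4 min normoxia,
with 30 s ON / 60 s OFF trials every 90 s from t = 90 s; alternate trials
coincide with gas transitions and are excluded, leaving 4 usable trials
(2 per gas level).  The reconstruction of variant B's usable-trial
pattern follows from its even trial spacing: trials 1, 3, 5, 7 start or
end at (or within 30 s after) a transition.

## Phase-based oxygen extraction fraction

Estimating `q_h` needs `Q0` (= OEF).  Instead of a literature value, the
hyperoxia:normoxia ratio `a` of extravascular phase along a line profile
across a large vein (sagittal sinus) can be used.  Because the
extravascular field pattern is linear in the intravascular susceptibility
*whatever the vessel geometry*, `a` equals the susceptibility ratio, and
with blood susceptibility linear in `Q` (haematocrit cancels):

    1 - Q0 = (dQ_h (dchi_oxy - dchi_deoxy) / (1 - a) - dchi_deoxy)
             / (dchi_oxy - dchi_deoxy)

The typeset grouping of this relation is ambiguous in print; the
implemented form is derived from the linear blood-susceptibility model and
validated by an exact forward/inverse round trip over
`Q0 ∈ [0.2, 0.6]`, `dQ_h ∈ [-0.12, -0.02]`.  Note `Q0` increases with
`a`: a ratio nearer 1 means a smaller *relative* oxygenation change for
the same absolute `dQ_h`.

Supporting machinery: a homodyne high-pass filter (complex image divided
by its Gaussian-smoothed version, default FWHM 4 mm) removes the smooth
background phase shift that hyperoxic air spaces induce; intravascular
samples are excluded by a magnitude threshold (default: the 98th
percentile of the profile magnitudes, configurable — the source analysis
says only "a high intensity threshold"); temporal unwrapping tracks the
nearest 2π multiple.  Spatial unwrapping is an input requirement.  The
synthetic fixture (`synth_vessel_phase()`) uses the infinite-cylinder
dipole field; the estimator itself never assumes that geometry, which the
geometry-invariance tests exercise directly.

## Handling an error in the assumed Q0

`rvCBV` is exactly invariant to the assumed `Q0` (rescaling `q_h` rescales
both slopes equally).  For `q_act`, refitting with a corrected abscissa
obeys the exact law

    q_act' = c q_act + (c - 1)(1 - M/M'),   c = Q0_assumed / Q0_measured

— linear in the Q0 error, but not purely proportional: there is an
intercept-offset term of order `(c - 1) · rvCBV/(1 + rvCBV)`.  The
conventional table conversion (`rescale_q_act()`) keeps only the
proportional part, which is how published per-subject values are
converted; `run_calibration()` refits instead.  Both behaviours are
unit-tested against the refit oracle.

## The simulator and its realism

`simulate_bold()` produces paradigm-locked ROI timecourses: the forward
relaxation model evaluated per timepoint, mapped to signal with the same
small-signal linearisation the estimator inverts
(`S = S0 (1 - TE dR2*)`), plus optional linear drift and white Gaussian
noise of SD `S0 / tSNR` (magnitude noise in the high-SNR regime; no
Rician floor, no physiological noise harmonics).  An exponential mapping
`S = S0 exp(-TE dR2*)` is available as an option; it is *not* the default
because the estimator's percent-to-dR2* conversion is the linear
approximation, and simulating through the exponential injects a ~3% slope
distortion that shows up as a systematic bias the estimator itself does
not have.  With the linear mapping, drift, and ideal boxcar onsets, the
full pipeline recovers the ground truth to machine precision — the
noiseless recovery tests rely on this.

BOLD onsets are ideal boxcars by default (the estimator averages
plateaus, and steady-state means are insensitive to onset shape); an
optional exponential onset stresses the 6 s window margins.

What passing these tests shows about real data is therefore limited to
estimator correctness and noise propagation: motion, physiological noise,
imperfect gas control, HRF transients and spatial heterogeneity are out
of the simulator's scope.

## Monte Carlo precision

`monte_carlo()` repeats simulate → preprocess → fit with order-independent
counter-derived sub-seeds and reports mean, SD and bias per parameter.
The default configuration reconstructs the group-mean operating point of
the source experiment (`M = 36%`, `M' = 48%`, `q_act = -0.39`,
`q_h = -0.17`, Paradigm A, tSNR 161, 10,000 replicates); the experiment's
own simulation did not state its exact ground truth or noise placement,
so this is a documented reconstruction, not a replication.  At these
settings the estimator spread is about 3.7% (absolute SD) for rvCBV and
1.8% for q_act, with bias below the Monte Carlo resolution, and the
spread scales as 1/tSNR.  The run takes well under a minute; problem
sizes in the test suite (40–150 replicates for property checks, 10,000
for the precision benchmark) were chosen to keep the whole suite around a
minute.

## Susceptibility error budget

Hyperoxia perturbs arterial blood and air spaces as well as venous blood:

* arterial saturation rises by 0.017 (110 → 500 mm Hg), shifting arterial
  susceptibility by −0.0018 × 10⁻⁶ (cgs), using the fully-deoxy minus
  fully-oxy haemoglobin difference of 0.264 × 10⁻⁶ and haematocrit 0.4;
* plasma-dissolved O2 contributes +0.0005 × 10⁻⁶ at normoxia and
  +0.0022 × 10⁻⁶ at hyperoxia (the dl→ml unit bridge in this formula is
  implemented explicitly and unit-tested, because the printed scaling
  factor is ambiguous);
* the venous saturation changes of 0.068 (hyperoxia) and ~0.14 (task)
  correspond to 0.0072 × 10⁻⁶ and ~0.0148 × 10⁻⁶;
* air at 60% O2 is more paramagnetic than air by 0.055 × 10⁻⁶ (the
  commonly quoted value is 0.054; the constants give 0.0546).

`susceptibility_budget()` assembles these; the arterial terms partially
cancel and are small against the venous effect, which is the quantitative
argument that the method's venous reading survives the arterial
confounds.

## Numerical and degenerate-input choices

* Susceptibilities are carried in units of 10⁻⁶ cgs throughout, matching
  tabulated values; pressures in mm Hg; saturations as fractions,
  percent only in human-facing output.
* OLS is unweighted, one point per usable trial per condition; no
  weighting scheme is specified by the source analysis.  Standard errors
  come from the regressions with first-order propagation (rest and
  active fits independent; intercept–slope covariance retained within
  the active fit); the Monte Carlo is the authoritative precision
  estimate.
* Degenerate inputs error early and specifically: a single q_h level
  (rank deficiency), a non-positive rest slope (non-physical calibration),
  venous saturation outside (0,1) (infeasible physiology), a phase ratio
  of 1 (no contrast), all-excluded profiles, empty trial windows, empty
  masks, zero-variance voxels (flagged `NA` in maps).
* Windows are half-open `[start, end)` on 0-based sample times `k · TR`.

## Known limitations

* The method assumes hyperoxia leaves CBF and CMRO2 unchanged
  (isocapnia makes this defensible) and haematocrit constant.
* Arterial-side susceptibility effects and arterial volume changes on
  activation bias M, M' and q_act at the few-percent level (see the
  error budget); no correction is applied.
* The linear relaxation model (exponent 1) is a high-field assumption; at
  1.5–3 T the intravascular contribution and diffusion narrowing break
  it, and this package deliberately does not implement the supra-linear
  variant.
* Phase-based Q0 is sensitive to profile selection and phase quality;
  the synthetic round trip bounds estimator error, not acquisition error.
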