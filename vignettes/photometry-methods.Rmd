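---
title: "Photometry preprocessing, peri-event analysis and simulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photometry preprocessing, peri-event analysis and simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoflux)
```

## The measurement and its artifacts

Fibre photometry records bulk fluorescence from a genetically encoded
sensor (a dopamine sensor such as dLight, or a calcium indicator such as
GCaMP in AgRP hunger neurons) through a chronically implanted optical
fibre. Two excitation wavelengths are interleaved: the 465 nm channel
reports ligand-dependent sensor fluorescence, while the 405 nm channel
excites the sensor at its isosbestic point, where fluorescence is
ligand-independent. The reference therefore carries the nuisance
structure — photobleaching and movement of the fibre or tissue — but not
the neural signal, which is the basis of the correction implemented here.

## Preprocessing model

`preprocess()` applies the stages in a fixed order:

1. **Crop** (`crop_initial()`, default 10 s): the start of the recording
   is dominated by laser power-up transients and is discarded.
2. **Smooth** (`moving_average()`): a centred moving average of the
   protocol's width is applied to *both* channels. At the trace edges the
   window truncates to the available samples, so constant signals are
   preserved exactly and no padding value is invented. Smoothing precedes
   downsampling so that it also acts as a crude anti-alias filter.
3. **Downsample** (`downsample_trace()`): non-overlapping bin means to the
   protocol rate (50 Hz). The rate ratio must be an integer; fractional
   ratios are rejected rather than silently resampled.
4. **Isosbestic fit** (`fit_reference()`): ordinary least squares of the
   signal on the reference over the full post-crop session,
   `signal ~ slope * reference + intercept`. The fit is global by default:
   a session-wide fit uses the whole bleaching trajectory to constrain the
   scaling, and avoids discontinuities at trial boundaries that per-window
   fits introduce. Since the stage functions are exposed individually, a
   per-segment fit can be run by calling `fit_reference()` on any subset,
   but it is deliberately not the default.
5. **dF/F** (`compute_dff()`):
   `dff = (signal - scaled) / (scaled)` with
   `scaled = slope * reference + intercept`. Samples where
   `|scaled| < 1e-6 * median(|scaled|)` are masked invalid rather than
   dropped, and the mask propagates into trial extraction; a division
   guard is needed because the model itself provides none.

Only OLS alignment is performed — no exponential detrending, high-pass
filtering or robust regression. The correction removes exactly the
components that are (affinely) shared with the reference channel.

## Peri-event analysis

Protocols (`load_protocol()`) bundle the analysis parameters. The four
built-ins cover dopamine responses to food-pellet approach
(`dlight_food`: window −30 to +60 s, baseline −30 to −20 s, summaries
0–5 s and 5–10 s, 5-s bins, no smoothing) and AgRP responses to pellets,
injections and slow-acting hormones (`agrp_food`, `agrp_injection`,
`agrp_hormone`; 1-s or 3-s smoothing, longer windows, baselines ending
well before the event so that handling during stimulus administration
cannot contaminate the normalisation). The pellet/injection summary
window +15 to +180 s is attached to both AgRP event protocols, and every
report labels the window it used, so either reading of which paradigm the
window belongs to can be reproduced by selecting the matching rows.
`agrp_injection` is a single preset covering injected stimuli: its window
follows the ghrelin description and its baseline the CCK description,
which are mutually consistent.

Events are mapped to samples by nearest-sample rounding, and windows are
half-open (`[pre, post)`), so every trial has exactly
`round((post - pre) * fs)` samples and a shared time axis. Each trial is
z-scored against the mean and sample SD (n − 1) of **its own** baseline;
trials with a degenerate baseline (SD below 1e-12) are invalidated.
Invalid trials (window outside the recording, masked dF/F samples in the
baseline, degenerate baseline) are dropped with a logged warning and
counted — never silently. Exclusion is per-trial here; excluding whole
animals (e.g. non-responders) is a scientific decision left to the user,
though `analyze_cohort()` does exclude and log animals with *no* valid
trials since they have no defined summary.

Averaging order is fixed: z-score per trial, average trials within an
animal, then compute window means, binned traces and trapezoidal AUC on
the per-animal mean trace, and run group statistics on per-animal values.
Trials are never pooled across animals, so each animal contributes one
observation per window regardless of trial count. Window means use the
half-open sample convention; the AUC uses the closed window so that it is
additive across adjacent windows split at a sample point.

## The simulator

`simulate_recording()` generates the measurement the pipeline assumes:

* event-locked transients `a * k(t - t_i)` with the double-exponential
  kernel `k(t) = exp(-t/tau_decay) - exp(-t/tau_rise)` (peak-normalised,
  support truncated at `5 * tau_decay`). Amplitude sign encodes direction:
  positive for dopamine release, negative for AgRP inhibition on food
  detection. Transients are *multiplicative* on the 465 nm brightness, as
  the sensor reports fractional fluorescence change;
* triple-term bleaching `B(t) = b0 (c1 e^{-t/tau1} + c2 e^{-t/tau2} + c3)`
  per channel, defaults losing roughly 10% over a session;
* a shared motion artifact: white noise low-passed with a 0.5-s moving
  average, re-standardised to unit SD and scaled by `artifact_sd` (so the
  parameter is the realised artifact SD), multiplicatively coupled into
  both channels with coupling `alpha` (default 1 — the same assumption
  under which isosbestic regression removes it);
* additive white channel noise, default 0.5% of each channel's `b0`.

Event gaps are uniform on [60, 180] s by default, emulating pellet
delivery at random 1–3-min intervals that prevents anticipatory
responses. Seeds are plumbed explicitly: a cohort's animals use
`master_seed + animal_index`, so any animal is reproducible in isolation.

What the simulator does **not** model: wavelength crosstalk, hemodynamic
contamination, sensor kinetics beyond the two-exponential kernel,
non-affine motion coupling, or slow drifts uncorrelated between channels.
Passing the validation suite therefore shows the pipeline is correct
under its own model assumptions; it does not certify performance on real
recordings where those assumptions fail (e.g. wavelength-dependent motion
coupling, where `alpha` away from 1 degrades the correction).

## Statistics

Group comparisons use the classical tests attached to this kind of
figure: `unpaired_t()` defaults to the pooled-variance Student form (with
Welch as an option, since variance homogeneity across groups is an
assumption, not a certainty), `paired_t()`, and `rank_sum()` with exact
enumeration for combined n ≤ 12 without ties and a midrank,
tie-corrected normal approximation otherwise — the method used is always
recorded in the result. `two_way_anova()` fits balanced complete
fixed-effects layouts only; unbalanced or repeated-measures designs are
rejected with a pointer to mixed models, which are out of scope.
`fisher_lsd()` performs unadjusted pairwise cell comparisons using the
residual mean square and its degrees of freedom; on a one-factor
two-group design it reduces exactly to the pooled t-test. Scalar
phenotype indices (`homa_ir()`, `odour_preference_index()`,
`percent_kcal_hfd()`, `normalized_latency()`, `ee_lean_corrected()`)
implement the standard formulas; lean-mass correction of energy
expenditure is the ratio form (EE / lean mass). A covariate (ANCOVA)
adjustment is a defensible alternative but changes the estimand; the
ratio is the package's default and the choice is documented here rather
than hidden.

## Numerical choices and problem sizes

* The z-score baseline uses the sample SD (n − 1).
* The dF/F division guard is relative (`1e-6` of the median |scaled|),
  so it is invariant to the units of the photodetector.
* Validation studies in the test-suite and in `scripts/acceptance.R` use
  compact sessions (75-s recordings, 100 Hz, two events per animal) for
  the replicated cohort studies — 500 null cohorts for type-I-error
  calibration and 200 cohorts for power — and longer sessions (260–1000 s,
  200 Hz, five events) for amplitude recovery and artifact suppression.
  These sizes give stable Monte-Carlo estimates (binomial SE of the
  type-I rate at 500 replicates is about 1 percentage point) while
  keeping the full validation run in minutes on one core.
* Amplitude-recovery checks compare the dF/F-scale trial-average peak
  against the closed-form smoothing-attenuated injected peak; z-scale
  values are used only for monotonicity, because the z normalisation is
  noise-referenced and has no fixed relation to the injected dF/F.

## Known limitations

* The isosbestic fit assumes an affine relation between channels over the
  whole session; slow relative drift between the channels' bleach shapes
  leaves a residual that the global fit cannot remove.
* `two_way_anova()` deliberately covers only balanced between-subject
  layouts; body-weight-curve style repeated-measures/mixed models are not
  provided.
* Event times are taken as given; no event detection from video or
  lick/approach sensors is included.
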