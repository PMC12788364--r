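---
title: "Methods: synthetic IMU gait signals and biomechanical loading statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic IMU gait signals and biomechanical loading statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitload)
```

## The measurement model

`gaitload` analyses distance running bouts recorded with three synchronised
tri-axial accelerometers: one at each distal tibia and one at the sacrum,
sampled at 120 Hz in units of g (1 g = 9.80665 m s^-2^). Each foot-ground
impact produces a sharp transient in the acceleration magnitude
$\lVert a \rVert = \sqrt{a_x^2 + a_y^2 + a_z^2}$. From the per-step magnitude
peaks the package derives four bout-level metrics:

* **CAD** — cadence, the frequency of combined left + right impact peaks,
  in steps per minute;
* **PTA** — peak tibial acceleration, the per-step magnitude maximum at a
  shank, averaged over the bout; the bilateral mean is
  $\bar a = \tfrac12 (a_L + a_R)$;
* **LA / aLA** — lateral asymmetry, $LA = (a_L - a_R)\,/\,\bar a$, with
  $aLA = |LA|$ used for group means so opposite-signed individual
  asymmetries cannot cancel; $LA$ is algebraically confined to $(-2, 2)$;
* **RSh** — residual shock, $RSh = a_{Sac}/\bar a$, the fraction of the
  tibial impact peak still visible at the sacrum ($1 - RSh$ is the shock
  attenuation achieved by ankles, knees and hips).

All metrics are computed over the steady portion of a bout, discarding a
15 s initialisation and finalisation margin (configurable, defaulting to
the protocol value).

### Peak detection

The field protocol specifies only "magnitude peak detection", so the
concrete policy is a package design choice. Local maxima of the magnitude
series must exceed an adaptive threshold, median + 4 MAD, which tracks the
noise floor around the 1 g gravity baseline at any noise scale. Retained
peaks must be separated by at least 0.35 s at a tibial site (one stride per
leg, adequate up to ~171 strides min^-1^ per leg) and 0.20 s at the sacrum
(every step, adequate up to 300 steps min^-1^). When two candidates
conflict, the larger magnitude wins and ties go to the earlier sample —
a deterministic, order-independent rule. Whether the original pipeline
averaged per-step peaks or per-stride maxima is not documented; per-step
averaging is implemented here. The results tables' "PTA" is taken to be the
bilateral mean $\bar a$, as implied by the asymmetry and residual-shock
definitions.

The sacral event count is computed as a cadence cross-check; the tibial
union is primary, and a warning is raised when the two deviate by more than
max(2%, one event) — the one-event floor absorbs window-edge quantisation
on short bouts.

## The synthetic-signal generator

No raw recordings are deposited for this protocol, so the package ships a
generator whose programmed ground truth the analysis stage must recover.
The stated world it emulates: a 10-subject cohort, each subject running
3 elevations (50, 1000, 2300 m AMSL) x 3 speeds (v1--v3) x 2 surfaces
(ROAD, TRAIL) = 18 bouts of at least 5 min at 120 Hz.

* **Step timing** is a renewal process at the programmed cadence with
  strictly alternating sides; inter-step intervals carry a configurable
  coefficient of variation (default 3%).
* **Impact shape** is unspecified in the protocol (only peaks are used);
  the generator uses a half-sine envelope with exponential decay over
  0.125 s — the simplest shape with a single controllable peak, short
  enough never to overlap the next step at up to 240 steps min^-1^. The
  waveform is sampled on the acquisition grid and rescaled so its discrete
  maximum equals the programmed amplitude exactly; with all variability at
  zero, every programmed parameter is recovered exactly.
* **Amplitudes**: the per-leg means invert the asymmetry index exactly,
  $a_L = PTA\,(1 + LA/2)$, $a_R = PTA\,(1 - LA/2)$; the sacral mean is
  $RSh \cdot PTA$. Per-step amplitudes vary with a default CV of 5%.
* **Noise** is additive white Gaussian per axis, default SD 0.1 g — small
  against 7--13 g tibial peaks. A 1 g gravity baseline rides on the axial
  channel.
* **Surface**: consistent with the null surface main effects in the
  reference results, TRAIL shifts no means; it increases amplitude CV and
  timing jitter by a relative +50% (configurable).
* **Defaults for unreported quantities** (amplitude CV, timing jitter,
  noise SD, the TRAIL increment) are engineering choices fixed once at
  values a wearable-sensing practitioner would call realistic; they are
  flagged in the configuration surface and never tuned against tests.

### Calibrated cohorts

`default_calibration()` targets the published group distributions: per-speed
marginals for all four metrics (e.g. PTA 7.8 ± 1.6, 10.6 ± 1.8,
12.5 ± 1.6 g; RSh 50.1 ± 8.0, 41.2 ± 7.4, 36.2 ± 7.6%) with additive
per-elevation offsets for cadence (166.8 → 164.6 spm from 50 to 2300 m) and
PTA (10.7/10.2/10.1 g). The cadence marginal at 1000 m is not tabulated
anywhere and is linearly interpolated (165.9 spm). Asymmetry and residual
shock carry no elevation or surface structure, matching their null main
effects. Cell-level interaction structure (the ROAD-only PTA reductions at
altitude) is only fragmentarily quantified in the source text and is left
configurable rather than defaulted.

Subject random effects are drawn from N(0, 1) and then standardised to
sample mean 0 / SD 1, so the programmed cohort marginal means equal the
calibration exactly at any cohort size. This is deliberate: the recovery
criteria compare a 10-subject cohort with ±0.2 g / ±1 pp tolerances, and
i.i.d. subject sampling alone would contribute ~0.5 g of SE — the check
would measure sampling noise, not pipeline fidelity. What a green recovery
test establishes is therefore that signal synthesis, peak detection and the
metric algebra are faithful end to end; it does **not** establish anything
about between-subject sampling variability, real impact waveforms, surface
irregularity, sensor drift, or soft-tissue artefacts, none of which the
generator emulates. Each subject keeps a fixed asymmetry sign across all
conditions (asymmetry as a stable individual trait); absolute asymmetry is
clamped at a 0.2% floor for extreme draws.

## Intensity prescription

Training speeds derive from the ventilatory-threshold speeds:
$v_1 = 0.9\,v_{VT1}$, $v_2 = \tfrac12 (v_{VT1} + v_{VT2})$,
$v_3 = v_{VT2}$. Under acute hypoxia, holding absolute speed constant
raises relative intensity; combining the literature rates (submaximal HR
+5.113% per 1000 m at the 55.00/62.17 reference fraction, maximal HR
−1.01% per 1000 m) multiplicatively gives

$$\bigl(1 + \tfrac{55.00}{62.17} \cdot 0.05113\bigr)\,(1 - 0.0101)
  = 1.0347 \text{ per } 1000\ \mathrm{m},$$

i.e. +3.5% per 1000 m. The speed reductions actually applied at the study
elevations are the protocol's literal values — 0% at 50 m, −3.3% at
1000 m, −7.8% at 2300 m. Note the 2300 m value is neither the linear
(7.59%) nor the compounded (7.24%) extrapolation of 3.3% per 1000 m; it is
an empirically spot-checked choice, so the package uses the lookup at the
three study elevations and the linear rate elsewhere, documented as an
extrapolation.

## Statistics

The analysis stage is a three-way fully within-subject ANOVA (elevation x
speed x surface) with the standard univariate partition: each of the seven
effects is tested against its own effect-by-subject interaction. Per
effect, sphericity is assessed with Mauchly's test on the orthonormal
contrast space (chi-square approximation with the second-order Box
expansion term, matching the canonical implementations to 10 decimal
places), and the Greenhouse–Geisser epsilon
$\varepsilon = \mathrm{tr}(A)^2 / (d\,\mathrm{tr}(A^2))$,
$A = M' S M$, rescales both degrees of freedom. Both the uncorrected and
GG-corrected p values are always reported; the primary `p` column applies
the correction only when Mauchly rejects at 0.05. One numerical caveat
worth knowing: $p_{GG} \ge p$ is guaranteed only where F is non-trivial;
for F well below 1 the inequality genuinely reverses. This is a property of
the F distribution shared by every standard implementation, and the
package's property tests assert the inequality wherever the uncorrected
p ≤ 0.25.

Effect sizes are partial eta squared
$SS_{eff}/(SS_{eff} + SS_{err})$ with Cohen bands 0.01/0.06/0.14, and for
paired post hoc comparisons Cohen's d with bands 0.2/0.5/0.8. The paired-d
variant is not specified in the protocol; the package reports
$d_z = \bar{D}/SD_D$ as primary (the convention coupled to paired-test
power calculations) and the average-variance $d_{av}$ alongside. Post hoc
families are pairwise comparisons within one factor, optionally at fixed
levels of conditioning factors, each family Bonferroni-corrected by its own
comparison count. Slope summaries ("+2.2 spm per km h^-1^") are ordinary
least-squares slopes of condition means against the condition covariate.

A worked small run:

```{r example, eval = FALSE}
cfg <- study_config(n_subjects = 10, seed = 1, duration_s = 300,
                    out_dir = "study_out")
res <- run_study(cfg)
res$marginals$speed_level
res$anova$pta_mean_g
```

## Numerical choices and degenerate inputs

* Bouts must exceed 30 s so the two 15 s margins leave a non-empty window;
  shorter bouts are rejected, as are cohorts of fewer than 2 subjects
  (statistics need 3).
* Programmed peak amplitudes must exceed the 1 g gravity baseline; the
  generator rejects parameter sets (e.g. very low residual shock on a low
  PTA) that cannot be embedded.
* All randomness flows from explicit integer seeds; identical
  configuration and seed give byte-identical CSV artifacts. Per-bout seeds
  are drawn once up front, so any bout can be regenerated in isolation
  from the design table.
* Detection ties (equal magnitudes within the minimum distance) resolve to
  the earlier sample; events are pruned greedily by descending magnitude.
* Two-level within factors are always spherical: epsilon = 1, Mauchly
  W = 1, p = 1 by construction.

## Known limitations

* The generator programs metric values directly per design cell; it does
  not model a biomechanical forward chain (ground-reaction forces,
  joint kinematics), gyroscope channels, or the device-internal 1000 Hz
  strap-down stage — only the analysed 120 Hz stream.
* Calibration encodes marginal structure only; published interaction
  fragments (ROAD-only PTA reductions of −5.4/−10.4/−11.9% at altitude)
  are not defaulted because their baselines are unspecified.
* The a-priori sample-size computation quoted for the original protocol
  (d = 0.92 from a 5 bpm difference, SD 8, r = 0.75) does not follow from
  the standard paired-d formula (≈0.88) and is deliberately not
  reproduced.
* Reported elevation slopes in the source abstract (−1.1 spm, −0.6 g per
  1000 m) are not exactly consistent with its printed per-elevation means
  (−1.0 spm, −0.27 g per 1000 m over 2250 m); the package's
  `condition_slopes()` always recomputes slopes from the means it is
  given, so its outputs follow the means.
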