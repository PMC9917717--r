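---
title: "Methods: wavelet coherence analysis of dyadic fNIRS hyperscanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet coherence analysis of dyadic fNIRS hyperscanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypercoh)
```

## The analysis problem

Hyperscanning records two interacting people simultaneously and asks
whether their brain signals synchronize, where, at which time scales, and
in response to which behaviors. `hypercoh` implements a complete analysis
chain for dyadic continuous-wave fNIRS (10 Hz, 20 channels per
participant by convention):

1. **Preprocessing** — modified Beer–Lambert conversion of dual-wavelength
   optical density into oxy-/deoxy-Hb, hemodynamic modality separation
   (HDMS) of cortical from systemic blood signals, and AR(50)
   pre-whitening.
2. **Coherence** — Morlet wavelet transform coherence (WTC) between every
   channel pair of the dyad on a 91-band, 1/10-octave grid
   (0.0072–3.68 Hz), cone-of-influence (COI) masked, averaged per band.
3. **Group statistics** — paired two-tailed t contrasts of the
   cooperative (COOP) versus individual (IND) condition per
   channel-channel-frequency (ch-ch-fr) cell, corrected with Storey's
   pFDR q-values.
4. **Behavior** — face-up events classified from head-pose pitch traces
   (z-score > 2 SD), combined into mutually exclusive dyad states
   (both-up / self-up / other-up).
5. **Event GLM** — gamma/log-link GLMs linking the coherence time course
   of candidate cells to the behavioral regressors, with a group-level
   both-up vs either-up paired contrast under Bonferroni correction.

A synthetic-data generator produces full experiments with controllable,
event-locked inter-brain coupling so that every stage — and the chain as
a whole — is testable without recordings.

## Preprocessing model

**Beer–Lambert.** Optical-density changes at 695 and 830 nm are inverted
per sample through the 2×2 extinction system
$\Delta OD(\lambda) = \left[\varepsilon_{HbO}(\lambda)\,\Delta HbO +
\varepsilon_{HbR}(\lambda)\,\Delta HbR\right] d \cdot DPF(\lambda)$.
With the default $DPF = 1$ the outputs are the relative mM·mm units
conventional for continuous-wave topography; the extinction matrix is
configurable and validated for conditioning (κ < 10⁶).

**HDMS.** Oxy/deoxy series are decomposed as $oxy = F + S$,
$deoxy = k_F F + k_S S$, where the functional (cortical) component has
negatively proportional chromophores ($k_F < 0$) and the systemic
component positively proportional ones ($k_S > 0$). The defaults
$k_F = -0.6$, $k_S = +0.5$ carry the required sign structure and are
fully configurable; the decomposition is an exact per-sample linear
solve, so constructed mixtures are recovered to machine precision. Only
the functional components feed coherence analysis.

**Pre-whitening.** Each channel is fitted with an AR(50) model
(Yule–Walker / Levinson–Durbin, via `stats::ar`) — 5 s of history at
10 Hz — and replaced by its one-step prediction residuals. Fits are per
channel and independent; all channels of a session are then left-trimmed
by the common 50 samples so cross-channel alignment is preserved. Serial
correlation (and with it, slow motion artifacts shared by the dyad) is
removed; WTC is invariant to per-series linear filtering up to smoothing
effects, so genuine narrow-band coupling survives.

## Wavelet coherence

The frequency grid places bands at $f_k = f_{min} 2^{k/10}$. The span
0.0072–3.68 Hz is 89.98 steps; the grid is built with half-step
tolerance (nearest-step rounding), giving exactly 91 bands with the last
band at 3.6864 Hz. The Morlet mother wavelet uses wavenumber
$\omega_0 = 6$; frequency converts to scale through the Fourier factor
$s = (\omega_0 + \sqrt{2 + \omega_0^2})/(4\pi f)$.

The CWT is FFT-based with zero padding to the next power of two; the
padding always lies outside the COI, which is set at the standard
$\sqrt{2}s$ e-folding distance from each record edge. Coherence follows
the smoothed-cross-spectrum formulation

$$R_k^2(t) = \frac{|S(s^{-1} W_{xy})|^2}{S(s^{-1}|W_x|^2)\; S(s^{-1}|W_y|^2)}$$

with the standard smoothing operator: a Gaussian in time with SD equal
to the scale, then a boxcar across scales spanning 0.6 scale
decorrelation lengths (5 bands on the 1/10-octave grid). Values are
clipped to [0, 1]; self-coherence is 1 inside the COI to 10⁻⁶. Band
means are computed over in-COI samples only; a fully masked band is
missing, never zero, and missing cells are excluded — not imputed — from
group statistics.

For a 20-channel montage the between-brain family contains 20 identical
pairs $(i,i)$ plus 190 unordered different pairs $\{i,j\}$ (210 total,
hence 210 × 91 = 19,110 cells); the within-brain family holds the 190
different pairs (17,290 cells). For a different pair, both orientations
$(A_i,B_j)$ and $(A_j,B_i)$ are computed and their coherence matrices
averaged by default — the merging rule for unordered pairs is not fixed
by convention, so `keep_both` is also available. Within-brain maps are
computed per participant and averaged within the dyad, keeping the dyad
as the statistical unit.

Two numerical notes. First, the Morlet bandwidth at $\omega_0 = 6$ is
roughly $f/6$ per SD (≈ 2.2 bands) and the scale boxcar spans 5 bands,
so an injected narrow-band signal elevates coherence over roughly ±7
bands; the *peak* localizes to within 1–2 grid steps of the injected
frequency, which is what the tests assert. Second, the chance level of
band-mean coherence is far from zero (≈ 0.32 for independent noise at
these smoothing widths) and rises at low frequencies in short records as
the COI erodes the averaging support; inferences therefore always rest
on condition contrasts or event regressors, never on raw coherence
magnitude.

## Group statistics

Per cell, dyad-level band means are contrasted COOP vs IND with a
two-tailed t-test. The test is paired by default: every dyad contributes
both conditions, making the paired design the natural choice; an
unpaired Welch variant is available by flag. A dyad missing either
condition is dropped from that cell only, and cells with fewer than 3
complete dyads are flagged untested rather than propagating NaN.

Storey's procedure estimates the null proportion
$\hat\pi_0 = \#\{p > \lambda\}/(m(1-\lambda))$ at the fixed default
$\lambda = 0.5$ (the smoothing-spline λ-tuning variant is deliberately
not used; λ is configurable), clips it to (0, 1], and computes
$q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$. Between- and
within-brain families are corrected separately, mirroring their separate
reporting. The implementation agrees with a brute-force evaluation of
the estimator definition to 10⁻¹².

Because adjacent bands are strongly correlated, one band represents each
channel pair: the band with the smallest p-value (ties to the lower band
index), optionally within a frequency window. GLM candidates are the
cells with p < 0.001 in the COOP > IND direction inside 0.03–0.1 Hz,
reduced to one representative band per pair.

## Behavioral events

Pitch traces (radians, OpenFace convention, 29.97 Hz) are z-scored per
participant per session over valid samples — session scope absorbs
session-level posture drift, and z-scoring removes between-participant
differences in absolute face height. A sample is face-up when z exceeds
2 SD in the face-raising direction (sign configurable for the camera
geometry). On pure Gaussian noise this classifies the upper ≈ 2.28% tail.
Tracking gaps of at most 0.5 s are linearly interpolated; longer gaps
are invalid and excluded from the moments and from detection.

Dyad labels are mutually exclusive by construction: both-up = A∧B,
self-up(A) = A∧¬B (which is other-up from B's side), and symmetric for
B. Before labeling, each track is cleaned with two morphology rules
chosen to suppress single-frame tracker jitter: gaps shorter than 0.2 s
are bridged, then runs shorter than 0.3 s dropped. Both default rules
can be set to 0 to disable (no such rules are fixed by convention).

The design matrix resamples the three boxcar regressors to the 10 Hz
coherence rate by nearest-sample selection — interpolation would break
their binary nature — plus a constant column. The delay-of-peak of the
hemodynamic response is handled in exactly one place: regressors are
shifted forward by 5 s relative to the coherence series (a regressor at
time t reads the behavioral track at t − 5 s), and out-of-range samples
are dropped from both sides.

## Event-related GLM

For each candidate cell and dyad, the coherence time course of the COOP
session (in-COI samples at the representative band) is regressed on the
design with a gamma error distribution and log link, fitted by IRLS
(`stats::glm.fit`). Coherence is strictly positive after clipping
non-positive samples at 10⁻⁶ (counted and reported); values are left
untransformed otherwise since gamma support is $(0, \infty)$. All-zero
regressors (a dyad without events of some type) get an NA coefficient
and the dyad is excluded pairwise downstream. Dispersion is estimated by
Pearson χ²/df, but only the β point estimates feed group statistics.
Because the unordered-pair coherence map is the orientation average, the
two orientation-specific designs are column permutations of one another,
so a single fit per cell suffices and
$\beta_{either} = \tfrac12(\beta_{self} + \beta_{other})$ — self-up of
one participant is other-up of the partner, so the two coefficients
describe the same dyadic state. Group inference is a paired two-tailed
t-test of $\beta_{both} - \beta_{either}$ per candidate at
α = 0.05/(number of candidates).

Event-locked averaging (`event_locked_wtc`) extracts fixed windows of
the coherence course around event onsets and averages them, with the
grand-mean coherence across channel combinations as the conventional
baseline; truncated windows are excluded and counted.

## The synthetic-data generator

`simulate_dyad` emulates the statistical structure the analysis assumes,
not neurovascular physiology:

- **Background**: per channel, spectrally shaped 1/f noise (exponent 1)
  plus a white floor (SD 0.5) — the canonical spectral profile of
  hemodynamic recordings.
- **Component structure**: functional parts have deoxy = −0.6 × oxy; a
  shared per-participant systemic component (amplitude 0.5) with
  deoxy = +0.5 × oxy is added to all channels, so HDMS is exercised with
  the exact sign structure it assumes.
- **Coupling**: listed channel pairs share a drifting-phase sinusoid
  (phase random walk, 0.02 rad/sample) added to both participants,
  gated by the lock mode — always, only during both-up, or only during
  either-up epochs — with 1 s raised-cosine ramps. The gate lags the
  behavioral epochs by a 5 s response delay, emulating the
  delay-of-peak the analysis corrects for.
- **Events**: dyad-level events arrive at 1/min with 3 ± 1 s durations
  (truncated at 0.5 s); 30% are both-up, the rest split between the
  participants. This puts each participant's face-up coverage in the
  few-percent range, matching the strict 2 SD classification on real
  traces (≈ 2.3% of samples).
- **Pose**: unit-variance Gaussian pitch noise with +5 SD excursions
  exactly during that participant's up epochs. Note that z-scoring
  inflates the denominator when excursions occupy a noticeable fraction
  of the trace, so detection recovery is bounded away from 100%
  (≈ 98% at default coverage).
- **Design**: `simulate_experiment` gives each dyad two COOP and two
  IND sessions — the crossed within-dyad design of turn-based
  hyperscanning experiments. Band means are averaged across
  same-condition sessions before the condition contrast, and the event
  GLM pools the coherence samples of all COOP sessions of a dyad.

What passing tests show — and what they do not: the generator produces
stationary Gaussian backgrounds, rectangular events, and perfectly
narrow-band coupling. Real recordings add motion artifacts, optode
drift, heartbeat/respiration lines, non-stationary behavior, and
anatomical variation; results on synthetic data validate the
*estimators*, not the field performance of the pipeline.

## Problem sizes used in the test suite

Unit and property tests run on compact series (1,500–10,000 samples)
and reduced grids. The end-to-end recovery experiment keeps the
experiment design of interest — 20 dyads, two COOP and two IND
10-minute sessions each, coupling at 0.09 Hz on one identical channel
pair only during either-up epochs, amplitude 3 — while using 3 channels per participant and the 29-band
1/10-octave sub-grid spanning the 0.03–0.1 Hz candidate window, with 8
recovery replicates (success bar ≥ 80%) and 5 null replicates (no
coupling; the expected median of Bonferroni-significant discoveries is
0). These sizes are the package's chosen balance between statistical
resolution and a test suite that runs everywhere in minutes.

## Known limitations

- No per-dyad WTC significance testing against AR(1) surrogates, no
  phase-of-coherence analysis, and no cluster-based correction.
- The orientation-averaging rule for unordered pairs and the
  mean-combination of self/other coefficients are defensible defaults,
  not identities; both have alternatives (`keep_both`, pooled
  regressors) that were deliberately not defaulted.
- Gamma GLM residual diagnostics are summarized (deviance, dispersion)
  but not acted on automatically; non-converged fits are excluded from
  group statistics.
- SNIRF support covers processed HbO/HbR blocks and raw CW intensities
  with wavelength indices; vendor-proprietary layouts are rejected
  explicitly.
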