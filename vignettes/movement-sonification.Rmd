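---
title: "Movement-quality features, sound models and mixed-model analysis"
author: "moveson"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-quality features, sound models and mixed-model analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moveson)
```

## What this package models

`moveson` implements the computational chain of an interactive-sonification
study of bodily movement: children move freely in a tracked room, their head
position drives a sound-synthesis engine in real time, and the question is
whether the character of the sound (smooth and wind-like versus choppy and
clicking) feeds back into the character of the movement. The package covers
the offline analysis side of that chain:

1. **Trajectory handling** — reading, validating and gap-handling 2D head
   trajectories sampled at a nominal 180 fps in a 4.66 × 5.40 m area, with
   room-centered coordinates in meters.
2. **Quality control** — trimming each 36–37 s observation to its 25 s
   middle (6 s lead and tail removed), screening for marker crossover,
   under-tracking and out-of-area movement, and min–max normalising pooled
   feature tables to [0, 1].
3. **Movement-quality indices** — Energy, Smoothness and Directness.
4. **Sound models** — offline renderings of three filtered-noise models
   with velocity-driven mappings and 8-channel ring spatialization.
5. **Synthetic data** — trajectory styles and cohort-structured feature
   tables with known ground truth, standing in for the study's undeposited
   recordings.
6. **Statistics** — random-intercept linear mixed models with
   likelihood-ratio tests, Tukey-family contrasts and marginal/conditional
   pseudo-R².

## The movement-quality indices

With $x(f), y(f)$ the head position at frame $f$ and dots denoting time
derivatives, the per-frame speed is $v = \sqrt{\dot x^2 + \dot y^2}$ and the
three indices are:

* **Energy Index**: $EI(f) = \tfrac{1}{2} v^2(f)$ — the kinetic energy of
  the tracked point with unit mass and a single tracked joint.
* **Smoothness Index**: the Pearson correlation
  $\rho(\log k, \log v)$ over short windows (30 ms by default), where
  $k = (\dot x \ddot y - \dot y \ddot x) / (\dot x^2 + \dot y^2)^{3/2}$
  is the signed planar curvature. Smooth, lawful movement couples speed to
  curvature (the two-thirds power law $v \propto k^{-1/3}$), making
  $\log k$ and $\log v$ nearly collinear within a window; jerky movement
  breaks that coupling. A simplified variant
  $1/(\sigma_{\log k}\,\sigma_{\log v})$ is also provided: it replaces the
  covariance by unity, which makes it positive, unbounded and
  unit-dependent. The Pearson form is the default precisely because the
  simplified form's scale is not comparable across datasets; both are
  exposed so either convention can be reproduced.
* **Directness Index**: chord length between the first and last points of
  an excerpt divided by the summed segment lengths, in $[0, 1]$ by the
  triangle inequality; 1 for rectilinear monotone movement.

### Numerical choices

Derivatives are central finite differences computed after a zero-phase
moving average (default 5 frames at 180 fps, ≈28 ms). Curvature involves
second derivatives of noisy 180 fps data; without smoothing the estimate is
noise-dominated on real recordings. The smoothing width is a reported
configuration knob, and the first/last few samples of any series carry
one-sided-difference edge effects — analyses here always evaluate interior
samples.

Curvature and $\log v$ degenerate at rest, so samples with
$v \le v_\mathrm{floor}$ (default $10^{-3}$ m/s) are masked. Windows need at
least 3 valid samples and nonzero variance of both logs; windows failing
that yield missing values rather than errors, and per-observation summaries
average over the valid windows only. Since curvature is signed, the
correlation uses $\log |k|$. Window hop equals window length
(non-overlapping), as only the window length is a meaningful parameter of
the definition.

The Directness Index is computed once per 25 s excerpt — the excerpt is the
movement unit of the analysis.

## The sound models

All three models filter seeded white noise through a time-varying two-pole
section whose center frequency and Q track normalized speed linearly across
the declared ranges (S1: 50–1100 Hz, Q 1.8–4.0, resonant; S2: 100–900 Hz,
Q 0.1–0.3, resonant; S3: 100–3000 Hz, Q 0.01–0.6, band-pass). The
"resonant" realization is the constant-peak-gain band-pass biquad, the
"band-pass" realization the constant-skirt-gain form, both in the standard
audio-cookbook parameterization with per-sample coefficient interpolation
(control rate 100 Hz by default; any rate above ~50 Hz is perceptually
equivalent).

Amplitude behaviour distinguishes the models. S1 and S2 multiply by a
band-limited random envelope — uniform [0, 1] targets drawn at 3 Hz (S1) or
18 Hz (S2) with linear interpolation between targets. S3 multiplies by
convex ramps of 250 ms launched at intervals interpolated linearly from
800 ms at rest down to 50 ms at full speed; each trigger restarts the ramp
and the envelope is zero once a ramp completes, which produces the model's
choppy, clicking character. Whether the interval shortens or lengthens with
speed is a configuration flag (`trigger_decreasing`), shortening by
default. The ramp shape is a single-parameter exponential approach
(curvature 4), a conventional slow-start percussive envelope; only the ramp
length is externally constrained.

Speed is normalized by `v_ref` (default 2 m/s, fast child locomotion) and
mapped to gain logarithmically: the level $20\log_{10} v_\mathrm{norm}$ is
mapped affinely from $[-60, 0]$ dB onto $[0, 1]$, with gain exactly zero at
rest — a trajectory with zero speed renders exact digital silence in every
model. The exact scaling constants of the original live system are not
recoverable; the floor is a documented default.

Spatialization places the source on a ring of 8 loudspeakers by
constant-power pairwise panning between the two speakers adjacent to the
azimuth; the distance-from-center control blends the gain vector toward the
uniform distribution $1/\sqrt 8$, and gains are renormalized so the summed
squared gain is 1 at every sample. Output is written as 16- or 24-bit PCM
WAV with a JSON sidecar recording the seed and mapping constants.

## The synthetic-data generator

No recordings from the original study are deposited, so the generator
defines the study conditions under which every stage is exercised:
trajectories confined to the 4.66 × 5.40 m area at 180 fps, 36 s
observations, and a three-level cohort (observations within participants
within groups).

Two stochastic styles encode the qualitative contrast the analysis is meant
to detect. The **smooth** style integrates an Ornstein–Uhlenbeck velocity
process with a 10 s relaxation time, low-passed over 0.4 s: sweeping,
continuously curving paths. The **jerky** style draws piecewise-constant
headings with abrupt turns at 3 per second — half of them near-reversals,
the back-and-forth shuffling typical of stop-start movement — and full
stops (speed exactly 0) at 0.25 per second, so the silence-at-rest property
of the sound chain is exercised end to end. Both are reflected specularly
at the walls and rescaled so the empirical mean speed equals `mean_speed`
(default 0.35 m/s: the time-averaged head speed of a young child moving
freely, including stops, is well below adult walking speed). Analytic
styles (straight, circle, square) provide closed-form oracles.

A deliberate limitation: over a 25 s excerpt in a room this small, any
path longer than the ~7 m diagonal is folded by the walls, so the
Directness Index of *any* style is confinement-dominated and noisy at that
scale. Style comparisons in the test suite therefore use 8 s movement
units, where the smooth style is near-ballistic and directness is
identifiable. What passing style-separation tests show is that the feature
pipeline ranks genuinely smoother/more direct synthetic movement above
jerkier movement — not that real children moved that way; the generator
does not model play dynamics, interpersonal entrainment or group
interaction.

The cohort generator draws
$y = \beta_0 + \beta_{\mathrm{model}} + \beta_s(\mathrm{session}-1) +
\beta_o(\mathrm{obs}-1) + u_{\mathrm{group}} + u_{\mathrm{participant}} +
\varepsilon$ with SDs 0.054 (group), 0.052 (participant) and 0.168
(residual) — the scale of normalized movement features in such cohorts —
and default fixed effects placing S3 0.06 below S1 = S2 with small negative
session (−0.043) and observation-number (−0.009) slopes. Ground truth
(including the drawn intercepts) is attached to the table.

## The mixed-model analysis

For each feature the package fits
`value ~ sound_model + session + observation_number + (1 | group_id) +
(1 | participant_id)` by REML (reported coefficients) or ML
(likelihood-ratio tests — REML likelihoods are not comparable across fixed
effects). Participants are coded nested by unique labels. Sound model uses
treatment contrasts with S1 as reference; session is a two-level factor;
observation number a numeric covariate. Fitting is delegated to `lme4`;
the module owns model construction and reporting. Single-level grouping
factors are dropped with their variance reported at the boundary 0 and an
explanatory message, and singular fits are flagged rather than hidden.

Likelihood-ratio tests report the true degrees of freedom of the factor
being dropped (2 for a three-level sound-model factor). Pairwise contrasts
use the studentized-range (Tukey) family via `multcomp::glht`.
Marginal and conditional pseudo-R² use the variance-partition formulation
for Gaussian random-intercept models:
$R^2_m = \mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) +
\sigma^2_g + \sigma^2_p + \sigma^2_e)$, with the conditional version adding
the random-intercept variances to the numerator.

## Problem sizes used in validation

The test suite validates parameter recovery on cohorts of 30 groups × 4
participants × 12 observations per sound model (4320 rows), checks the
contrast sign over 100 simulated cohorts at that size, estimates the
likelihood-ratio type-I error from 500 null cohorts at a reduced size of 6
groups × 3 participants × 6 observations (large enough for the chi-square
approximation to be calibrated), and evaluates style separation over 100
seeded smooth/jerky pairs of 8 s each. Audio contracts are checked on 2–6 s
renders at 16 kHz; the renderer itself defaults to 44.1 kHz.

## Known limitations

* The Smoothness Index windows contain only ~5 samples at 180 fps and
  30 ms; the correlation is therefore a local collinearity measure, and
  its sampling distribution under unstructured motion has substantial
  spread (mean |ρ| ≈ 0.44 for 5 iid samples). Longer windows trade
  temporal resolution for stability.
* The simplified smoothness variant is dimensional: rescaling units
  rescales the index. It is provided for fidelity, not recommended.
* Marker-crossover screening uses a speed-threshold proxy (default
  10 m/s); it cannot recover the manual judgement used on real data, and
  no attempt is made to re-identify swapped markers.
* The sound renderings are offline reconstructions of the documented
  behaviour of the original live patch objects, not sample-exact
  emulations of them.
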