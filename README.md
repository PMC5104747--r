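# moveson

Movement-quality analysis and interactive-sonification rendering for 2D
motion-capture trajectories.

## The problem

In interactive sonification of bodily movement, a person's motion drives a
sound-synthesis engine in real time, and one wants to know whether the
character of the sound feeds back into the character of the movement.
Answering that requires a full computational chain: quality-controlled
head trajectories, movement-quality features, reproducible renderings of
the sound models, and a hierarchical statistical analysis of
feature-by-sound-model effects. `moveson` implements that chain for 2D
head trajectories captured at a nominal 180 fps in a 4.66 × 5.40 m tracked
area, and ships a synthetic-data generator so every stage is testable with
known ground truth.

## What it computes

**Movement-quality indices** per 25 s observation excerpt, with speed
$v=\sqrt{\dot x^2+\dot y^2}$ and signed planar curvature
$k = (\dot x\ddot y - \dot y\ddot x)/(\dot x^2+\dot y^2)^{3/2}$:

* Energy Index $EI = \tfrac12 v^2$ (kinetic energy, unit mass);
* Smoothness Index $SI = \rho(\log k, \log v)$ over 30 ms windows — the
  curvature–velocity coupling of smooth movement (two-thirds power law
  $v \propto k^{-1/3}$) drives $|SI|$ toward 1;
* Directness Index $DI = \text{chord} / \text{path length} \in [0,1]$.

**Sound models** S1–S3: seeded white noise through a time-varying two-pole
filter whose center frequency and Q track normalized speed (S1 50–1100 Hz
/ Q 1.8–4.0 resonant, S2 100–900 Hz / 0.1–0.3 resonant, S3 100–3000 Hz /
0.01–0.6 band-pass), amplitude-modulated by random envelopes (3 Hz / 18 Hz)
or velocity-triggered 250 ms ramps (every 50–800 ms), gained
logarithmically from speed so rest is exact silence, and spatialized on an
8-speaker ring with constant-power panning. Output is plain PCM WAV.

**Statistics**: random-intercept linear mixed models
`feature ~ sound_model + session + observation_number + (1|group) +
(1|participant)` with ML likelihood-ratio tests, Tukey-family pairwise
contrasts, and marginal/conditional pseudo-R².

## Worked example

```r
library(moveson)

## one synthetic observation per style, features per excerpt
smooth <- gen_trajectory("smooth", duration = 37, seed = 1)
jerky  <- gen_trajectory("jerky",  duration = 37, seed = 1)
rbind(
  summarize_features(trim_observation(smooth)),
  summarize_features(trim_observation(jerky))
)
#>      EI_mean    SI_mean SI_absmean n_windows        DI
#> 1 0.05746545 -0.1289423  0.8058833       833 0.3021901
#> 2 0.08792767 -0.1450300  0.4236797       598 0.1421231

## sonify the smooth observation with model S1
ctrl  <- control_from_trajectory(smooth)
mono  <- render_model(ctrl, sound_model_params("S1"), sr = 44100, seed = 1)
ring  <- spatialize(mono, ctrl)
write_audio(ring, "smooth_S1.wav", metadata_path = "smooth_S1.json")

## simulate a cohort and fit the mixed model
coh <- gen_cohort(n_groups = 3, n_participants_per_group = 4, seed = 1)
fit <- fit_feature_lmm(coh)
pairwise_contrasts(fit)
#>      pair    estimate         se   p_adjusted
#> 1 S2 - S1 -0.02848085 0.01936599 3.050969e-01
#> 2 S3 - S1 -0.09375874 0.01936599 3.901059e-06
#> 3 S3 - S2 -0.06527789 0.01936599 2.236005e-03
pseudo_r2(fit)
#> $marginal
#> [1] 0.09893903
#> $conditional
#> [1] 0.2578417
```

The smooth style scores a higher smoothness magnitude (|SI| 0.81 vs 0.42)
and higher directness (0.30 vs 0.14) than the jerky style, and the fitted
cohort recovers the generated sound-model contrast (S3 below S1 and S2,
here −0.065 ± 0.019 for S3 − S2) with the share of variance explained by
fixed effects (marginal R² ≈ 0.10) well below that explained once
participant and group intercepts are added (conditional R² ≈ 0.26).

## Package layout

* `R/trajectory.R`, `R/preprocess.R` — trajectory I/O, manifests, gap
  handling, trimming, exclusion rules, normalization
* `R/kinematics.R`, `R/features.R` — derivatives, speed, curvature, and
  the three indices
* `R/sonification.R`, `R/audio_io.R`, `src/biquad.cpp` — sound models,
  ring spatialization, WAV I/O
* `R/synthetic.R` — trajectory styles and cohort simulation
* `R/statistics.R` — mixed models, LR tests, contrasts, pseudo-R²
* `vignettes/movement-sonification.Rmd` — the methods vignette
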