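---
title: "Monitoring task compliance in perimetry: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring task compliance in perimetry: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complimetry)
```

This vignette is the package's account of its science: what each method
assumes, which tunable parameters matter and why their defaults are what
they are, what the synthetic generator does and does not emulate, and where
the design was genuinely open.

## 1. The measurement problem

A static threshold perimetry test estimates differential light sensitivity
(DLS) at 24 locations (the central ±15° × ±9° of the 24-2 grid) by an
adaptive staircase of stimulus presentations, summarised as mean
sensitivity (MS), the arithmetic mean of the 24 dB values. Decibels here
are attenuation relative to a maximum-luminance stimulus,
`dB = 10·log10(3183.1 / DLS[cd/m²])`: higher dB means a dimmer stimulus was
still seen. The test is long and attention-demanding, so a patient's
lapses contaminate both individual responses and the final scores. The
package quantifies that contamination from webcam-derived facial features,
at two granularities: the absolute MS difference between two same-eye
tests, and misses on individual trials whose stimulus was more than 3 dB
brighter than the location's threshold estimate.

## 2. Biomarkers

Per-frame features are read from the CSV output of a facial-analysis
pipeline (detection confidence and success flag, gaze angles, head pose,
FACS action-unit intensities). Frames failing the success flag or
a confidence floor (default 0.75, configurable in `read_frame_table()`)
are marked invalid and excluded *before* any distance or mean is formed.
The upstream tool stores gaze angles and pose rotations in radians while
all analysis here is in degrees, so the reader converts both by default
(`angles_in_radians = TRUE`); the flag exists for tables already in
degrees.

The three movement biomarkers are Sn dispersions of the valid frames'
feature vectors: gaze ⟨x, y⟩ in degrees, head location ⟨x, y, z⟩ in mm,
head rotation ⟨yaw, pitch, roll⟩ in degrees. Sn — the median over points of
the median Euclidean distance to the other points — was chosen over
variance-type spread measures because webcam tracking produces occasional
gross outliers and non-Gaussian scatter; Sn tolerates up to half the frames
being junk. Numerical conventions, fixed because the statistic's value
depends on them: the finite-sample factor `c_n` is 1; medians of even
counts are the mean of the two central order statistics; the inner median
for point *i* runs over its n − 1 distances. The implementation is the
direct O(n²) distance-matrix form — exact, and fast enough for the ~1200
frames of a 4-minute session.

Expression biomarkers are mean per-frame sums of AU intensities (sadness:
AU4 + AU15; surprise: AU1 + AU2 + AU25 + AU26; blink: AU45), in the
upstream tool's arbitrary intensity units with 0 meaning absence. Whether
blinks should be counted by graded intensity or binary presence is not
decidable from intensity semantics alone; intensity is the default, and
`presence = TRUE` switches every AU biomarker to presence coding. Mean
response latency averages onset-to-press times over responded trials only
— a missed trial has no latency, and imputing one would conflate the two
error channels.

### The composite

The composite is `Σ ωᵢ·z(Xᵢ)` with `ωᵢ = ρᵢ/Σρⱼ`, where ρᵢ is the Pearson
correlation between biomarker *i* and the error measure across the
analysis cohort. This is deliberately crude — a guard against overfitting
cohorts of a few dozen eyes, not an optimal combiner. Choices a user
should know about:

* z-scores are standardised against the analysis cohort itself (sample SD,
  n − 1), not an external norm; for twice-tested eyes the two sessions'
  biomarkers are mean-averaged *before* standardisation.
* Negative ρᵢ are kept with their sign, implementing the weight formula
  literally. If Σρⱼ ≤ 0 the weights are undefined and the fit errors
  rather than silently taking absolute values.
* The composite is invariant to positive affine rescaling of any input
  column (the z-scoring absorbs units). Under a *negative* scale factor
  the column's ρ flips sign and changes the normaliser Σρⱼ, so literal
  invariance cannot hold; this is a property of the printed weight rule,
  not of the implementation.

## 3. Test-by-test association

`testretest_association()` uses ordinary Pearson correlation per biomarker
and for the composite. The display line is a geometric-mean (reduced major
axis) regression — slope `sign(r)·SD(error)/SD(biomarker)` through the
means — because both axes are noisy measurements and an OLS slope would
depend on the arbitrary choice of regressor. Outlier handling is manual
and logged: `exclude` drops named rows and records them in the result;
there is no automatic rule, because a single flagged point in a small
cohort is a judgement call that should stay visible.

## 4. Trial-by-trial lapse analysis

A trial is "visible" when `threshold_dB − stimulus_dB > 3` strictly, the
threshold being the session's own final estimate at that location. The
3 dB margin is a doubling of stimulus intensity, far above the ~1 dB
spread of a healthy frequency-of-seeing curve, so a miss there is treated
as a lapse. The margin is a parameter; boundary trials at exactly 3 dB are
excluded. Caveat inherited from the design: threshold estimates are
themselves noisy, and severely damaged locations can have much shallower
frequency-of-seeing slopes, so the visible set is indicative, not
guaranteed — misclassified trials dilute, rather than inflate, the
reported associations.

Windowed biomarkers use each trial's frames plus the 20 frames (4 s at
5 Hz) before onset — the information available in real time. The window
length is a parameter, the default being an order-of-magnitude choice
rather than an optimised value. A window ends at onset + latency for
responded trials and onset + 1.5 s otherwise. Latency is excluded from the
trial-level analysis by construction.

`fit_lapse_model()` fits hit/miss on the *raw* biomarker by binomial
logistic regression (IRLS via `glm`, tolerance 1e-8, max 100 iterations)
and reports the 1-df deviance χ² against the intercept-only model.
Complete separation is flagged and no p-value reported. The binned summary
(four log-spaced bins over the positive biomarker range, geometric-mean
midpoints) exists for display only; Wilson 95% intervals are used because
they behave sensibly at hit rates near 1, where these data live.
Non-positive biomarker values — possible only for degenerate inputs — go to
the first bin and are logged. Analyses pool all eyes without a clustering
adjustment; with ~100+ visible trials per session the per-session
contribution to any one bin is small, but p-values should be read as
descriptive, not exact.

## 5. Compliance-weighted ZEST

ZEST keeps a posterior over a discrete threshold domain (default 0–40 dB
in 0.5 dB steps, uniform prior; a custom prior can be supplied) and
updates it each trial with the likelihood of the observed response under a
cumulative-Gaussian frequency-of-seeing model
`p(seen) = γ + (1−γ−λ)·Φ((T−s)/σ)` (defaults σ = 1 dB, γ = λ = 0.03).
The compliance extension raises trial *i*'s likelihood term to a weight
αᵢ ∈ [0, 1]; equivalently, αᵢ multiplies the log-likelihood, which is how
the implementation computes it. All accumulation is in log space, so long
tracks cannot underflow; α = 0 short-circuits and leaves the posterior
bit-identical, and α = 1 is bit-identical to the same code with the
weighting removed. Stimulus placement defaults to the posterior mean
snapped to the domain (classic ZEST); a minimum-expected-entropy rule is
available. Stopping supports a trial cap, a posterior-SD target and an
entropy target, with a `did_not_complete` flag when the cap is hit before
the accuracy target — the principled alternative to accepting a
non-compliant participant's spurious threshold.

The map from a raw compliance estimate θ (e.g. a composite z-score) to α
is not dictated by the weighting idea; any monotone map into [0, 1] is
admissible. The package default is a decreasing logistic
`α = 1/(1 + exp(k(θ − θ0)))` with k = 1.5, θ0 = 1: a trial one SD worse
than the cohort mean gets half weight, typical trials near-full weight.
The prior, placement and stopping defaults are conventional choices, not a
claim about any particular instrument's settings.

## 6. The synthetic generator

`generate_session()` emulates exactly the structure the analyses assume —
no more. A two-state Markov chain (attentive/lapsed) at the frame level,
parameterised by stationary lapsed occupancy and mean lapse dwell (default
0.15 and 10 frames), drives: per-axis Gaussian jitter around fixed
baselines for gaze/head channels (lapsed state scales the SDs, default
×3); truncated-Gaussian AU intensities with state-dependent means;
state-dependent response latencies; and suppression of responses on
visible trials with probability `lapse_inflation` (default 0.3) while
lapsed. A per-subject trait shifts lapsed occupancy on the log-odds scale
(`coupling`, default 1), so one latent quantity produces both larger
biomarkers and more measurement error — the coupling the analyses are
meant to recover. Thresholds are estimated by actually running the ZEST
engine on the generated responses (mode `"zest"`), so MS error emerges
mechanistically from lapses rather than being injected; a `"shortcut"`
mode (truth + Gaussian noise scaled by `exp(coupling·trait)`) exists for
fast unit tests.

Default session geometry: 5 Hz for 240 s (~1200 frames), 24 locations × 6
presentations = 144 trials — a realistic 4-minute screen-perimetry
assessment. With the default observer (λ = 0.03) and lapse process, the
expected visible-trial miss rate lands near 4–5%.

What the generator does *not* emulate, and therefore what passing tests do
not show about real data: temporally structured head drift or saccade
dynamics (frames are conditionally independent given the state); realistic
AU intensity distributions or inter-AU correlation; fatigue trends within
a session; asymmetric or eccentricity-dependent threshold noise; and any
particular instrument's trial sequencing. Tests against the generator
validate the *estimators and the pipeline plumbing*, not the clinical
effect sizes.

## 7. Numerical and testing choices

* Medians: `stats::median` convention throughout (mean of central pair for
  even counts).
* ZEST posteriors renormalise after every update; batch and sequential
  updates agree to 1e-9, and hit/miss order at a stimulus commutes.
* Degenerate inputs error loudly rather than return defaults: fewer than 2
  points for Sn (NA biomarker), fewer than 3 sessions for the composite,
  zero-variance columns, Σρ ≤ 0, responded trials without latency, grids
  without all 24 locations.
* Reproducibility: every generator call takes an explicit seed;
  `generate_cohort()` derives per-session seeds as
  `seed + 1009·subject + session`, and identical seeds give bit-identical
  sessions.
* Problem sizes in the shipped tests and acceptance script — 40-subject
  cohorts, 200 paired ZEST replicates, 500 null replicates at n = 2000,
  100-seed convergence sweeps, 1000-instance Sn oracle checks — were
  chosen as the smallest sizes at which the corresponding properties are
  stable, keeping the whole suite to a few minutes on one CPU.

## 8. Known limitations

The package analyses features a face-analysis tool has already extracted;
it does not do vision. Biomarker units are those of the upstream tool and
are not calibrated across tools. The composite's weights are fitted on the
same cohort whose association is then reported — the study design this
mirrors accepts that circularity in exchange for simplicity at small n,
and the package reports exactly what that procedure produces. Trial-level
pooling ignores within-eye clustering. And the weighted-ZEST benefit shown
in simulation assumes α is informative about true lapses; with an
uninformative α the weighting only discards information (the paired
simulation in `pipeline_zest_demo()` makes that trade-off measurable).
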