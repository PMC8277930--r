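---
title: "Quantifying movement synchrony in psychotherapy dyads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying movement synchrony in psychotherapy dyads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dyadsync` implements a complete pipeline for quantifying nonverbal
movement synchrony between two interacting people — here framed as a
patient and a therapist filmed by separate stationary cameras — and for
relating that synchrony to therapy outcome. This vignette explains the
models and procedures, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the methodology left choices open.

## 1. Motion energy analysis

Movement is quantified from video without any tracking: for each pair of
consecutive grayscale frames, `motion_energy()` counts the pixels inside a
fixed region of interest (ROI) whose absolute grey-level difference
*strictly* exceeds a threshold (default 12 grey levels on the 0–255
scale, a conservative setting that suppresses sensor flicker). A
recording of $n$ frames yields $n-1$ energy samples at the frame rate.
Counting changed pixels (rather than summing difference magnitudes)
follows the established motion-energy convention; a
sum-of-absolute-differences variant is available via
`mea_config(method = "sad")`.

The preprocessing chain, in fixed order
(`mea_preprocess()`):

1. **ROI-size standardization** — values are scaled by
   `scale / roi_area` (default scale 100, i.e. percent of ROI pixels
   active), so differently sized regions are comparable. Area scaling is
   used; a range normalization could be substituted upstream if desired.
2. **Despiking** — values at or above 10 SD of the raw series (the SD is
   computed once on the input, not recursively — the simplest reading of
   an "exclude ≥ 10 SD" rule) are treated as video errors and replaced by
   the last retained value (a leading spike becomes 0).
3. **Control-ROI filtering** — a control region where no genuine movement
   can occur flags frames with global artifacts (brightness flicker,
   compression glitches); wherever its standardized energy reaches 5, the
   person's value is replaced by carry-forward. The threshold is
   interpreted on the ROI-standardized scale and is configurable because
   its units are convention-dependent.
4. **Smoothing** — a zero-phase (forward–backward) Butterworth low-pass,
   default order 2 with 2 Hz cutoff: slow enough to suppress frame-rate
   flicker, fast enough to preserve gross body movement. The exact
   parameters are a design choice, surfaced in `mea_config()`. Odd
   reflection padding suppresses the start/end transients of the
   two-pass filter; negative filter output is clipped to zero.
5. **Resampling** — block averaging to 10 samples/s, so that the 0.1 s
   lag step of the cross-correlation grid equals exactly one sample.

Every stage appends itself and its parameters to the series' provenance
list, which is serialized next to the data.

## 2. Windowed lagged cross-correlation synchrony

Synchrony is measured by `windowed_ccf()`: the two partners' preprocessed
series are split into non-overlapping 1-minute windows (a trailing
partial window is dropped), and within each window the Pearson
correlation is computed between the patient segment and the therapist
segment shifted by every lag in a symmetric grid — by default ±5 s in
0.1 s steps, i.e. 50 strictly positive lags, 50 strictly negative lags
and lag zero (101 columns). Lags are applied *within* the window: a lag
of $\ell$ samples correlates the $n-|\ell|$ overlapping samples, with no
borrowing across window boundaries — windows stay independent. Positive
lags mean the therapist's signal is taken later than the patient's.
Zero-variance segments yield missing cells rather than arbitrary values.

`grand_average()` collapses the windows × lags matrix to one session
score: the mean of $|\mathrm{atanh}(r)|$ over all valid cells. The
Fisher z-transform linearizes the correlation scale before averaging and
the absolute value counts leading and following equally; both follow the
convention of the movement-synchrony literature this methodology comes
from, and both are toggleable flags recorded on the result (lag 0 is
included by default and can be excluded). Correlations at exactly ±1
(possible only in degenerate synthetic cases) are clamped just inside
the open interval before `atanh`. The index is reported in Fisher-z
units without back-transformation; all comparisons in the pipeline are
internally consistent. Per dyad, `dyad_trait()` takes the median of the
session scores (midpoint of the central order statistics for even
counts) as a robust trait-synchrony summary.

The windows × lags computation is implemented in a small C++ kernel
(two-pass centered sums); `windowed_ccf_naive()` is a pure-R triple-loop
reference used in the tests, where both implementations must agree to
1e-12.

## 3. Pseudo-synchrony: the chance level

Some apparent synchrony arises by coincidence. The chance level is
estimated by *pseudo-interactions* (`shuffle_pairs()`): patient streams
re-paired with therapist streams from **different dyads** — people who
never interacted — with unequal lengths truncated to the shorter stream
from the start. Same-dyad pairings are excluded even across sessions
because they retain dyad-specific interaction style; a relaxed
`"cross_session"` scheme exists for sensitivity analyses. Pairings are
drawn uniformly with replacement so any requested null size (the study
convention is 500) is available regardless of dyad count, and a random
offset is deliberately not applied in truncation (start-aligned
truncation keeps the surrogate maximally comparable).

`null_test()` compares genuine and pseudo synchrony indices with a Welch
two-sample t-test (unequal variances, Welch–Satterthwaite df) and
reports Cohen's *d* on the pooled SD. `pseudo_standardize()` then
expresses every genuine session index in SD units of the null:
$z = (\text{index} - \bar{x}_{\text{pseudo}}) / s_{\text{pseudo}}$. This
pseudo-standardized score is the response variable of the outcome model;
standardization happens here, once, and not again inside the model
stage.

## 4. The outcome model

`fit_sync_model()` fits a Gaussian linear mixed model by REML with the
pseudo-standardized session synchrony as response, a random intercept
per dyad, and fixed effects for: outcome change in personality
functioning (LoPF-Q total, follow-up minus baseline), outcome change in
psychosocial functioning (CGAS), the patient/therapist average
post-session goodness rating (SEQ, 7-point), session number, mid-therapy
alliance (WAI-SR, entered as a dyad-constant predictor), and the two
baseline severities as controls. Synchrony is the response — not a
predictor — so the hypothesized correlates and confounders can be tested
jointly while sharing variance.

`stepwise_eliminate()` reduces the model backward in the conventional
order: the random intercept first, by a REML likelihood-ratio test
against the fixed-effects-only linear model ($\chi^2_1$, α = 0.05), then
fixed effects one at a time, removing the term with the largest
Satterthwaite-type p-value while it exceeds α. The intercept is always
retained and the full elimination trace is returned. The procedure is
authored in the package and cross-checked in the test suite against the
reference implementation in `lmerTest`.

Reporting (`model_report()`) includes: standardized coefficients
$\beta_j \cdot s_{x_j} / s_y$ with identically scaled standard errors
(the intercept is standardized as the prediction at predictor means
relative to the response mean); the variance components $\sigma^2$ and
$\tau_{00}$; the intraclass correlation
$\mathrm{ICC} = \tau_{00}/(\tau_{00}+\sigma^2)$; the
variance-decomposition coefficients of determination
$R^2_m = \sigma^2_f/(\sigma^2_f+\tau_{00}+\sigma^2)$ and
$R^2_c = (\sigma^2_f+\tau_{00})/(\sigma^2_f+\tau_{00}+\sigma^2)$, where
$\sigma^2_f$ is the variance of the fixed-effect predictions; the
deviance (−2 ML log-likelihood); and Benjamini–Hochberg adjusted
p-values. The BH family covers only the hypothesis-bearing predictors
(the outcome-change and goodness terms); confounders report raw p, as
is conventional when they are not hypothesis tests. Singular
random-effect fits are flagged, not silently dropped.

## 5. The synthetic-data generator

No clinical recordings ship with the package; everything is validated on
synthetic data with planted ground truth, emitted alongside the data so
tests never re-derive it.

**Movement level** (`gen_movement()`). Each partner's own movement is a
rectified AR(1) process (default coefficient 0.8 at 10 Hz) driven by
Gaussian innovations plus Poisson-timed exponential bursts (default 6
events/min, mean amplitude 4), giving nonnegative, bursty,
autocorrelated traces of the kind frame differencing produces. Coupling
is lagged linear mixing confined to "on" epochs: inside an epoch partner
B is $(1-c)\cdot\text{own} + c\cdot A(t-\text{lag})$; epochs alternate as
a two-state Markov chain with 60 s mean on-duration and a stationary
on-fraction parameter — reflecting the observation that real interaction
alternates between synchronous and non-synchronous modes rather than
holding continuous synchrony. The marginal movement model is a stand-in:
no distributional summaries of real motion-energy traces were available
to calibrate against, so it aims at qualitative realism (burstiness,
autocorrelation, nonnegativity), not quantitative match.

**Frame level** (`gen_frame_stack()`). A filled square blob on a uniform
background moves horizontally by `round(movement[t])` pixels per frame,
bouncing off the frame edges; pixel intensities are chosen so every
moved pixel clears the detection threshold by a wide margin. Moving a
$d \times d$ blob by $dx \le d$ pixels changes exactly $2 d \, dx$
pixels, so motion-energy output can be checked against an analytic
truth, frame by frame. Optional salt noise, redrawn each frame with
amplitude at or below the pixel threshold, perturbs no count. Human
silhouettes, camera noise models and compression artifacts are out of
scope.

**Study level** (`gen_study()`). Defaults emulate a small
completed-therapy sample: 16 dyads × 22 sessions (352 sessions, the
order of magnitude of a ~356-session study), a dyad synchrony trait with
between-dyad SD 0.99 against within-dyad SD 0.84 — by construction the
between-dyad SD must strictly exceed the within-dyad SD, which puts the
model-scale ICC near 0.5 — a mild downward session trend (−0.02 per
session, centered mid-therapy), an outcome slope of −28 LoPF points per
synchrony unit with residual SD 41 (yielding a session-level
synchrony/outcome correlation near −0.43), and a goodness slope of
−0.07 points per synchrony unit (correlation near −0.1). CGAS change,
baselines and alliance carry no planted synchrony effect. Sessions per
dyad below 13 (half of a planned 25) violate the inclusion floor and
must be requested explicitly (`min_sessions`), which small pipeline
demonstrations do. SEQ ratings are generated as continuous values
clipped to [1, 7] — a deliberate simplification of the integer Likert
scale that avoids planting discretization attenuation into recovery
tests.

`run_pipeline()` connects the levels: each session's planted synchrony
is mapped to a movement-coupling weight by a clamped linear map
(`coupling_from_sync()`, 0.18 coupling units per synchrony unit around
the trait mean). The map is pipeline plumbing, not a calibrated
quantity; end-to-end runs therefore recover the planted *ordering* of
dyads but attenuate variance components relative to the table-level
analysis, since three-minute demonstrations estimate each session index
from only three windows.

## 6. Numerical choices and degenerate inputs

- Strict inequality at the pixel threshold: a difference of exactly 12
  does not count. Documented and tested as a boundary case.
- Despiking of a zero-variance series is the identity; a spike at the
  first sample becomes 0 (there is no earlier value to carry).
- A control series entirely at/above threshold produces an all-zero
  output (the carried leading zero) rather than an error.
- Resampling with a non-integer rate ratio uses the nearest integer
  block and records the achieved rate; the trailing partial block is
  dropped.
- Correlation cells from zero-variance window segments are missing and
  excluded from grand averages; a session with no valid cells yields a
  missing index with a warning.
- `|r| ≥ 1` is clamped to `1 - 1e-12` before `atanh`.
- Welch comparison of two zero-variance groups is an error, as is
  pseudo-standardization with a null SD of 0.
- Median tie-break: midpoint of the central order statistics.
- All generators are deterministic under a supplied seed, restore the
  caller's RNG state, and produce independent output under distinct
  seeds.

## 7. Problem sizes in the tests and acceptance script

Simulation-based checks run at deliberately reduced scale: 3-minute
sessions at 10 samples/s (three 1-minute windows), mini-studies of 8
genuine sessions over 4 dyads against 16 surrogate pairings for
calibration curves (400 replicates for the type-I rate, 200 per coupling
level for power curves), and 16 × 22 table-level studies for
mixed-model recovery (100 replicates). These sizes estimate the same
operating characteristics as larger runs with proportionally wider
Monte-Carlo error; the full-scale settings (60-minute sessions, a
500-pair null) remain the package defaults where a single run is
involved.

## 8. Known limitations

- A dyad-constant predictor in the outcome model is effectively tested
  on dyad-level degrees of freedom (~14 with 16 dyads). With a
  session-level standardized beta of 0.4, that yields moderate
  (~55–65%) retention under backward elimination — a property of the
  design's information content, not of the implementation; tests that
  demand near-certain retention at this effect size will fail for any
  correct implementation at n = 16 dyads.
- Passing recovery tests on synthetic data shows the estimators are
  consistent with their own generative assumptions (linear lagged
  coupling, Gaussian mixed model); it cannot certify behaviour under
  real-world violations such as nonstationary camera noise, occlusion,
  or non-linear coordination.
- The synchrony measure is linear and movement-based; symbolic or
  vocal coordination, peak-based "synchronization intervals" and
  leading/pacing decompositions are out of scope.
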