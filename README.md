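# dyadsync

Movement synchrony — the temporal coordination of two interacting
people's body movement — is a robust nonverbal correlate of how
psychotherapy goes: more synchronous patient–therapist dyads tend to
show better outcomes. Measuring it from routine session video requires
a chain of steps, each with small but consequential conventions:
quantifying movement from video, scoring coordination per session,
separating genuine coordination from coincidence, and relating the
per-session scores to outcome without ignoring that sessions are nested
in dyads. `dyadsync` implements that chain as a tested R package for
psychotherapy process researchers and, more generally, for anyone
analyzing coordination between two simultaneously recorded movement
signals.

The pipeline:

1. **Motion energy analysis (MEA).** For each consecutive frame pair,
   movement is the count of pixels in a fixed region of interest (ROI)
   whose grey-level change strictly exceeds a threshold (default 12).
   Preprocessing: ROI-size standardization, despiking at 10 SD with
   last-observation-carried-forward, artifact replacement wherever a
   control ROI (a region that should never move) shows energy ≥ 5,
   zero-phase Butterworth smoothing (order 2, 2 Hz), and block-average
   resampling to 10 samples/s.
2. **Windowed lagged cross-correlation.** Within non-overlapping 1-min
   windows, Pearson correlations between the partners' series at every
   lag ℓ ∈ {−5, −4.9, …, 4.9, 5} s (50 steps of 0.1 s in each
   direction plus lag 0). The session's synchrony index is the grand
   average of |atanh r| over all windows × lags; the dyad's trait
   synchrony is the median of its session indices.
3. **Pseudo-synchrony null.** Chance-level synchrony is estimated from
   surrogate "interactions" that pair each patient stream with a
   therapist stream from a *different* dyad (default n = 500). Genuine
   vs pseudo indices are compared by a Welch two-sample t-test with
   Cohen's *d*; genuine indices are then *pseudo-standardized*:
   z = (index − mean_pseudo) / sd_pseudo.
4. **Outcome model.** A Gaussian mixed model with the
   pseudo-standardized session synchrony as response, a random
   intercept per dyad, and fixed effects for outcome change
   (personality functioning LoPF-Q and psychosocial functioning CGAS),
   post-session goodness ratings (SEQ), session number, mid-therapy
   alliance (WAI-SR) and baseline severities; backward elimination
   (random effect by likelihood ratio, fixed effects by Satterthwaite
   t), standardized betas, ICC = τ₀₀/(τ₀₀+σ²), marginal/conditional R²,
   and Benjamini–Hochberg adjustment for the hypothesis-bearing terms.

No clinical videos ship with the package. A first-class synthetic-data
module generates every input with planted ground truth: bursty
autocorrelated movement series with lagged, epoch-wise coupling;
grayscale frame stacks whose changed-pixel counts are analytically
known; and full study tables (16 dyads × 22 sessions by default) in
which synchrony is a dyad trait linked to outcome. All statistical
properties of the pipeline are validated against that ground truth.

## Worked example

Twelve 5-minute sessions from four simulated dyads at moderate planted
coupling, scored and tested against their own shuffle null:

```r
library(dyadsync)

sessions <- lapply(1:12, function(i)
  gen_movement(
    movement_sim_spec(n_samples = 3000, rate = 10, coupling = 0.5,
                      lag_s = 0.5, seed = 100 + i),
    dyad_id = (i - 1) %/% 3 + 1, session_id = i))

sync <- session_sync_table(sessions)
head(sync, 3)
#>  dyad_id session_id       sync n_windows n_valid
#>        1          1 0.07596957         5     505
#>        1          2 0.06794833         5     505
#>        1          3 0.09617550         5     505

surr   <- shuffle_pairs(sessions, n = 100, seed = 999)
pseudo <- session_sync_table(surr$pairs)
nt <- null_test(sync$sync, pseudo$sync)
nt
#> <null_comparison> genuine 0.0812 vs pseudo 0.0639: t(12.1) = 5.195,
#>   p = 0.0002194, Cohen's d = 2.266

z <- pseudo_standardize(sync$sync, pseudo = nt)
round(tapply(z, sync$dyad_id, dyad_trait), 2)
#>    1    2    3    4
#> 1.70 2.15 2.16 4.18
```

Each `sync` value is the mean absolute Fisher-z cross-correlation over
5 windows × 101 lags (505 cells); ~0.06 is what chance produces for
600-sample windows, so the genuine mean of 0.081 against the pseudo
mean of 0.064 is a large, significant excess (*d* = 2.27 at this
planted coupling). After pseudo-standardization, every dyad sits 1.7 to
4.2 null-SDs above chance — the coordination is real, and its level is
a stable property of the dyad.

The complete analysis — study simulation, MEA validation, synchrony and
null, the outcome mixed model, and calibration curves — lives in the
numbered scripts under `analysis/` (run them in order from the
repository root; outputs go to `results/`):

```sh
Rscript analysis/01_simulate.R      # study tables, manifest, example recording
Rscript analysis/02_mea.R           # frame differencing vs analytic truth
Rscript analysis/03_synchrony_null.R
Rscript analysis/04_outcome_model.R # Table-style mixed-model report
Rscript analysis/05_calibration.R   # type-I, power curve, effect recovery
```

`analysis/04_outcome_model.R`, for example, reduces the full model to
the planted-active terms and prints a report of the form

```
<sync_model_reduction> kept: lopf_change, session_no; random intercept kept
sigma^2 = 0.69  tau00 = 0.57  ICC = 0.46
Marginal R2 / Conditional R2 = 0.212 / 0.571
```

meaning: with LoPF outcome change and session number retained, dyad
identity still accounts for ~46% of residual synchrony variance, and
fixed plus random effects together explain ~57% of the total.

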