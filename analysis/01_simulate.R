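#!/usr/bin/env Rscript
# Simulate the synthetic study: dyad-level outcome tables, session-level
# evaluation tables with planted per-session synchrony, a recording
# manifest with exclusions, and one example dyadic movement recording
# rendered both as time series and as a grayscale frame stack.
#
# Writes: results/data/

suppressMessages(library(dyadsync))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260

## Study tables: 16 dyads x 22 sessions, synchrony a dyad trait
spec <- study_sim_spec(seed = seed)
study <- gen_study(spec)
write_study_tables(study, out)
cat(sprintf("study: %d dyads, %d sessions -> %s/{sessions,dyads}.csv\n",
            nrow(study$dyads), nrow(study$sessions), out))

## Recording manifest with planted exclusions, and the data accounting
manifest <- simulate_manifest(study, n_withdrawn = 14, n_failed = 11,
                              seed = seed + 1)
write_manifest(manifest, file.path(out, "manifest.csv"))
acc <- account_sessions(manifest)
cat(sprintf("accounting: %d administered - %d withdrawn - %d failed = %d analyzable\n",
            acc$administered,
            acc$by_status[["consent_withdrawn"]],
            acc$by_status[["technical_failure"]],
            acc$analyzable))

## One example session recording: coupled, bursty movement series
dyad <- gen_movement(
  movement_sim_spec(n_samples = 3 * 600, rate = 10, coupling = 0.5,
                    lag_s = 0.5, seed = seed + 2),
  dyad_id = 1, session_id = 1)
write_series(dyad$patient, file.path(out, "example_patient.csv"))
write_series(dyad$therapist, file.path(out, "example_therapist.csv"))
cat(sprintf("example recording: %d samples at %g Hz, planted coupling %.1f\n",
            length(dyad$patient$values), dyad$patient$rate,
            attr(dyad, "ground_truth")$coupling))

## A short validation frame stack (blob movement with known pixel counts)
fs <- gen_frame_stack(pmin(6, round(dyad$patient$values[1:60])),
                      dims = c(48, 96), blob_size = 6, rate = 10,
                      noise_amp = 10, seed = seed + 3)
write_frame_stack(fs, file.path(out, "example_frames"))
cat(sprintf("frame stack: %d frames of 48x96 px -> %s/example_frames/\n",
            dim(fs$frames)[3], out))
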