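# Shared fixture builders and independent oracles.

# Short dyadic recording at study-like settings (10 Hz), scaled down in
# length so a full windowed CCF stays cheap.
quick_session <- function(seed, coupling = 0.5, minutes = 3, rate = 10,
                          dyad_id = 1L, session_id = 1L, ...) {
  gen_movement(
    movement_sim_spec(n_samples = minutes * 60 * rate, rate = rate,
                      coupling = coupling, seed = seed, ...),
    dyad_id = dyad_id, session_id = session_id)
}

# A set of sessions spread over dyads (2 sessions per dyad).
quick_study_sessions <- function(n_sessions, seed, coupling = 0,
                                 minutes = 3, ...) {
  lapply(seq_len(n_sessions), function(i) {
    quick_session(seed * 1000 + i, coupling = coupling, minutes = minutes,
                  dyad_id = (i - 1) %/% 2 + 1, session_id = i, ...)
  })
}

# Genuine-vs-pseudo Welch p-value for one simulated mini-study.
null_pvalue <- function(seed, coupling, n_sessions = 8, n_surrogate = 16,
                        minutes = 3) {
  sess <- quick_study_sessions(n_sessions, seed, coupling = coupling,
                               minutes = minutes)
  st <- session_sync_table(sess)
  surr <- shuffle_pairs(sess, n = n_surrogate, seed = seed * 1000 + 999)
  pt <- session_sync_table(surr$pairs)
  null_test(st$sync, pt$sync)$p
}

# Dyad series wrapped around two plain numeric vectors.
toy_dyad <- function(p, t, rate = 10, dyad_id = 1L, session_id = 1L) {
  dyad_series(mea_series(p, rate), mea_series(t, rate),
              dyad_id = dyad_id, session_id = session_id)
}

# Tiny frame stack: d x d blob moved by the given per-step displacements.
toy_stack <- function(dx, dims = c(32, 48), blob = 6, rate = 10, ...) {
  gen_frame_stack(dx, dims = dims, blob_size = blob, rate = rate, ...)
}

# Study spec with a planted session-level synchrony/outcome correlation
# (std beta) for the LoPF change term; other settings at their defaults.
spec_with_std_beta <- function(std_beta, seed, b = 26, ...) {
  defaults <- study_sim_spec(seed = 1)
  B <- defaults$trait_sync_sd^2
  sdy <- sqrt(B + defaults$within_dyad_sd^2)
  sdx <- b * B / (std_beta * sdy)
  s <- sqrt(sdx^2 - b^2 * B)
  study_sim_spec(outcome_slope = -b,
                 noise_sds = list(lopf = s, cgas = 10, goodness = 0.9,
                                  goodness_split = 0.4),
                 seed = seed, ...)
}

# Model table taking the planted per-session synchrony as the response
# (no movement simulation involved).
table_from_study <- function(study) {
  st <- data.frame(dyad_id = study$sessions$dyad_id,
                   session_no = study$sessions$session_no,
                   sync_z = study$sessions$sync_true)
  build_table(st, study$sessions, study$dyads)
}
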