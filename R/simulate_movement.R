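#' Specification for a simulated dyadic movement recording
#'
#' Describes the marginal movement process of each partner and the lagged
#' coupling between them. Each partner's own movement is a rectified AR(1)
#' process driven by Gaussian innovations plus Poisson-timed exponential
#' bursts, which mimics the bursty, nonnegative, autocorrelated character
#' of motion-energy traces. During coupled epochs (alternating on/off
#' states with geometric durations, mean on-duration 60 s) partner B's
#' signal is a linear mix of their own process and partner A's process
#' delayed by `lag_s`.
#'
#' @param n_samples number of samples per partner.
#' @param rate sampling rate, samples/s.
#' @param ar_coef AR(1) coefficient in `[0, 1)`.
#' @param burst_rate movement-burst rate, events per minute.
#' @param burst_amp mean burst amplitude (energy units).
#' @param noise_sd innovation SD (energy units).
#' @param coupling mixing weight in `[0, 1]`; 0 = independent partners,
#'   1 = partner B is a pure delayed copy of partner A.
#' @param lag_s signed coupling lag in seconds, `|lag_s| <= 5`; positive
#'   means B follows A.
#' @param coupled_fraction long-run fraction of time spent in the coupled
#'   state, in `[0, 1]`.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `movement_sim_spec`.
#' @export
movement_sim_spec <- function(n_samples, rate = 10, ar_coef = 0.8,
                              burst_rate = 6, burst_amp = 4, noise_sd = 1,
                              coupling = 0.5, lag_s = 0.5,
                              coupled_fraction = 0.5, seed = NULL) {
  stopifnot(n_samples > 0, rate > 0,
            ar_coef >= 0, ar_coef < 1,
            burst_rate >= 0, burst_amp >= 0, noise_sd >= 0,
            coupling >= 0, coupling <= 1,
            abs(lag_s) <= 5,
            coupled_fraction >= 0, coupled_fraction <= 1)
  structure(
    list(n_samples = as.integer(n_samples), rate = rate, ar_coef = ar_coef,
         burst_rate = burst_rate, burst_amp = burst_amp, noise_sd = noise_sd,
         coupling = coupling, lag_s = lag_s,
         coupled_fraction = coupled_fraction, seed = seed),
    class = "movement_sim_spec"
  )
}

# One partner's own movement: rectified AR(1) + Poisson-timed exponential
# bursts fed through the same recursion.
sim_own_process <- function(spec) {
  n <- spec$n_samples
  e <- stats::rnorm(n, 0, spec$noise_sd)
  p_burst <- spec$burst_rate / (60 * spec$rate)
  hits <- stats::rbinom(n, 1L, min(1, p_burst))
  nb <- sum(hits)
  if (nb > 0) {
    e[hits == 1L] <- e[hits == 1L] + spec$burst_amp * stats::rexp(nb)
  }
  x <- as.numeric(stats::filter(e, spec$ar_coef, method = "recursive"))
  pmax(x, 0)
}

# Alternating coupled/uncoupled epochs as a two-state Markov chain with
# mean on-duration 60 s and stationary on-fraction `frac`.
sim_epochs <- function(n, rate, frac) {
  if (frac <= 0) return(rep(FALSE, n))
  if (frac >= 1) return(rep(TRUE, n))
  mean_on <- 60 * rate                      # samples
  mean_off <- mean_on * (1 - frac) / frac
  p_exit_on <- 1 / mean_on
  p_exit_off <- 1 / mean_off
  state <- logical(n)
  s <- stats::runif(1) < frac
  flip <- stats::runif(n)
  for (t in seq_len(n)) {
    state[t] <- s
    if (s && flip[t] < p_exit_on) s <- FALSE
    else if (!s && flip[t] < p_exit_off) s <- TRUE
  }
  state
}

#' Simulate a coupled dyadic movement recording
#'
#' Generates two nonnegative movement series. Partner A is their own
#' process; partner B equals
#' `(1 - coupling) * own + coupling * A(delayed by lag_s)` inside coupled
#' epochs and their own process elsewhere. Ground truth (coupling, lag,
#' epoch mask) is attached as the `"ground_truth"` attribute.
#'
#' @param spec a [movement_sim_spec()].
#' @param dyad_id,session_id identifiers stored on the result.
#' @return A [dyad_series()].
#' @export
gen_movement <- function(spec, dyad_id = 1L, session_id = 1L) {
  stopifnot(inherits(spec, "movement_sim_spec"))
  n <- spec$n_samples
  lag_k <- as.integer(round(spec$lag_s * spec$rate))
  if (abs(lag_k) >= n) stop("coupling lag exceeds the series length")
  out <- with_seed(spec$seed, {
    a <- sim_own_process(spec)
    own_b <- sim_own_process(spec)
    epochs <- sim_epochs(n, spec$rate, spec$coupled_fraction)
    idx <- seq_len(n) - lag_k
    valid <- idx >= 1L & idx <= n
    a_shift <- rep(NA_real_, n)
    a_shift[valid] <- a[idx[valid]]
    on <- epochs & valid
    b <- own_b
    b[on] <- (1 - spec$coupling) * own_b[on] + spec$coupling * a_shift[on]
    list(a = a, b = b, epochs = epochs)
  })
  prov <- list(list(step = "simulated",
                    params = list(coupling = spec$coupling,
                                  lag_s = spec$lag_s, seed = spec$seed)))
  ds <- dyad_series(
    mea_series(out$a, spec$rate, provenance = prov),
    mea_series(out$b, spec$rate, provenance = prov),
    dyad_id = dyad_id, session_id = session_id, genuine = TRUE
  )
  attr(ds, "ground_truth") <- list(coupling = spec$coupling,
                                   lag_s = spec$lag_s,
                                   coupled_fraction = mean(out$epochs),
                                   epochs = out$epochs)
  ds
}

#' Render a movement series as a synthetic grayscale frame stack
#'
#' Builds a validation input for motion energy analysis with exactly
#' computable frame-to-frame pixel changes: a filled square blob on a
#' uniform background moves horizontally at each frame by
#' `round(movement[t]) * step_px` pixels, bouncing off the frame edges; a
#' single displacement too large for the frame is an error. Moving a
#' `d x d` blob by `dx <= d` pixels
#' changes exactly `2 * d * dx` pixels (and `2 * d^2` when `dx >= d`); the
#' per-frame truth is attached as attribute `"true_changed_pixels"`.
#' Optional per-pixel salt noise, uniform on `{0, ..., noise_amp}` and
#' redrawn each frame, perturbs consecutive-frame differences by at most
#' `noise_amp` grey levels, so with `noise_amp` at or below the MEA pixel
#' threshold the motion-energy output is unchanged.
#'
#' @param movement [mea_series()] or numeric vector of per-step movement
#'   magnitudes (displacements in pixels after rounding).
#' @param dims frame `(height, width)` in pixels.
#' @param blob_size blob side length `d` in pixels.
#' @param step_px pixels of displacement per unit movement.
#' @param base_intensity,blob_intensity background and blob grey levels;
#'   their difference should exceed the MEA threshold by a safe margin.
#' @param noise_amp salt-noise amplitude in grey levels (0 = none).
#' @param rate frame rate; defaults to the movement series rate or 10.
#' @param seed integer seed for the noise, or `NULL`.
#' @return A [frame_stack()] with `length(movement) + 1` frames.
#' @export
gen_frame_stack <- function(movement, dims = c(64, 64), blob_size = 8,
                            step_px = 1, base_intensity = 40,
                            blob_intensity = 220, noise_amp = 0,
                            rate = NULL, seed = NULL) {
  mv <- if (inherits(movement, "mea_series")) movement$values
        else as.numeric(movement)
  if (is.null(rate)) {
    rate <- if (inherits(movement, "mea_series")) movement$rate else 10
  }
  d <- as.integer(blob_size)
  stopifnot(d >= 1, dims[1] >= d, dims[2] >= d,
            base_intensity >= 0, blob_intensity <= 255 - noise_amp,
            abs(blob_intensity - base_intensity) > noise_amp)
  dx <- as.integer(round(mv)) * as.integer(step_px)
  if (any(dx < 0)) stop("movement magnitudes must be nonnegative")
  n_frames <- length(dx) + 1L
  row0 <- as.integer((dims[1] - d) %/% 2 + 1L)
  col <- as.integer((dims[2] - d) %/% 2 + 1L)
  col_max <- as.integer(dims[2] - d + 1L)
  direction <- 1L
  cols <- integer(n_frames)
  cols[1] <- col
  for (t in seq_along(dx)) {
    cand <- col + direction * dx[t]
    if (cand < 1L || cand > col_max) {       # bounce off the frame edge
      direction <- -direction
      cand <- col + direction * dx[t]
    }
    if (cand < 1L || cand > col_max) {
      stop("blob would leave the frame at step ", t,
           "; reduce movement amplitude or enlarge the frame")
    }
    col <- cand
    cols[t + 1L] <- col
  }
  frames <- array(base_intensity, dim = c(dims[1], dims[2], n_frames))
  for (t in seq_len(n_frames)) {
    frames[row0:(row0 + d - 1L), cols[t]:(cols[t] + d - 1L), t] <-
      blob_intensity
  }
  if (noise_amp > 0) {
    frames <- with_seed(seed, {
      frames + array(sample.int(noise_amp + 1L, length(frames),
                                replace = TRUE) - 1L,
                     dim = dim(frames))
    })
  }
  fs <- frame_stack(frames, rate = rate)
  attr(fs, "true_changed_pixels") <- 2L * d * pmin(dx, d)
  fs
}
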