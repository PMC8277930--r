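#' Symmetric lag grid for cross-correlation
#'
#' Builds the grid of time lags at which windowed cross-correlations are
#' evaluated: `max_lag_s / step_s` steps in each direction plus lag zero.
#' The defaults (5 s at 0.1 s resolution) give 50 strictly negative and 50
#' strictly positive lags, 101 in total.
#'
#' @param max_lag_s maximum absolute lag in seconds.
#' @param step_s lag step in seconds; must divide `max_lag_s`.
#' @return An object of class `lag_grid` with fields `lags` (seconds,
#'   ascending, including 0), `max_lag_s`, `step_s`, `n_positive`.
#' @export
make_lag_grid <- function(max_lag_s = 5, step_s = 0.1) {
  stopifnot(max_lag_s >= 0, step_s > 0)
  k <- max_lag_s / step_s
  if (abs(k - round(k)) > 1e-9) {
    stop("step_s must divide max_lag_s")
  }
  k <- as.integer(round(k))
  structure(
    list(lags = step_s * seq.int(-k, k), max_lag_s = max_lag_s,
         step_s = step_s, n_positive = k),
    class = "lag_grid"
  )
}

#' @exportS3Method base::print
print.lag_grid <- function(x, ...) {
  cat(sprintf("<lag_grid> +/-%g s in steps of %g s (%d lags)\n",
              x$max_lag_s, x$step_s, length(x$lags)))
  invisible(x)
}

# Naive reference implementation: window x lag x sample triple loop with
# explicit mean-centered sums. Kept exported for verification against the
# compiled kernel.
#' Reference windowed cross-correlation (naive triple loop)
#'
#' Computes the same windows-by-lags correlation matrix as
#' [windowed_ccf()] with an explicit sample-by-sample loop. Slow; intended
#' as an independent cross-check of the fast kernel.
#'
#' @inheritParams windowed_ccf
#' @return Numeric matrix, windows by lags.
#' @export
windowed_ccf_naive <- function(dyad, grid = make_lag_grid(), window_s = 60,
                               overlap_s = 0) {
  p <- dyad$patient$values
  tt <- dyad$therapist$values
  rate <- dyad$patient$rate
  nw <- as.integer(round(window_s * rate))
  hop <- as.integer(round((window_s - overlap_s) * rate))
  lag_k <- as.integer(round(grid$lags * rate))
  starts <- seq.int(1L, length(p) - nw + 1L, by = hop)
  out <- matrix(NA_real_, length(starts), length(lag_k))
  for (w in seq_along(starts)) {
    i0 <- starts[w]
    for (j in seq_along(lag_k)) {
      k <- lag_k[j]
      m <- nw - abs(k)
      if (m < 3) next
      xs <- if (k >= 0) i0 else i0 - k
      ys <- if (k >= 0) i0 + k else i0
      mx <- 0; my <- 0
      for (i in 0:(m - 1)) {
        mx <- mx + p[xs + i]
        my <- my + tt[ys + i]
      }
      mx <- mx / m; my <- my / m
      sxx <- 0; syy <- 0; sxy <- 0
      for (i in 0:(m - 1)) {
        dx <- p[xs + i] - mx
        dy <- tt[ys + i] - my
        sxx <- sxx + dx * dx; syy <- syy + dy * dy; sxy <- sxy + dx * dy
      }
      if (sxx > 0 && syy > 0) out[w, j] <- sxy / sqrt(sxx * syy)
    }
  }
  out
}

#' Windowed lagged cross-correlation matrix for one session
#'
#' Splits the session into consecutive windows (default 1 min, no
#' overlap; a trailing partial window is dropped) and, within each window,
#' computes the Pearson correlation between the patient segment and the
#' therapist segment shifted by each grid lag, using the `n - |lag|`
#' overlapping samples. A positive lag means the therapist's signal is
#' taken later than the patient's (therapist follows). Zero-variance
#' segments yield `NA`.
#'
#' @param dyad a [dyad_series()].
#' @param grid a [make_lag_grid()].
#' @param window_s window length in seconds.
#' @param overlap_s window overlap in seconds (0 = non-overlapping).
#' @return A numeric matrix (windows x lags) of class `ccf_windows` with
#'   attributes `lags_s`, `window_s`, `overlap_s`, `rate`, `n_valid`,
#'   `dyad_id`, `session_id`.
#' @export
windowed_ccf <- function(dyad, grid = make_lag_grid(), window_s = 60,
                         overlap_s = 0) {
  stopifnot(inherits(dyad, "dyad_series"), inherits(grid, "lag_grid"),
            window_s > 0, overlap_s >= 0, overlap_s < window_s)
  p <- dyad$patient$values
  tt <- dyad$therapist$values
  rate <- dyad$patient$rate
  nw <- as.integer(round(window_s * rate))
  if (length(p) < nw) {
    stop("series shorter than one window (", window_s, " s at ", rate,
         " Hz)")
  }
  hop <- as.integer(round((window_s - overlap_s) * rate))
  lag_k <- as.integer(round(grid$lags * rate))
  starts <- seq.int(1L, length(p) - nw + 1L, by = hop)
  out <- matrix(NA_real_, nrow = length(starts), ncol = length(lag_k))
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + nw - 1L)
    out[w, ] <- ccf_lags_kernel(p[idx], tt[idx], lag_k)
  }
  structure(out, class = c("ccf_windows", "matrix", "array"),
            lags_s = grid$lags, window_s = window_s, overlap_s = overlap_s,
            rate = rate, n_valid = sum(!is.na(out)),
            dyad_id = dyad$dyad_id, session_id = dyad$session_id)
}

#' @exportS3Method base::print
print.ccf_windows <- function(x, ...) {
  cat(sprintf(
    "<ccf_windows> %d windows x %d lags (%d valid cells), %g s windows\n",
    nrow(x), ncol(x), attr(x, "n_valid"), attr(x, "window_s")))
  invisible(x)
}

#' Grand-average synchrony index for one session
#'
#' Aggregates a windows-by-lags cross-correlation matrix to a single
#' session-level synchrony score: by default the mean of the absolute
#' Fisher-z-transformed correlations over all valid cells (the
#' movement-synchrony lineage convention). Both transforms can be toggled
#' and are recorded on the result. Correlations with `|r| >= 1` are
#' clamped just inside the open interval before the z-transform.
#'
#' @param ccf a [windowed_ccf()] matrix.
#' @param use_abs take absolute values before averaging.
#' @param use_fisher_z apply `atanh` before averaging.
#' @param include_lag0 include the lag-0 column (default `TRUE`).
#' @return An object of class `sync_index` with fields `value`,
#'   `n_windows`, `n_valid`, the transform flags and identifiers; `value`
#'   is `NA` (with a warning) when no valid cells exist.
#' @export
grand_average <- function(ccf, use_abs = TRUE, use_fisher_z = TRUE,
                          include_lag0 = TRUE) {
  stopifnot(inherits(ccf, "ccf_windows"))
  v <- unclass(ccf)
  if (!include_lag0) {
    v <- v[, attr(ccf, "lags_s") != 0, drop = FALSE]
  }
  vals <- as.vector(v)
  if (use_fisher_z) {
    vals <- atanh(pmin(1 - 1e-12, pmax(-1 + 1e-12, vals)))
  }
  if (use_abs) vals <- abs(vals)
  n_valid <- sum(!is.na(vals))
  value <- if (n_valid > 0) mean(vals, na.rm = TRUE) else {
    warning("no valid cross-correlation cells; synchrony index is NA")
    NA_real_
  }
  structure(
    list(value = value, n_windows = nrow(ccf), n_valid = n_valid,
         use_abs = use_abs, use_fisher_z = use_fisher_z,
         include_lag0 = include_lag0,
         dyad_id = attr(ccf, "dyad_id"), session_id = attr(ccf, "session_id")),
    class = "sync_index"
  )
}

#' @exportS3Method base::print
print.sync_index <- function(x, ...) {
  cat(sprintf("<sync_index> %.4f (%d valid cells over %d windows)%s%s\n",
              x$value, x$n_valid, x$n_windows,
              if (x$use_abs) " abs" else "",
              if (x$use_fisher_z) " fisher-z" else ""))
  invisible(x)
}

#' @export
as.numeric.sync_index <- function(x, ...) x$value

#' Dyad-level trait synchrony
#'
#' The median of a dyad's session-level synchrony indices — a robust
#' summary of how synchronous the pair characteristically is.
#'
#' @param indices numeric vector, or list of [grand_average()] results.
#' @return The median as a single number.
#' @export
dyad_trait <- function(indices) {
  v <- if (is.list(indices)) {
    vapply(indices, function(i) {
      if (inherits(i, "sync_index")) i$value else as.numeric(i)
    }, numeric(1))
  } else as.numeric(indices)
  if (length(v) < 1) stop("at least one session index is required")
  stats::median(v, na.rm = TRUE)
}

#' Session synchrony table for a set of dyadic sessions
#'
#' Convenience wrapper running [windowed_ccf()] and [grand_average()] over
#' a list of sessions and returning a tidy per-session table.
#'
#' @param sessions list of [dyad_series()].
#' @param grid,window_s,overlap_s passed to [windowed_ccf()].
#' @param ... passed to [grand_average()].
#' @return Data frame with columns `dyad_id`, `session_id`, `sync`,
#'   `n_windows`, `n_valid`.
#' @export
session_sync_table <- function(sessions, grid = make_lag_grid(),
                               window_s = 60, overlap_s = 0, ...) {
  rows <- lapply(sessions, function(d) {
    gi <- grand_average(windowed_ccf(d, grid, window_s, overlap_s), ...)
    data.frame(dyad_id = d$dyad_id, session_id = d$session_id,
               sync = gi$value, n_windows = gi$n_windows,
               n_valid = gi$n_valid)
  })
  do.call(rbind, rows)
}
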