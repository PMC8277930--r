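#' Pseudo-interaction surrogate pairings
#'
#' Builds a pseudo-synchrony data set by between-subjects shuffling:
#' patient streams are re-paired with therapist streams from *different*
#' dyads, so each surrogate "session" pairs two people who never
#' interacted. `n` pairings are drawn uniformly with replacement from the
#' valid pairing space; unequal stream lengths are truncated to the
#' shorter, from the start. The relaxed scheme `"cross_session"` allows
#' same-dyad pairings as long as the session differs.
#'
#' @param sessions list of genuine [dyad_series()].
#' @param n number of surrogate pairs (default 500).
#' @param seed integer seed or `NULL`.
#' @param scheme `"between_dyad"` (default) or `"cross_session"`.
#' @return An object of class `surrogate_set`: list with `pairs` (list of
#'   [dyad_series()] with `genuine = FALSE`), `n`, `scheme`, `seed` and a
#'   `truncation` data frame logging the retained length per pair.
#' @export
shuffle_pairs <- function(sessions, n = 500, seed = NULL,
                          scheme = c("between_dyad", "cross_session")) {
  scheme <- match.arg(scheme)
  stopifnot(n >= 1)
  if (length(sessions) < 2) {
    stop("need at least 2 sessions to build surrogate pairings")
  }
  dyads <- vapply(sessions, function(s) as.character(s$dyad_id), character(1))
  sess <- vapply(sessions, function(s) as.character(s$session_id),
                 character(1))
  ns <- length(sessions)
  grid <- expand.grid(i = seq_len(ns), j = seq_len(ns))
  ok <- if (scheme == "between_dyad") {
    dyads[grid$i] != dyads[grid$j]
  } else {
    !(dyads[grid$i] == dyads[grid$j] & sess[grid$i] == sess[grid$j])
  }
  grid <- grid[ok, , drop = FALSE]
  if (nrow(grid) == 0) {
    stop("no valid surrogate pairings: need streams from at least two ",
         if (scheme == "between_dyad") "dyads" else "sessions")
  }
  with_seed(seed, {
    pick <- grid[sample.int(nrow(grid), n, replace = TRUE), , drop = FALSE]
    pairs <- vector("list", n)
    kept <- integer(n)
    for (r in seq_len(n)) {
      p <- sessions[[pick$i[r]]]$patient
      tt <- sessions[[pick$j[r]]]$therapist
      len <- min(length(p$values), length(tt$values))
      kept[r] <- len
      p$values <- p$values[seq_len(len)]
      tt$values <- tt$values[seq_len(len)]
      pairs[[r]] <- dyad_series(
        p, tt,
        dyad_id = sprintf("%s|%s", dyads[pick$i[r]], dyads[pick$j[r]]),
        session_id = sprintf("surr%04d", r), genuine = FALSE)
    }
    structure(
      list(pairs = pairs, n = n, scheme = scheme, seed = seed,
           truncation = data.frame(
             pair = seq_len(n),
             patient_from = pick$i, therapist_from = pick$j,
             retained = kept)),
      class = "surrogate_set"
    )
  })
}

#' @exportS3Method base::print
print.surrogate_set <- function(x, ...) {
  cat(sprintf("<surrogate_set> %d pseudo-interaction pairs (%s shuffling)\n",
              x$n, gsub("_", "-", x$scheme)))
  invisible(x)
}

#' Welch test of genuine vs pseudo-synchrony
#'
#' Compares genuine session synchrony indices with a pseudo-synchrony null
#' distribution using a Welch two-sample t-test (unequal variances,
#' Welch-Satterthwaite degrees of freedom) and reports Cohen's d on the
#' pooled SD.
#'
#' @param genuine,pseudo numeric vectors (or lists of [grand_average()]
#'   results) of synchrony indices; each needs at least 2 values.
#' @return An object of class `null_comparison`: `t`, `df`, `p` (two
#'   sided), `d`, `genuine_mean`, `pseudo_mean`, `pseudo_sd`, group sizes.
#' @export
null_test <- function(genuine, pseudo) {
  as_vals <- function(x) {
    if (is.list(x)) {
      vapply(x, function(i) if (inherits(i, "sync_index")) i$value
                            else as.numeric(i), numeric(1))
    } else as.numeric(x)
  }
  g <- as_vals(genuine)
  ps <- as_vals(pseudo)
  g <- g[is.finite(g)]
  ps <- ps[is.finite(ps)]
  if (length(g) < 2 || length(ps) < 2) {
    stop("both groups need at least 2 finite synchrony values")
  }
  if (stats::var(g) == 0 && stats::var(ps) == 0) {
    stop("zero variance in both groups; the Welch test is undefined")
  }
  tt <- stats::t.test(g, ps, var.equal = FALSE)
  n1 <- length(g); n2 <- length(ps)
  sp <- sqrt(((n1 - 1) * stats::var(g) + (n2 - 1) * stats::var(ps)) /
               (n1 + n2 - 2))
  structure(
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value,
         d = if (sp > 0) (mean(g) - mean(ps)) / sp else 0,
         genuine_mean = mean(g), pseudo_mean = mean(ps),
         pseudo_sd = stats::sd(ps), n_genuine = n1, n_pseudo = n2),
    class = "null_comparison"
  )
}

#' @exportS3Method base::print
print.null_comparison <- function(x, ...) {
  cat(sprintf(
    "<null_comparison> genuine %.4f vs pseudo %.4f: t(%.1f) = %.3f, p = %.4g, Cohen's d = %.3f\n",
    x$genuine_mean, x$pseudo_mean, x$df, x$t, x$p, x$d))
  invisible(x)
}

#' Standardize synchrony against the pseudo-synchrony distribution
#'
#' Expresses synchrony values in SD units of the shuffle null:
#' `z = (value - pseudo_mean) / pseudo_sd`. When a `null_comparison` or a
#' numeric pseudo distribution is given, its mean and SD are used.
#'
#' @param values numeric vector of synchrony indices.
#' @param pseudo_mean,pseudo_sd null-distribution moments; `pseudo_sd`
#'   must be positive.
#' @param pseudo optional numeric vector (or [null_test()] result) from
#'   which the moments are taken instead.
#' @return Numeric vector of pseudo-standardized values.
#' @export
pseudo_standardize <- function(values, pseudo_mean = NULL, pseudo_sd = NULL,
                               pseudo = NULL) {
  if (!is.null(pseudo)) {
    if (inherits(pseudo, "null_comparison")) {
      pseudo_mean <- pseudo$pseudo_mean
      pseudo_sd <- pseudo$pseudo_sd
    } else {
      pv <- as.numeric(pseudo)
      pseudo_mean <- mean(pv)
      pseudo_sd <- stats::sd(pv)
    }
  }
  if (is.null(pseudo_mean) || is.null(pseudo_sd)) {
    stop("provide pseudo_mean and pseudo_sd, or a pseudo distribution")
  }
  if (!is.finite(pseudo_sd) || pseudo_sd <= 0) {
    stop("pseudo_sd must be positive")
  }
  (as.numeric(values) - pseudo_mean) / pseudo_sd
}
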