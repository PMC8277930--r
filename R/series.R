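#' Motion-energy time series
#'
#' Lightweight container for a per-person movement magnitude series, as
#' produced by frame differencing ([motion_energy()]) or by simulation
#' ([gen_movement()]). Carries the sampling rate, the source ROI area (if
#' any) and a provenance list recording every preprocessing step applied,
#' with its parameters, in order.
#'
#' @param values numeric vector of nonnegative movement magnitudes.
#' @param rate sampling rate in samples per second.
#' @param roi_area pixel area of the source region of interest, or `NA`.
#' @param provenance list of `list(step =, params =)` entries.
#' @return An object of class `mea_series`.
#' @export
mea_series <- function(values, rate, roi_area = NA_real_, provenance = list()) {
  stopifnot(is.numeric(values), length(rate) == 1L, is.finite(rate), rate > 0)
  structure(
    list(values = as.numeric(values), rate = as.numeric(rate),
         roi_area = as.numeric(roi_area), provenance = provenance),
    class = "mea_series"
  )
}

#' @exportS3Method base::print
print.mea_series <- function(x, ...) {
  cat(sprintf("<mea_series> %d samples @ %g Hz (%.1f s)\n",
              length(x$values), x$rate, length(x$values) / x$rate))
  if (length(x$provenance)) {
    cat("  provenance:", paste(provenance_steps(x), collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
length.mea_series <- function(x) length(x$values)

#' @export
as.numeric.mea_series <- function(x, ...) x$values

add_provenance <- function(series, step, params = list()) {
  series$provenance <- c(series$provenance,
                         list(list(step = step, params = params)))
  series
}

#' Names of the preprocessing steps applied to a series, in order
#'
#' @param series an [mea_series()] object.
#' @return Character vector of step names.
#' @export
provenance_steps <- function(series) {
  vapply(series$provenance, function(p) p$step, character(1))
}

#' Aligned patient/therapist movement series for one session
#'
#' A dyadic session container pairing the two partners' motion-energy
#' series. Surrogate (pseudo-interaction) pairings carry `genuine = FALSE`.
#'
#' @param patient,therapist [mea_series()] objects with equal rates.
#' @param dyad_id,session_id identifiers.
#' @param genuine logical; `FALSE` for artificial pairings of streams from
#'   people who never interacted.
#' @return An object of class `dyad_series`.
#' @export
dyad_series <- function(patient, therapist, dyad_id = NA, session_id = NA,
                        genuine = TRUE) {
  stopifnot(inherits(patient, "mea_series"), inherits(therapist, "mea_series"))
  if (!isTRUE(all.equal(patient$rate, therapist$rate))) {
    stop("patient and therapist series must share a sampling rate")
  }
  if (length(patient$values) != length(therapist$values)) {
    stop("patient and therapist series must have equal length; ",
         "truncate surrogate pairings before constructing the dyad")
  }
  structure(
    list(patient = patient, therapist = therapist,
         dyad_id = dyad_id, session_id = session_id, genuine = isTRUE(genuine)),
    class = "dyad_series"
  )
}

#' @exportS3Method base::print
print.dyad_series <- function(x, ...) {
  cat(sprintf("<dyad_series> dyad %s session %s: %d samples @ %g Hz%s\n",
              as.character(x$dyad_id), as.character(x$session_id),
              length(x$patient$values), x$patient$rate,
              if (x$genuine) "" else " [surrogate]"))
  invisible(x)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
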