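#' Specification for a simulated therapy study
#'
#' Defines a study of `n_dyads` patient-therapist pairs, each contributing
#' `sessions_per_dyad` sessions. Synchrony is generated on the
#' pseudo-standardized scale (SD units of a shuffle null): each dyad has a
#' stable synchrony trait, sessions vary around it with a smaller
#' within-dyad SD and a mild linear trend over the course of therapy.
#' Outcome change in personality functioning (LoPF-Q total, follow-up
#' minus baseline, negative = improvement) is linearly related to the
#' dyad's synchrony trait; post-session goodness ratings (7-point) are
#' weakly related to the session's synchrony. Psychosocial functioning
#' change (CGAS), baseline severities and mid-therapy alliance (WAI-SR)
#' are generated without a synchrony effect.
#'
#' Default magnitudes emulate a small completed-therapy sample: 16 dyads,
#' 22 sessions each, a between-dyad synchrony SD of about 1.0 against a
#' within-dyad SD of about 0.84 (intraclass correlation near 0.5), an
#' outcome slope giving a session-level synchrony/outcome correlation near
#' -0.43, and a goodness slope giving a correlation near -0.1.
#'
#' @param n_dyads number of dyads.
#' @param sessions_per_dyad sessions per dyad; the study floor is
#'   `min_sessions` (13, half of a planned 25) unless overridden.
#' @param trait_sync_mean,trait_sync_sd mean and between-dyad SD of the
#'   dyad synchrony trait (pseudo-standardized units).
#' @param within_dyad_sd within-dyad session-to-session SD; must be
#'   strictly smaller than `trait_sync_sd`.
#' @param outcome_slope LoPF-change points per synchrony unit (negative:
#'   more synchrony, more improvement).
#' @param goodness_slope SEQ goodness points per synchrony unit.
#' @param session_trend synchrony units per session (centered mid-therapy).
#' @param noise_sds named list of residual SDs: `lopf`, `cgas`, `goodness`,
#'   `goodness_split` (rater disagreement around the dyad-average rating).
#' @param lopf_base_mean,lopf_base_sd,cgas_base_mean,cgas_base_sd,wai_mean,wai_sd
#'   baseline and alliance distributions.
#' @param lopf_change_mean,cgas_change_mean mean outcome changes.
#' @param min_sessions inclusion floor for sessions per dyad; set lower
#'   only for reduced-scale demonstrations.
#' @param seed integer seed or `NULL`.
#' @return An object of class `study_sim_spec`.
#' @export
study_sim_spec <- function(n_dyads = 16, sessions_per_dyad = 22,
                           trait_sync_mean = 1.0, trait_sync_sd = 0.99,
                           within_dyad_sd = 0.84,
                           outcome_slope = -28, goodness_slope = -0.07,
                           session_trend = -0.02,
                           noise_sds = list(lopf = 41, cgas = 10,
                                            goodness = 0.9,
                                            goodness_split = 0.4),
                           lopf_base_mean = 230, lopf_base_sd = 40,
                           cgas_base_mean = 55, cgas_base_sd = 8,
                           wai_mean = 3.8, wai_sd = 0.6,
                           lopf_change_mean = -25, cgas_change_mean = 8,
                           min_sessions = 13, seed = NULL) {
  stopifnot(n_dyads >= 1, sessions_per_dyad >= 1,
            trait_sync_sd > 0, within_dyad_sd > 0)
  if (trait_sync_sd <= within_dyad_sd) {
    stop("between-dyad SD (trait_sync_sd) must strictly exceed ",
         "within_dyad_sd: synchrony is a dyad trait by construction")
  }
  if (sessions_per_dyad < min_sessions) {
    stop("sessions_per_dyad is below the inclusion floor of ", min_sessions,
         " sessions; pass min_sessions explicitly for reduced-scale runs")
  }
  needed <- c("lopf", "cgas", "goodness", "goodness_split")
  stopifnot(all(needed %in% names(noise_sds)))
  structure(
    list(n_dyads = as.integer(n_dyads),
         sessions_per_dyad = as.integer(sessions_per_dyad),
         trait_sync_mean = trait_sync_mean, trait_sync_sd = trait_sync_sd,
         within_dyad_sd = within_dyad_sd, outcome_slope = outcome_slope,
         goodness_slope = goodness_slope, session_trend = session_trend,
         noise_sds = noise_sds,
         lopf_base_mean = lopf_base_mean, lopf_base_sd = lopf_base_sd,
         cgas_base_mean = cgas_base_mean, cgas_base_sd = cgas_base_sd,
         wai_mean = wai_mean, wai_sd = wai_sd,
         lopf_change_mean = lopf_change_mean,
         cgas_change_mean = cgas_change_mean, seed = seed),
    class = "study_sim_spec"
  )
}

#' Simulate study tables with planted ground truth
#'
#' Generates a session-level table (true per-session synchrony, patient
#' and therapist goodness ratings, session number) and a dyad-level
#' outcome table (baseline/follow-up LoPF-Q and CGAS, mid-therapy WAI-SR).
#' Planted quantities (dyad traits, true session synchrony, slopes) are
#' attached as the `"ground_truth"` attribute so downstream tests never
#' re-derive them.
#'
#' @param spec a [study_sim_spec()].
#' @return A list of class `study_tables` with elements `sessions` and
#'   `dyads` (data frames).
#' @export
gen_study <- function(spec) {
  stopifnot(inherits(spec, "study_sim_spec"))
  with_seed(spec$seed, {
    nd <- spec$n_dyads
    ns <- spec$sessions_per_dyad
    trait <- stats::rnorm(nd, spec$trait_sync_mean, spec$trait_sync_sd)
    dyad_id <- seq_len(nd)

    session_no <- rep(seq_len(ns), times = nd)
    dyad_of <- rep(dyad_id, each = ns)
    trend <- spec$session_trend * (session_no - (ns + 1) / 2)
    sync_true <- trait[dyad_of] + trend +
      stats::rnorm(nd * ns, 0, spec$within_dyad_sd)

    g_avg <- 5.3 + spec$goodness_slope * sync_true +
      stats::rnorm(nd * ns, 0, spec$noise_sds$goodness)
    split <- stats::rnorm(nd * ns, 0, spec$noise_sds$goodness_split)
    clamp17 <- function(x) pmin(7, pmax(1, x))
    sessions <- data.frame(
      dyad_id = dyad_of,
      session_no = session_no,
      sync_true = sync_true,
      seq_goodness_pat = clamp17(g_avg + split),
      seq_goodness_ther = clamp17(g_avg - split)
    )

    lopf_change <- spec$lopf_change_mean +
      spec$outcome_slope * (trait - spec$trait_sync_mean) +
      stats::rnorm(nd, 0, spec$noise_sds$lopf)
    cgas_change <- spec$cgas_change_mean +
      stats::rnorm(nd, 0, spec$noise_sds$cgas)
    lopf_base <- stats::rnorm(nd, spec$lopf_base_mean, spec$lopf_base_sd)
    cgas_base <- pmin(100, pmax(1, stats::rnorm(nd, spec$cgas_base_mean,
                                                spec$cgas_base_sd)))
    dyads <- data.frame(
      dyad_id = dyad_id,
      lopf_base = lopf_base,
      lopf_fu = lopf_base + lopf_change,
      cgas_base = cgas_base,
      cgas_fu = pmin(100, pmax(1, cgas_base + cgas_change)),
      wai_sr = pmin(5, pmax(1, stats::rnorm(nd, spec$wai_mean, spec$wai_sd)))
    )

    out <- structure(list(sessions = sessions, dyads = dyads),
                     class = "study_tables")
    attr(out, "ground_truth") <- list(
      trait = trait, lopf_change = lopf_change, cgas_change = cgas_change,
      outcome_slope = spec$outcome_slope,
      goodness_slope = spec$goodness_slope,
      session_trend = spec$session_trend,
      trait_sync_sd = spec$trait_sync_sd,
      within_dyad_sd = spec$within_dyad_sd
    )
    out
  })
}

#' @exportS3Method base::print
print.study_tables <- function(x, ...) {
  cat(sprintf("<study_tables> %d dyads, %d sessions\n",
              nrow(x$dyads), nrow(x$sessions)))
  invisible(x)
}

#' Build a session manifest with exclusion statuses
#'
#' Turns a simulated study's session table into a recording manifest,
#' marking a chosen number of sessions as excluded (consent withdrawal or
#' technical failure) for data-accounting checks. Consent withdrawals are
#' taken from a single dyad, mirroring how consent is withdrawn per person
#' rather than per session.
#'
#' @param study a [gen_study()] result.
#' @param n_withdrawn sessions lost to consent withdrawal.
#' @param n_failed sessions lost to technical or human failure.
#' @param seed integer seed or `NULL`.
#' @return A data frame with columns `dyad_id`, `session_no`,
#'   `patient_media_path`, `therapist_media_path`, `status`.
#' @export
simulate_manifest <- function(study, n_withdrawn = 0, n_failed = 0,
                              seed = NULL) {
  stopifnot(inherits(study, "study_tables"))
  s <- study$sessions
  n <- nrow(s)
  stopifnot(n_withdrawn + n_failed <= n)
  with_seed(seed, {
    status <- rep("analyzable", n)
    if (n_withdrawn > 0) {
      wd <- sample(unique(s$dyad_id), 1)
      cand <- which(s$dyad_id == wd)
      if (length(cand) < n_withdrawn) cand <- seq_len(n)
      status[cand[seq_len(n_withdrawn)]] <- "consent_withdrawn"
    }
    pool <- which(status == "analyzable")
    if (n_failed > 0) {
      status[sample(pool, n_failed)] <- "technical_failure"
    }
    data.frame(
      dyad_id = s$dyad_id, session_no = s$session_no,
      patient_media_path = sprintf("dyad%02d_s%02d_patient.csv",
                                   s$dyad_id, s$session_no),
      therapist_media_path = sprintf("dyad%02d_s%02d_therapist.csv",
                                     s$dyad_id, s$session_no),
      status = status
    )
  })
}
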