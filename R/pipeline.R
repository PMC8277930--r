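#' Map a planted synchrony level to a movement coupling weight
#'
#' The study simulator plants synchrony on the pseudo-standardized scale;
#' movement simulation needs a mixing weight in `[0, 1]`. This linear map
#' (clamped to `[0.02, 0.92]`) centers at the study's trait mean so that
#' dyads above/below average synchrony get above/below average coupling.
#'
#' @param sync planted synchrony values.
#' @param center synchrony value mapped to the midpoint coupling.
#' @param midpoint,slope coupling at `center` and per-synchrony-unit gain.
#' @return Coupling weights in `[0.02, 0.92]`.
#' @export
coupling_from_sync <- function(sync, center = 1.0, midpoint = 0.35,
                               slope = 0.18) {
  pmin(0.92, pmax(0.02, midpoint + slope * (sync - center)))
}

#' Run the full synchrony study pipeline on simulated recordings
#'
#' End-to-end orchestration over synthetic data: simulates study tables
#' and per-session dyadic movement recordings (coupling driven by each
#' session's planted synchrony), computes windowed lagged
#' cross-correlation synchrony per session, builds the shuffle-based
#' pseudo-synchrony null, Welch-tests genuine against pseudo synchrony,
#' pseudo-standardizes the session indices, fits the random-intercept
#' outcome model and reduces it by backward elimination. All tables are
#' written as CSV (scalars and the null comparison as JSON) together with
#' a provenance sidecar recording the configuration and seed. Per-session
#' failures are logged and skipped rather than aborting the run.
#'
#' @param out_dir output directory.
#' @param study_spec a [study_sim_spec()].
#' @param session_minutes recording length per session.
#' @param rate sampling rate of the simulated movement series.
#' @param n_surrogate number of pseudo-interaction pairs.
#' @param grid lag grid; windows are `window_s` seconds, non-overlapping.
#' @param window_s synchrony window length (seconds).
#' @param drop_sessions optional data frame (`dyad_id`, `session_no`) of
#'   sessions to exclude before analysis.
#' @param seed integer seed controlling every random stage.
#' @return List of class `sync_pipeline_result`: `sync_table`,
#'   `null_comparison`, `model_table`, `reduction`, `report`, `skipped`,
#'   `paths`.
#' @export
run_pipeline <- function(out_dir, study_spec, session_minutes = 3,
                         rate = 10, n_surrogate = 20,
                         grid = make_lag_grid(), window_s = 60,
                         drop_sessions = NULL, seed = 1L) {
  stopifnot(inherits(study_spec, "study_sim_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study_spec$seed <- if (is.null(study_spec$seed)) seed else study_spec$seed
  study <- gen_study(study_spec)
  sessions <- study$sessions
  if (!is.null(drop_sessions)) {
    drop_key <- paste(drop_sessions$dyad_id, drop_sessions$session_no)
    sessions <- sessions[!(paste(sessions$dyad_id, sessions$session_no)
                           %in% drop_key), , drop = FALSE]
  }
  write_study_tables(study, file.path(out_dir, "study"))

  n_samples <- as.integer(session_minutes * 60 * rate)
  skipped <- character(0)
  dyads <- vector("list", nrow(sessions))
  # per-session seeds derive from stable identifiers so that dropping a
  # session leaves every other session's simulation unchanged
  dyad_idx <- match(sessions$dyad_id, unique(study$sessions$dyad_id))
  for (r in seq_len(nrow(sessions))) {
    row <- sessions[r, ]
    spec <- movement_sim_spec(
      n_samples = n_samples, rate = rate,
      coupling = coupling_from_sync(row$sync_true,
                                    center = study_spec$trait_sync_mean),
      lag_s = 0.5, coupled_fraction = 0.6,
      seed = seed + 1000L + 997L * dyad_idx[r] + as.integer(row$session_no))
    dyads[[r]] <- tryCatch(
      gen_movement(spec, dyad_id = row$dyad_id, session_id = row$session_no),
      error = function(e) {
        skipped <<- c(skipped, sprintf("dyad %s session %s: %s",
                                       row$dyad_id, row$session_no,
                                       conditionMessage(e)))
        NULL
      })
  }
  dyads <- Filter(Negate(is.null), dyads)
  if (length(dyads) == 0) stop("no session could be simulated")

  sync_tab <- session_sync_table(dyads, grid = grid, window_s = window_s)
  names(sync_tab)[names(sync_tab) == "session_id"] <- "session_no"
  utils::write.csv(sync_tab, file.path(out_dir, "session_sync.csv"),
                   row.names = FALSE)

  surr <- shuffle_pairs(dyads, n = n_surrogate, seed = seed + 2L)
  pseudo_tab <- session_sync_table(surr$pairs, grid = grid,
                                   window_s = window_s)
  utils::write.csv(pseudo_tab, file.path(out_dir, "pseudo_sync.csv"),
                   row.names = FALSE)
  nt <- null_test(sync_tab$sync, pseudo_tab$sync)
  jsonlite::write_json(unclass(nt), file.path(out_dir, "null_test.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  sync_tab$sync_z <- pseudo_standardize(sync_tab$sync, pseudo = nt)
  trait_tab <- stats::aggregate(sync_z ~ dyad_id, sync_tab, dyad_trait)
  names(trait_tab)[2] <- "trait_sync"
  utils::write.csv(trait_tab, file.path(out_dir, "dyad_trait.csv"),
                   row.names = FALSE)

  model_tab <- build_table(sync_tab, sessions, study$dyads)
  reduction <- stepwise_eliminate(model_tab)
  report <- model_report(reduction)
  utils::write.csv(report$fixed, file.path(out_dir, "model_fixed.csv"),
                   row.names = FALSE)
  utils::write.csv(reduction$trace,
                   file.path(out_dir, "elimination_trace.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(sigma2 = report$sigma2, tau00 = report$tau00, icc = report$icc,
         r2_marginal = report$r2_marginal,
         r2_conditional = report$r2_conditional,
         deviance = report$deviance, singular = report$singular,
         n_obs = report$n_obs, n_dyads = report$n_dyads),
    file.path(out_dir, "model_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  jsonlite::write_json(
    list(seed = seed, rate = rate, session_minutes = session_minutes,
         n_surrogate = n_surrogate, window_s = window_s,
         max_lag_s = grid$max_lag_s, lag_step_s = grid$step_s,
         n_sessions = length(dyads), skipped = skipped,
         package_version = as.character(utils::packageVersion("dyadsync"))),
    file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(
    list(sync_table = sync_tab, null_comparison = nt,
         model_table = model_tab, reduction = reduction, report = report,
         skipped = skipped, paths = out_dir),
    class = "sync_pipeline_result"
  )
}

#' @exportS3Method base::print
print.sync_pipeline_result <- function(x, ...) {
  cat(sprintf("<sync_pipeline_result> %d sessions analyzed -> %s\n",
              nrow(x$sync_table), x$paths))
  print(x$null_comparison)
  print(x$reduction)
  invisible(x)
}
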