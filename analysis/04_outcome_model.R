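#!/usr/bin/env Rscript
# Mixed-model association of session synchrony with therapy outcome and
# session evaluations at the full study scale (16 dyads x 22 sessions):
# random intercept per dyad, backward elimination, standardized
# coefficients, ICC, marginal/conditional R2, BH-adjusted p-values.
#
# Reads:  results/data/ (from 01_simulate.R)
# Writes: results/model/

suppressMessages(library(dyadsync))
out <- "results/model"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

study <- read_study_tables("results/data")
sync_tab <- data.frame(dyad_id = study$sessions$dyad_id,
                       session_no = study$sessions$session_no,
                       sync_z = study$sessions$sync_true)
tab <- build_table(sync_tab, study$sessions, study$dyads)
cat(sprintf("model table: %d analyzable sessions from %d dyads\n",
            nrow(tab), length(unique(tab$dyad_id))))

## Full model, then backward elimination (random effect first, then the
## fixed effect with the largest Satterthwaite p, repeatedly)
reduction <- stepwise_eliminate(tab)
print(reduction)
utils::write.csv(reduction$trace, file.path(out, "elimination_trace.csv"),
                 row.names = FALSE)

report <- model_report(reduction)
print(report)
utils::write.csv(report$fixed, file.path(out, "fixed_effects.csv"),
                 row.names = FALSE)
jsonlite::write_json(
  list(sigma2 = report$sigma2, tau00 = report$tau00, icc = report$icc,
       r2_marginal = report$r2_marginal,
       r2_conditional = report$r2_conditional,
       deviance = report$deviance, n_obs = report$n_obs,
       n_dyads = report$n_dyads),
  file.path(out, "model_summary.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
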