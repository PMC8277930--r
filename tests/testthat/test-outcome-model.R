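test_that("the modelling table joins losslessly and derives change scores", {
  study <- gen_study(study_sim_spec(n_dyads = 6, sessions_per_dyad = 14,
                                    seed = 2))
  tab <- table_from_study(study)
  expect_equal(nrow(tab), 6 * 14)
  expect_equal(attr(tab, "n_dropped"), 0)
  expect_equal(tab$lopf_change,
               (study$dyads$lopf_fu - study$dyads$lopf_base)[tab$dyad_id])
  expect_true(all(tab$seq_goodness >= 1 & tab$seq_goodness <= 7))

  # missing synchrony rows are dropped and counted
  st <- data.frame(dyad_id = study$sessions$dyad_id,
                   session_no = study$sessions$session_no,
                   sync_z = study$sessions$sync_true)
  st$sync_z[c(3, 40)] <- NA
  tab2 <- build_table(st, study$sessions, study$dyads)
  expect_equal(nrow(tab2), 6 * 14 - 2)
  expect_equal(attr(tab2, "n_dropped"), 2)

  # duplicate keys are an error; disjoint keys give an empty table
  expect_error(build_table(rbind(st, st[1, ]), study$sessions, study$dyads),
               "duplicate")
  st3 <- st
  st3$session_no <- st3$session_no + 1000
  expect_warning(out <- build_table(st3, study$sessions, study$dyads),
                 "empty")
  expect_equal(nrow(out), 0)
})

test_that("ICC follows the variance-component identity", {
  expect_equal(icc(0.71, 0.67), 0.67 / 1.38, tolerance = 1e-12)
  expect_equal(icc(1.3, 0), 0)
  expect_equal(icc(0.4, 0.4), 0.5)
  expect_error(icc(0, 0.5))
})

test_that("fitted variance components satisfy the ICC identity exactly", {
  study <- gen_study(study_sim_spec(n_dyads = 10, sessions_per_dyad = 14,
                                    seed = 9))
  fit <- fit_sync_model(table_from_study(study))
  rep <- model_report(fit)
  expect_equal(rep$icc, rep$tau00 / (rep$tau00 + rep$sigma2),
               tolerance = 1e-10)
  expect_gte(rep$r2_conditional, rep$r2_marginal)
  # R2c - R2m is exactly the random-intercept share of total variance
  x <- lme4::getME(fit, "X")
  var_f <- var(as.numeric(x %*% lme4::fixef(fit)))
  expect_equal(rep$r2_conditional - rep$r2_marginal,
               rep$tau00 / (var_f + rep$tau00 + rep$sigma2),
               tolerance = 1e-10)
})

test_that("variance-decomposition R2 matches a long-form computation", {
  study <- gen_study(study_sim_spec(n_dyads = 12, sessions_per_dyad = 16,
                                    seed = 14))
  tab <- table_from_study(study)
  fit <- fit_sync_model(tab, predictors = c("lopf_change", "session_no"))
  r2 <- r2_nakagawa(fit)
  x <- lme4::getME(fit, "X")
  var_f <- var(as.numeric(x %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  tau <- as.numeric(vc$dyad_id[1, 1]); sg <- attr(vc, "sc")^2
  expect_equal(unname(r2["marginal"]), var_f / (var_f + tau + sg),
               tolerance = 1e-12)
  expect_equal(unname(r2["conditional"]),
               (var_f + tau) / (var_f + tau + sg), tolerance = 1e-12)

  # intercept-only model: marginal 0, conditional equals the ICC
  fit0 <- lmerTest::lmer(sync_z ~ 1 + (1 | dyad_id), data = tab)
  r20 <- r2_nakagawa(fit0)
  expect_equal(unname(r20["marginal"]), 0)
  expect_equal(unname(r20["conditional"]), model_report(fit0)$icc,
               tolerance = 1e-12)
})

test_that("a no-clustering design yields near-zero ICC", {
  # response drawn iid across dyads: the true random-intercept variance
  # is 0, so the fitted ICC must be near 0 (and may be flagged singular)
  set.seed(77)
  tab <- data.frame(dyad_id = rep(1:14, each = 14),
                    session_no = rep(1:14, times = 14),
                    sync_z = rnorm(14 * 14),
                    lopf_change = rep(rnorm(14, 0, 40), each = 14),
                    seq_goodness = runif(14 * 14, 3, 6))
  fit <- fit_sync_model(tab, predictors = c("lopf_change", "seq_goodness"))
  expect_lt(model_report(fit)$icc, 0.05)
})

test_that("standardized coefficients match the closed-form scaling", {
  study <- gen_study(study_sim_spec(n_dyads = 8, sessions_per_dyad = 14,
                                    seed = 21))
  tab <- table_from_study(study)
  fit <- fit_sync_model(tab, predictors = c("lopf_change", "seq_goodness"))
  sb <- standardized_betas(fit)
  co <- lme4::fixef(fit)
  mf <- stats::model.frame(fit)
  for (term in c("lopf_change", "seq_goodness")) {
    expect_equal(sb$std_beta[sb$term == term],
                 unname(co[term]) * sd(mf[[term]]) / sd(mf$sync_z),
                 tolerance = 1e-12)
    expect_equal(sign(sb$std_beta[sb$term == term]),
                 sign(sb$estimate[sb$term == term]))
  }
  # pre-scaled data: standardized and raw slopes coincide
  tab2 <- tab
  tab2$sync_z <- as.numeric(scale(tab2$sync_z))
  tab2$lopf_change <- as.numeric(scale(tab2$lopf_change))
  fit2 <- fit_sync_model(tab2, predictors = "lopf_change")
  sb2 <- standardized_betas(fit2)
  i <- sb2$term == "lopf_change"
  expect_equal(sb2$std_beta[i], sb2$estimate[i], tolerance = 1e-9)
  # intercept standardized at predictor means: model mean vs sample mean
  expect_lt(abs(sb2$std_beta[sb2$term == "(Intercept)"]), 0.05)
})

test_that("Benjamini-Hochberg adjustment reproduces hand-stepped values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("backward elimination removes pure-noise predictors but keeps the random intercept", {
  spec <- study_sim_spec(n_dyads = 12, sessions_per_dyad = 16,
                         outcome_slope = 0, goodness_slope = 0,
                         session_trend = 0, seed = 31)
  kept_counts <- integer(0)
  random_kept <- logical(0)
  for (s in 1:5) {
    spec$seed <- 310 + s
    tab <- table_from_study(gen_study(spec))
    red <- stepwise_eliminate(tab)
    kept_counts <- c(kept_counts, length(red$kept))
    random_kept <- c(random_kept, red$random_kept)
  }
  expect_true(all(random_kept))          # planted ICC > 0
  expect_lte(mean(kept_counts), 1)       # noise terms mostly eliminated
  # the intercept survives even when every predictor is dropped
  expect_true(all(vapply(1:5, function(s) {
    spec$seed <- 310 + s
    red <- stepwise_eliminate(table_from_study(gen_study(spec)))
    "(Intercept)" %in% standardized_betas(red$fit)$term
  }, logical(1))))
})

test_that("elimination is idempotent on an already-reduced model", {
  study <- gen_study(study_sim_spec(seed = 44))
  tab <- table_from_study(study)
  red1 <- stepwise_eliminate(tab)
  red2 <- stepwise_eliminate(tab, predictors = red1$kept)
  expect_setequal(red2$kept, red1$kept)
  expect_equal(red2$random_kept, red1$random_kept)
})

test_that("elimination agrees with the established mixed-model step procedure", {
  study <- gen_study(study_sim_spec(seed = 101))
  tab <- table_from_study(study)
  red <- stepwise_eliminate(tab)
  # lmerTest::step re-evaluates the model call, so the data must be
  # reachable from the global environment
  assign(".step_tab", tab, envir = globalenv())
  on.exit(rm(".step_tab", envir = globalenv()), add = TRUE)
  full <- lmerTest::lmer(
    sync_z ~ lopf_change + cgas_change + seq_goodness + session_no +
      wai_sr + lopf_base + cgas_base + (1 | dyad_id),
    data = get(".step_tab", envir = globalenv()))
  full@call$data <- quote(.step_tab)
  st <- lmerTest::step(full, reduce.random = FALSE, alpha.fixed = 0.05)
  kept_ref <- attr(terms(lmerTest::get_model(st)), "term.labels")
  kept_ref <- kept_ref[!grepl("\\|", kept_ref)]
  expect_setequal(red$kept, kept_ref)
})

test_that("adding a truly active predictor decreases the deviance", {
  study <- gen_study(study_sim_spec(seed = 55))
  tab <- table_from_study(study)
  m0 <- fit_sync_model(tab, predictors = "cgas_change", reml = FALSE)
  m1 <- fit_sync_model(tab, predictors = c("cgas_change", "lopf_change"),
                       reml = FALSE)
  expect_lt(-2 * as.numeric(logLik(m1)), -2 * as.numeric(logLik(m0)))
})

test_that("a session-level effect of 0.4 SD among noise predictors is retained reliably", {
  # goodness slope scaled so the session-level synchrony/goodness
  # correlation is 0.4; all other predictors are pure noise
  base <- study_sim_spec(seed = 1)
  sdy <- sqrt(base$trait_sync_sd^2 + base$within_dyad_sd^2)
  g <- 0.45                      # goodness residual SD
  c_needed <- 0.4 * g / (sdy * sqrt(1 - 0.4^2))
  kept <- vapply(1:20, function(s) {
    spec <- study_sim_spec(outcome_slope = 0, session_trend = 0,
                           goodness_slope = -c_needed,
                           noise_sds = list(lopf = 41, cgas = 10,
                                            goodness = g,
                                            goodness_split = 0.2),
                           seed = 900 + s)
    red <- stepwise_eliminate(table_from_study(gen_study(spec)))
    "seq_goodness" %in% red$kept
  }, logical(1))
  expect_gte(mean(kept), 0.9)
})

test_that("planted dyad-level effects are recovered with small bias in sign and size", {
  # planted session-level std beta 0.4 for the LoPF-change term
  betas <- vapply(1:30, function(s) {
    spec <- spec_with_std_beta(0.4, seed = 4000 + s)
    tab <- table_from_study(gen_study(spec))
    fit <- fit_sync_model(tab, predictors = "lopf_change")
    standardized_betas(fit)$std_beta[2]
  }, numeric(1))
  expect_lt(mean(betas), 0)
  expect_lt(abs(mean(betas) - (-0.4)) / 0.4, 0.2)
})
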