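#' Assemble the session-level modelling table
#'
#' Inner-joins per-session synchrony indices with the session evaluation
#' table and the dyad-level outcome table, and derives the model
#' variables: average goodness rating, outcome change scores (follow-up
#' minus baseline) and baseline severities. Sessions without a (finite)
#' synchrony value are dropped and counted in attribute `n_dropped`.
#'
#' @param sync_table data frame with `dyad_id`, `session_no` and a
#'   synchrony column `sync_z` (pseudo-standardized) or `sync`.
#' @param sessions session table with `dyad_id`, `session_no`,
#'   `seq_goodness_pat`, `seq_goodness_ther`.
#' @param dyads dyad table with `dyad_id`, `lopf_base`, `lopf_fu`,
#'   `cgas_base`, `cgas_fu`, `wai_sr`.
#' @return Data frame with one row per analyzable session: `dyad_id`,
#'   `session_no`, `sync_z`, `seq_goodness`, `lopf_change`, `cgas_change`,
#'   `lopf_base`, `cgas_base`, `wai_sr`.
#' @export
build_table <- function(sync_table, sessions, dyads) {
  if (!"sync_z" %in% names(sync_table)) {
    if ("sync" %in% names(sync_table)) {
      sync_table$sync_z <- sync_table$sync
    } else stop("sync_table needs a sync_z (or sync) column")
  }
  if (!"session_no" %in% names(sync_table) &&
      "session_id" %in% names(sync_table)) {
    sync_table$session_no <- sync_table$session_id
  }
  key <- function(d) paste(d$dyad_id, d$session_no, sep = "\r")
  if (anyDuplicated(key(sync_table)) || anyDuplicated(key(sessions))) {
    stop("duplicate (dyad_id, session_no) keys")
  }
  if (anyDuplicated(dyads$dyad_id)) stop("duplicate dyad_id keys")
  tab <- merge(sync_table[, c("dyad_id", "session_no", "sync_z")],
               sessions, by = c("dyad_id", "session_no"))
  tab <- merge(tab, dyads, by = "dyad_id")
  if (nrow(tab) == 0) {
    warning("no overlapping (dyad_id, session_no) keys; table is empty")
  }
  n_in <- nrow(tab)
  tab <- tab[is.finite(tab$sync_z), , drop = FALSE]
  out <- data.frame(
    dyad_id = tab$dyad_id,
    session_no = tab$session_no,
    sync_z = tab$sync_z,
    seq_goodness = (tab$seq_goodness_pat + tab$seq_goodness_ther) / 2,
    lopf_change = tab$lopf_fu - tab$lopf_base,
    cgas_change = tab$cgas_fu - tab$cgas_base,
    lopf_base = tab$lopf_base,
    cgas_base = tab$cgas_base,
    wai_sr = tab$wai_sr
  )
  out <- out[order(out$dyad_id, out$session_no), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_in - nrow(out)
  out
}

default_predictors <- function() {
  c("lopf_change", "cgas_change", "seq_goodness", "session_no",
    "wai_sr", "lopf_base", "cgas_base")
}

build_formula <- function(response, predictors, random) {
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  if (random) rhs <- paste(rhs, "+ (1 | dyad_id)")
  stats::as.formula(paste(response, "~", rhs))
}

fit_terms <- function(data, response, predictors, random, reml = TRUE) {
  f <- build_formula(response, predictors, random)
  if (random) {
    lmerTest::lmer(f, data = data, REML = reml)
  } else {
    stats::lm(f, data = data)
  }
}

#' Random-intercept mixed model for session synchrony
#'
#' Fits a Gaussian linear mixed model with the (pseudo-standardized)
#' session synchrony as response, the given fixed-effect predictors, and a
#' random intercept per dyad, by REML. Satterthwaite degrees of freedom
#' are used for the fixed-effect t-tests.
#'
#' @param data a [build_table()] result (or any data frame with the model
#'   columns and `dyad_id`).
#' @param predictors character vector of fixed-effect terms; defaults to
#'   outcome change (LoPF, CGAS), session goodness, session number,
#'   alliance, and the baseline severities.
#' @param response response column name (default `"sync_z"`).
#' @param reml fit by REML (default) or ML.
#' @return A fitted `lmerModLmerTest` object.
#' @export
fit_sync_model <- function(data, predictors = default_predictors(),
                           response = "sync_z", reml = TRUE) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(predictors %in% names(data)))
  if (length(unique(data$dyad_id)) < 2) {
    stop("need at least 2 dyads for a random intercept")
  }
  fit_terms(data, response, predictors, random = TRUE, reml = reml)
}

model_parts <- function(fit) {
  if (inherits(fit, "lmerMod")) {
    vc <- lme4::VarCorr(fit)
    tau00 <- as.numeric(vc$dyad_id[1, 1])
    sigma2 <- attr(vc, "sc")^2
    list(is_mixed = TRUE, tau00 = tau00, sigma2 = sigma2,
         singular = lme4::isSingular(fit),
         coefs = stats::coef(summary(fit)),
         data = stats::model.frame(fit))
  } else {
    list(is_mixed = FALSE, tau00 = 0,
         sigma2 = summary(fit)$sigma^2, singular = FALSE,
         coefs = stats::coef(summary(fit)),
         data = stats::model.frame(fit))
  }
}

#' Intraclass correlation from variance components
#'
#' The dyad random-intercept share of total residual variance,
#' `tau00 / (tau00 + sigma2)`.
#'
#' @param sigma2 residual variance (> 0).
#' @param tau00 random-intercept variance (>= 0).
#' @return The ICC as a single number.
#' @export
icc <- function(sigma2, tau00) {
  stopifnot(sigma2 > 0, tau00 >= 0)
  tau00 / (tau00 + sigma2)
}

#' Marginal and conditional R-squared for a random-intercept model
#'
#' Variance-decomposition coefficients of determination:
#' `R2m = var_f / (var_f + tau00 + sigma2)` and
#' `R2c = (var_f + tau00) / (var_f + tau00 + sigma2)`, where `var_f` is
#' the variance of the fixed-effect predictions.
#'
#' @param fit a fitted `lmer` (or `lm`, for which `tau00 = 0`) model.
#' @return Named numeric vector `c(marginal =, conditional =)`.
#' @export
r2_nakagawa <- function(fit) {
  if (inherits(fit, "lmerMod")) {
    x <- lme4::getME(fit, "X")
    var_f <- stats::var(as.numeric(x %*% lme4::fixef(fit)))
    p <- model_parts(fit)
  } else {
    var_f <- stats::var(stats::fitted(fit))
    p <- model_parts(fit)
  }
  tot <- var_f + p$tau00 + p$sigma2
  c(marginal = var_f / tot, conditional = (var_f + p$tau00) / tot)
}

#' Standardized fixed-effect coefficients
#'
#' Scales each slope by `sd(predictor) / sd(response)` (standard errors
#' identically), so coefficients are comparable across predictors. The
#' intercept's standardized value is the model prediction at the predictor
#' means, expressed in response SD units relative to the response mean.
#'
#' @param fit a fitted `lmer` or `lm` model.
#' @return Data frame with `term`, `estimate`, `se`, `std_beta`, `std_se`.
#' @export
standardized_betas <- function(fit) {
  p <- model_parts(fit)
  mf <- p$data
  yname <- names(mf)[1]
  sdy <- stats::sd(mf[[yname]])
  co <- p$coefs
  terms <- rownames(co)
  out <- data.frame(term = terms, estimate = co[, "Estimate"],
                    se = co[, "Std. Error"], std_beta = NA_real_,
                    std_se = NA_real_, row.names = NULL)
  for (i in seq_along(terms)) {
    tn <- terms[i]
    if (tn == "(Intercept)") next
    if (!tn %in% names(mf)) next
    sdx <- stats::sd(mf[[tn]])
    if (sdx == 0) stop("zero-variance predictor: ", tn)
    out$std_beta[i] <- co[i, "Estimate"] * sdx / sdy
    out$std_se[i] <- co[i, "Std. Error"] * sdx / sdy
  }
  if ("(Intercept)" %in% terms) {
    xbar <- vapply(terms, function(tn) {
      if (tn == "(Intercept)") 1 else mean(mf[[tn]])
    }, numeric(1))
    mu_at_means <- sum(co[, "Estimate"] * xbar)
    i0 <- which(terms == "(Intercept)")
    out$std_beta[i0] <- (mu_at_means - mean(mf[[yname]])) / sdy
    out$std_se[i0] <- co[i0, "Std. Error"] / sdy
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

fixed_pvalues <- function(fit) {
  co <- if (inherits(fit, "lmerModLmerTest")) {
    stats::coef(summary(fit, ddf = "Satterthwaite"))
  } else {
    stats::coef(summary(fit))
  }
  pcol <- grep("^Pr\\(", colnames(co), value = TRUE)[1]
  stats::setNames(co[, pcol], rownames(co))
}

# REML likelihood-ratio test of the random intercept against the fixed
# effects-only linear model with the same design.
random_intercept_lrt <- function(data, response, predictors) {
  m1 <- fit_terms(data, response, predictors, random = TRUE, reml = TRUE)
  m0 <- fit_terms(data, response, predictors, random = FALSE)
  lr <- max(0, 2 * (as.numeric(stats::logLik(m1)) -
                      as.numeric(stats::logLik(m0, REML = TRUE))))
  list(lr = lr, p = stats::pchisq(lr, df = 1, lower.tail = FALSE))
}

#' Backward elimination of model terms
#'
#' Model reduction in the conventional order: the random intercept first,
#' by a REML likelihood-ratio test against the fixed-effects-only model,
#' then fixed effects one at a time, removing the term with the largest
#' Satterthwaite-type p-value while it exceeds `alpha`. The intercept is
#' always retained. The full elimination trace is recorded.
#'
#' @param data the modelling table (see [build_table()]).
#' @param predictors starting fixed-effect terms.
#' @param response response column (default `"sync_z"`).
#' @param alpha retention threshold (default 0.05).
#' @return List of class `sync_model_reduction`: `fit` (final model,
#'   `lmer` or `lm`), `kept` (character), `random_kept` (logical), `trace`
#'   (data frame of elimination steps).
#' @export
stepwise_eliminate <- function(data, predictors = default_predictors(),
                               response = "sync_z", alpha = 0.05) {
  stopifnot(is.data.frame(data), length(predictors) >= 1)
  trace <- list()
  rt <- random_intercept_lrt(data, response, predictors)
  random_kept <- rt$p <= alpha
  trace[[1]] <- data.frame(
    step = 1L, part = "random", term = "(1 | dyad_id)",
    statistic = rt$lr, p = rt$p,
    action = if (random_kept) "kept" else "eliminated")
  kept <- predictors
  step_no <- 1L
  repeat {
    fit <- fit_terms(data, response, kept, random = random_kept)
    pv <- fixed_pvalues(fit)
    pv <- pv[names(pv) != "(Intercept)"]
    if (length(pv) == 0 || max(pv) <= alpha) break
    worst <- names(pv)[which.max(pv)]
    step_no <- step_no + 1L
    trace[[length(trace) + 1L]] <- data.frame(
      step = step_no, part = "fixed", term = worst,
      statistic = NA_real_, p = unname(max(pv)), action = "eliminated")
    kept <- setdiff(kept, worst)
  }
  pv_final <- fixed_pvalues(fit)
  for (tn in setdiff(names(pv_final), "(Intercept)")) {
    step_no <- step_no + 1L
    trace[[length(trace) + 1L]] <- data.frame(
      step = step_no, part = "fixed", term = tn, statistic = NA_real_,
      p = unname(pv_final[tn]), action = "kept")
  }
  structure(
    list(fit = fit, kept = kept, random_kept = random_kept,
         trace = do.call(rbind, trace), alpha = alpha,
         response = response, data = data),
    class = "sync_model_reduction"
  )
}

#' @exportS3Method base::print
print.sync_model_reduction <- function(x, ...) {
  cat(sprintf(
    "<sync_model_reduction> kept: %s; random intercept %s\n",
    if (length(x$kept)) paste(x$kept, collapse = ", ") else "(none)",
    if (x$random_kept) "kept" else "eliminated"))
  invisible(x)
}

#' Full model report (fixed effects, variance components, fit indices)
#'
#' Produces the standard mixed-model report for a (possibly reduced)
#' synchrony model: per-term estimates, standard errors, standardized
#' coefficients, 95% confidence intervals, p-values with
#' Benjamini-Hochberg adjustment for the hypothesis-bearing predictors,
#' plus residual and random-intercept variances, ICC, marginal and
#' conditional R-squared, and the deviance (-2 ML log-likelihood).
#'
#' @param fit a fitted model, or a [stepwise_eliminate()] result.
#' @param hypothesis_terms terms whose p-values enter the BH family
#'   (confounders report raw p only).
#' @return List of class `sync_model_report`: `fixed` (data frame),
#'   `sigma2`, `tau00`, `icc`, `r2_marginal`, `r2_conditional`,
#'   `deviance`, `singular`, `n_obs`, `n_dyads`.
#' @export
model_report <- function(fit,
                         hypothesis_terms = c("lopf_change", "cgas_change",
                                              "seq_goodness")) {
  if (inherits(fit, "sync_model_reduction")) fit <- fit$fit
  p <- model_parts(fit)
  sb <- standardized_betas(fit)
  pv <- fixed_pvalues(fit)
  fixed <- data.frame(
    term = sb$term, estimate = sb$estimate, se = sb$se,
    std_beta = sb$std_beta, std_se = sb$std_se,
    ci_low = sb$estimate - 1.96 * sb$se,
    ci_high = sb$estimate + 1.96 * sb$se,
    std_ci_low = sb$std_beta - 1.96 * sb$std_se,
    std_ci_high = sb$std_beta + 1.96 * sb$std_se,
    p = unname(pv[sb$term]), p_adj = NA_real_
  )
  in_family <- fixed$term %in% hypothesis_terms
  if (any(in_family)) {
    fixed$p_adj[in_family] <- bh_adjust(fixed$p[in_family])
  }
  r2 <- r2_nakagawa(fit)
  dev <- if (inherits(fit, "lmerMod")) {
    as.numeric(-2 * stats::logLik(lme4::refitML(fit)))
  } else {
    as.numeric(-2 * stats::logLik(fit))
  }
  n_dyads <- if ("dyad_id" %in% names(p$data)) {
    length(unique(p$data$dyad_id))
  } else NA_integer_
  structure(
    list(fixed = fixed, sigma2 = p$sigma2, tau00 = p$tau00,
         icc = if (p$is_mixed) icc(p$sigma2, p$tau00) else 0,
         r2_marginal = unname(r2["marginal"]),
         r2_conditional = unname(r2["conditional"]),
         deviance = dev, singular = p$singular,
         n_obs = nrow(p$data), n_dyads = n_dyads),
    class = "sync_model_report"
  )
}

#' @exportS3Method base::print
print.sync_model_report <- function(x, digits = 3, ...) {
  cat("Fixed effects:\n")
  print(cbind(term = x$fixed$term,
              round(x$fixed[, -1], digits)), row.names = FALSE)
  cat(sprintf("\nsigma^2 = %.2f  tau00 = %.2f  ICC = %.2f\n",
              x$sigma2, x$tau00, x$icc))
  cat(sprintf("Marginal R2 / Conditional R2 = %.3f / %.3f\n",
              x$r2_marginal, x$r2_conditional))
  cat(sprintf("Deviance = %.3f  (%d sessions, %d dyads)%s\n",
              x$deviance, x$n_obs, x$n_dyads,
              if (x$singular) "  [singular fit]" else ""))
  invisible(x)
}
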