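# Condition (fixed) and subject (random) effects: logistic mixed model for
# catch success, linear mixed models for kinematic parameters, and the
# AIC comparison against fixed-effects-only companions.

model_comparison <- function(response, fixed, aic_mixed, aic_fixed,
                             verdict, flags = character(), n = NA_integer_,
                             aic_mixed_reml = NA_real_) {
  structure(list(response = response, fixed = fixed,
                 aic_mixed = aic_mixed, aic_fixed = aic_fixed,
                 verdict = verdict, flags = flags, n = n,
                 aic_mixed_reml = aic_mixed_reml),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s (n = %d)\n", x$response, x$n))
  cat(sprintf("  AIC mixed %.2f vs fixed-only %.2f -> subject effect %s\n",
              x$aic_mixed, x$aic_fixed,
              if (is.na(x$verdict)) "undetermined"
              else if (x$verdict) "supported" else "not supported"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  print(x$fixed, digits = 3)
  invisible(x)
}

fixed_effects_table <- function(est, se) {
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             ci_lo = unname(est - 1.96 * se), ci_hi = unname(est + 1.96 * se),
             p = unname(2 * pnorm(-abs(est / se))))
}

check_table <- function(table, needed) {
  miss <- setdiff(needed, names(table))
  if (length(miss)) {
    ck_stop(paste("trial table lacks columns:", paste(miss, collapse = ", ")),
            "catchkin_invalid_parameter")
  }
}

#' Mixed logistic model of catch success
#'
#' Models the caught/non-caught outcome with fixed effects of flight time,
#' arrival height and trial number and a random intercept per subject, and
#' compares its AIC with a fixed-effects-only logistic regression. A lower
#' AIC for the mixed model indicates inter-individual differences in
#' success.
#'
#' @param table A trial table with columns `Y` (0/1), `T`, `Z`, `trial`,
#'   `subject`.
#' @param include_trial Include trial number as a fixed effect.
#' @return A `model_comparison`.
#' @export
fit_success_glmm <- function(table, include_trial = TRUE) {
  check_table(table, c("Y", "T", "Z", "subject", if (include_trial) "trial"))
  if (length(unique(table$subject)) < 2 || length(unique(table$Y)) < 2) {
    ck_stop("need >= 2 subjects and both outcomes present", "catchkin_invalid_parameter")
  }
  rhs <- if (include_trial) "T + Z + trial" else "T + Z"
  flags <- character()
  m1 <- withCallingHandlers(
    suppressMessages(
      lme4::glmer(as.formula(paste("Y ~", rhs, "+ (1 | subject)")),
                  data = table, family = binomial())),
    warning = function(w) {
      flags <<- unique(c(flags, "glmer_warning"))
      invokeRestart("muffleWarning")
    })
  m0 <- glm(as.formula(paste("Y ~", rhs)), data = table, family = binomial())
  est <- lme4::fixef(m1)
  se <- sqrt(diag(as.matrix(vcov(m1))))
  verdict <- AIC(m1) < AIC(m0)
  if (any(abs(est) > 15)) {
    flags <- c(flags, "possible_separation")
    verdict <- NA
  }
  model_comparison("success", fixed_effects_table(est, se),
                   AIC(m1), AIC(m0), verdict, flags, nrow(table))
}

#' Linear mixed model for a kinematic parameter
#'
#' Fits `response ~ T + Z + (1 | subject)` by REML for the fixed-effect
#' estimates, and compares AICs against the fixed-effects-only linear model.
#' For the AIC comparison the mixed model is refitted by maximum likelihood,
#' since REML likelihoods are not comparable with plain least-squares fits;
#' the REML AIC is reported alongside.
#'
#' @param table Trial table; rows with missing response are dropped.
#' @param response Name of the response column.
#' @param include_trial Include trial number as a fixed effect.
#' @return A `model_comparison`.
#' @export
fit_kinematic_lmm <- function(table, response, include_trial = FALSE) {
  check_table(table, c(response, "T", "Z", "subject", if (include_trial) "trial"))
  tab <- table[!is.na(table[[response]]), , drop = FALSE]
  if (nrow(tab) < 10) ck_stop("need >= 10 non-missing response values", "catchkin_invalid_parameter")
  flags <- character()
  if (var(tab[[response]]) < 1e-12) {
    return(model_comparison(response, data.frame(), NA_real_, NA_real_, NA,
                            "degenerate_constant_response", nrow(tab)))
  }
  rhs <- if (include_trial) "T + Z + trial" else "T + Z"
  f1 <- as.formula(paste(response, "~", rhs, "+ (1 | subject)"))
  f0 <- as.formula(paste(response, "~", rhs))
  m1 <- tryCatch(
    withCallingHandlers(
      suppressMessages(lme4::lmer(f1, data = tab, REML = TRUE)),
      warning = function(w) {
        flags <<- unique(c(flags, "lmm_warning"))
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(m1)) {
    return(model_comparison(response, data.frame(), NA_real_, NA_real_, NA,
                            "lmm_fit_failure", nrow(tab)))
  }
  if (lme4::isSingular(m1)) flags <- c(flags, "singular_fit")
  m1_ml <- withCallingHandlers(
    suppressMessages(lme4::refitML(m1)),
    warning = function(w) {
      flags <<- unique(c(flags, "lmm_warning"))
      invokeRestart("muffleWarning")
    })
  m0 <- lm(f0, data = tab)
  est <- lme4::fixef(m1)
  se <- sqrt(diag(as.matrix(vcov(m1))))
  model_comparison(response, fixed_effects_table(est, se),
                   AIC(m1_ml), AIC(m0), AIC(m1_ml) < AIC(m0),
                   flags, nrow(tab), aic_mixed_reml = AIC(m1))
}

#' Per-subject regressions on practice and performance
#'
#' Ordinary least-squares regression of a kinematic parameter on trial
#' number (practice) and outcome (performance), fitted separately per
#' subject; subjects with too few trials are skipped with a note.
#'
#' @param table Trial table with `subject`, `trial`, `Y` and the response.
#' @param response Name of the response column.
#' @param min_trials Minimum rows per subject.
#' @return A data frame with one row per fitted subject: slope of the
#'   response on trial number, its standard error and p-value, and the
#'   outcome coefficient when estimable; skipped subjects are listed in the
#'   `skipped` attribute.
#' @export
per_subject_regressions <- function(table, response, min_trials = 10) {
  check_table(table, c(response, "subject", "trial", "Y"))
  out <- list(); skipped <- character()
  for (s in unique(table$subject)) {
    tab <- table[table$subject == s & !is.na(table[[response]]), , drop = FALSE]
    if (nrow(tab) < min_trials) { skipped <- c(skipped, s); next }
    with_y <- length(unique(tab$Y)) > 1
    f <- as.formula(paste(response, "~ trial", if (with_y) "+ Y" else ""))
    fit <- lm(f, data = tab)
    sm <- suppressWarnings(summary(fit))$coefficients
    out[[s]] <- data.frame(
      subject = s, n = nrow(tab),
      slope_trial = sm["trial", "Estimate"], se_trial = sm["trial", "Std. Error"],
      p_trial = sm["trial", "Pr(>|t|)"],
      slope_outcome = if (with_y) sm["Y", "Estimate"] else NA_real_,
      p_outcome = if (with_y) sm["Y", "Pr(>|t|)"] else NA_real_)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(subject = character(), n = integer(), slope_trial = numeric(),
               se_trial = numeric(), p_trial = numeric(),
               slope_outcome = numeric(), p_outcome = numeric())
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
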