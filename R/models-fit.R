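# Mixed-model fitting layer: a common interface over lmerTest/lm with Wald
# CIs, type-III partial eta squared, Nakagawa marginal/conditional R2 and
# variance components, plus the likelihood-ratio screen of random terms.

#' Partial eta squared from a type-III F statistic
#'
#' `(F * df1) / (F * df1 + df2)`; the conventional effect-size bands are
#' small ~0.01, medium ~0.06, large ~0.14.
#'
#' @param f_stat F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (> 0).
#' @return Effect size in `[0, 1]` (vectorized).
#' @export
partial_eta_squared <- function(f_stat, df1, df2) {
  stopifnot(all(f_stat >= 0, na.rm = TRUE), all(df1 > 0), all(df2 > 0))
  (f_stat * df1) / (f_stat * df1 + df2)
}

#' Declare a model specification
#'
#' @param name Registry name of the model.
#' @param formula Model formula as a string; random effects in lme4 bar
#'   syntax (a formula without bars is fit by ordinary least squares).
#' @param data_level Which model table the formula resolves against
#'   (`"item"`, `"checkin"`, `"participant_day"`, `"night"`,
#'   `"participant"`).
#' @param reml Restricted maximum likelihood? (Maximum likelihood is used
#'   when models are compared by likelihood ratio.)
#' @return A `model_spec` list.
#' @export
model_spec <- function(name, formula, data_level = "item", reml = TRUE) {
  structure(list(name = name, formula = formula, data_level = data_level,
                 reml = reml), class = "model_spec")
}

# Nakagawa variance-partition R2 for a gaussian lmer fit.
nakagawa_r2 <- function(fit) {
  mm <- stats::model.matrix(fit)
  var_f <- stats::var(as.vector(mm %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_r <- sum(vc$vcov[vc$grp != "Residual"])
  var_e <- vc$vcov[vc$grp == "Residual"]
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

# term label per coefficient (factor levels share their term's eta_p^2)
coef_terms <- function(fit) {
  mm <- stats::model.matrix(fit)
  asgn <- attr(mm, "assign")
  tt <- tryCatch(stats::terms(fit), error = function(e) NULL)
  if (is.null(asgn) || is.null(tt)) return(colnames(mm))
  labels <- attr(tt, "term.labels")
  c("(Intercept)", labels)[asgn + 1]
}

#' Fit one model of the registry
#'
#' Fits a linear mixed-effects model (REML by default, via lme4/lmerTest)
#' when the formula contains random terms, otherwise an ordinary linear
#' model. Reports per fixed effect the estimate, Wald 95% CI (normal
#' approximation for mixed fits), p-value (Wald z for mixed fits, t for lm)
#' and type-III partial eta squared (Satterthwaite F for mixed fits);
#' variance components; Nakagawa marginal/conditional R2; and singularity /
#' convergence flags. A response with zero variance short-circuits to a
#' degenerate result (all coefficients 0) rather than an error, and fits are
#' deterministic given the data.
#'
#' @param spec A [model_spec()].
#' @param data The table named by `spec$data_level` (or any data frame the
#'   formula resolves against).
#' @param effects Compute type-III effect sizes? Disable in bulk
#'   simulations where only estimates/CIs are consumed.
#' @return An `emw_fit` list: `name`, `formula`, `method`, `coefficients`
#'   tibble, `varcomp`, `r2_marginal`, `r2_conditional`, `n_obs`,
#'   `singular`, `converged`, `degenerate`, `error`.
#' @export
fit_lmm <- function(spec, data, effects = TRUE) {
  f <- stats::as.formula(spec$formula)
  environment(f) <- environment()
  res <- list(name = spec$name, formula = spec$formula, method = NA_character_,
              coefficients = NULL, varcomp = NULL,
              r2_marginal = NA_real_, r2_conditional = NA_real_,
              n_obs = NA_integer_, singular = FALSE, converged = TRUE,
              degenerate = FALSE, error = NA_character_,
              random_structure = "random intercepts as specified (nested terms coded participant:unit)")
  class(res) <- "emw_fit"

  mf <- tryCatch(
    stats::model.frame(lme4::subbars(f), data = data, na.action = stats::na.omit),
    error = function(e) e)
  if (inherits(mf, "error")) {
    res$error <- conditionMessage(mf)
    res$converged <- FALSE
    return(res)
  }
  y <- stats::model.response(mf)
  res$n_obs <- length(y)
  has_bars <- length(lme4::findbars(f)) > 0

  if (length(y) < 2 || stats::var(y) == 0) {
    # degenerate response: all betas 0, flagged
    trm <- attr(stats::terms(lme4::nobars(f)), "term.labels")
    res$method <- if (has_bars) "lmer" else "lm"
    res$degenerate <- TRUE
    res$coefficients <- tibble::tibble(
      coef = c("(Intercept)", trm), term = c("(Intercept)", trm),
      estimate = 0, se = NA_real_, statistic = NA_real_, p = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, eta_p_sq = NA_real_)
    return(res)
  }

  if (has_bars) {
    res$method <- "lmer"
    warn <- character(0)
    fit <- withCallingHandlers(
      tryCatch(lmerTest::lmer(f, data = data, REML = spec$reml,
                              na.action = stats::na.omit),
               error = function(e) e),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage"))
    if (inherits(fit, "error")) {
      res$error <- conditionMessage(fit)
      res$converged <- FALSE
      return(res)
    }
    res$singular <- lme4::isSingular(fit)
    res$converged <- !any(grepl("failed to converge", warn))

    sm <- stats::coef(summary(fit))
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
    q <- stats::qnorm(0.975)
    aov3 <- if (!effects) NULL else tryCatch(
      suppressMessages(stats::anova(fit, type = 3, ddf = "Satterthwaite")),
      error = function(e) NULL)
    eta <- rep(NA_real_, length(est))
    terms_per_coef <- coef_terms(fit)
    if (!is.null(aov3) && nrow(aov3) > 0) {
      eta_term <- partial_eta_squared(aov3[, "F value"], aov3[, "NumDF"],
                                      aov3[, "DenDF"])
      names(eta_term) <- rownames(aov3)
      eta <- unname(eta_term[terms_per_coef])
    }
    res$coefficients <- tibble::tibble(
      coef = rownames(sm), term = terms_per_coef,
      estimate = est, se = se, statistic = z, p = p,
      ci_low = est - q * se, ci_high = est + q * se, eta_p_sq = eta)
    vc <- as.data.frame(lme4::VarCorr(fit))
    res$varcomp <- tibble::tibble(group = vc$grp, variance = vc$vcov,
                                  sd = vc$sdcor)
    r2 <- nakagawa_r2(fit)
    res$r2_marginal <- r2[["marginal"]]
    res$r2_conditional <- r2[["conditional"]]
  } else {
    res$method <- "lm"
    fit <- tryCatch(stats::lm(f, data = data, na.action = stats::na.omit),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      res$error <- conditionMessage(fit)
      res$converged <- FALSE
      return(res)
    }
    sm <- stats::coef(summary(fit))
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    p <- sm[, "Pr(>|t|)"]
    dfres <- stats::df.residual(fit)
    q <- stats::qt(0.975, dfres)
    terms_per_coef <- coef_terms(fit)
    eta <- rep(NA_real_, length(est))
    aov3 <- if (!effects) NULL else
      tryCatch(car::Anova(fit, type = 3), error = function(e) NULL)
    if (!is.null(aov3)) {
      rows <- setdiff(rownames(aov3), c("(Intercept)", "Residuals"))
      eta_term <- partial_eta_squared(aov3[rows, "F value"],
                                      aov3[rows, "Df"], dfres)
      names(eta_term) <- rows
      eta <- unname(eta_term[terms_per_coef])
    }
    res$coefficients <- tibble::tibble(
      coef = rownames(sm), term = terms_per_coef,
      estimate = est, se = se, statistic = sm[, "t value"], p = p,
      ci_low = est - q * se, ci_high = est + q * se, eta_p_sq = eta)
    res$varcomp <- tibble::tibble(group = "Residual",
                                  variance = stats::sigma(fit)^2,
                                  sd = stats::sigma(fit))
    res$r2_marginal <- summary(fit)$r.squared
    res$r2_conditional <- summary(fit)$r.squared
  }
  res
}

#' @export
print.emw_fit <- function(x, ...) {
  cat(sprintf("<emw_fit> %s [%s] n=%s%s%s\n", x$name, x$method, x$n_obs,
              if (isTRUE(x$singular)) " (singular)" else "",
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  if (!is.na(x$error)) {
    cat("  error:", x$error, "\n")
    return(invisible(x))
  }
  cat(sprintf("  %s\n", x$formula))
  print(as.data.frame(x$coefficients), digits = 3)
  cat(sprintf("  R2 marginal %.3f / conditional %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Likelihood-ratio screen of random terms
#'
#' Fits the intercept-only (unconditioned) model carrying every candidate
#' random intercept and tests each term by single-term deletion
#' (`lmerTest::ranova`); terms with p < alpha are retained for the
#' downstream model specifications. Single-term deletions are nested by
#' construction; requesting a term that is not a column-resolvable grouping
#' is rejected as a non-nested comparison.
#'
#' @param data Table containing `response` and the grouping columns.
#' @param response Response column name.
#' @param terms Random-intercept grouping expressions, e.g.
#'   `c("participant_id", "participant_id:day_f")`.
#' @param alpha Retention threshold.
#' @return Tibble term, lrt, df, p, keep.
#' @export
random_effect_test <- function(data, response = "score",
                               terms = c("participant_id",
                                         "participant_id:day_f",
                                         "participant_id:item_type",
                                         "participant_id:time_of_day"),
                               alpha = 0.05) {
  cols <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0)
    stop("non-nested comparison requested: grouping column(s) not in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  fml <- stats::as.formula(paste(
    response, "~ 1 +", paste(sprintf("(1 | %s)", terms), collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = data, REML = TRUE,
                   na.action = stats::na.omit)))
  rt <- suppressMessages(suppressWarnings(lmerTest::ranova(fit)))
  rows <- rownames(rt)[-1]  # first row is <none>
  out <- tibble::tibble(
    term = sub("^\\(1 \\| (.*)\\)$", "\\1", rows),
    lrt = pmax(0, rt$LRT[-1]),
    df = rt$Df[-1],
    p = rt$`Pr(>Chisq)`[-1])
  out$keep <- !is.na(out$p) & out$p < alpha
  out
}
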