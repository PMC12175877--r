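# The model registry: the study's suite of mixed-effects analyses, fit in a
# fixed order on the model-ready tables.

# Random structure retained after the unconditioned screen: participant,
# day-within-participant and item-type-within-participant intercepts; time
# of day is treated as fixed-only downstream.
.re_item <- "(1 | participant_id) + (1 | participant_id:day_f) + (1 | participant_id:item_type)"
.re_checkin <- "(1 | participant_id) + (1 | participant_id:day_f)"

#' The registry of model specifications
#'
#' In order: M0 unconditioned (random terms only); M1 item score on MDD with
#' age, sex, item type and time of day; M2 adds MDD x time-of-day and MDD x
#' item-type interactions (diurnal variation and mood-vs-anxiety contrast in
#' cases); M3 baseline PHQ-9 convergence; M4 concurrent mood ~ anxiety; M5
#' adds the preceding check-in's anxiety (T-1); M6 mood on its own T-1..T-3
#' lags; M7 weekly stress, concurrent and one-week lagged; M7b ordinary
#' linear model of stress counts on group; M8a daily steps on MDD, M8b score
#' on daily steps; M9a TST on MDD, M9b TIB on MDD, M9c per-participant nap
#' counts on MDD (ordinary linear model), M9d per-participant CoV of TST on
#' MDD (ordinary linear model), M9e score on the previous night's TST.
#'
#' @return Named list of [model_spec()]s.
#' @export
model_registry <- function() {
  sp <- list(
    model_spec("m0_unconditioned",
               paste("score ~ 1 +", .re_item,
                     "+ (1 | participant_id:time_of_day)"),
               "item"),
    model_spec("m1_mdd_main",
               paste("score ~ mdd + age + sex + item_type + time_of_day +",
                     .re_item), "item"),
    model_spec("m2_mdd_interactions",
               paste("score ~ mdd + age + sex + item_type + time_of_day +",
                     "mdd:time_of_day + mdd:item_type +", .re_item), "item"),
    model_spec("m3_phq9_convergence",
               paste("score ~ phq9 + age + sex +", .re_item), "item"),
    model_spec("m4_mood_anxiety",
               paste("mood_score ~ anxiety_score + mdd + age + sex +",
                     .re_checkin), "checkin"),
    model_spec("m5_mood_anxiety_lag1",
               paste("mood_score ~ anxiety_score + lag1_anxiety + mdd +",
                     "age + sex +", .re_checkin), "checkin"),
    model_spec("m6_mood_autoregressive",
               paste("mood_score ~ lag1_mood + lag2_mood + lag3_mood +",
                     "mdd + age + sex +", .re_checkin), "checkin"),
    model_spec("m7_stress",
               paste("sum_score ~ stress_n + stress_n_lag + mdd + age +",
                     "sex +", .re_checkin), "checkin"),
    model_spec("m7b_stress_group_lm",
               "stress_total ~ mdd + age + sex", "participant"),
    model_spec("m8a_steps_mdd",
               paste("steps ~ mdd + age + sex + (1 | participant_id)"),
               "participant_day"),
    model_spec("m8b_score_steps",
               paste("sum_score ~ same_day_steps + mdd + age + sex +",
                     .re_checkin), "checkin"),
    model_spec("m9a_tst_mdd",
               "tst_min ~ mdd + age + sex + (1 | participant_id)", "night"),
    model_spec("m9b_tib_mdd",
               "tib_min ~ mdd + age + sex + (1 | participant_id)", "night"),
    model_spec("m9c_naps_mdd", "n_naps ~ mdd + age + sex", "participant"),
    model_spec("m9d_covtst_mdd", "cov_tst ~ mdd + age + sex", "participant"),
    model_spec("m9e_score_prev_tst",
               paste("sum_score ~ prev_night_tst + mdd + age + sex +",
                     .re_checkin), "checkin"))
  stats::setNames(sp, vapply(sp, `[[`, "", "name"))
}

#' Fit the whole model registry
#'
#' Fits every [model_registry()] specification against the model data bundle
#' ([build_model_data()]). A failed fit is reported with its flag and the
#' registry continues. The unconditioned model additionally carries the
#' likelihood-ratio screen of its random terms as `$random_test`.
#'
#' @param data Model data bundle from [build_model_data()].
#' @param specs Optional replacement list of [model_spec()]s.
#' @return Named list of `emw_fit` results (class `emw_registry`).
#' @export
run_registry <- function(data, specs = model_registry()) {
  out <- lapply(specs, function(sp) {
    d <- data[[sp$data_level]]
    if (is.null(d)) {
      res <- structure(list(
        name = sp$name, formula = sp$formula, method = NA_character_,
        coefficients = NULL, varcomp = NULL, r2_marginal = NA_real_,
        r2_conditional = NA_real_, n_obs = 0L, singular = FALSE,
        converged = FALSE, degenerate = FALSE,
        error = sprintf("input table '%s' unavailable", sp$data_level)),
        class = "emw_fit")
      return(res)
    }
    tryCatch(fit_lmm(sp, d), error = function(e) {
      structure(list(name = sp$name, formula = sp$formula,
                     method = NA_character_, coefficients = NULL,
                     varcomp = NULL, r2_marginal = NA_real_,
                     r2_conditional = NA_real_, n_obs = NA_integer_,
                     singular = FALSE, converged = FALSE, degenerate = FALSE,
                     error = conditionMessage(e)), class = "emw_fit")
    })
  })
  if ("m0_unconditioned" %in% names(out) && !is.null(data$item)) {
    out$m0_unconditioned$random_test <- tryCatch(
      random_effect_test(data$item), error = function(e) NULL)
  }
  class(out) <- "emw_registry"
  out
}

#' Flatten registry results to one long table
#'
#' @param registry An `emw_registry`.
#' @return Tibble model, coef, term, estimate, ci_low, ci_high, p, eta_p_sq,
#'   r2_marginal, r2_conditional, n_obs, method, singular, degenerate, error.
#' @export
registry_results <- function(registry) {
  rows <- lapply(registry, function(r) {
    if (is.null(r$coefficients)) {
      return(tibble::tibble(
        model = r$name, coef = NA_character_, term = NA_character_,
        estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p = NA_real_, eta_p_sq = NA_real_,
        r2_marginal = NA_real_, r2_conditional = NA_real_,
        n_obs = r$n_obs, method = r$method,
        singular = r$singular, degenerate = r$degenerate, error = r$error))
    }
    tibble::tibble(
      model = r$name, coef = r$coefficients$coef, term = r$coefficients$term,
      estimate = r$coefficients$estimate,
      ci_low = r$coefficients$ci_low, ci_high = r$coefficients$ci_high,
      p = r$coefficients$p, eta_p_sq = r$coefficients$eta_p_sq,
      r2_marginal = r$r2_marginal, r2_conditional = r$r2_conditional,
      n_obs = r$n_obs, method = r$method,
      singular = r$singular, degenerate = r$degenerate, error = r$error)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.emw_registry <- function(x, ...) {
  cat(sprintf("<emw_registry> %d fitted models\n", length(x)))
  for (r in x) {
    status <- if (!is.na(r$error)) paste("ERROR:", r$error)
    else sprintf("n=%d%s", r$n_obs, if (isTRUE(r$singular)) " singular" else "")
    cat(sprintf("  %-22s %-5s %s\n", r$name, r$method, status))
  }
  invisible(x)
}
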