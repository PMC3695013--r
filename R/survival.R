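#' Prepare time-to-conversion data from a cohort table
#'
#' Builds the survival pair (time in days, event indicator) used by the Cox
#' and Kaplan-Meier analyses. Converters contribute their time from the
#' baseline visit to the first visit with an AD diagnosis as an event;
#' stable subjects are censored at their follow-up duration, truncated at 3
#' years (`censor_days = 1095`).
#'
#' @param cohort A data frame with logical `event` (converted to AD) and
#'   `time_to_event_days` (time to first AD visit for converters, follow-up
#'   duration for censored subjects).
#' @param censor_days Truncation for censored follow-up (default 1095).
#' @return The cohort with added columns `surv_time` and `surv_event`.
#' @export
prepare_survival <- function(cohort, censor_days = 1095) {
  if (!all(c("event", "time_to_event_days") %in% names(cohort))) {
    abort("`cohort` needs `event` and `time_to_event_days` columns.")
  }
  if (any(is.na(cohort$time_to_event_days))) {
    abort("every row needs an event time or a follow-up duration.")
  }
  if (any(cohort$time_to_event_days <= 0)) {
    abort("times must be positive.")
  }
  dplyr::mutate(
    cohort,
    surv_time = ifelse(.data$event, .data$time_to_event_days,
                       pmin(.data$time_to_event_days, censor_days)),
    surv_event = as.logical(.data$event)
  )
}

#' Cox proportional-hazards regression for conversion to AD
#'
#' Univariate Cox regression of time to conversion on one baseline
#' predictor, adjusted for age, education years and sex (partial
#' likelihood, Breslow tie handling). A continuous predictor yields a
#' hazard rate per unit; a factor predictor (e.g. BrainAGE quartiles, with
#' the lowest quartile as reference, or a median split) yields hazard
#' ratios per category. The overall model chi-squared compares the full
#' model against the covariate-only null.
#'
#' @param data A data frame with `surv_time` and `surv_event` (see
#'   [prepare_survival()]).
#' @param predictor Column (unquoted) holding the main predictor.
#' @param covariates Character vector of adjustment columns present in
#'   `data` (default `chronological_age`, `education_years`, `sex`); use
#'   `character(0)` for an unadjusted fit.
#' @param level Confidence level for the hazard CIs.
#' @return An object of class `brainage_cox` with `terms` (tibble of
#'   predictor terms: hazard ratio, CI, Wald statistic, p), `overall_chisq`,
#'   `overall_df`, `overall_p`, the underlying `survival::coxph` fit, and a
#'   `flagged` note when the likelihood is monotone (complete separation).
#' @export
cox_fit <- function(data, predictor,
                    covariates = c("chronological_age", "education_years",
                                   "sex"),
                    level = 0.95) {
  pq <- enquo(predictor)
  pname <- quo_name(pq)
  if (!all(c("surv_time", "surv_event") %in% names(data))) {
    abort("run `prepare_survival()` first: need surv_time/surv_event.")
  }
  if (sum(data$surv_event) < 1L) {
    abort("no events: Cox model not estimable.")
  }
  covariates <- intersect(covariates, names(data))
  pred_vals <- eval_tidy(pq, data)
  if (is.ordered(pred_vals)) {
    # treatment contrasts against the lowest category, not polynomial ones
    pred_vals <- factor(pred_vals, ordered = FALSE)
  }
  dd <- dplyr::mutate(data, .predictor = pred_vals)
  rhs <- paste(c(".predictor", covariates), collapse = " + ")
  flagged <- NULL
  fit <- withCallingHandlers(
    survival::coxph(
      stats::as.formula(paste("survival::Surv(surv_time, surv_event) ~", rhs)),
      data = dd, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w))) {
        flagged <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }
    })
  null_fit <- if (length(covariates)) {
    survival::coxph(
      stats::as.formula(paste("survival::Surv(surv_time, surv_event) ~",
                              paste(covariates, collapse = " + "))),
      data = dd, ties = "breslow")
  } else NULL
  ll_null <- if (is.null(null_fit)) fit$loglik[1] else null_fit$loglik[2]
  sm <- summary(fit, conf.int = level)
  is_pred <- grepl("^\\.predictor", rownames(sm$coefficients))
  co <- sm$coefficients[is_pred, , drop = FALSE]
  ci <- sm$conf.int[is_pred, , drop = FALSE]
  terms <- tibble::tibble(
    term = sub("^\\.predictor", pname, rownames(co)),
    estimate = co[, "coef"],
    hazard_ratio = co[, "exp(coef)"],
    ci_low = ci[, 3], ci_high = ci[, 4],
    wald = (co[, "z"])^2,
    p.value = co[, "Pr(>|z|)"]
  )
  df_pred <- sum(is_pred)
  chisq <- 2 * (fit$loglik[2] - ll_null)
  structure(
    list(terms = terms, predictor = pname,
         overall_chisq = chisq, overall_df = df_pred,
         overall_p = stats::pchisq(chisq, df_pred, lower.tail = FALSE),
         n = fit$n, n_events = fit$nevent,
         covariates = covariates, fit = fit, flagged = flagged),
    class = "brainage_cox"
  )
}

#' @export
print.brainage_cox <- function(x, ...) {
  cat(sprintf("<cox> predictor '%s' (n=%d, %d events), overall chisq=%.2f (df=%d, p=%.3g)\n",
              x$predictor, x$n, x$n_events, x$overall_chisq, x$overall_df,
              x$overall_p))
  print(x$terms)
  if (!is.null(x$flagged)) cat("flagged:", x$flagged, "\n")
  invisible(x)
}

#' @export
tidy.brainage_cox <- function(x, ...) x$terms

#' @export
glance.brainage_cox <- function(x, ...) {
  tibble::tibble(predictor = x$predictor, n = x$n, n_events = x$n_events,
                 overall_chisq = x$overall_chisq, overall_df = x$overall_df,
                 overall_p = x$overall_p,
                 flagged = !is.null(x$flagged))
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimate of the conversion-free survival function per
#' stratum, with the cumulative AD incidence `1 - S(t)` and the
#' complementary log-log transform `log(-log(S))` used to check the
#' proportional-hazards assumption.
#'
#' @param data A data frame with `surv_time` and `surv_event`.
#' @param strata Optional column (unquoted) defining strata (e.g. BrainAGE
#'   quartiles).
#' @return An object of class `brainage_km`: tibble `curves` with columns
#'   `stratum`, `time`, `n_risk`, `n_event`, `survival`, `std_err`,
#'   `cumulative_incidence`, `cloglog`.
#' @export
kaplan_meier <- function(data, strata = NULL) {
  if (!all(c("surv_time", "surv_event") %in% names(data))) {
    abort("run `prepare_survival()` first: need surv_time/surv_event.")
  }
  sq <- enquo(strata)
  if (rlang::quo_is_null(sq)) {
    dd <- dplyr::mutate(data, .stratum = "all")
  } else {
    dd <- dplyr::mutate(data, .stratum = as.character(eval_tidy(sq, data)))
  }
  if (any(is.na(dd$.stratum)) || any(table(dd$.stratum) == 0)) {
    abort("empty or missing stratum.")
  }
  fit <- survival::survfit(
    survival::Surv(surv_time, surv_event) ~ .stratum, data = dd)
  strat <- if (is.null(fit$strata)) {
    rep(unique(dd$.stratum), length(fit$time))
  } else {
    rep(sub("^\\.stratum=", "", names(fit$strata)), fit$strata)
  }
  curves <- tibble::tibble(
    stratum = strat, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, survival = fit$surv, std_err = fit$std.err,
    cumulative_incidence = 1 - fit$surv,
    cloglog = ifelse(fit$surv > 0 & fit$surv < 1,
                     log(-log(fit$surv)), NA_real_)
  )
  structure(list(curves = curves, fit = fit), class = "brainage_km")
}

#' @export
print.brainage_km <- function(x, ...) {
  cat(sprintf("<kaplan-meier> %d strata, %d time points\n",
              length(unique(x$curves$stratum)), nrow(x$curves)))
  invisible(x)
}

#' @export
tidy.brainage_km <- function(x, ...) x$curves

#' @importFrom rlang .data
NULL
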