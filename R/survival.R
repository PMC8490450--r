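# Five-year-censored survival comparison: Kaplan-Meier estimation, log-rank
# testing and Cox proportional-hazards models over subtype labels and
# clinical covariates. Built on the survival package; Efron tie handling.

#' Administratively censor a clinical table at a horizon
#'
#' Observations with `time_days` beyond the horizon are set to the horizon
#' with `event = 0`; an event exactly at the horizon is kept (inclusive
#' boundary). Default horizon: 5 years = 1826 days.
#'
#' @param clinical data.frame with `time_days` and `event`.
#' @param horizon_days censoring horizon.
#' @return the clinical table with capped times.
#' @export
censor_at <- function(clinical, horizon_days = 1826) {
  over <- clinical$time_days > horizon_days
  clinical$event[over] <- 0L
  clinical$time_days[over] <- horizon_days
  clinical
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with the median defined by the first-crossing
#' rule: the earliest time at which the estimate drops to 0.5 or below
#' (`NA` when the curve never crosses).
#'
#' @param times event/censoring times.
#' @param events 0/1 event indicators.
#' @return list of class `km_curve`: `time`, `at_risk`, `events`, `surv`,
#'   `median_time`.
#' @export
km_estimate <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1L]] else NA_real_
  structure(list(time = fit$time, at_risk = fit$n.risk, events = fit$n.event,
                 surv = fit$surv, median_time = med),
            class = "km_curve")
}

#' k-group log-rank test
#'
#' @param times event/censoring times.
#' @param events 0/1 event indicators.
#' @param groups group labels (>= 2 groups).
#' @return list: `chisq`, `df` (k - 1), `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("log-rank needs at least 2 groups")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd_$n) - 1L
  list(chisq = sd_$chisq, df = df,
       p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling. Character/factor
#' covariates are expanded against their stated referent level (class
#' referent `HCC` by convention). A covariate constant across samples is an
#' error (non-identifiable); fewer than 5 events per parameter draws a
#' warning.
#'
#' @param clinical data.frame with `time_days`, `event` and the covariate
#'   columns.
#' @param covariates covariate column names to include.
#' @param referents named list/vector mapping covariate names to referent
#'   levels for categorical covariates.
#' @return list of class `cox_result`: `table` (per expanded term:
#'   `hazard_ratio`, `se_log_hr`, `p_value`, `ci_lower`, `ci_upper`),
#'   `fit` (the coxph object), `covariates`, `referents`.
#' @export
cox_fit <- function(clinical, covariates, referents = list(class = "HCC")) {
  missing <- setdiff(covariates, colnames(clinical))
  if (length(missing)) stop("covariate(s) absent: ", paste(missing, collapse = ", "))
  dat <- clinical[, c("time_days", "event", covariates), drop = FALSE]
  for (cv in covariates) {
    v <- dat[[cv]]
    if (length(unique(v)) < 2L)
      stop("covariate '", cv, "' is constant across samples")
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      if (cv %in% names(referents)) {
        if (!referents[[cv]] %in% levels(v))
          stop("referent level '", referents[[cv]], "' absent from '", cv, "'")
        v <- stats::relevel(v, ref = referents[[cv]])
      }
      dat[[cv]] <- v
    }
  }
  fml <- stats::as.formula(paste("survival::Surv(time_days, event) ~",
                                 paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  n_par <- length(stats::coef(fit))
  n_events <- sum(dat$event)
  if (n_events < 5L * n_par)
    warning("only ", n_events, " events for ", n_par,
            " parameters (< 5 events per parameter)")
  sm <- summary(fit)
  tab <- data.frame(term = rownames(sm$coefficients),
                    hazard_ratio = sm$coefficients[, "exp(coef)"],
                    se_log_hr = sm$coefficients[, "se(coef)"],
                    p_value = sm$coefficients[, "Pr(>|z|)"],
                    ci_lower = sm$conf.int[, "lower .95"],
                    ci_upper = sm$conf.int[, "upper .95"],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, fit = fit, covariates = covariates,
                 referents = referents),
            class = "cox_result")
}
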