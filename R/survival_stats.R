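# Kaplan-Meier estimation, log-rank comparison, and Cox proportional-
# hazards fits for stratified cohorts. Backed by the survival package;
# results are repackaged into plain tables for the pipeline writers.

#' Kaplan-Meier product-limit estimate
#'
#' Events at a time precede censorings at the same time (standard
#' convention). The median is the earliest time at which the survival
#' probability drops to 0.5 or below, NA if never reached.
#'
#' @param time non-negative follow-up times (months).
#' @param event logical/0-1 event indicators.
#' @return list of class `"km_curve"`: `time`, `surv`, `n_risk`, `n_event`,
#'   `n_censor`, `median`.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0, na.rm = TRUE)) {
    abort_icb("negative survival time", "icb_validation_error")
  }
  keep <- !is.na(time) & !is.na(event)
  if (!sum(keep)) abort_icb("no usable samples", "icb_validation_error")
  fit <- survival::survfit(survival::Surv(time[keep], as.numeric(event[keep])) ~ 1)
  # earliest time at which S drops to 0.5 or below (no interpolation)
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else NA_real_
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 median = med, n = sum(keep), n_excluded = sum(!keep)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s\n",
              x$n, sum(x$n_event),
              ifelse(is.na(x$median), "not reached", format(x$median))))
  invisible(x)
}

#' Log-rank test across strata
#'
#' Standard (unweighted) log-rank chi-squared with k - 1 degrees of
#' freedom; two-sided p.
#'
#' @param time,event survival outcome vectors.
#' @param strata per-sample stratum labels (>= 2 distinct).
#' @return an `"icb_test"` (method `"logrank"`, statistic = chi-squared).
#' @export
logrank_test <- function(time, event, strata) {
  keep <- !is.na(time) & !is.na(event) & !is.na(strata)
  time <- time[keep]; event <- as.numeric(event[keep]); strata <- strata[keep]
  k <- length(unique(strata))
  if (k < 2L) abort_icb("log-rank needs >= 2 strata", "icb_validation_error")
  sd <- survival::survdiff(survival::Surv(time, event) ~ strata)
  p <- stats::pchisq(sd$chisq, df = k - 1L, lower.tail = FALSE)
  .as_test_result("logrank", unname(sd$chisq), p)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling; hazard ratios with Wald
#' 95% confidence intervals and p-values. Non-convergence or a monotone
#' likelihood (infinite coefficient) is flagged via the `converged`
#' attribute.
#'
#' @param time,event survival outcome vectors.
#' @param covariates data.frame of covariates (numeric, logical, or
#'   factor/character).
#' @param ties tie-handling method passed to [survival::coxph()].
#' @return data.frame (term, coef, hr, ci_low, ci_high, se, p) with
#'   attributes `converged` and `n`.
#' @export
cox_fit <- function(time, event, covariates, ties = "efron") {
  covariates <- as.data.frame(covariates)
  keep <- !is.na(time) & !is.na(event) & stats::complete.cases(covariates)
  if (sum(keep) < 2L || sum(as.numeric(event[keep])) < 2L) {
    abort_icb("Cox fit needs >= 2 events", "icb_validation_error")
  }
  dat <- covariates[keep, , drop = FALSE]
  constant <- vapply(dat, function(v) length(unique(v)) < 2L, logical(1L))
  if (any(constant)) {
    abort_icb(sprintf("constant covariate(s): %s",
                      paste(names(dat)[constant], collapse = ", ")),
              "icb_validation_error")
  }
  dat$.time <- time[keep]
  dat$.event <- as.numeric(event[keep])
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat, ties = ties)
  )
  co <- summary(fit)$coefficients
  ci <- summary(fit)$conf.int
  out <- data.frame(term = rownames(co), coef = co[, "coef"],
                    hr = co[, "exp(coef)"],
                    ci_low = ci[, "lower .95"], ci_high = ci[, "upper .95"],
                    se = co[, "se(coef)"], p = co[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  monotone <- any(abs(co[, "coef"]) > 15) || any(!is.finite(co[, "se(coef)"]))
  attr(out, "converged") <- is.null(fit$info) && !monotone
  if (monotone) warn_icb("monotone likelihood suspected in Cox fit")
  attr(out, "n") <- sum(keep)
  attr(out, "n_excluded") <- sum(!keep)
  out
}
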