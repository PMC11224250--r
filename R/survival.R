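## Survival layer: Kaplan-Meier, log-rank, Cox hazard ratios, and the
## 4-category combination of model strata with clinical metrics.

#' Kaplan-Meier estimate with risk table
#'
#' Product-limit estimator of the survival function, computed with
#' `survival::survfit`.  The returned step function starts at S(0) = 1,
#' is non-increasing, and drops only at event times.
#'
#' @param time follow-up times (months).
#' @param event event indicator (1 = progression/death, 0 = censored).
#' @return List with `time`, `surv`, `n_risk`, `n_event`, and `S`, a
#'   step function of time.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  S <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, S = S)
}

#' k-group log-rank test
#'
#' Standard log-rank chi-square statistic with `k - 1` degrees of
#' freedom, computed with `survival::survdiff`.
#'
#' @param time follow-up times.
#' @param event event indicators.
#' @param group group labels (factor or character; `k >= 2` non-empty
#'   levels).
#' @return List with `statistic`, `df`, `p`, `stars`.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("log-rank test needs at least two groups")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1
  p <- stats::pchisq(sd_$chisq, df = df, lower.tail = FALSE)
  list(statistic = unname(sd_$chisq), df = df, p = p, stars = p_stars(p))
}

#' Significance star coding
#'
#' The conventional star coding of raw log-rank p-values:
#' `*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001, `****` p <= 0.0001.
#'
#' @param p p-value(s).
#' @return Character vector of star codes (`"ns"` when p > 0.05).
#' @export
p_stars <- function(p) {
  vapply(p, function(x) {
    if (x <= 1e-4) "****" else if (x <= 1e-3) "***"
    else if (x <= 0.01) "**" else if (x <= 0.05) "*" else "ns"
  }, character(1))
}

#' Univariable Cox hazard ratio with 95% confidence interval
#'
#' Partial-likelihood estimate (Efron tie handling, appropriate for
#' month-resolution times) with a normal-approximation interval on the
#' log hazard ratio.  Monotone-likelihood (complete separation) is
#' flagged and the interval reported as unbounded.
#'
#' @param time follow-up times.
#' @param event event indicators.
#' @param indicator binary (logical or 0/1) group indicator; the hazard
#'   ratio is for `indicator == TRUE` versus the rest.
#' @return List with `hr`, `ci` (length 2), `p`, `separated` flag.
#' @export
cox_hr <- function(time, event, indicator) {
  indicator <- as.logical(indicator)
  if (length(unique(indicator)) < 2) stop("indicator must have both levels")
  if (sum(event) < 1) stop("no events")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ indicator,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  separated <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se) || se > 50
  ci <- if (separated) c(0, Inf) else exp(beta + c(-1.96, 1.96) * se)
  p <- if (separated) NA_real_ else
    2 * stats::pnorm(-abs(beta / se))
  list(hr = exp(beta), ci = ci, p = p, separated = separated)
}

#' Combine a model stratum with a clinical prognostic flag
#'
#' Assigns each patient to one of four categories: (1) good prognostic
#' metric with neither AA nor PP signalling; (2) good metric with one or
#' more of AA/PP; (3) poor metric without combined AAPP signalling;
#' (4) poor metric with AAPP signalling.
#'
#' @param model_group character vector in `c("AAPP", "AA_or_PP",
#'   "Other")`.
#' @param poor_flag logical vector; `TRUE` = poor prognostic metric
#'   (e.g. IPI 4-5, stage 4, poor genetic cluster, prior treatment).
#' @return Integer vector 1-4 with a descriptive factor in attribute
#'   `label`; returned as an ordered factor.
#' @export
combine_strata <- function(model_group, poor_flag) {
  stopifnot(length(model_group) == length(poor_flag),
            all(model_group %in% c("AAPP", "AA_or_PP", "Other")))
  poor_flag <- as.logical(poor_flag)
  cat_ <- ifelse(!poor_flag & model_group == "Other", 1L,
          ifelse(!poor_flag, 2L,
          ifelse(model_group != "AAPP", 3L, 4L)))
  labels <- c("good+neither", "good+AA/PP", "poor+notAAPP", "poor+AAPP")
  factor(labels[cat_], levels = labels, ordered = TRUE)
}
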