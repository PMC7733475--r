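#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function; at tied times events
#' precede censorings (the standard convention).
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators (1 = event observed).
#' @return list of class `km_curve`: `time` (distinct times), `surv`
#'   (step values), `n_risk`, `n_event`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  if (any(times < 0)) stop("negative time(s)")
  stopifnot(length(times) == length(events), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event),
            class = "km_curve")
}

#' Mantel-Cox log-rank test for two groups
#'
#' Chi-square statistic from the observed-minus-expected event counts with
#' hypergeometric variance at each distinct event time; p from the
#' chi-square distribution with 1 df.
#'
#' @param times_a,events_a follow-up and indicators, group A.
#' @param times_b,events_b follow-up and indicators, group B.
#' @return list: `chi2`, `p`, `observed` and `expected` (length-2, A then B).
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (sum(events_a) + sum(events_b) == 0)
    stop("no events in either group: log-rank undefined")
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- rep(c(0L, 1L), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chi2 <- sd$chisq
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Cox proportional-hazards fit
#'
#' Multivariate Cox regression by Newton-Raphson maximization of the partial
#' likelihood with Efron tie correction (Breslow selectable). Constant
#' covariate columns are dropped with a warning. Wraps the `survival`
#' package's fitter and reports per-covariate Wald tests.
#'
#' @param times,events follow-up and 0/1 indicators.
#' @param covariates data.frame or matrix of covariates (numeric or factor).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param max_iter,tol Newton iteration controls.
#' @return list of class `cox_fit`: `coef`, `se`, `hr`, `p` (per covariate),
#'   `loglik`, `score_chi2` (global score test at beta = 0), `iterations`,
#'   `converged`, `dropped` (names of constant columns removed).
#' @export
cox_ph_fit <- function(times, events, covariates, ties = c("efron", "breslow"),
                       max_iter = 50L, tol = 1e-9) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  stopifnot(length(times) == length(events), nrow(covariates) == length(times))
  keep <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) > 1,
                 logical(1))
  dropped <- names(covariates)[!keep]
  if (length(dropped) > 0)
    warning("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
  covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0) stop("no non-constant covariates remain")

  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties,
                         control = survival::coxph.control(iter.max = max_iter,
                                                           eps = tol))
  sfit <- summary(fit)
  structure(list(coef = stats::coef(fit),
                 se = sfit$coefficients[, "se(coef)"],
                 hr = exp(stats::coef(fit)),
                 p = sfit$coefficients[, "Pr(>|z|)"],
                 loglik = fit$loglik[2],
                 score_chi2 = unname(sfit$sctest["test"]),
                 iterations = fit$iter,
                 converged = fit$iter < max_iter,
                 dropped = dropped),
            class = "cox_fit")
}

#' Maximally selected survival cutpoint for a continuous marker
#'
#' Scans candidate cutpoints (midpoints between consecutive distinct order
#' statistics leaving at least `minprop` of the samples on each side) and
#' returns the one maximizing the absolute standardized log-rank statistic
#' between the resulting high/low groups.
#'
#' The log-rank p-value computed after this maximization is strongly
#' anti-conservative (the cut was chosen to maximize the very statistic
#' being tested); it is returned as `p_logrank` for screening with
#' subsequent multiple-testing adjustment, with that caveat.
#'
#' @param marker numeric marker (e.g. an event's PSI or a gene's expression).
#' @param times,events follow-up and 0/1 indicators.
#' @param minprop minimum fraction of samples in each group (default 0.1).
#' @return list of class `cutpoint_result`: `cutpoint`, `statistic` (signed:
#'   positive when the high group has more events than expected), `n_high`,
#'   `n_low`, `labels` (`"high"`/`"low"` per sample), `p_logrank`.
#' @export
optimal_cutpoint <- function(marker, times, events, minprop = 0.1) {
  stopifnot(length(marker) == length(times), length(times) == length(events))
  if (length(unique(marker)) < 2) stop("marker must have >= 2 distinct values")
  n <- length(marker)
  minn <- max(1L, ceiling(minprop * n))
  ord <- order(marker)
  sorted <- marker[ord]
  cut_after <- seq(minn, n - minn)
  cut_after <- cut_after[sorted[cut_after] < sorted[cut_after + 1]]
  if (length(cut_after) == 0) stop("no feasible cutpoint under minprop")
  cands <- (sorted[cut_after] + sorted[cut_after + 1]) / 2

  best <- NULL
  for (cp in cands) {
    hi <- marker > cp
    if (sum(events[hi]) + sum(events[!hi]) == 0) next
    sd <- survival::survdiff(survival::Surv(times, events) ~ hi)
    stat <- sign(sd$obs[2] - sd$exp[2]) * sqrt(sd$chisq)
    if (is.null(best) || abs(stat) > abs(best$statistic)) {
      best <- list(cutpoint = cp, statistic = stat, chi2 = sd$chisq)
    }
  }
  if (is.null(best)) stop("no candidate cut with any events")
  hi <- marker > best$cutpoint
  structure(list(cutpoint = best$cutpoint,
                 statistic = best$statistic,
                 n_high = sum(hi), n_low = sum(!hi),
                 labels = ifelse(hi, "high", "low"),
                 p_logrank = stats::pchisq(best$chi2, 1, lower.tail = FALSE)),
            class = "cutpoint_result")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("cox_fit (", if (x$converged) "converged" else "NOT converged",
      ", ", x$iterations, " iterations)\n", sep = "")
  print(data.frame(coef = x$coef, hr = x$hr, se = x$se, p = x$p))
  invisible(x)
}
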