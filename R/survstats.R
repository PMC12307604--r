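# Survival and association statistics used to evaluate the atlas models.
# Kaplan-Meier, Cox and log-rank computations are delegated to the survival
# package; AUC, correlation and chi-squared are thin, explicit wrappers so
# the conventions (tie handling, continuity correction) are pinned down.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function. Subjects censored at an
#' event time are counted as at risk through that event.
#'
#' @param time follow-up times (>= 0).
#' @param event event indicator, 1 = event, 0 = censored.
#' @return a `km_curve` data.frame: time, n_risk, n_event, n_censor,
#'   survival; `S(0) = 1` and the function is a right-continuous step.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop("negative follow-up time")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability from a Kaplan-Meier curve at given times
#' @param curve a `km_curve`.
#' @param at times at which to evaluate S(t).
#' @return numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, at) {
  vapply(at, function(t) {
    i <- which(curve$time <= t)
    if (length(i) == 0) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Cox proportional-hazards fit
#'
#' Wraps `survival::coxph` (Newton-Raphson partial-likelihood maximization,
#' Efron ties by default) and returns a forest-plot-ready coefficient table
#' with hazard ratios, Wald 95% CIs on the log-HR scale and Wald p-values.
#' Non-estimable terms (e.g. constant covariates) are flagged rather than
#' silently dropped.
#'
#' @param data data.frame of covariates (factors are one-hot encoded against
#'   their first level).
#' @param time,event survival outcome.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return a `cox_fit`: data.frame (term, coef, se, z, p, hr, hr_lo, hr_hi,
#'   flagged) with attributes `loglik`, `n`, `n_events`.
#' @export
cox_fit <- function(data, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  data <- as.data.frame(data)
  df <- cbind(data.frame(.time = time, .event = event), data)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = df, ties = ties))
  s <- summary(fit)
  co <- s$coefficients
  flagged <- is.na(co[, "coef"]) | co[, "se(coef)"] > 100
  out <- data.frame(term = rownames(co),
                    coef = co[, "coef"], se = co[, "se(coef)"],
                    z = co[, "z"], p = co[, "Pr(>|z|)"],
                    hr = exp(co[, "coef"]),
                    hr_lo = exp(co[, "coef"] - 1.959964 * co[, "se(coef)"]),
                    hr_hi = exp(co[, "coef"] + 1.959964 * co[, "se(coef)"]),
                    flagged = flagged,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (any(flagged, na.rm = TRUE))
    warning("non-estimable or unstable coefficient(s): ",
            paste(out$term[flagged], collapse = ", "))
  attr(out, "loglik") <- fit$loglik[length(fit$loglik)]
  attr(out, "n") <- fit$n
  attr(out, "n_events") <- fit$nevent
  class(out) <- c("cox_fit", "data.frame")
  out
}

#' Log-rank test
#'
#' Standard two-sided log-rank test across two or more groups
#' (`survival::survdiff`).
#'
#' @param time,event survival outcome.
#' @param group group labels (>= 2 non-empty groups).
#' @return list: statistic (chi-squared), df, p.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2) stop("log-rank test needs at least 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1
  list(statistic = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Area under the ROC curve
#'
#' The Mann-Whitney probability that a random positive scores above a random
#' negative, with half credit for ties; equivalently the rank-sum AUC. Works
#' for both continuous scores and binary (categorical high/low) scores.
#'
#' @param outcome binary outcome (0/1 or two-level factor); both classes must
#'   be present.
#' @param score numeric risk score (higher = more positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(outcome, score) {
  if (is.factor(outcome) || is.character(outcome))
    outcome <- as.integer(as.factor(outcome)) - 1L
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary")
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(score)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pearson correlation with two-sided t-test
#'
#' @param x,y numeric vectors, length >= 3, non-zero variance.
#' @return list: r, p, n.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Chi-squared test of association
#'
#' Pearson chi-squared on an r x c contingency table, without continuity
#' correction by default (configurable).
#'
#' @param tab contingency table or matrix of counts.
#' @param correct apply Yates continuity correction (2x2 only).
#' @return list: statistic, df, p, expected.
#' @export
chi2_association <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column sum (expected cell count 0)")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

# Administrative censoring at a horizon (months): events after the horizon
# are treated as censored at the horizon.
truncate_horizon <- function(time, event, horizon) {
  over <- time > horizon
  list(time = pmin(time, horizon), event = ifelse(over, 0L, as.integer(event)))
}
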