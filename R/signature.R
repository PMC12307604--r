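# Derivation and application of the stability-selected prognostic CpG
# signature: risk-adjusted Cox EWAS, L1-penalized Cox stability selection
# over repeated cross-validated fits, and a linear M-value hazard score
# dichotomized at the training median.

#' Risk-adjusted Cox EWAS
#'
#' Fits one proportional-hazards model per CpG: time-to-death on the CpG
#' M-value plus the adjustment covariates (e.g. clinical risk group as a
#' categorical indicator set). Survival is administratively censored at
#' `horizon_months` before fitting, so the association targets 5-year
#' time-to-death. CpGs whose fit fails or is degenerate (constant M-value,
#' non-convergence) are flagged with `p = 1`.
#'
#' @param mvalues M-value matrix (samples x probes), complete.
#' @param time,event overall-survival outcome (months, 0/1).
#' @param covariates optional data.frame of adjustment covariates.
#' @param horizon_months administrative censoring horizon (default 60).
#' @param ties Cox tie handling, `"efron"` default.
#' @return an `ewas_result` data.frame: probe_id, coef, se, z, p, flagged;
#'   attributes `n`, `n_events`, `covariates`.
#' @export
cox_ewas <- function(mvalues, time, event, covariates = NULL,
                     horizon_months = 60, ties = "efron") {
  stopifnot(is.matrix(mvalues), nrow(mvalues) == length(time),
            length(time) == length(event))
  if (anyNA(mvalues)) stop("M-value matrix must be complete")
  tr <- truncate_horizon(time, event, horizon_months)
  if (sum(tr$event) < 10)
    stop("need at least 10 events within the horizon for a Cox EWAS")
  base <- data.frame(.time = tr$time, .event = tr$event)
  if (!is.null(covariates)) base <- cbind(base, as.data.frame(covariates))
  fml <- stats::as.formula("survival::Surv(.time, .event) ~ .")
  probes <- colnames(mvalues)
  res <- matrix(NA_real_, length(probes), 4,
                dimnames = list(probes, c("coef", "se", "z", "p")))
  flagged <- logical(length(probes))
  for (j in seq_along(probes)) {
    mj <- mvalues[, j]
    if (stats::sd(mj) < 1e-12) { flagged[j] <- TRUE; next }
    df <- cbind(base, .m = mj)
    fit <- tryCatch(
      suppressWarnings(survival::coxph(fml, data = df, ties = ties)),
      error = function(e) NULL)
    if (is.null(fit)) { flagged[j] <- TRUE; next }
    i <- match(".m", names(stats::coef(fit)))
    b <- stats::coef(fit)[i]
    se <- sqrt(diag(fit$var))[i]
    if (is.na(b) || is.na(se) || se > 100) { flagged[j] <- TRUE; next }
    res[j, ] <- c(b, se, b / se, 2 * stats::pnorm(-abs(b / se)))
  }
  res[flagged, "p"] <- 1
  out <- data.frame(probe_id = probes, res, flagged = flagged,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n") <- nrow(mvalues)
  attr(out, "n_events") <- sum(tr$event)
  attr(out, "covariates") <- if (is.null(covariates)) character() else
    colnames(as.data.frame(covariates))
  class(out) <- c("ewas_result", "data.frame")
  out
}

#' Select EWAS candidates at a significance threshold
#'
#' Probes with `p < alpha` (strict inequality), ordered by increasing p. The
#' default threshold is 1e-5.
#'
#' @param ewas an `ewas_result` from [cox_ewas()].
#' @param alpha significance threshold in (0, 1).
#' @return character vector of probe ids (may be empty, with a warning).
#' @export
select_candidates <- function(ewas, alpha = 1e-5) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  hit <- ewas$p < alpha & !ewas$flagged
  if (!any(hit)) {
    warning("no CpG passed the EWAS threshold alpha = ", alpha)
    return(character())
  }
  ewas$probe_id[hit][order(ewas$p[hit])]
}

#' Stability selection of a prognostic CpG signature
#'
#' Repeatedly fits an L1-penalized Cox model of (horizon-truncated) survival
#' on the candidate M-values. Each iteration draws a random `subsample`
#' fraction of the cohort, reshuffles its fold assignment, and picks the
#' penalty by `n_folds`-fold cross-validated partial likelihood (the
#' one-standard-error rule by default; see Details). Probes whose
#' coefficient is non-zero in at least `freq_threshold` of the iterations
#' form the signature; their final coefficients come from a joint
#' unpenalized Cox refit on the full cohort (with a light ridge fallback on
#' singularity), and the dichotomization cutoff is the median training
#' hazard score.
#'
#' @details The penalty within each iteration is chosen from a shared
#' log-spaced path computed once on the full candidate matrix. With
#' `lambda_rule = "1se"` the largest penalty within one standard error of
#' the cross-validation optimum is used, the standard parsimony rule for
#' selection-consistency; `"min"` (the CV-optimal penalty) is selectable but
#' admits many spurious candidates into the active set. The per-iteration
#' subsampling is what gives the selection frequencies their meaning: with
#' the full cohort refit every time, the active set at a given penalty is a
#' deterministic function of the data and a noise probe that sneaks in once
#' stays in every iteration, whereas under subsampling only effects stable
#' across perturbed cohorts reach high frequency.
#'
#' @param mvalues candidate M-value matrix (samples x candidate probes).
#' @param time,event overall-survival outcome.
#' @param n_iter number of cross-validation iterations (default 1000).
#' @param n_folds folds per iteration (default 10).
#' @param freq_threshold selection-frequency cutoff (default 0.95).
#' @param subsample fraction of the cohort drawn (without replacement) per
#'   iteration (default 0.8).
#' @param seed integer; subsamples and fold reshuffles are derived from it,
#'   so the whole procedure is deterministic.
#' @param horizon_months administrative censoring horizon (default 60).
#' @param lambda_rule `"1se"` (default) or `"min"`.
#' @return a `cpg_signature`: entries (probe_id, coefficient), cutoff,
#'   selection_frequencies, and fit metadata.
#' @export
stability_select <- function(mvalues, time, event, n_iter = 1000,
                             n_folds = 10, freq_threshold = 0.95,
                             subsample = 0.8, seed = 1,
                             horizon_months = 60,
                             lambda_rule = c("1se", "min")) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(is.matrix(mvalues), nrow(mvalues) == length(time))
  if (ncol(mvalues) < 2) stop("need at least 2 candidate probes")
  if (subsample <= 0 || subsample > 1) stop("subsample must lie in (0, 1]")
  tr <- truncate_horizon(time, event, horizon_months)
  if (sum(tr$event) < n_folds)
    stop("need at least as many events as folds")
  y <- survival::Surv(tr$time, tr$event)
  path <- glmnet::glmnet(mvalues, y, family = "cox", nlambda = 30,
                         lambda.min.ratio = 0.05)$lambda
  n <- nrow(mvalues)
  n_sub <- max(n_folds, floor(subsample * n))
  sel <- matrix(FALSE, n_iter, ncol(mvalues))
  set.seed(derive_seed(seed, "stability-folds"))
  for (it in seq_len(n_iter)) {
    idx <- sort(sample.int(n, n_sub))
    if (sum(tr$event[idx]) < n_folds) { next }  # degenerate draw: no selection
    foldid <- sample(rep_len(seq_len(n_folds), n_sub))
    cv <- glmnet::cv.glmnet(mvalues[idx, , drop = FALSE], y[idx, ],
                            family = "cox", foldid = foldid, lambda = path)
    s <- if (lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
    b <- as.numeric(stats::coef(cv, s = s))
    sel[it, ] <- b != 0
  }
  freq <- colMeans(sel)
  names(freq) <- colnames(mvalues)
  keep <- names(freq)[freq >= freq_threshold]
  if (length(keep) == 0)
    stop(sprintf(paste0("no probe reached selection frequency %.2f ",
                        "(max observed %.2f); consider lowering freq_threshold"),
                 freq_threshold, max(freq)))
  refit_df <- as.data.frame(mvalues[, keep, drop = FALSE])
  refit_df$.time <- tr$time; refit_df$.event <- tr$event
  fit <- tryCatch(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = refit_df),
    warning = function(w) NULL, error = function(e) NULL)
  if (is.null(fit) || anyNA(stats::coef(fit))) {
    # ridge-stabilized fallback for singular/ill-conditioned refits
    fit <- survival::coxph(
      survival::Surv(tr$time, tr$event) ~ survival::ridge(mvalues[, keep],
                                                          theta = 1e-4))
    coefs <- stats::setNames(stats::coef(fit), keep)
  } else {
    coefs <- stats::setNames(stats::coef(fit)[keep], keep)
  }
  sig <- structure(list(entries = data.frame(probe_id = keep,
                                             coefficient = as.numeric(coefs),
                                             stringsAsFactors = FALSE),
                        cutoff = NA_real_,
                        selection_frequencies = freq,
                        n_iter = n_iter, n_folds = n_folds,
                        freq_threshold = freq_threshold,
                        subsample = subsample,
                        lambda_rule = lambda_rule, seed = seed,
                        horizon_months = horizon_months),
                   class = "cpg_signature")
  sig$cutoff <- stats::median(hazard_score(sig, mvalues))
  sig
}

#' Linear hazard score of a CpG signature
#'
#' `score_s = sum_i coefficient_i * M(s, probe_i)`: the signature's linear
#' combination evaluated on a sample's M-values.
#'
#' @param signature a `cpg_signature`.
#' @param mvalues M-value matrix containing every signature probe.
#' @return named numeric vector, one score per sample.
#' @export
hazard_score <- function(signature, mvalues) {
  stopifnot(inherits(signature, "cpg_signature"))
  probes <- signature$entries$probe_id
  absent <- setdiff(probes, colnames(mvalues))
  if (length(absent))
    stop("signature probe(s) absent from matrix: ",
         paste(absent, collapse = ", "))
  drop(mvalues[, probes, drop = FALSE] %*% signature$entries$coefficient)
}

#' Dichotomize hazard scores into risk groups
#'
#' `score > cutoff` is `"high"`, `score <= cutoff` is `"low"`; at the
#' training-median cutoff this is the 50% split used to define the high and
#' low signature groups.
#'
#' @param scores numeric hazard scores.
#' @param cutoff finite threshold.
#' @return character vector of `"high"`/`"low"`.
#' @export
dichotomize <- function(scores, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  ifelse(scores > cutoff, "high", "low")
}

#' Score and group new samples with a fitted signature
#'
#' @param object a `cpg_signature`.
#' @param mvalues M-value matrix.
#' @param ... unused.
#' @return data.frame: sample_id, hazard_score, group.
#' @export
predict.cpg_signature <- function(object, mvalues, ...) {
  s <- hazard_score(object, mvalues)
  data.frame(sample_id = rownames(mvalues) %||% as.character(seq_along(s)),
             hazard_score = as.numeric(s),
             group = dichotomize(s, object$cutoff),
             stringsAsFactors = FALSE)
}

#' @export
print.cpg_signature <- function(x, ...) {
  cat(sprintf("CpG survival signature: %d probes, cutoff %.4f\n",
              nrow(x$entries), x$cutoff))
  cat(sprintf("  stability selection: %d x %d-fold CV, frequency >= %.2f (%s rule)\n",
              x$n_iter, x$n_folds, x$freq_threshold, x$lambda_rule))
  invisible(x)
}

#' @export
coef.cpg_signature <- function(object, ...) {
  stats::setNames(object$entries$coefficient, object$entries$probe_id)
}

#' Write a signature as a JSON document
#' @param signature a `cpg_signature`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path) {
  jsonlite::write_json(
    list(probes = signature$entries$probe_id,
         coefficients = signature$entries$coefficient,
         cutoff = signature$cutoff,
         selection_frequencies = as.list(signature$selection_frequencies)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
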