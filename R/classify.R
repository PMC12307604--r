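# Gradient-boosted classifiers on the embedding coordinates, plus the
# evaluation metrics used throughout the atlas.

# The base learner is deliberately soft: shallow stumps, small learning
# rate, aggressive row/column subsampling and substantial L2. Boosted trees
# left unregularized drive their margins to saturation, which makes the
# class probabilities meaningless exactly where the confidence gate needs
# them -- in the empty space between clusters, where an ambiguous specimen
# must come out below the 50% gate rather than confidently inside one
# class's region.
.default_cv_grid <- function() {
  expand.grid(reg_alpha = c(0, 1), reg_lambda = c(10, 20),
              KEEP.OUT.ATTRS = FALSE)
}

.xgb_base_params <- function(seed) {
  list(eta = 0.02, max_depth = 2, subsample = 0.4, colsample_bytree = 0.4,
       nthread = 1, seed = seed)
}

# Cross-validated grid search shared by both classifiers. `objective` is
# "multi:softprob" (num_class set) or "binary:logistic". Returns the best
# parameter row, the pooled out-of-fold predictions and the final model
# trained on all data, serialized to raw bytes.
.xgb_cv_train <- function(feat, y, weights, objective, num_class = NULL,
                          seed = 1, nrounds = 150, cv_grid = NULL,
                          n_folds = 5) {
  grid <- cv_grid %||% .default_cv_grid()
  base <- .xgb_base_params(seed)
  set.seed(derive_seed(seed, "cv-folds"))
  folds <- stratified_folds(y, n_folds)
  n <- length(y)
  losses <- numeric(nrow(grid))
  oof_best <- NULL
  for (g in seq_len(nrow(grid))) {
    params <- c(base, list(objective = objective,
                           reg_alpha = grid$reg_alpha[g],
                           reg_lambda = grid$reg_lambda[g]))
    if (!is.null(num_class)) params$num_class <- num_class
    oof <- if (is.null(num_class)) numeric(n) else matrix(NA_real_, n, num_class)
    for (k in seq_len(n_folds)) {
      tr <- folds != k
      dtr <- xgboost::xgb.DMatrix(feat[tr, , drop = FALSE], label = y[tr],
                                  weight = weights[tr])
      fit <- xgboost::xgb.train(params = params, data = dtr, nrounds = nrounds,
                                verbose = 0)
      p <- predict(fit, xgboost::xgb.DMatrix(feat[!tr, , drop = FALSE]))
      if (is.null(num_class)) oof[!tr] <- p else oof[!tr, ] <- p
    }
    eps <- 1e-15
    losses[g] <- if (is.null(num_class)) {
      -mean(y * log(pmax(oof, eps)) + (1 - y) * log(pmax(1 - oof, eps)))
    } else {
      -mean(log(pmax(oof[cbind(seq_len(n), y + 1)], eps)))
    }
    if (g == which.min(losses[seq_len(g)])) oof_best <- oof
  }
  best <- which.min(losses)
  params <- c(base, list(objective = objective,
                         reg_alpha = grid$reg_alpha[best],
                         reg_lambda = grid$reg_lambda[best]))
  if (!is.null(num_class)) params$num_class <- num_class
  dall <- xgboost::xgb.DMatrix(feat, label = y, weight = weights)
  final <- xgboost::xgb.train(params = params, data = dall, nrounds = nrounds,
                              verbose = 0)
  list(raw = xgboost::xgb.save.raw(final), best_params = grid[best, ],
       cv_loss = losses[best], oof = oof_best)
}

#' Train the multi-class subtype classifier
#'
#' A gradient-boosted decision-tree one-vs-rest multiclass model on the
#' embedding coordinates. Hyperparameters are chosen by stratified 5-fold
#' cross-validation over a small grid of L1/L2 penalty strengths, with
#' inverse-frequency instance weights so rare subtypes carry equal class
#' weight. Cross-validated accuracy and Cohen's kappa (from the pooled
#' out-of-fold predictions at the selected configuration) are recorded on the
#' returned model.
#'
#' @param coords coordinate matrix (samples x dims), rownames = sample ids.
#' @param labels character vector of subtype labels; every represented class
#'   needs at least 2 samples.
#' @param vocabulary optional controlled label list; labels outside it are
#'   rejected. Defaults to the labels observed.
#' @param seed integer; training is deterministic given the seed.
#' @param nrounds boosting rounds (default 150).
#' @param cv_grid data.frame with columns `reg_alpha`, `reg_lambda`.
#' @return a `subtype_classifier` with elements `classes`, `cv_metrics`,
#'   `best_params` and the serialized booster.
#' @export
train_subtype <- function(coords, labels, vocabulary = NULL, seed = 1,
                          nrounds = 150, cv_grid = NULL) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  if (nrow(coords) != length(labels))
    stop("coords and labels length mismatch")
  if (!is.null(vocabulary)) {
    bad <- setdiff(labels, vocabulary)
    if (length(bad))
      stop("labels outside the controlled vocabulary: ",
           paste(unique(bad), collapse = ", "))
  }
  tab <- table(labels)
  if (any(tab < 2))
    stop("class(es) with a single sample: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  classes <- sort(names(tab))
  if (length(classes) == 1) {
    return(structure(list(classes = classes, trivial = TRUE,
                          n_dims = ncol(coords), seed = seed),
                     class = "subtype_classifier"))
  }
  y <- match(labels, classes) - 1L
  w <- as.numeric(length(labels) / (length(classes) * tab[labels]))
  fit <- .xgb_cv_train(coords, y, w, "multi:softprob",
                       num_class = length(classes), seed = seed,
                       nrounds = nrounds, cv_grid = cv_grid)
  oof_lab <- classes[max.col(fit$oof)]
  cvm <- classification_metrics(labels, oof_lab, vocabulary = classes)
  structure(list(classes = classes, trivial = FALSE, raw = fit$raw,
                 best_params = fit$best_params, n_dims = ncol(coords),
                 seed = seed,
                 cv_metrics = list(accuracy = cvm$accuracy,
                                   cohens_kappa = cvm$cohens_kappa,
                                   weighted_f1 = cvm$weighted_f1,
                                   per_class_concordance = cvm$per_class_concordance)),
            class = "subtype_classifier")
}

#' Predict subtypes with confidence gating
#'
#' Returns the full class-probability vector per sample, the top and
#' second-most-likely labels, and a confidence gate: a call is confident only
#' when the top probability reaches `confidence_cutoff` (default 0.5); below
#' it the display label is `"Not confident"`.
#'
#' @param object a `subtype_classifier`.
#' @param coords coordinate matrix with the same dimensionality as training.
#' @param confidence_cutoff gate on the maximum class probability.
#' @param ... unused.
#' @return data.frame: sample_id, top_label, second_label, confidence,
#'   confident, display_label, then one probability column per class.
#' @export
predict.subtype_classifier <- function(object, coords,
                                       confidence_cutoff = 0.5, ...) {
  coords <- as.matrix(coords)
  if (ncol(coords) != object$n_dims)
    stop(sprintf("expected %d coordinates per sample, got %d",
                 object$n_dims, ncol(coords)))
  n <- nrow(coords)
  if (isTRUE(object$trivial)) {
    probs <- matrix(1, n, 1, dimnames = list(NULL, object$classes))
  } else {
    booster <- xgboost::xgb.load.raw(object$raw)
    probs <- predict(booster, xgboost::xgb.DMatrix(coords))
    probs <- matrix(probs, nrow = n, byrow = FALSE)
    colnames(probs) <- object$classes
  }
  probs <- probs / rowSums(probs)
  top_i <- max.col(probs, ties.method = "first")
  second_i <- vapply(seq_len(n), function(i) {
    if (ncol(probs) == 1) return(NA_integer_)
    order(probs[i, ], decreasing = TRUE)[2]
  }, integer(1))
  conf <- probs[cbind(seq_len(n), top_i)]
  confident <- conf >= confidence_cutoff
  out <- data.frame(
    sample_id = rownames(coords) %||% as.character(seq_len(n)),
    top_label = object$classes[top_i],
    second_label = ifelse(is.na(second_i), NA_character_,
                          object$classes[second_i]),
    confidence = conf,
    confident = confident,
    display_label = ifelse(confident, object$classes[top_i], "Not confident"),
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(probs))
}

#' @export
print.subtype_classifier <- function(x, ...) {
  cat(sprintf("subtype classifier: %d classes on %d coordinates\n",
              length(x$classes), x$n_dims))
  if (!is.null(x$cv_metrics))
    cat(sprintf("  5-fold CV: accuracy %.3f, kappa %.3f, weighted F1 %.3f\n",
                x$cv_metrics$accuracy, x$cv_metrics$cohens_kappa,
                x$cv_metrics$weighted_f1))
  invisible(x)
}

#' Train the 5-year mortality classifier
#'
#' Binary gradient-boosted classifier of death within `horizon_months` on the
#' embedding coordinates. Training labels follow the dead/alive rule: dead if
#' the death event occurred at or before the horizon; alive if follow-up
#' reaches the horizon; samples censored before the horizon have an undefined
#' label and are excluded from training (their count is recorded), though
#' they still receive predictions at inference.
#'
#' @param coords coordinate matrix (samples x dims).
#' @param os_time overall survival time in months.
#' @param os_event event indicator, 1 = death.
#' @param horizon_months label horizon (default 60, i.e. 5 years).
#' @param seed,nrounds,cv_grid as in [train_subtype()].
#' @return a `risk_classifier` with CV metrics and the serialized booster.
#' @export
train_risk <- function(coords, os_time, os_event, horizon_months = 60,
                       seed = 1, nrounds = 150, cv_grid = NULL) {
  coords <- as.matrix(coords)
  stopifnot(length(os_time) == nrow(coords),
            length(os_event) == nrow(coords))
  if (!all(os_event %in% c(0, 1))) stop("os_event must be 0/1")
  dead <- os_event == 1 & os_time <= horizon_months
  alive <- os_time >= horizon_months
  usable <- dead | alive
  excluded <- sum(!usable)
  y <- as.integer(dead[usable])
  if (length(unique(y)) < 2 || min(table(y)) < 10)
    stop("need at least 10 samples per outcome class within the horizon")
  feat <- coords[usable, , drop = FALSE]
  tab <- table(y)
  w <- as.numeric(length(y) / (2 * tab[as.character(y)]))
  fit <- .xgb_cv_train(feat, y, w, "binary:logistic", seed = seed,
                       nrounds = nrounds, cv_grid = cv_grid)
  auc_cv <- roc_auc(y, fit$oof)
  structure(list(raw = fit$raw, best_params = fit$best_params,
                 n_dims = ncol(coords), horizon_months = horizon_months,
                 n_excluded_censored = excluded, seed = seed,
                 cv_metrics = list(auc = auc_cv, logloss = fit$cv_loss)),
            class = "risk_classifier")
}

#' Predict 5-year mortality risk
#'
#' @param object a `risk_classifier`.
#' @param coords coordinate matrix.
#' @param cutoff probability cutoff for the high/low grouping (default 0.5).
#' @param ... unused.
#' @return data.frame: sample_id, p_death_5y, group (`"high"` iff
#'   `p_death_5y >= cutoff`).
#' @export
predict.risk_classifier <- function(object, coords, cutoff = 0.5, ...) {
  coords <- as.matrix(coords)
  if (ncol(coords) != object$n_dims)
    stop(sprintf("expected %d coordinates per sample, got %d",
                 object$n_dims, ncol(coords)))
  booster <- xgboost::xgb.load.raw(object$raw)
  p <- as.numeric(predict(booster, xgboost::xgb.DMatrix(coords)))
  data.frame(sample_id = rownames(coords) %||% as.character(seq_len(nrow(coords))),
             p_death_5y = p,
             group = ifelse(p >= cutoff, "high", "low"),
             stringsAsFactors = FALSE)
}

#' @export
print.risk_classifier <- function(x, ...) {
  cat(sprintf("5-year mortality classifier on %d coordinates (horizon %d months)\n",
              x$n_dims, x$horizon_months))
  cat(sprintf("  5-fold CV AUC %.3f; %d censored-before-horizon sample(s) excluded\n",
              x$cv_metrics$auc, x$n_excluded_censored))
  invisible(x)
}

#' Multi-class evaluation metrics
#'
#' Accuracy, support-weighted F1, Cohen's kappa (chance agreement from the
#' marginal products), per-class concordance (the diagonal of the
#' row-normalized confusion matrix, i.e. per-class recall) and the normalized
#' confusion matrix itself.
#'
#' @param truth,predicted equal-length label vectors.
#' @param vocabulary optional label universe (defaults to labels observed in
#'   either vector).
#' @return list: accuracy, weighted_f1, cohens_kappa, per_class_concordance
#'   (named by class), normalized_confusion, counts.
#' @export
classification_metrics <- function(truth, predicted, vocabulary = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) == 0) stop("empty input")
  if (length(truth) != length(predicted)) stop("length mismatch")
  lev <- vocabulary %||% sort(unique(c(truth, predicted)))
  bad <- setdiff(c(truth, predicted), lev)
  if (length(bad)) stop("labels outside vocabulary: ", paste(bad, collapse = ", "))
  cm <- table(factor(truth, lev), factor(predicted, lev))
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  p_o <- acc
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  support <- rowSums(cm)
  prec <- diag(cm) / pmax(colSums(cm), 1)
  rec <- ifelse(support > 0, diag(cm) / support, NA_real_)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- support > 0
  wf1 <- sum(f1[present] * support[present]) / sum(support[present])
  norm_cm <- cm / pmax(support, 1)
  list(accuracy = acc, weighted_f1 = wf1, cohens_kappa = kappa,
       per_class_concordance = stats::setNames(as.numeric(rec), lev),
       normalized_confusion = norm_cm, counts = cm)
}
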