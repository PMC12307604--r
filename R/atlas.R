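#' Pipeline configuration
#'
#' All tunable thresholds of the training and inference pipeline in one
#' place. Defaults: probes with over 5% missing calls are dropped
#' (`missing_threshold = 0.05`); PCA outlier removal uses 2 components at 4
#' score-SD; the EWAS candidate threshold is `1e-5`; stability selection runs
#' 1000 iterations of 10-fold CV with a 0.95 selection-frequency rule; the
#' subtype confidence gate and the risk-probability cutoff both sit at 0.5;
#' survival is truncated at a 60-month horizon.
#'
#' @param missing_threshold QC missing-fraction cutoff for probes.
#' @param pca_components,pca_k_sd PCA outlier-removal parameters.
#' @param epsilon M-value clamp (see [beta_to_m()]).
#' @param ewas_alpha EWAS significance threshold.
#' @param stability_iters,stability_folds,freq_threshold stability-selection
#'   parameters.
#' @param lambda_rule penalty rule inside stability selection (`"1se"`/`"min"`).
#' @param confidence_cutoff subtype confidence gate on the top probability.
#' @param risk_cutoff probability cutoff defining the high/low risk group.
#' @param horizon_months survival horizon (5 years).
#' @param n_dims_vis,n_dims_clf embedding dimensionalities (visualization /
#'   classification).
#' @param myeloid_pattern regex on subtype labels marking myeloid (AML/MDS)
#'   classes for prognostic gating.
#' @param nrounds boosting rounds for both classifiers.
#' @return a `atlas_config` list.
#' @export
atlas_config <- function(missing_threshold = 0.05, pca_components = 2,
                         pca_k_sd = 4, epsilon = 1e-6, ewas_alpha = 1e-5,
                         stability_iters = 1000, stability_folds = 10,
                         freq_threshold = 0.95, lambda_rule = "1se",
                         confidence_cutoff = 0.5, risk_cutoff = 0.5,
                         horizon_months = 60, n_dims_vis = 2, n_dims_clf = 5,
                         myeloid_pattern = "^(AML|MDS|APL)",
                         nrounds = 150) {
  if (ewas_alpha <= 0 || ewas_alpha >= 1) stop("ewas_alpha must lie in (0, 1)")
  if (missing_threshold <= 0 || missing_threshold >= 1)
    stop("missing_threshold must lie in (0, 1)")
  if (freq_threshold <= 0 || freq_threshold > 1)
    stop("freq_threshold must lie in (0, 1]")
  structure(list(missing_threshold = missing_threshold,
                 pca_components = pca_components, pca_k_sd = pca_k_sd,
                 epsilon = epsilon, ewas_alpha = ewas_alpha,
                 stability_iters = stability_iters,
                 stability_folds = stability_folds,
                 freq_threshold = freq_threshold, lambda_rule = lambda_rule,
                 confidence_cutoff = confidence_cutoff,
                 risk_cutoff = risk_cutoff, horizon_months = horizon_months,
                 n_dims_vis = n_dims_vis, n_dims_clf = n_dims_clf,
                 myeloid_pattern = myeloid_pattern, nrounds = nrounds),
            class = "atlas_config")
}

#' Train a methylation atlas
#'
#' The full training pipeline on a beta matrix plus sample annotations:
#' QC exclusion cascade, batch-mean imputation, empirical-Bayes batch
#' correction, 2-D (visualization) and 5-D (classification) embeddings, the
#' multi-class subtype classifier, the binary 5-year mortality classifier,
#' and the Cox-EWAS / stability-selection CpG survival signature. Prognostic
#' models are trained on the myeloid subset (labels matching
#' `config$myeloid_pattern`) with available survival data. Every stage is
#' seeded from `seed`, so refitting with the same inputs is byte-identical.
#'
#' @param betas beta matrix (samples x probes, `NA` = missing).
#' @param samples sample table; needs `sample_id` and, where available,
#'   `batch`, `who2022_label`, `risk_group`, `os_time`, `os_event`.
#' @param reference a [cpg_reference()] covering (a superset of) the probes.
#' @param masks,qc_fail_samples,nonhematopoietic_samples passed to
#'   [qc_cascade()].
#' @param config an [atlas_config()].
#' @param seed master seed.
#' @return a `meth_atlas` model bundle: reference (subset to QC-surviving
#'   probes), discovery means, both embeddings, subtype model, risk model,
#'   signature, QC report and config.
#' @export
atlas_fit <- function(betas, samples, reference = NULL, masks = list(),
                      qc_fail_samples = character(),
                      nonhematopoietic_samples = character(),
                      config = atlas_config(), seed = 1) {
  stopifnot(inherits(config, "atlas_config"))
  samples <- as.data.frame(samples)
  if (!"sample_id" %in% names(samples)) stop("samples needs a sample_id column")
  if (!all(rownames(betas) %in% samples$sample_id))
    stop("every matrix row must have a sample-table entry")
  samples <- samples[match(rownames(betas), samples$sample_id), , drop = FALSE]

  qc <- qc_cascade(betas, masks = masks,
                   missing_threshold = config$missing_threshold,
                   qc_fail_samples = qc_fail_samples,
                   nonhematopoietic_samples = nonhematopoietic_samples,
                   pca = list(n_components = config$pca_components,
                              k_sd = config$pca_k_sd))
  x <- qc$matrix
  samples <- samples[match(rownames(x), samples$sample_id), , drop = FALSE]

  batch <- samples$batch %||% rep("batch_1", nrow(x))
  x <- impute_batch_mean(x, batch)
  if (length(unique(batch)) > 1) x <- combat_correct(x, batch)

  if (is.null(reference)) {
    reference <- cpg_reference(probe_id = colnames(x), chrom = "chrUn",
                               start = 10L * seq_len(ncol(x)),
                               genome_build = "unspecified")
  } else {
    keep <- reference$probe_id %in% colnames(x)
    reference <- cpg_reference(reference$probe_id[keep],
                               reference$chrom[keep], reference$start[keep],
                               attr(reference, "genome_build"))
    x <- x[, reference$probe_id, drop = FALSE]
  }
  discovery_means <- colMeans(x)

  emb_vis <- fit_embedding(x, n_dims = config$n_dims_vis,
                           seed = derive_seed(seed, "embed-vis"))
  emb_clf <- fit_embedding(x, n_dims = config$n_dims_clf,
                           seed = derive_seed(seed, "embed-clf"))

  labels <- samples$who2022_label
  labelled <- !is.na(labels)
  tab <- table(labels[labelled])
  usable_classes <- names(tab)[tab >= 2]
  train_rows <- labelled & labels %in% usable_classes
  subtype_model <- train_subtype(emb_clf$coords[train_rows, , drop = FALSE],
                                 labels[train_rows],
                                 seed = derive_seed(seed, "subtype"),
                                 nrounds = config$nrounds)

  # prognostic models are trained on every survival-annotated sample; a
  # disease-restricted design (e.g. AML only) is expressed by annotating
  # survival only for that subset
  prog_rows <- !is.na(samples$os_time %||% rep(NA_real_, nrow(x))) &
    !is.na(samples$os_event %||% rep(NA_real_, nrow(x)))

  risk_model <- NULL
  signature <- NULL
  if (sum(prog_rows) >= 50) {
    risk_model <- tryCatch(
      train_risk(emb_clf$coords[prog_rows, , drop = FALSE],
                 samples$os_time[prog_rows], samples$os_event[prog_rows],
                 horizon_months = config$horizon_months,
                 seed = derive_seed(seed, "risk"),
                 nrounds = config$nrounds),
      error = function(e) {
        warning("risk model not trained: ", conditionMessage(e)); NULL
      })
    mv <- beta_to_m(x[prog_rows, , drop = FALSE], config$epsilon)
    covars <- if (!is.null(samples$risk_group))
      data.frame(risk_group = factor(samples$risk_group[prog_rows],
                                     levels = c("low", "standard", "high")))
    ewas <- tryCatch(
      cox_ewas(mv, samples$os_time[prog_rows], samples$os_event[prog_rows],
               covariates = covars, horizon_months = config$horizon_months),
      error = function(e) {
        warning("EWAS not run: ", conditionMessage(e)); NULL
      })
    if (!is.null(ewas)) {
      cand <- suppressWarnings(select_candidates(ewas, config$ewas_alpha))
      if (length(cand) >= 2) {
        signature <- tryCatch(
          stability_select(mv[, cand, drop = FALSE],
                           samples$os_time[prog_rows],
                           samples$os_event[prog_rows],
                           n_iter = config$stability_iters,
                           n_folds = config$stability_folds,
                           freq_threshold = config$freq_threshold,
                           seed = derive_seed(seed, "stability"),
                           horizon_months = config$horizon_months,
                           lambda_rule = config$lambda_rule),
          error = function(e) {
            warning("signature not derived: ", conditionMessage(e)); NULL
          })
      } else {
        warning("fewer than 2 EWAS candidates; signature not derived")
      }
    }
  }

  structure(list(reference = reference, discovery_means = discovery_means,
                 embedding_vis = emb_vis, embedding_clf = emb_clf,
                 subtype_model = subtype_model, risk_model = risk_model,
                 signature = signature, qc_report = qc$report,
                 config = config, seed = seed,
                 n_train = nrow(x),
                 version = as.character(utils::packageVersion("methatlas"))),
            class = "meth_atlas")
}

#' Predict on new array-format samples with a trained atlas
#'
#' Aligns the new beta matrix to the atlas reference (absent probes and
#' missing calls are imputed from the discovery means), maps the samples into
#' the classification embedding and applies the requested models. Prognostic
#' outputs are reported for every sample; the per-sample confidence/myeloid
#' gate applied to single specimens lives in [classify_specimen()].
#'
#' @param object a `meth_atlas`.
#' @param newdata beta matrix (samples x probes).
#' @param type `"all"` (default), `"subtype"`, `"risk"` or `"signature"`.
#' @param ... unused.
#' @return data.frame keyed by sample_id with the requested predictions.
#' @export
predict.meth_atlas <- function(object, newdata,
                               type = c("all", "subtype", "risk", "signature"),
                               ...) {
  type <- match.arg(type)
  if (nrow(newdata) == 0) stop("no samples to predict")
  x <- align_to_reference(newdata, object$reference, object$discovery_means)
  coords <- predict(object$embedding_clf, x)
  out <- data.frame(sample_id = rownames(x), stringsAsFactors = FALSE)
  if (type %in% c("all", "subtype")) {
    sub <- predict(object$subtype_model, coords,
                   confidence_cutoff = object$config$confidence_cutoff)
    out <- cbind(out, sub[, setdiff(names(sub), "sample_id")])
  }
  if (type %in% c("all", "risk")) {
    if (is.null(object$risk_model)) {
      if (type == "risk") stop("component absent: no risk model in this atlas")
    } else {
      r <- predict(object$risk_model, coords, cutoff = object$config$risk_cutoff)
      out$p_death_5y <- r$p_death_5y
      out$risk_group <- r$group
    }
  }
  if (type %in% c("all", "signature")) {
    if (is.null(object$signature)) {
      if (type == "signature")
        stop("component absent: no CpG signature in this atlas")
    } else {
      mv <- beta_to_m(x, object$config$epsilon)
      s <- predict(object$signature, mv)
      out$hazard_score <- s$hazard_score
      out$signature_group <- s$group
    }
  }
  out
}

#' @export
print.meth_atlas <- function(x, ...) {
  cat("Methylation atlas model bundle\n")
  cat(sprintf("  reference: %d CpG loci (%s)\n", nrow(x$reference),
              attr(x$reference, "genome_build")))
  cat(sprintf("  trained on %d samples; embeddings: %d-D (vis), %d-D (clf)\n",
              x$n_train, x$embedding_vis$n_dims, x$embedding_clf$n_dims))
  cat(sprintf("  subtype classes: %d; risk model: %s; signature: %s\n",
              length(x$subtype_model$classes),
              if (is.null(x$risk_model)) "absent" else "present",
              if (is.null(x$signature)) "absent" else
                sprintf("%d CpGs", nrow(x$signature$entries))))
  invisible(x)
}

#' @export
summary.meth_atlas <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$qc_report)
  if (!is.null(object$subtype_model$cv_metrics)) {
    cat("\n"); print(object$subtype_model)
  }
  if (!is.null(object$risk_model)) { cat("\n"); print(object$risk_model) }
  if (!is.null(object$signature)) { cat("\n"); print(object$signature) }
  invisible(object)
}

#' @export
coef.meth_atlas <- function(object, ...) {
  if (is.null(object$signature))
    stop("component absent: no CpG signature in this atlas")
  coef(object$signature)
}

#' Scatter plot of the 2-D atlas embedding
#' @param x a `meth_atlas`.
#' @param labels optional per-training-sample labels to color by.
#' @param ... passed to [graphics::plot()].
#' @export
plot.meth_atlas <- function(x, labels = NULL, ...) {
  co <- x$embedding_vis$coords
  col <- if (is.null(labels)) 1 else as.integer(as.factor(labels))
  graphics::plot(co[, 1], co[, 2], col = col, pch = 16,
                 xlab = "dim1", ylab = "dim2",
                 main = "methylome atlas (2-D embedding)", ...)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(as.factor(labels)),
                     col = seq_along(levels(as.factor(labels))), pch = 16,
                     cex = 0.7)
  invisible(x)
}
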