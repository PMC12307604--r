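#' Quality-control exclusion cascade
#'
#' Applies the preprocessing exclusions in a fixed order; the per-stage counts
#' are order-dependent, so the order is part of the contract:
#' \enumerate{
#'   \item drop probes on the sex-linked / non-CpG mask;
#'   \item drop probes on the unreliable-probe mask;
#'   \item drop samples that failed upstream array QC (supplied as a list --
#'     detection p-values are computed at IDAT level, outside this package);
#'   \item drop probes whose missing fraction exceeds `missing_threshold`;
#'   \item drop listed non-hematopoietic samples;
#'   \item drop PCA outlier samples (see [pca_outliers()]).
#' }
#'
#' @param x beta matrix (samples x probes, `NA` = missing).
#' @param masks list with optional character elements `sex_noncpg` and
#'   `unreliable` (probe ids).
#' @param missing_threshold drop probes with missing fraction strictly above
#'   this (default 0.05, i.e. over 5 percent missing).
#' @param qc_fail_samples,nonhematopoietic_samples character sample-id lists.
#' @param pca `NULL` to skip outlier removal, or a list with `n_components`
#'   (default 2) and `k_sd` (default 4) passed to [pca_outliers()].
#' @return list with elements `matrix` (filtered beta matrix) and `report`
#'   (a `qc_report`: per-stage removal counts, stage log, final dimensions).
#' @export
qc_cascade <- function(x, masks = list(), missing_threshold = 0.05,
                       qc_fail_samples = character(),
                       nonhematopoietic_samples = character(),
                       pca = list(n_components = 2, k_sd = 4)) {
  validate_beta_matrix(x)
  if (!is.numeric(missing_threshold) || missing_threshold <= 0 ||
      missing_threshold >= 1)
    stop("missing_threshold must lie in (0, 1)")
  removed <- c(sex_linked_noncpg = 0L, unreliable = 0L, sample_qc_fail = 0L,
               high_missing_cpgs = 0L, nonhematopoietic = 0L, pca_outliers = 0L)
  log <- character()
  note <- function(stage, what, n) {
    log <<- c(log, sprintf("%s: removed %d %s", stage, n, what))
  }

  drop_probes <- function(m, ids) m[, !(colnames(m) %in% ids), drop = FALSE]
  drop_samples <- function(m, ids, stage) {
    unknown <- setdiff(ids, rownames(m))
    if (length(unknown))
      warning(sprintf("%s: %d listed sample id(s) not present (e.g. '%s')",
                      stage, length(unknown), unknown[1]))
    m[!(rownames(m) %in% ids), , drop = FALSE]
  }

  ids <- intersect(masks$sex_noncpg %||% character(), colnames(x))
  removed["sex_linked_noncpg"] <- length(ids)
  x <- drop_probes(x, ids)
  note("sex_linked_noncpg", "probes", length(ids))

  ids <- intersect(masks$unreliable %||% character(), colnames(x))
  removed["unreliable"] <- length(ids)
  x <- drop_probes(x, ids)
  note("unreliable", "probes", length(ids))

  n0 <- nrow(x)
  x <- drop_samples(x, qc_fail_samples, "sample_qc_fail")
  removed["sample_qc_fail"] <- n0 - nrow(x)
  note("sample_qc_fail", "samples", n0 - nrow(x))

  frac <- colMeans(is.na(x))
  high <- frac > missing_threshold
  removed["high_missing_cpgs"] <- sum(high)
  x <- x[, !high, drop = FALSE]
  note("high_missing_cpgs", "probes", sum(high))

  n0 <- nrow(x)
  x <- drop_samples(x, nonhematopoietic_samples, "nonhematopoietic")
  removed["nonhematopoietic"] <- n0 - nrow(x)
  note("nonhematopoietic", "samples", n0 - nrow(x))

  if (!is.null(pca) && nrow(x) > (pca$n_components %||% 2)) {
    out <- pca_outliers(x, n_components = pca$n_components %||% 2,
                        k_sd = pca$k_sd %||% 4)
    removed["pca_outliers"] <- length(out)
    x <- x[!(rownames(x) %in% out), , drop = FALSE]
    note("pca_outliers", "samples", length(out))
  } else {
    note("pca_outliers", "samples (skipped)", 0L)
  }

  report <- structure(list(removed = removed, log = log,
                           dim = dim(x),
                           missing_threshold = missing_threshold),
                      class = "qc_report")
  list(matrix = x, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC cascade report\n")
  for (line in x$log) cat(" -", line, "\n")
  cat(sprintf("final matrix: %d samples x %d probes\n", x$dim[1], x$dim[2]))
  invisible(x)
}

#' PCA-based sample outlier detection
#'
#' Projects probe-centered beta values (missing entries mean-filled for the
#' projection only) onto the top principal components and flags samples whose
#' Mahalanobis-style distance in score space -- each component standardized by
#' its score standard deviation -- exceeds `k_sd`.
#'
#' @param x beta matrix (samples x probes).
#' @param n_components number of leading components (default 2).
#' @param k_sd distance threshold in score standard deviations (default 4).
#' @return character vector of outlying sample ids (possibly empty).
#' @export
pca_outliers <- function(x, n_components = 2, k_sd = 4) {
  validate_beta_matrix(x)
  if (n_components < 1) stop("n_components must be >= 1")
  if (nrow(x) <= n_components)
    stop("need more samples than components for PCA outlier detection")
  m <- x
  if (anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    mu[is.na(mu)] <- 0
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2]]
  }
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = n_components)
  sc <- p$x
  sds <- apply(sc, 2, stats::sd)
  z <- sweep(sc, 2, ifelse(sds > 0, sds, Inf), "/")
  d <- sqrt(rowSums(z^2))
  rownames(x)[d > k_sd]
}

#' Batch-mean imputation of missing beta values
#'
#' Each missing entry is replaced by the mean of the observed values for the
#' same probe within the same batch; if a (batch, probe) cell has no observed
#' value at all, the global probe mean is used instead (counted in the
#' `global_fallbacks` attribute). Observed entries are never altered.
#'
#' @param x beta matrix with missing values.
#' @param batch character/factor of length `nrow(x)`.
#' @return complete beta matrix; attribute `global_fallbacks` counts cells
#'   imputed from the global probe mean.
#' @export
impute_batch_mean <- function(x, batch) {
  validate_beta_matrix(x)
  if (length(batch) != nrow(x)) stop("batch must have one entry per sample")
  if (!anyNA(x)) {
    attr(x, "global_fallbacks") <- 0L
    return(x)
  }
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing))
    stop("probe(s) missing in all samples (should have been removed by QC): ",
         paste(utils::head(colnames(x)[all_missing], 3), collapse = ", "))
  global <- colMeans(x, na.rm = TRUE)
  fallbacks <- 0L
  batch <- as.character(batch)
  for (b in unique(batch)) {
    rows <- batch == b
    sub <- x[rows, , drop = FALSE]
    nm <- colSums(!is.na(sub))
    bm <- colMeans(sub, na.rm = TRUE)
    none <- nm == 0
    bm[none] <- global[none]
    idx <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(idx)) {
      fallbacks <- fallbacks + sum(none[idx[, 2]])
      sub[idx] <- bm[idx[, 2]]
      x[rows, ] <- sub
    }
  }
  attr(x, "global_fallbacks") <- sum(fallbacks)
  x
}
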