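#' Fit the methylome embedding
#'
#' Compresses a complete beta matrix to `n_dims` coordinates: 2 for
#' visualization, 5 as the feature space of the subtype and risk classifiers.
#' The backend is principal-component analysis of the probe-centered beta
#' matrix, which gives a deterministic fit, an exact linear out-of-sample
#' transform (a training sample maps exactly onto its stored coordinate), and
#' preserves the cluster geometry the downstream classifiers rely on.
#' Component signs are normalized (largest-magnitude loading positive) so
#' fits are reproducible across platforms.
#'
#' @param x complete beta matrix (samples x probes).
#' @param n_dims number of coordinates (default 5).
#' @param seed recorded for provenance; the fit itself is deterministic.
#' @return a `meth_embedding`: probe order, centering vector, loading matrix,
#'   training coordinates, per-component variance.
#' @export
fit_embedding <- function(x, n_dims = 5, seed = 1) {
  validate_beta_matrix(x)
  if (anyNA(x))
    stop("embedding requires a complete matrix; impute missing values first")
  if (nrow(x) < 10 * n_dims)
    stop(sprintf("need at least %d samples to fit a %d-dimensional embedding",
                 10 * n_dims, n_dims))
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_dims)
  rot <- p$rotation
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    k <- which.max(abs(rot[, j]))
    sign(rot[k, j]) < 0
  }, logical(1))
  rot[, flip] <- -rot[, flip]
  coords <- p$x
  coords[, flip] <- -coords[, flip]
  colnames(coords) <- colnames(rot) <- paste0("dim", seq_len(n_dims))
  structure(list(n_dims = as.integer(n_dims), seed = seed,
                 probes = colnames(x), center = p$center,
                 rotation = rot, coords = coords, sdev = p$sdev[seq_len(n_dims)]),
            class = "meth_embedding")
}

#' Map new samples onto a fitted embedding
#'
#' @param object a `meth_embedding` from [fit_embedding()].
#' @param newdata complete beta matrix whose columns match the training probe
#'   order exactly.
#' @param ... unused.
#' @return coordinate matrix, one row per sample, columns `dim1..dimd`.
#' @export
predict.meth_embedding <- function(object, newdata, ...) {
  if (nrow(newdata) == 0)
    return(matrix(numeric(), 0, object$n_dims,
                  dimnames = list(NULL, paste0("dim", seq_len(object$n_dims)))))
  if (!identical(colnames(newdata), object$probes))
    stop("probe order of new samples does not match the embedding's training order")
  if (anyNA(newdata)) stop("new samples contain missing values; impute first")
  sweep(newdata, 2, object$center) %*% object$rotation
}

#' @export
print.meth_embedding <- function(x, ...) {
  cat(sprintf("methylome embedding: %d probes -> %d coordinates (%d training samples)\n",
              length(x$probes), x$n_dims, nrow(x$coords)))
  invisible(x)
}

#' Export embedding coordinates as a delimited table
#' @param object a `meth_embedding`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(object, path) {
  stopifnot(inherits(object, "meth_embedding"))
  dt <- data.table::data.table(sample_id = rownames(object$coords), object$coords)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
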