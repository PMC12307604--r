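#' Validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix with samples as rows and CpG probes
#' as columns. Row names are sample identifiers, column names are probe
#' identifiers and `NA` encodes a missing call. All non-missing entries must
#' lie in \[0, 1\].
#'
#' @param x numeric matrix, samples x probes, with unique dimnames.
#' @return `x`, invisibly, after validation.
#' @export
validate_beta_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("beta matrix must be a numeric matrix (samples x probes)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("beta matrix must carry sample ids as rownames and probe ids as colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample ids in beta matrix")
  if (anyDuplicated(colnames(x)))
    stop("duplicate probe ids in beta matrix")
  v <- x[!is.na(x)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    bad <- which(x < 0 | x > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("beta value outside [0,1] at sample '%s', probe '%s': %g",
                 rownames(x)[bad[1]], colnames(x)[bad[2]], x[bad[1], bad[2]]))
  }
  invisible(x)
}

#' Convert beta values to M-values
#'
#' The logit-scale transform `M = log2(beta / (1 - beta))`, with beta clamped
#' to `[epsilon, 1 - epsilon]` first so the result is always finite. Fully
#' methylated or unmethylated calls (beta exactly 0 or 1) occur routinely in
#' low-coverage nanopore data; the clamp keeps them on the scale.
#'
#' @param beta numeric vector or matrix of fractions in \[0, 1\].
#' @param epsilon clamp bound in (0, 0.5); default `1e-6`.
#' @return M-values with the same shape (and dimnames) as `beta`.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must lie in (0, 0.5)")
  v <- beta[!is.na(beta)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("beta values must lie in [0, 1]")
  b <- clamp(beta, epsilon, 1 - epsilon)
  log2(b / (1 - b))
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (2^M + 1)`.
#'
#' @param m numeric vector or matrix of M-values.
#' @return beta values in (0, 1) with the same shape as `m`.
#' @export
m_to_beta <- function(m) {
  e <- 2^m
  e / (e + 1)
}
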