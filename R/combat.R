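#' Empirical-Bayes batch correction
#'
#' Location/scale batch adjustment with a parametric empirical-Bayes prior and
#' a batch-only design (no biological covariates), applied on the beta scale
#' and clamped back to \[0, 1\]. Backed by `sva::ComBat`. With a single batch
#' the input is returned unchanged; probes with (near-)zero variance across
#' all samples are passed through untouched, since they carry no batch signal
#' and would destabilize the standardization.
#'
#' @param x complete beta matrix (samples x probes); no missing values.
#' @param batch character/factor of length `nrow(x)`; every batch needs at
#'   least 2 samples.
#' @return batch-corrected beta matrix, same dimnames as `x`.
#' @export
combat_correct <- function(x, batch) {
  validate_beta_matrix(x)
  if (anyNA(x))
    stop("combat_correct requires a complete matrix; run impute_batch_mean first")
  if (length(batch) != nrow(x)) stop("batch must have one entry per sample")
  batch <- as.character(batch)
  tab <- table(batch)
  if (any(tab < 2))
    stop("batch(es) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  if (length(tab) < 2) return(x)
  dat <- t(x)                               # probes x samples for ComBat
  v <- apply(dat, 1, stats::var)
  fixed <- v < 1e-12
  out <- dat
  if (any(!fixed)) {
    adj <- suppressMessages(
      sva::ComBat(dat = dat[!fixed, , drop = FALSE], batch = batch,
                  mod = NULL, par.prior = TRUE))
    out[!fixed, ] <- adj
  }
  res <- t(out)
  res[] <- clamp(res, 0, 1)
  dimnames(res) <- dimnames(x)
  res
}
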