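# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a reproducible child seed from a base seed and a stream label.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

# Stratified fold assignment: every class is spread across folds.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
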