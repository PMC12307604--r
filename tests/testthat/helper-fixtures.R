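# Shared fixtures, built once per test run. The default synthetic cohort and
# an atlas trained on a 70% split of it are reused by the end-to-end and
# acceptance tests; cheaper fixtures are built inline in the test files.

.fixtures <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generate_cohort(cohort_spec(seed = 1))
  .fixtures$cohort
}

# Deterministic 70/30 split of the shared cohort.
shared_split <- function() {
  if (is.null(.fixtures$split)) {
    co <- shared_cohort()
    n <- nrow(co$betas)
    set.seed(41)
    train <- sort(sample(n, round(0.7 * n)))
    .fixtures$split <- list(train = train, test = setdiff(seq_len(n), train))
  }
  .fixtures$split
}

shared_atlas <- function() {
  if (is.null(.fixtures$atlas)) {
    co <- shared_cohort()
    sp <- shared_split()
    cfg <- atlas_config(stability_iters = 50)
    .fixtures$atlas <- atlas_fit(co$betas[sp$train, , drop = FALSE],
                                 co$samples[sp$train, , drop = FALSE],
                                 reference = co$reference,
                                 config = cfg, seed = 1)
  }
  .fixtures$atlas
}

# Small cohort + quick atlas for cheap structural tests.
small_atlas <- function() {
  if (is.null(.fixtures$small)) {
    spec <- cohort_spec(n_samples = 150, n_cpgs = 400, n_subtypes = 3,
                        markers_per_subtype = 40, n_candidates = 40,
                        n_prognostic = 4, seed = 7)
    co <- generate_cohort(spec)
    cfg <- atlas_config(stability_iters = 10)
    .fixtures$small <- list(
      cohort = co,
      atlas = suppressWarnings(
        atlas_fit(co$betas, co$samples, reference = co$reference,
                  config = cfg, seed = 7)))
  }
  .fixtures$small
}

# Adjusted Rand index between two label vectors (pair-counting form).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# Two well-separated Gaussian clusters in beta space.
make_cluster_betas <- function(n_per = 60, n_probes = 200, delta = 0.4,
                               seed = 11) {
  set.seed(seed)
  n <- 2 * n_per
  base <- matrix(runif(n * n_probes, 0.25, 0.45), n, n_probes)
  base[(n_per + 1):n, ] <- base[(n_per + 1):n, ] + delta
  base <- pmin(pmax(base, 0), 1)
  dimnames(base) <- list(sprintf("s%03d", seq_len(n)),
                         sprintf("cg%04d", seq_len(n_probes)))
  list(betas = base, labels = rep(c("A", "B"), each = n_per))
}
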