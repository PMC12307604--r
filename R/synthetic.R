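# Synthetic cohort generator: subtype-structured bimodal methylomes with
# batch effects, missingness, proportional-hazards survival tied to planted
# prognostic CpGs, and coverage-limited bedMethyl observations of the same
# methylomes. Everything is deterministic under the cohort-spec seed.

#' Specification of a synthetic methylation cohort
#'
#' The defaults describe the desk-scale study cohort used throughout the
#' package's tests: 600 samples x 2,000 CpGs, 6 subtypes with 100 marker
#' probes each (beta offset 0.4), 2 batches with a +0.05 additive shift, 2%
#' missing calls, and 200 survival-candidate probes of which 10 carry a
#' planted per-M-value log hazard ratio of 0.8 (alternating sign) under an
#' exponential baseline with ~30% independent uniform censoring. This
#' mirrors, at reduced scale, the 200-candidate-to-signature selection
#' geometry of the full-size application.
#'
#' @param n_samples,n_cpgs cohort dimensions.
#' @param n_subtypes number of planted subtypes (cluster structure).
#' @param markers_per_subtype,marker_offset marker probes per subtype and the
#'   beta offset applied to them (toward the opposite methylation state).
#' @param n_batches,batch_shift batch count; batch `b` is shifted by
#'   `(b-1) * batch_shift` before clamping.
#' @param missing_rate missing-completely-at-random call rate.
#' @param n_candidates,n_prognostic,prognostic_loghr survival-candidate pool
#'   size, number of planted prognostic probes among them, and the planted
#'   per-M-value log hazard ratio (applied with alternating sign).
#' @param baseline_hazard exponential baseline hazard per month.
#' @param risk_group_loghr log hazard ratio per clinical risk-group step
#'   (low -> standard -> high); the risk group is assigned independently of
#'   the planted CpGs, so the CpG signature carries information beyond it.
#' @param censoring_rate target fraction censored (independent uniform).
#' @param subtype_names optional label vector (length `n_subtypes`); the
#'   default mixes myeloid (`AML_*`), lymphoblastic (`ALL_*`) and a control
#'   class.
#' @param seed master seed; the generator is byte-deterministic under it.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 600, n_cpgs = 2000, n_subtypes = 6,
                        markers_per_subtype = 100, marker_offset = 0.4,
                        n_batches = 2, batch_shift = 0.05,
                        missing_rate = 0.02, n_candidates = 200,
                        n_prognostic = 10, prognostic_loghr = 0.8,
                        baseline_hazard = 0.02, risk_group_loghr = 0.5,
                        censoring_rate = 0.3,
                        subtype_names = NULL, seed = 1) {
  spec <- list(n_samples = n_samples, n_cpgs = n_cpgs,
               n_subtypes = n_subtypes,
               markers_per_subtype = markers_per_subtype,
               marker_offset = marker_offset, n_batches = n_batches,
               batch_shift = batch_shift, missing_rate = missing_rate,
               n_candidates = n_candidates, n_prognostic = n_prognostic,
               prognostic_loghr = prognostic_loghr,
               baseline_hazard = baseline_hazard,
               risk_group_loghr = risk_group_loghr,
               censoring_rate = censoring_rate,
               subtype_names = subtype_names %||%
                 .default_subtype_names(n_subtypes),
               seed = seed)
  if (length(spec$subtype_names) != n_subtypes)
    stop("subtype_names must have length n_subtypes")
  if (n_subtypes * markers_per_subtype + n_candidates > n_cpgs)
    stop("n_cpgs too small for the requested markers and candidates")
  if (marker_offset < 0 || marker_offset > 1)
    stop("marker_offset must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (n_prognostic > n_candidates)
    stop("n_prognostic cannot exceed n_candidates")
  class(spec) <- "cohort_spec"
  spec
}

.default_subtype_names <- function(k) {
  if (k == 1) return("AML_1")
  if (k == 2) return(c("AML_1", "ALL_1"))
  n_my <- ceiling((k - 1) / 2)
  n_ly <- k - 1 - n_my
  c(paste0("AML_", seq_len(n_my)),
    if (n_ly > 0) paste0("ALL_", seq_len(n_ly)), "control")
}

#' Generate a synthetic methylation cohort
#'
#' Baseline betas are drawn per probe from a bimodal Beta mixture
#' (Beta(1, 8) / Beta(8, 1), component fixed per probe) so methylomes have
#' the usual two-peaked distribution; survival-candidate probes use a
#' mid-range Beta(4, 4) so their M-values vary continuously. Subtype marker
#' probes are offset toward the opposite methylation state for samples of
#' their subtype; batch shifts are added and the matrix clamped to \[0, 1\];
#' missing calls are MCAR. Survival times follow a proportional-hazards model
#' with linear predictor `sum(planted log-HR x centered M-value)` over the
#' planted probes plus an independent clinical risk-group term, exponential
#' baseline, and independent uniform censoring calibrated to the target
#' censoring rate. Because the risk group is assigned independently of the
#' planted CpGs, a risk-group-adjusted EWAS retains the full CpG signal --
#' the planted signature carries prognostic information beyond the clinical
#' assignment.
#'
#' @param spec a [cohort_spec()].
#' @return list: `betas` (samples x probes, `NA` = missing), `samples`
#'   (sample table: batch, tissue, labels, OS/EFS), `truth` (per-sample true
#'   subtype and linear predictor; per-probe planted role), `reference`
#'   (a [cpg_reference()] laying the probes out on a synthetic genome).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; p <- spec$n_cpgs; k <- spec$n_subtypes
  probe_ids <- sprintf("cg%06d", seq_len(p))
  sample_ids <- sprintf("S%04d", seq_len(n))

  role <- rep("null", p)
  marker_of <- rep(NA_integer_, p)
  n_mark <- k * spec$markers_per_subtype
  if (n_mark > 0) {
    role[seq_len(n_mark)] <- "subtype_marker"
    marker_of[seq_len(n_mark)] <- rep(seq_len(k), each = spec$markers_per_subtype)
  }
  cand_idx <- n_mark + seq_len(spec$n_candidates)
  role[cand_idx] <- "candidate_null"
  prog_idx <- cand_idx[seq_len(spec$n_prognostic)]
  role[prog_idx] <- "prognostic"

  subtype <- sample(rep_len(spec$subtype_names, n))
  batch <- sample(rep_len(paste0("batch_", seq_len(spec$n_batches)), n))

  # per-probe bimodal baseline; candidates mid-range for continuous M-values
  comp_high <- sample(c(TRUE, FALSE), p, replace = TRUE)
  betas <- matrix(NA_real_, n, p, dimnames = list(sample_ids, probe_ids))
  is_cand <- seq_len(p) %in% cand_idx
  for (j in seq_len(p)) {
    if (is_cand[j]) {
      betas[, j] <- stats::rbeta(n, 4, 4)
    } else if (comp_high[j]) {
      betas[, j] <- stats::rbeta(n, 8, 1)
    } else {
      betas[, j] <- stats::rbeta(n, 1, 8)
    }
  }
  for (j in which(role == "subtype_marker")) {
    rows <- subtype == spec$subtype_names[marker_of[j]]
    betas[rows, j] <- betas[rows, j] +
      if (comp_high[j]) -spec$marker_offset else spec$marker_offset
  }
  betas[] <- clamp(betas, 0, 1)
  if (all(betas %in% c(0, 1)))
    stop("infeasible spec: offsets pushed all beta mass to the bounds")

  # survival: planted CpGs plus an independent clinical risk-group effect,
  # generated before batch effects and missingness
  mv <- beta_to_m(betas[, prog_idx, drop = FALSE])
  mv <- sweep(mv, 2, colMeans(mv))
  loghr <- spec$prognostic_loghr * rep_len(c(1, -1), spec$n_prognostic)
  eta_cpg <- drop(mv %*% loghr)
  risk_group <- sample(c("low", "standard", "high"), n, replace = TRUE,
                       prob = c(0.3, 0.4, 0.3))
  rg_step <- match(risk_group, c("low", "standard", "high")) - 2L
  eta <- eta_cpg + spec$risk_group_loghr * rg_step
  t_event <- stats::rexp(n, rate = spec$baseline_hazard * exp(eta))
  cmax <- tryCatch(
    stats::uniroot(function(c) mean(pmin(t_event, c)) / c - spec$censoring_rate,
                   interval = c(min(t_event) / 100, max(t_event) * 100))$root,
    error = function(e) max(t_event))
  cens <- stats::runif(n, 0, cmax)
  os_time <- pmin(t_event, cens)
  os_event <- as.integer(t_event <= cens)
  t_efs <- t_event * stats::runif(n, 0.6, 1)
  efs_time <- pmin(t_efs, cens)
  efs_event <- as.integer(t_efs <= cens)

  # batch shift then clamp, then MCAR missingness
  shift <- (match(batch, paste0("batch_", seq_len(spec$n_batches))) - 1) *
    spec$batch_shift
  betas <- clamp(betas + shift, 0, 1)
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(n * p) < spec$missing_rate, n, p)
    betas[mask] <- NA_real_
  }

  samples <- data.frame(
    sample_id = sample_ids, batch = batch,
    tissue = sample(c("BM", "PB"), n, replace = TRUE, prob = c(0.7, 0.3)),
    timepoint = "diagnosis",
    who2022_label = subtype,
    risk_group = as.character(risk_group),
    mrd1 = sample(c("positive", "negative"), n, replace = TRUE),
    os_time = os_time, os_event = os_event,
    efs_time = efs_time, efs_event = efs_event,
    stringsAsFactors = FALSE)

  reference <- cpg_reference(probe_id = probe_ids, chrom = "chr1",
                             start = 100L + 10L * seq_len(p),
                             genome_build = "hg38")
  truth <- list(
    samples = data.frame(sample_id = sample_ids, subtype = subtype,
                         linear_predictor = eta, cpg_predictor = eta_cpg,
                         event_time = t_event,
                         stringsAsFactors = FALSE),
    probes = data.frame(probe_id = probe_ids, role = role,
                        marker_of = ifelse(is.na(marker_of), NA_character_,
                                           spec$subtype_names[marker_of]),
                        loghr = replace(rep(0, p), prog_idx, loghr),
                        stringsAsFactors = FALSE),
    candidates = probe_ids[cand_idx])
  list(betas = betas, samples = samples, truth = truth, reference = reference,
       spec = spec)
}

#' Draw one synthetic methylome from a subtype's generator
#'
#' Produces a fresh sample with the same per-probe distributions the cohort
#' used for the given subtype (no batch effect, no missingness). Used to
#' simulate new specimens for the inference path.
#'
#' @param cohort output of [generate_cohort()].
#' @param subtype one of the spec's subtype names, or `"midpoint"` together
#'   with `pair` to draw a specimen halfway between two subtype centroids.
#' @param pair two subtype names (for `subtype = "midpoint"`).
#' @param seed integer seed.
#' @return named beta vector over the cohort reference.
#' @export
draw_specimen <- function(cohort, subtype, pair = NULL, seed = 1) {
  spec <- cohort$spec
  set.seed(seed)
  truth_sub <- cohort$truth$samples$subtype
  centroid <- function(s) {
    rows <- truth_sub == s
    # centroid in the pre-batch generator sense: expected beta per probe
    colMeans(cohort$betas[rows, , drop = FALSE], na.rm = TRUE)
  }
  if (identical(subtype, "midpoint")) {
    stopifnot(length(pair) == 2)
    mu <- (centroid(pair[1]) + centroid(pair[2])) / 2
  } else {
    stopifnot(subtype %in% spec$subtype_names)
    mu <- centroid(subtype)
  }
  jitter <- stats::rnorm(length(mu), 0, 0.03)
  clamp(mu + jitter, 0, 1)
}

#' Write a methylome as a modkit-style bedMethyl file
#'
#' Simulates a coverage-limited long-read observation of a methylome: per
#' reference locus, valid coverage is Poisson(`mean_coverage`) split evenly
#' across the two strands, modified counts are Binomial(coverage, beta), and
#' one record per covered strand is written in the modkit dialect (18
#' columns, percent column consistent with the counts). Loci with zero drawn
#' coverage are absent from the file.
#'
#' @param beta named beta vector aligned to `reference`.
#' @param reference a [cpg_reference()].
#' @param path output file.
#' @param mean_coverage mean total valid coverage per locus (> 0).
#' @param seed integer seed.
#' @param mod_code modification code to write (default `"m"`).
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(beta, reference, path, mean_coverage = 30,
                            seed = 1, mod_code = "m") {
  stopifnot(inherits(reference, "cpg_reference"))
  if (mean_coverage <= 0) stop("mean_coverage must be > 0")
  if (length(beta) != nrow(reference))
    stop("beta vector does not match the reference")
  set.seed(seed)
  p <- nrow(reference)
  cov_f <- stats::rpois(p, mean_coverage / 2)
  cov_r <- stats::rpois(p, mean_coverage / 2)
  mod_f <- stats::rbinom(p, cov_f, beta)
  mod_r <- stats::rbinom(p, cov_r, beta)
  line <- function(chrom, pos, strand, cov, mod) {
    pct <- ifelse(cov > 0, 100 * mod / cov, 0)
    sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t255,0,0\t%d\t%.2f\t%d\t%d\t0\t0\t0\t0\t0",
            chrom, pos, pos + 1L, mod_code, pmin(cov, 1000L), strand,
            pos, pos + 1L, cov, pct, mod, cov - mod)
  }
  keep_f <- cov_f > 0; keep_r <- cov_r > 0
  lines <- c(
    line(reference$chrom[keep_f], reference$start[keep_f], "+",
         cov_f[keep_f], mod_f[keep_f]),
    line(reference$chrom[keep_r], reference$start[keep_r] + 1L, "-",
         cov_r[keep_r], mod_r[keep_r]))
  ord <- order(c(reference$chrom[keep_f], reference$chrom[keep_r]),
               c(reference$start[keep_f], reference$start[keep_r] + 1L))
  writeLines(lines[ord], path)
  invisible(path)
}
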