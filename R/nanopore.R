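# Ingest of modkit-style bedMethyl calls: parse, collapse the two strands of
# each CG onto the forward-strand reference locus, impute unobserved loci
# from the discovery means, and run the confidence-gated inference path.

#' Parse a modkit-style bedMethyl file
#'
#' Reads the tab-delimited bedMethyl dialect (9 core columns; the extended
#' count columns are used when present). Records are filtered to `mod_code`
#' (default `"m"`, 5mC). Records whose percent-modified disagrees with their
#' counts by more than 0.1 points are flagged and excluded; malformed lines
#' are skipped and counted, and more than 10% malformed lines is an error.
#'
#' @param path bedMethyl file.
#' @param mod_code modification code to keep (default `"m"`).
#' @return data.frame: chrom, start, strand, coverage, n_mod, beta;
#'   attributes `n_skipped` (malformed) and `n_inconsistent`.
#' @export
parse_bedmethyl <- function(path, mod_code = "m") {
  if (!file.exists(path)) stop("bedMethyl file not found: ", path)
  raw <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                           data.table = FALSE)
  if (ncol(raw) < 9)
    stop("bedMethyl needs at least the 9 core columns: ", path)
  n_in <- nrow(raw)
  ok <- !is.na(raw[[2]]) & !is.na(raw[[3]]) & raw[[6]] %in% c("+", "-", ".")
  cov <- suppressWarnings(as.numeric(if (ncol(raw) >= 10) raw[[10]] else raw[[5]]))
  pct <- suppressWarnings(as.numeric(raw[[min(11, ncol(raw))]]))
  has_counts <- ncol(raw) >= 12
  ok <- ok & !is.na(cov) & !is.na(pct) & pct >= 0 & pct <= 100
  n_skipped <- sum(!ok)
  if (n_skipped > 0.1 * n_in)
    stop(sprintf("more than 10%% malformed bedMethyl lines (%d of %d): %s",
                 n_skipped, n_in, path))
  raw <- raw[ok, , drop = FALSE]; cov <- cov[ok]; pct <- pct[ok]
  keep <- raw[[4]] == mod_code
  raw <- raw[keep, , drop = FALSE]; cov <- cov[keep]; pct <- pct[keep]
  if (has_counts) {
    n_mod <- suppressWarnings(as.numeric(raw[[12]]))
    consistent <- is.na(n_mod) | cov == 0 |
      abs(pct - 100 * n_mod / cov) <= 0.1
  } else {
    n_mod <- round(pct / 100 * cov)
    consistent <- rep(TRUE, nrow(raw))
  }
  n_inconsistent <- sum(!consistent)
  if (n_inconsistent)
    message(sprintf("parse_bedmethyl: excluded %d record(s) with inconsistent counts",
                    n_inconsistent))
  raw <- raw[consistent, , drop = FALSE]
  out <- data.frame(chrom = as.character(raw[[1]]),
                    start = as.integer(raw[[2]]),
                    strand = as.character(raw[[6]]),
                    coverage = cov[consistent],
                    n_mod = ifelse(is.na(n_mod[consistent]),
                                   round(pct[consistent] / 100 * cov[consistent]),
                                   n_mod[consistent]),
                    stringsAsFactors = FALSE)
  out$beta <- ifelse(out$coverage > 0, out$n_mod / out$coverage, NA_real_)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_inconsistent") <- n_inconsistent
  out
}

#' Collapse strand-level calls onto reference CpG loci
#'
#' Each reference locus is a forward-strand CG dinucleotide spanning
#' `[start, start+2)`. The forward-strand record sits at `start`, the
#' reverse-strand record at `start + 1`; their modified/valid counts are
#' pooled, and the pooled fraction is the locus beta. Loci with pooled
#' coverage below `min_coverage` are left missing. The result is independent
#' of record order.
#'
#' @param records data.frame from [parse_bedmethyl()].
#' @param reference a [cpg_reference()].
#' @param min_coverage minimum pooled valid coverage for an observed call
#'   (default 1).
#' @return a `methylome_vector`: list with probe_ids, beta, coverage, source
#'   (`"observed"`/`"missing"`), and an `observed_fraction`.
#' @export
collapse_strands <- function(records, reference, min_coverage = 1) {
  stopifnot(inherits(reference, "cpg_reference"))
  key_plus <- paste(reference$chrom, reference$start)
  key_minus <- paste(reference$chrom, reference$start + 1L)
  rkey <- paste(records$chrom, records$start)
  # aggregate duplicate records per (position, strand) by summing counts
  agg <- function(keys, want_strand) {
    sel <- records$strand %in% c(want_strand, ".")
    i <- which(sel)
    idx <- match(rkey[i], keys)
    ok <- !is.na(idx)
    cov <- numeric(length(keys)); mod <- numeric(length(keys))
    if (any(ok)) {
      t1 <- tapply(records$coverage[i][ok], idx[ok], sum)
      t2 <- tapply(records$n_mod[i][ok], idx[ok], sum)
      cov[as.integer(names(t1))] <- t1
      mod[as.integer(names(t2))] <- t2
    }
    list(cov = cov, mod = mod)
  }
  fw <- agg(key_plus, "+")
  rv <- agg(key_minus, "-")
  cov <- fw$cov + rv$cov
  mod <- fw$mod + rv$mod
  hit_rate <- mean(cov > 0)
  if (nrow(records) > 100 && hit_rate < 0.01)
    stop(sprintf(paste0("only %.2f%% of reference loci have coverage; ",
                        "likely genome-build mismatch"), 100 * hit_rate))
  observed <- cov >= min_coverage
  beta <- ifelse(observed & cov > 0, mod / cov, NA_real_)
  structure(list(probe_ids = reference$probe_id,
                 beta = stats::setNames(beta, reference$probe_id),
                 coverage = stats::setNames(cov, reference$probe_id),
                 source = ifelse(observed, "observed", "missing"),
                 observed_fraction = mean(observed),
                 genome_build = attr(reference, "genome_build")),
            class = "methylome_vector")
}

#' Impute unobserved loci from the discovery-cohort means
#'
#' Every missing locus receives the per-probe mean beta of the discovery
#' (training) cohort; observed entries are untouched and the provenance is
#' recorded per locus.
#'
#' @param vector a `methylome_vector`.
#' @param discovery_means named numeric vector of per-probe means covering
#'   the reference.
#' @return completed `methylome_vector` with source `"imputed"` where filled.
#' @export
impute_discovery_mean <- function(vector, discovery_means) {
  stopifnot(inherits(vector, "methylome_vector"))
  miss <- is.na(vector$beta)
  if (!any(miss)) return(vector)
  if (vector$observed_fraction == 0)
    warning("0% of reference loci observed; output equals the discovery means")
  need <- vector$probe_ids[miss]
  absent <- need[!(need %in% names(discovery_means))]
  if (length(absent))
    stop("discovery means absent for missing locus/loci: ",
         paste(utils::head(absent, 3), collapse = ", "))
  vector$beta[miss] <- discovery_means[need]
  vector$source[miss] <- "imputed"
  vector
}

#' @export
print.methylome_vector <- function(x, ...) {
  cat(sprintf("methylome vector: %d loci, %.1f%% observed (build %s)\n",
              length(x$probe_ids), 100 * mean(x$source == "observed"),
              x$genome_build %||% "?"))
  invisible(x)
}

#' Confidence-gated classification of a single specimen
#'
#' Runs the full inference path on one (post-imputation) methylome vector:
#' embedding transform, subtype prediction with confidence gating, and --
#' only when the confident top call is a myeloid class (AML/MDS-like) -- the
#' 5-year mortality classifier and the CpG hazard-score signature. A warning
#' is attached when fewer than 10% of reference loci were directly observed.
#'
#' @param atlas a fitted `meth_atlas` (see [atlas_fit()]).
#' @param vector a complete `methylome_vector` aligned to the atlas reference.
#' @param sample_id identifier used in the report.
#' @return a `specimen_report`: subtype block (label, confidence, second
#'   call), optional risk and signature blocks with a `prognostic_reason`
#'   when absent, and a QC block (observed fraction, coverage summary).
#' @export
classify_specimen <- function(atlas, vector, sample_id = "specimen") {
  stopifnot(inherits(atlas, "meth_atlas"), inherits(vector, "methylome_vector"))
  if (!identical(vector$probe_ids, atlas$reference$probe_id))
    stop("methylome vector does not match the atlas reference")
  if (anyNA(vector$beta))
    stop("methylome vector has missing loci; run impute_discovery_mean first")
  qc_warnings <- character()
  obs <- mean(vector$source == "observed")
  if (obs < 0.10)
    qc_warnings <- c(qc_warnings,
                     sprintf("only %.1f%% of reference loci observed", 100 * obs))
  x <- matrix(vector$beta, nrow = 1,
              dimnames = list(sample_id, vector$probe_ids))
  coords5 <- predict(atlas$embedding_clf, x)
  sub <- predict(atlas$subtype_model, coords5,
                 confidence_cutoff = atlas$config$confidence_cutoff)
  myeloid <- grepl(atlas$config$myeloid_pattern, sub$top_label)
  risk <- NULL; signature <- NULL
  reason <- NULL
  if (!sub$confident) {
    reason <- "not confident"
  } else if (!myeloid) {
    reason <- "non-myeloid"
  } else {
    if (!is.null(atlas$risk_model))
      risk <- predict(atlas$risk_model, coords5,
                      cutoff = atlas$config$risk_cutoff)
    if (!is.null(atlas$signature)) {
      mv <- beta_to_m(x, atlas$config$epsilon)
      signature <- predict(atlas$signature, mv)
    }
    if (is.null(risk) && is.null(signature))
      reason <- "component absent"
  }
  structure(list(sample_id = sample_id,
                 subtype = sub,
                 risk = risk,
                 signature = signature,
                 prognostic_reason = reason,
                 qc = list(observed_fraction = obs,
                           median_coverage = stats::median(
                             vector$coverage[vector$source == "observed"]),
                           warnings = qc_warnings)),
            class = "specimen_report")
}

#' @export
print.specimen_report <- function(x, ...) {
  cat("specimen:", x$sample_id, "\n")
  cat(sprintf("  subtype: %s (confidence %.2f; second: %s)\n",
              x$subtype$display_label, x$subtype$confidence,
              x$subtype$second_label))
  if (!is.null(x$risk))
    cat(sprintf("  5-year mortality: p = %.3f (%s risk)\n",
                x$risk$p_death_5y, x$risk$group))
  if (!is.null(x$signature))
    cat(sprintf("  signature hazard score: %.3f (%s)\n",
                x$signature$hazard_score, x$signature$group))
  if (!is.null(x$prognostic_reason))
    cat("  prognostic models not applied:", x$prognostic_reason, "\n")
  cat(sprintf("  QC: %.1f%% loci observed, median coverage %s\n",
              100 * x$qc$observed_fraction, format(x$qc$median_coverage)))
  for (w in x$qc$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Write a specimen report as JSON
#' @param report a `specimen_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_specimen_report <- function(report, path) {
  jsonlite::write_json(
    list(sample_id = report$sample_id,
         subtype = as.list(report$subtype[
           , c("top_label", "second_label", "confidence", "confident",
               "display_label")]),
         risk = if (!is.null(report$risk))
           as.list(report$risk[, c("p_death_5y", "group")]),
         signature = if (!is.null(report$signature))
           as.list(report$signature[, c("hazard_score", "group")]),
         prognostic_reason = report$prognostic_reason,
         qc = report$qc),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
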