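bm_line <- function(chrom, start, code, strand, cov, pct, nmod, ncan) {
  sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t255,0,0\t%d\t%.1f\t%d\t%d\t0\t0\t0\t0\t0",
          chrom, start, start + 1L, code, cov, strand, start, start + 1L,
          cov, pct, nmod, ncan)
}

test_that("bedMethyl parsing filters, validates and flags inconsistencies", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    bm_line("chr1", 100, "m", "+", 30, 80.0, 24, 6),
    bm_line("chr1", 101, "h", "-", 30, 10.0, 3, 27),     # wrong mod code
    bm_line("chr1", 200, "m", "-", 30, 80.0, 20, 10)),   # 20/30 != 80%
    f)
  expect_message(rec <- parse_bedmethyl(f, mod_code = "m"), "inconsistent")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$chrom, "chr1")
  expect_equal(rec$start, 100L)
  expect_equal(rec$coverage, 30)
  expect_equal(rec$beta, 0.8)
  expect_identical(attr(rec, "n_inconsistent"), 1L)
})

test_that("heavily malformed files are a hard error", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(bm_line("chr1", 100, "m", "+", 10, 50, 5, 5),
               "garbage line", "another\tbad"), f)
  expect_error(parse_bedmethyl(f), "malformed")
  expect_error(parse_bedmethyl("/nonexistent/file.bed"), "not found")
})

test_that("strand collapsing pools counts onto the forward-strand locus", {
  ref <- cpg_reference(c("cg1", "cg2", "cg3"), rep("chr1", 3),
                       c(100L, 200L, 300L))
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    bm_line("chr1", 100, "m", "+", 10, 80.0, 8, 2),    # cg1 forward
    bm_line("chr1", 101, "m", "-", 10, 60.0, 6, 4),    # cg1 reverse
    bm_line("chr1", 201, "m", "-", 5, 100.0, 5, 0),    # cg2 reverse only
    bm_line("chr1", 301, "m", "-", 2, 50.0, 1, 1)),    # cg3, low coverage
    f)
  rec <- parse_bedmethyl(f)
  vec <- collapse_strands(rec, ref, min_coverage = 3)
  expect_equal(unname(vec$beta["cg1"]), 0.7)           # (8+6)/(10+10)
  expect_equal(unname(vec$coverage["cg1"]), 20)
  expect_equal(unname(vec$beta["cg2"]), 1.0)
  expect_equal(unname(vec$coverage["cg2"]), 5)
  expect_true(is.na(vec$beta["cg3"]))                  # below min_coverage
  expect_identical(unname(vec$source), c("observed", "observed", "missing"))
  # record order does not matter
  vec2 <- collapse_strands(rec[rev(seq_len(nrow(rec))), ], ref,
                           min_coverage = 3)
  expect_identical(vec2$beta, vec$beta)
})

test_that("a build mismatch (no locus hits) is detected", {
  ref <- cpg_reference(sprintf("cg%03d", 1:5), rep("chr9", 5),
                       as.integer(1:5 * 1000))
  rec <- data.frame(chrom = "chr1", start = 1:200, strand = "+",
                    coverage = 10, n_mod = 5, beta = 0.5)
  expect_error(collapse_strands(rec, ref), "build mismatch")
})

test_that("discovery-mean imputation completes a vector without touching observations", {
  ref <- cpg_reference(c("cg1", "cg2"), c("chr1", "chr1"), c(100L, 200L))
  vec <- structure(list(probe_ids = ref$probe_id,
                        beta = c(cg1 = 0.9, cg2 = NA),
                        coverage = c(cg1 = 12, cg2 = 0),
                        source = c("observed", "missing"),
                        observed_fraction = 0.5),
                   class = "methylome_vector")
  means <- c(cg1 = 0.5, cg2 = 0.42)
  out <- impute_discovery_mean(vec, means)
  expect_equal(unname(out$beta), c(0.9, 0.42))
  expect_identical(out$source, c("observed", "imputed"))
  # fully observed vector is untouched
  vec2 <- vec; vec2$beta[] <- c(0.9, 0.8); vec2$source <- rep("observed", 2)
  vec2$observed_fraction <- 1
  expect_identical(impute_discovery_mean(vec2, means), vec2)
  # fully missing vector warns and equals the means
  vec3 <- vec; vec3$beta[] <- NA; vec3$source <- rep("missing", 2)
  vec3$observed_fraction <- 0
  expect_warning(out3 <- impute_discovery_mean(vec3, means), "0%")
  expect_equal(unname(out3$beta), unname(means))
  # absent mean for a missing locus is an error
  expect_error(impute_discovery_mean(vec, means["cg1"]), "cg2")
})

test_that("synthetic bedMethyl writes are consistent and recoverable", {
  ref <- cpg_reference(sprintf("cg%04d", 1:500), rep("chr1", 500),
                       as.integer(seq(1000, by = 10, length.out = 500)))
  beta <- rep(1, 500)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bedmethyl(beta, ref, f, mean_coverage = 10, seed = 1)
  rec <- parse_bedmethyl(f)
  expect_true(all(rec$beta == 1))                      # beta 1 -> 100% modified
  # sparse coverage leaves loci absent
  write_bedmethyl(rep(0.5, 500), ref, f, mean_coverage = 0.5, seed = 2)
  rec2 <- parse_bedmethyl(f)
  vecs <- collapse_strands(rec2, ref)
  expect_lt(vecs$observed_fraction, 1)
  # deep coverage recovers the source betas
  set.seed(3)
  b <- runif(500)
  write_bedmethyl(b, ref, f, mean_coverage = 10000, seed = 3)
  vec <- collapse_strands(parse_bedmethyl(f), ref)
  expect_lt(max(abs(vec$beta - b)), 0.02)
  expect_error(write_bedmethyl(b, ref, f, mean_coverage = 0), "mean_coverage")
})

test_that("specimen classification gates prognostic models correctly", {
  co <- shared_cohort()
  atlas <- shared_atlas()
  run_specimen <- function(beta) {
    f <- withr::local_tempfile(fileext = ".bed")
    write_bedmethyl(beta, co$reference, f, mean_coverage = 30, seed = 101)
    vec <- collapse_strands(parse_bedmethyl(f), atlas$reference)
    vec <- impute_discovery_mean(vec, atlas$discovery_means)
    classify_specimen(atlas, vec)
  }
  # a clean myeloid specimen gets the full prognostic block
  rep_aml <- run_specimen(draw_specimen(co, "AML_1", seed = 201))
  expect_identical(rep_aml$subtype$top_label, "AML_1")
  expect_true(rep_aml$subtype$confident)
  expect_false(is.null(rep_aml$risk))
  expect_false(is.null(rep_aml$signature))
  # a lymphoblastic specimen is typed but not risk-scored
  rep_all <- run_specimen(draw_specimen(co, "ALL_1", seed = 202))
  expect_match(rep_all$subtype$top_label, "^ALL")
  expect_null(rep_all$risk)
  expect_identical(rep_all$prognostic_reason, "non-myeloid")
  # an ambiguous specimen between two centroids is not confidently called
  rep_mid <- run_specimen(draw_specimen(co, "midpoint",
                                        pair = c("AML_1", "AML_2"),
                                        seed = 203))
  expect_false(rep_mid$subtype$confident)
  expect_identical(rep_mid$subtype$display_label, "Not confident")
  expect_identical(rep_mid$prognostic_reason, "not confident")
})
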