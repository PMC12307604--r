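#' Construct a CpG reference
#'
#' The reference fixes the probe universe and, crucially, the column order of
#' every matrix in a trained atlas: all components of a model bundle agree on
#' this ordering. Coordinates are 0-based half-open on the forward strand; a
#' CpG locus spans exactly two bases (the CG dinucleotide), so `end = start + 2`.
#'
#' @param probe_id character, unique probe identifiers (array style, e.g. "cg...").
#' @param chrom character chromosome names.
#' @param start integer 0-based position of the C of the CG on the forward strand.
#' @param genome_build tag recorded with the reference (default "hg38").
#' @return a `cpg_reference`: data.frame with columns probe_id, chrom, start, end.
#' @export
cpg_reference <- function(probe_id, chrom, start, genome_build = "hg38") {
  probe_id <- as.character(probe_id)
  chrom <- as.character(chrom)
  start <- as.integer(start)
  if (anyDuplicated(probe_id))
    stop("duplicate probe_id in CpG reference: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  if (anyDuplicated(paste(chrom, start)))
    stop("duplicate (chrom, start) in CpG reference")
  if (any(!nzchar(chrom))) stop("empty chromosome name in CpG reference")
  ref <- data.frame(probe_id = probe_id, chrom = chrom,
                    start = start, end = start + 2L,
                    stringsAsFactors = FALSE)
  attr(ref, "genome_build") <- genome_build
  class(ref) <- c("cpg_reference", "data.frame")
  ref
}

#' Read a CpG reference from a BED4 file
#'
#' Expects BED (0-based half-open) with the probe identifier in the name
#' (4th) column. Every interval must have length 2 (a CG dinucleotide).
#'
#' @param path BED file path.
#' @param genome_build tag recorded with the reference (default "hg38").
#' @return a [cpg_reference()].
#' @export
read_cpg_reference <- function(path, genome_build = "hg38") {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) stop("empty CpG reference BED: ", path)
  nm <- gr$name
  if (is.null(nm) || anyNA(nm))
    stop("CpG reference BED must carry probe ids in column 4")
  w <- GenomicRanges::width(gr)
  if (any(w != 2)) {
    bad <- which(w != 2)[1]
    stop(sprintf("CpG reference interval of length %d at line %d (must be 2)",
                 w[bad], bad))
  }
  cpg_reference(probe_id = nm,
                chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1L,
                genome_build = genome_build)
}

#' Write a CpG reference as BED4
#' @param ref a [cpg_reference()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cpg_reference <- function(ref, path) {
  stopifnot(inherits(ref, "cpg_reference"))
  utils::write.table(ref[, c("chrom", "start", "end", "probe_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a sample x probe beta matrix from delimited text
#'
#' The canonical orientation is samples as rows with the sample identifier in
#' the first column; array exports with probes as rows are accepted via
#' `orientation = "probes_as_rows"` and transposed. Empty cells and "NA" are
#' read as missing. If a reference is supplied, columns are subset and
#' reordered to the reference order; probes absent from the reference are
#' dropped (counted in the `dropped_probes` attribute) and reference probes
#' absent from the table are reported in the `absent_probes` attribute.
#'
#' @param path delimited text file (TSV/CSV autodetected by [data.table::fread()]).
#' @param reference optional [cpg_reference()] to align columns against.
#' @param orientation `"samples_as_rows"` (default) or `"probes_as_rows"`.
#' @return validated beta matrix (see [validate_beta_matrix()]), with
#'   attributes `dropped_probes` and `absent_probes` when `reference` is given.
#' @export
read_beta_matrix <- function(path, reference = NULL,
                             orientation = c("samples_as_rows", "probes_as_rows")) {
  orientation <- match.arg(orientation)
  dt <- data.table::fread(path, na.strings = c("", "NA"), header = TRUE,
                          data.table = FALSE)
  if (ncol(dt) < 2) stop("beta matrix table needs an id column plus data: ", path)
  ids <- as.character(dt[[1]])
  num <- dt[, -1, drop = FALSE]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad)) {
    col <- names(num)[which(bad)[1]]
    v <- suppressWarnings(as.numeric(num[[col]]))
    row <- which(is.na(v) & !is.na(num[[col]]))[1]
    stop(sprintf("non-numeric beta value in column '%s', row %d of %s",
                 col, row %||% NA_integer_, path))
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (orientation == "probes_as_rows") m <- t(m)
  validate_beta_matrix(m)
  if (!is.null(reference)) {
    keep <- colnames(m) %in% reference$probe_id
    dropped <- sum(!keep)
    m <- m[, keep, drop = FALSE]
    absent <- setdiff(reference$probe_id, colnames(m))
    m <- m[, intersect(reference$probe_id, colnames(m)), drop = FALSE]
    attr(m, "dropped_probes") <- dropped
    attr(m, "absent_probes") <- absent
    if (dropped > 0)
      message(sprintf("read_beta_matrix: dropped %d probe(s) absent from reference", dropped))
  }
  m
}

#' Write a beta matrix as TSV (samples as rows)
#' @param x beta matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path) {
  validate_beta_matrix(x)
  dt <- data.table::data.table(sample_id = rownames(x), x)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a probe mask (one probe id per line)
#'
#' Lines starting with `#` are comments. Duplicates are collapsed. An empty
#' file yields an empty set with a warning.
#'
#' @param path text file.
#' @return character vector of unique probe ids.
#' @export
read_probe_mask <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- unique(lines)
  if (length(ids) == 0) warning("probe mask is empty: ", path)
  ids
}

# Schema version of the serialized atlas container.
.bundle_schema <- "methatlas-bundle/1"

#' Save / load a trained atlas
#'
#' The container is an RDS file wrapping the `meth_atlas` object together with
#' a schema-version string; [load_atlas()] refuses containers written under a
#' different schema. Saving and loading round-trips predictions bit-identically.
#'
#' @param atlas a fitted [atlas_fit()] object.
#' @param path file path.
#' @return `path` invisibly for `save_atlas`; the `meth_atlas` for `load_atlas`.
#' @export
save_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "meth_atlas"))
  saveRDS(list(schema = .bundle_schema, atlas = atlas), path)
  invisible(path)
}

#' @rdname save_atlas
#' @export
load_atlas <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read atlas bundle '", path,
                                           "': ", conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$schema))
    stop("not an atlas bundle: ", path)
  if (!identical(obj$schema, .bundle_schema))
    stop(sprintf("atlas bundle schema mismatch: file has '%s', package expects '%s'",
                 obj$schema, .bundle_schema))
  obj$atlas
}

# Align a beta matrix to the reference probe order, imputing absent or missing
# probes from the supplied per-probe means (the discovery means at inference).
align_to_reference <- function(x, reference, means = NULL) {
  validate_beta_matrix(x)
  probes <- reference$probe_id
  out <- matrix(NA_real_, nrow(x), length(probes),
                dimnames = list(rownames(x), probes))
  common <- intersect(probes, colnames(x))
  out[, common] <- x[, common]
  if (!is.null(means)) {
    if (is.null(names(means))) names(means) <- probes
    for (j in seq_along(probes)) {
      miss <- is.na(out[, j])
      if (any(miss)) out[miss, j] <- means[[probes[j]]]
    }
  }
  out
}
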