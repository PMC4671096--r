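# Single-sample VCF ingestion and emission.
#
# Parsing is delegated to vcfR; this layer enforces the contracts the
# benchmark relies on: exactly one sample, uppercase ACGT alleles,
# unordered diploid genotypes (phase discarded), NA for missing QUAL,
# and skip-with-warning for half-calls and non-diploid genotypes.

#' Read a single-sample VCF into a callset
#'
#' Parses a VCF v4.x file with exactly one sample column and returns a
#' [callset()] table. Multi-allelic records are preserved (comma-joined
#' ALT) until [split_multiallelic()]. Phase separators (`|`) are
#' discarded: genotypes are stored as sorted allele-index pairs. A QUAL
#' of `"."` becomes `NA` (missing, not 0). Half-calls (e.g. `./1`) and
#' non-diploid genotypes are skipped with a warning; the number skipped
#' is available as `attr(x, "n_skipped")`.
#'
#' @param path Path to a VCF file (plain text or bgzip/gzip).
#' @param caller_id,aligner_id,dataset_id Provenance labels attached to
#'   every record.
#' @return A [callset()] with attribute `n_skipped` (count of records
#'   dropped for half-calls/non-diploid genotypes).
#' @seealso [write_vcf()], [split_multiallelic()]
#' @export
read_vcf <- function(path, caller_id = NA_character_,
                     aligner_id = NA_character_,
                     dataset_id = NA_character_) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  x <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(x@gt) || ncol(x@gt) < 2L) {
    stop("unsupported input: VCF has no sample column: ", path, call. = FALSE)
  }
  if (ncol(x@gt) > 2L) {
    stop("unsupported input: multi-sample VCF (", ncol(x@gt) - 1L,
         " samples): ", path, call. = FALSE)
  }
  n <- nrow(x@fix)
  if (n == 0L) {
    out <- callset()
    setattr(out, "n_skipped", 0L)
    return(out)
  }
  fix <- x@fix
  # line numbers for error reporting: meta lines + #CHROM header + record
  line0 <- length(x@meta) + 1L
  chrom <- as.character(fix[, "CHROM"])
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    stop("malformed VCF: non-integer POS at line ",
         line0 + which(is.na(pos))[1L], call. = FALSE)
  }
  ref <- toupper(as.character(fix[, "REF"]))
  alt <- toupper(as.character(fix[, "ALT"]))
  bad <- grepl("[^ACGT]", ref) | grepl("[^ACGT,]", alt) | is.na(alt) | alt == ""
  if (any(bad)) {
    stop("malformed VCF: non-ACGT REF/ALT at line ",
         line0 + which(bad)[1L], call. = FALSE)
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))  # "." -> NA
  filter <- as.character(fix[, "FILTER"])
  filter[is.na(filter)] <- "."

  gt_str <- as.character(vcfR::extract.gt(x, element = "GT"))
  dp <- suppressWarnings(
    as.integer(vcfR::extract.gt(x, element = "DP", as.numeric = TRUE)))

  gt_parts <- strsplit(gt_str, "[/|]")
  idx <- lapply(gt_parts, function(g) suppressWarnings(as.integer(g)))
  ok <- vapply(idx, function(g) length(g) == 2L && !anyNA(g), logical(1L))
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    warning(sprintf(
      "skipped %d record(s) with half-call or non-diploid genotypes", n_skipped),
      call. = FALSE)
  }
  g1 <- vapply(idx, function(g) if (length(g) >= 1L) g[1L] else NA_integer_,
               integer(1L))
  g2 <- vapply(idx, function(g) if (length(g) >= 2L) g[2L] else NA_integer_,
               integer(1L))
  out <- callset(
    chrom = chrom[ok], pos = pos[ok], ref = ref[ok], alt = alt[ok],
    gt1 = pmin(g1, g2)[ok], gt2 = pmax(g1, g2)[ok],
    qual = qual[ok], depth = dp[ok], filter = filter[ok],
    caller_id = caller_id, aligner_id = aligner_id, dataset_id = dataset_id
  )
  setattr(out, "n_skipped", n_skipped)
  out
}

#' Write a callset as a single-sample VCF
#'
#' Records are written sorted by (chrom, pos); missing QUAL is emitted
#' as `"."`. `read_vcf(write_vcf(x))` preserves all modeled fields
#' (chrom, pos, ref, alt, unordered genotype, qual, depth, filter).
#'
#' @param x A [callset()].
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, sample_name = "SAMPLE") {
  stopifnot(inherits(x, "data.frame"))
  dt <- as.data.table(x)
  if (nrow(dt)) dt <- dt[order(chrom, pos)]
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  if (nrow(dt)) {
    qual_s <- ifelse(is.na(dt$qual), ".",
                     formatC(dt$qual, format = "g", digits = 15))
    gt_s <- paste0(dt$gt1, "/", dt$gt2)
    has_dp <- !is.na(dt$depth)
    fmt <- ifelse(has_dp, "GT:DP", "GT")
    samp <- ifelse(has_dp, paste0(gt_s, ":", dt$depth), gt_s)
    body <- paste(dt$chrom, dt$pos, ".", dt$ref, dt$alt, qual_s,
                  dt$filter, ".", fmt, samp, sep = "\t")
  } else {
    body <- character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}
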