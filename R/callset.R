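# Core tabular container for variant calls.
#
# A callset is a data.table with one row per VCF record (possibly
# multi-allelic: `alt` holds a comma-separated allele list until
# split_multiallelic()). Genotypes are unordered diploid pairs stored as
# sorted integer indices (gt1 <= gt2; 0 = REF, k >= 1 = k-th ALT), so
# phase is discarded on ingestion. QUAL is numeric with NA for the VCF
# missing value "."; a missing QUAL fails every numeric threshold.

CALLSET_COLS <- c(
  "chrom", "pos", "ref", "alt", "gt1", "gt2", "qual", "depth",
  "filter", "caller_id", "aligner_id", "dataset_id"
)

#' Build a callset table
#'
#' Assembles and validates the tabular variant container used throughout
#' the package: one row per single-sample VCF record, with an unordered
#' diploid genotype stored as sorted allele indices (`0` = REF,
#' `k >= 1` = k-th ALT allele).
#'
#' @param chrom Character vector of contig names. Contig names are
#'   matched as exact strings everywhere in the package (`"chr1"` is not
#'   `"1"`).
#' @param pos Integer vector of 1-based VCF positions.
#' @param ref,alt Character vectors of REF and ALT alleles (ALT may be a
#'   comma-separated list for multi-allelic records). Lowercase is
#'   normalized to uppercase; characters outside `A,C,G,T` (and the
#'   comma separator in `alt`) are rejected.
#' @param gt1,gt2 Integer allele indices of the diploid genotype; stored
#'   sorted so that `gt1 <= gt2`.
#' @param qual Numeric Phred-scaled variant quality; `NA` for missing.
#' @param depth Optional integer read depth (`DP`); `NA` when absent.
#' @param filter VCF FILTER string (`"PASS"` or `"."` pass by default
#'   downstream).
#' @param caller_id,aligner_id,dataset_id Free-text provenance labels
#'   used by the concordance and variance analyses.
#' @return A `data.table` of class `"callset"`.
#' @export
#' @examples
#' callset(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
#'         gt1 = 0L, gt2 = 1L, qual = 50)
callset <- function(chrom = character(), pos = integer(),
                    ref = character(), alt = character(),
                    gt1 = integer(), gt2 = integer(),
                    qual = NA_real_, depth = NA_integer_,
                    filter = "PASS",
                    caller_id = NA_character_,
                    aligner_id = NA_character_,
                    dataset_id = NA_character_) {
  n <- length(pos)
  dt <- data.table(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    gt1 = as.integer(gt1),
    gt2 = as.integer(gt2),
    qual = rep_len(as.numeric(qual), n),
    depth = rep_len(as.integer(depth), n),
    filter = rep_len(as.character(filter), n),
    caller_id = rep_len(as.character(caller_id), n),
    aligner_id = rep_len(as.character(aligner_id), n),
    dataset_id = rep_len(as.character(dataset_id), n)
  )
  # unordered genotype: store sorted
  flip <- !is.na(dt$gt1) & !is.na(dt$gt2) & dt$gt1 > dt$gt2
  if (any(flip)) {
    tmp <- dt$gt1[flip]
    dt[flip, gt1 := dt$gt2[flip]]
    dt[flip, gt2 := tmp]
  }
  validate_callset(dt)
  setattr(dt, "class", c("callset", class(dt)))
  dt[]
}

validate_callset <- function(dt) {
  if (nrow(dt) == 0L) return(invisible(dt))
  if (any(dt$pos < 1L)) stop("callset: POS must be >= 1", call. = FALSE)
  bad_ref <- grepl("[^ACGT]", dt$ref)
  if (any(bad_ref)) {
    stop("callset: REF contains characters outside {A,C,G,T} at row ",
         which(bad_ref)[1L], call. = FALSE)
  }
  bad_alt <- grepl("[^ACGT,]", dt$alt) | dt$alt == ""
  if (any(bad_alt)) {
    stop("callset: ALT contains characters outside {A,C,G,T} at row ",
         which(bad_alt)[1L], call. = FALSE)
  }
  n_alt <- lengths(strsplit(dt$alt, ",", fixed = TRUE))
  if (isTRUE(any(dt$gt2 > n_alt, na.rm = TRUE))) {
    stop("callset: genotype index exceeds number of ALT alleles at row ",
         which(dt$gt2 > n_alt)[1L], call. = FALSE)
  }
  invisible(dt)
}

as_callset <- function(dt) {
  stopifnot(all(CALLSET_COLS %in% names(dt)))
  if (!inherits(dt, "callset")) {
    setattr(dt, "class", c("callset", class(dt)))
  }
  dt[]
}

is_het <- function(dt) dt$gt1 != dt$gt2

# allele sequences carried by a genotype, given per-row ref and the
# (single) alt of a split record
gt_alleles <- function(ref, alt, gt1, gt2) {
  pick <- function(i) ifelse(i == 0L, ref, alt)
  list(a1 = pick(gt1), a2 = pick(gt2))
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("<callset> %d record(s)\n", nrow(x)))
  NextMethod()
}
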