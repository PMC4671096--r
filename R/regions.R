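# Region sets: 0-based half-open genomic intervals (BED convention),
# kept merged and sorted. Interval algebra is delegated to
# IRanges/GenomicRanges; this layer fixes the coordinate convention
# (BED-native internally, VCF POS converted at the variant boundary).

#' Construct a region set
#'
#' A region set is a sorted, merged list of 0-based half-open intervals
#' `[start, end)`. Overlapping and book-ended (adjacent) intervals are
#' merged on construction, so the stored intervals are pairwise
#' disjoint.
#'
#' @param chrom Character vector of contig names.
#' @param start,end Integer 0-based half-open bounds, `start < end`.
#' @param label Free-text label carried as an attribute.
#' @return A `data.table` of class `"region_set"` with columns
#'   `chrom`, `start`, `end`.
#' @export
#' @examples
#' region_set(c("chr1", "chr1"), c(10L, 15L), c(20L, 30L))  # one interval [10,30)
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), label = "") {
  dt <- data.table(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end))
  if (nrow(dt) && any(dt$start >= dt$end)) {
    stop("region_set: start >= end at row ", which(dt$start >= dt$end)[1L],
         call. = FALSE)
  }
  if (nrow(dt) && any(dt$start < 0L)) {
    stop("region_set: negative start", call. = FALSE)
  }
  dt <- merge_intervals(dt)
  setattr(dt, "class", c("region_set", class(dt)))
  setattr(dt, "label", label)
  dt[]
}

# merge overlapping/adjacent intervals per chrom via IRanges::reduce
merge_intervals <- function(dt) {
  if (nrow(dt) == 0L) return(dt)
  out <- dt[, {
    r <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
    list(start = IRanges::start(r) - 1L, end = IRanges::end(r))
  }, by = chrom]
  setorder(out, chrom, start)
  out
}

as_granges <- function(rs) {
  GenomicRanges::GRanges(
    seqnames = rs$chrom,
    ranges = IRanges::IRanges(start = rs$start + 1L, end = rs$end))
}

#' Read a BED file into a region set
#'
#' Reads a 3+ column BED (0-based half-open); extra columns are
#' ignored. Intervals are merged and sorted. Lines with `start >= end`
#' raise a parse error naming the line.
#'
#' @param path Path to a BED file.
#' @param label Optional label for the region set.
#' @return A [region_set()].
#' @export
read_bed <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(region_set(label = label))
  raw <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
               colClasses = list(character = 1))
  if (nrow(raw) == 0L) return(region_set(label = label))
  if (ncol(raw) < 3L) stop("malformed BED (", path, "): fewer than 3 columns",
                           call. = FALSE)
  start <- suppressWarnings(as.integer(raw[[2L]]))
  end <- suppressWarnings(as.integer(raw[[3L]]))
  bad <- is.na(start) | is.na(end) | start >= end
  if (any(bad)) {
    stop("malformed BED (", path, "): bad interval at line ", which(bad)[1L],
         call. = FALSE)
  }
  region_set(chrom = raw[[1L]], start = start, end = end, label = label)
}

#' Write a region set as 3-column BED
#' @param x A [region_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (nrow(x)) {
    writeLines(paste(x$chrom, x$start, x$end, sep = "\t"), path)
  } else {
    writeLines(character(), path)
  }
  invisible(path)
}

#' Intersect two region sets
#'
#' Exact interval intersection under half-open semantics: book-ended
#' intervals (e.g. `[10,20)` and `[20,30)`) share no base and intersect
#' to nothing.
#'
#' @param a,b [region_set()] objects.
#' @param label Label for the result.
#' @return A [region_set()] with
#'   `covered_length(result) <= min(covered_length(a), covered_length(b))`.
#' @export
intersect_regions <- function(a, b, label = "intersection") {
  if (nrow(a) == 0L || nrow(b) == 0L) return(region_set(label = label))
  common <- intersect(unique(a$chrom), unique(b$chrom))
  if (length(common) == 0L) return(region_set(label = label))
  ga <- as_granges(a[chrom %in% common])
  gb <- as_granges(b[chrom %in% common])
  gi <- suppressWarnings(GenomicRanges::intersect(ga, gb))
  region_set(chrom = as.character(GenomicRanges::seqnames(gi)),
             start = GenomicRanges::start(gi) - 1L,
             end = GenomicRanges::end(gi), label = label)
}

#' Total number of bases covered by a region set
#' @param x A [region_set()].
#' @return Non-negative integer (sum of interval widths).
#' @export
covered_length <- function(x) {
  if (nrow(x) == 0L) return(0L)
  sum(x$end - x$start)
}

#' Restrict variants to an evaluation territory
#'
#' Keeps a variant iff its reference span `[pos - 1, pos - 1 + nchar(ref))`
#' (0-based half-open) is fully contained in a single interval of the
#' territory. Full containment (not mere overlap) is required so that
#' deletions half-inside a region edge are not scored against truth that
#' was clipped at the same edge. The number of dropped records is
#' attached as `attr(out, "n_dropped")`.
#'
#' @param x A [callset()] (or primitive callset).
#' @param territory A [region_set()].
#' @return The filtered callset, same class as `x`.
#' @export
restrict_variants <- function(x, territory) {
  cls <- class(x)
  if (nrow(x) == 0L) {
    setattr(x, "n_dropped", 0L)
    return(x)
  }
  if (nrow(territory) == 0L) {
    out <- x[0L]
    setattr(out, "class", cls)
    setattr(out, "n_dropped", nrow(x))
    return(out)
  }
  gx <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$pos, end = x$pos + nchar(x$ref) - 1L))
  gt <- as_granges(territory)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gx, gt, type = "within"))
  keep_idx <- sort(unique(S4Vectors::queryHits(hits)))
  out <- x[keep_idx]
  setattr(out, "class", cls)
  setattr(out, "n_dropped", nrow(x) - length(keep_idx))
  out
}
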