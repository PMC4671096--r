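# Multi-caller concordance: merge per-aligner callsets for each caller,
# filter at a QUAL threshold, and partition the union of call keys into
# Venn regions (one per non-empty subset of callers).

call_key <- function(dt, genotype_aware = TRUE) {
  if (genotype_aware) {
    paste(dt$chrom, dt$pos, dt$ref, dt$alt, dt$gt1, dt$gt2, sep = ":")
  } else {
    paste(dt$chrom, dt$pos, dt$ref, dt$alt, sep = ":")
  }
}

#' Merge per-aligner callsets for one caller
#'
#' Union over the call identity `(chrom, pos, ref, alt, genotype)`;
#' when the same call was produced from several aligners, the maximum
#' QUAL is kept.
#'
#' @param callsets A list of primitive callsets (one per aligner).
#' @return A single callset of the same class as the first element.
#' @export
merge_aligners <- function(callsets) {
  stopifnot(length(callsets) >= 1L)
  cls <- class(callsets[[1L]])
  all_ <- rbindlist(lapply(callsets, as.data.table), use.names = TRUE,
                    fill = TRUE)
  if (nrow(all_) == 0L) return(callsets[[1L]])
  setorder(all_, chrom, pos, ref, alt, gt1, gt2, -qual, na.last = TRUE)
  out <- all_[!duplicated(all_, by = c("chrom", "pos", "ref", "alt",
                                       "gt1", "gt2"))]
  setattr(out, "class", cls)
  out[]
}

#' Venn concordance of multiple callers
#'
#' Filters each caller's callset at `qual >= qual_min` (missing QUAL
#' fails), assigns every surviving call identity to exactly one Venn
#' region (the exact subset of callers containing it) and reports
#' region sizes as percentages of the union. By default the call
#' identity includes the genotype, so a site called with different
#' genotypes by two callers is discordant; set `genotype_aware = FALSE`
#' for site-level identity. Per-caller-relative percentages are also
#' returned so either denominator convention can be read off.
#'
#' @param callsets Named list (caller -> primitive callset), 2-4
#'   callers.
#' @param qual_min QUAL threshold (default 20).
#' @param genotype_aware Include the genotype in the call identity?
#' @return A `data.table` of class `"venn_concordance"`: one row per
#'   non-empty Venn region with `region` (caller names joined by
#'   `"&"`), `n`, `pct` (of the union; sums to 100), and attribute
#'   `per_caller` (region sizes as a percentage of each caller's total).
#' @export
venn_concordance <- function(callsets, qual_min = 20,
                             genotype_aware = TRUE) {
  stopifnot(length(callsets) >= 2L, !is.null(names(callsets)))
  callers <- names(callsets)
  keys <- lapply(callsets, function(cs) {
    dt <- as.data.table(cs)
    dt <- dt[!is.na(qual) & qual >= qual_min]
    unique(call_key(dt, genotype_aware))
  })
  universe <- unique(unlist(keys, use.names = FALSE))
  if (length(universe) == 0L) {
    stop("venn_concordance: union of filtered callsets is empty",
         call. = FALSE)
  }
  member <- vapply(keys, function(k) universe %in% k,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  region <- apply(member, 1L, function(m) paste(callers[m], collapse = "&"))
  tab <- data.table(region = region)[, .(n = .N), by = region]
  tab[, pct := 100 * n / length(universe)]
  # percentages relative to each caller's own filtered total
  sizes <- lengths(keys)
  per_caller <- lapply(callers, function(cl) {
    sub <- tab[grepl(paste0("(^|&)", cl, "(&|$)"), region)]
    data.table(region = sub$region, n = sub$n,
               pct_of_caller = 100 * sub$n / sizes[[cl]])
  })
  names(per_caller) <- callers
  setorder(tab, -n)
  setattr(tab, "class", unique(c("venn_concordance", class(tab))))
  setattr(tab, "per_caller", per_caller)
  setattr(tab, "n_union", length(universe))
  tab[]
}

#' Summarize Venn concordance across datasets
#'
#' Aggregates per-dataset Venn tables into the mean and sample standard
#' deviation of each region's percentage across datasets (regions
#' absent from a dataset count as 0 percent there).
#'
#' @param venns Named list of [venn_concordance()] tables, one per
#'   dataset.
#' @return A `data.table` with `region`, `mean_pct`, `sd_pct` and the
#'   per-dataset percentages in wide columns.
#' @export
concordance_summary <- function(venns) {
  stopifnot(length(venns) >= 1L)
  if (is.null(names(venns))) {
    names(venns) <- paste0("dataset", seq_along(venns))
  }
  long <- rbindlist(lapply(names(venns), function(d) {
    data.table(dataset_id = d, region = venns[[d]]$region,
               pct = venns[[d]]$pct)
  }))
  wide <- dcast(long, region ~ dataset_id, value.var = "pct", fill = 0)
  pc <- as.matrix(wide[, -1L])
  wide[, `:=`(mean_pct = rowMeans(pc),
              sd_pct = apply(pc, 1L, function(r) {
                if (length(r) < 2L) NA_real_ else sd(r)
              }))]
  setcolorder(wide, c("region", "mean_pct", "sd_pct"))
  setorder(wide, -mean_pct)
  wide[]
}
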