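# Genotype-aware comparison of a query callset against the gold
# standard: every call and every truth variant ends up in exactly one
# match result (TP, FP, FN, or GENOTYPE_ERROR), and SNP genotype errors
# are typed as IR (ignoring the reference allele), AR (adding the
# reference allele) or OTHER.

MATCH_CATEGORIES <- c("TP", "FP", "FN", "GENOTYPE_ERROR")
ERROR_CLASSES <- c("IR", "AR", "OTHER", "NONE")

#' Type a SNP genotyping error as IR, AR or OTHER
#'
#' Given an erroneous diploid SNP genotype and the gold-standard
#' genotype at the same site (as unordered pairs of allele sequences),
#' returns the error class:
#' * `IR` (ignoring the reference allele): the call is hom-alt `{A,A}`
#'   while the truth is het `{R,A}` for the same alternative allele `A`;
#' * `AR` (adding the reference allele): the call is het `{R,A}` while
#'   the truth is hom-alt `{A,A}`;
#' * `OTHER`: any other discordant pair (e.g. call `{A,A}` vs truth
#'   `{A,B}`, call `{A,B}` vs truth `{A,A}`, call `{R,A}` vs truth
#'   `{R,B}`).
#'
#' The three classes are exhaustive and mutually exclusive over all
#' unequal diploid genotype pairs.
#'
#' @param call_gt,truth_gt Character vectors of length 2: the allele
#'   sequences of the call and truth genotypes (order irrelevant).
#' @param ref The reference allele sequence at the site.
#' @return One of `"IR"`, `"AR"`, `"OTHER"`.
#' @export
#' @examples
#' classify_error(c("G", "G"), c("A", "G"), ref = "A")  # "IR"
#' classify_error(c("A", "G"), c("G", "G"), ref = "A")  # "AR"
classify_error <- function(call_gt, truth_gt, ref) {
  stopifnot(length(call_gt) == 2L, length(truth_gt) == 2L)
  cg <- sort(call_gt)
  tg <- sort(truth_gt)
  if (identical(cg, tg)) {
    stop("classify_error: genotypes are identical, not an error",
         call. = FALSE)
  }
  classify_error_vec(cg[1L], cg[2L], tg[1L], tg[2L], ref)
}

# vectorized core over sorted allele pairs
classify_error_vec <- function(c1, c2, t1, t2, ref) {
  call_hom_alt <- c1 == c2 & c1 != ref
  call_het_ra <- c1 != c2 & (c1 == ref | c2 == ref)
  call_alt <- fifelse(c1 == ref, c2, c1)
  truth_hom_alt <- t1 == t2 & t1 != ref
  truth_het_ra <- t1 != t2 & (t1 == ref | t2 == ref)
  truth_alt <- fifelse(t1 == ref, t2, t1)
  fifelse(call_hom_alt & truth_het_ra & call_alt == truth_alt, "IR",
          fifelse(call_het_ra & truth_hom_alt & call_alt == truth_alt, "AR",
                  "OTHER"))
}

#' Match a query callset against a truth set
#'
#' Joins normalized, territory-restricted calls and truth variants on
#' the key `(chrom, pos, ref, alt)`:
#' * same key, same unordered genotype: `TP`;
#' * same key, different genotype: `GENOTYPE_ERROR`, typed by
#'   [classify_error()] for SNPs (indel genotype mismatches are typed
#'   `OTHER`);
#' * a SNP call whose key is unmatched but that shares `(chrom, pos,
#'   ref)` with an unmatched truth SNP (a different alternative allele
#'   at the same site): `GENOTYPE_ERROR` / `OTHER`;
#' * remaining unmatched calls: `FP`; remaining unmatched truth: `FN`.
#'
#' Every call and every truth variant appears in exactly one result row.
#' Duplicate keys within one callset keep the highest-QUAL record (the
#' collision count is attached as `attr(out, "n_collisions")`). Records
#' whose FILTER is not `PASS` or `.` are excluded beforehand unless
#' `keep_filtered = TRUE`.
#'
#' @param calls,truth Primitive callsets from [decompose()], restricted
#'   to the same territory with [restrict_variants()].
#' @param keep_filtered Keep FILTER-failing call records?
#' @return A `data.table` of class `"match_results"`: one row per match
#'   result with the call fields (`qual`, `depth`, genotype), the truth
#'   genotype, `category` and `error_class`.
#' @export
match_callset <- function(calls, truth, keep_filtered = FALSE) {
  calls <- as.data.table(calls)
  truth <- as.data.table(truth)
  if (!keep_filtered && nrow(calls)) {
    calls <- calls[filter %in% c("PASS", ".")]
  }
  if (!"vclass" %in% names(calls)) calls[, vclass := variant_class(ref, alt)]
  if (!"vclass" %in% names(truth)) truth[, vclass := variant_class(ref, alt)]

  dedupe <- function(dt) {
    if (nrow(dt) == 0L) return(list(dt = dt, n = 0L))
    setorder(dt, chrom, pos, ref, alt, -qual, na.last = TRUE)
    dup <- duplicated(dt, by = c("chrom", "pos", "ref", "alt"))
    list(dt = dt[!dup], n = sum(dup))
  }
  dc <- dedupe(copy(calls)); calls <- dc$dt
  dtr <- dedupe(copy(truth)); truth <- dtr$dt
  if (dc$n > 0L) {
    warning(dc$n, " duplicate call key(s): kept highest QUAL", call. = FALSE)
  }

  key_of <- function(dt) paste(dt$chrom, dt$pos, dt$ref, dt$alt, sep = ":")
  calls[, key_ := key_of(calls)]
  truth[, key_ := key_of(truth)]

  matched <- merge(
    calls[, .(key_, chrom, pos, ref, alt, vclass, gt1, gt2, qual, depth,
              caller_id, aligner_id, dataset_id)],
    truth[, .(key_, gt1, gt2)],
    by = "key_", suffixes = c("", ".t"))
  setnames(matched, c("gt1.t", "gt2.t"), c("truth_gt1", "truth_gt2"))
  matched[, truth_alt := alt]

  un_calls <- calls[!key_ %in% matched$key_]
  un_truth <- truth[!key_ %in% matched$key_]

  # same-site different-alt SNPs: genotype error (OTHER) rather than FP+FN
  cross <- merge(
    un_calls[vclass == "SNP",
             .(chrom, pos, ref, alt, vclass, gt1, gt2, qual, depth,
               caller_id, aligner_id, dataset_id)],
    un_truth[vclass == "SNP", .(chrom, pos, ref, alt, gt1, gt2)],
    by = c("chrom", "pos", "ref"), suffixes = c("", ".t"))
  if (nrow(cross)) {
    # one pairing per site: keep first truth alt per call key
    cross <- cross[!duplicated(cross, by = c("chrom", "pos", "ref", "alt"))]
    cross <- cross[!duplicated(cross, by = c("chrom", "pos", "ref", "alt.t"))]
    setnames(cross, c("gt1.t", "gt2.t", "alt.t"),
             c("truth_gt1", "truth_gt2", "truth_alt"))
    cross[, key_ := paste(chrom, pos, ref, alt, sep = ":")]
    cross_truth_key <- paste(cross$chrom, cross$pos, cross$ref,
                             cross$truth_alt, sep = ":")
    un_calls <- un_calls[!key_ %in% cross$key_]
    un_truth <- un_truth[!key_ %in% cross_truth_key]
  } else {
    cross <- NULL
  }

  paired <- rbind(matched,
                  if (!is.null(cross)) cross[, names(matched), with = FALSE],
                  use.names = TRUE)
  if (nrow(paired)) {
    same_gt <- paired$gt1 == paired$truth_gt1 & paired$gt2 == paired$truth_gt2 &
      paired$alt == paired$truth_alt
    ca <- gt_alleles(paired$ref, paired$alt, paired$gt1, paired$gt2)
    ta <- gt_alleles(paired$ref, paired$truth_alt,
                     paired$truth_gt1, paired$truth_gt2)
    ecls <- classify_error_vec(pmin(ca$a1, ca$a2), pmax(ca$a1, ca$a2),
                               pmin(ta$a1, ta$a2), pmax(ta$a1, ta$a2),
                               paired$ref)
    paired[, category := fifelse(same_gt, "TP", "GENOTYPE_ERROR")]
    paired[, error_class := fifelse(same_gt, "NONE",
                                    fifelse(vclass == "SNP", ecls, "OTHER"))]
  } else {
    paired[, `:=`(category = character(), error_class = character())]
  }

  fp <- un_calls[, .(chrom, pos, ref, alt, vclass, gt1, gt2, qual, depth,
                     caller_id, aligner_id, dataset_id)]
  if (nrow(fp)) {
    fp[, `:=`(truth_gt1 = NA_integer_, truth_gt2 = NA_integer_,
              truth_alt = NA_character_, category = "FP",
              error_class = "NONE")]
  } else {
    fp[, `:=`(truth_gt1 = integer(), truth_gt2 = integer(),
              truth_alt = character(), category = character(),
              error_class = character())]
  }
  fn <- un_truth[, .(chrom, pos, ref, alt, vclass,
                     caller_id, aligner_id, dataset_id)]
  if (nrow(fn)) {
    fn[, `:=`(gt1 = NA_integer_, gt2 = NA_integer_, qual = NA_real_,
              depth = NA_integer_, truth_gt1 = un_truth$gt1,
              truth_gt2 = un_truth$gt2, truth_alt = un_truth$alt,
              category = "FN", error_class = "NONE")]
  } else {
    fn[, `:=`(gt1 = integer(), gt2 = integer(), qual = numeric(),
              depth = integer(), truth_gt1 = integer(),
              truth_gt2 = integer(), truth_alt = character(),
              category = character(), error_class = character())]
  }
  cols <- c("chrom", "pos", "ref", "alt", "vclass", "gt1", "gt2", "qual",
            "depth", "truth_gt1", "truth_gt2", "truth_alt",
            "caller_id", "aligner_id", "dataset_id",
            "category", "error_class")
  paired[, key_ := NULL]
  out <- rbind(paired[, cols, with = FALSE], fp[, cols, with = FALSE],
               fn[, cols, with = FALSE], use.names = TRUE)
  setorder(out, chrom, pos, ref, alt)
  setattr(out, "class", unique(c("match_results", class(out))))
  setattr(out, "n_collisions", dc$n)
  out[]
}

#' Confusion counts at a QUAL threshold
#'
#' Counts TP, FP, FN and genotype errors among calls with
#' `qual >= qual_min` (a missing QUAL fails every threshold). Truth
#' sites whose only call fell below the threshold are counted as FN.
#' When a territory is supplied, `tn_universe` is the number of covered
#' bases minus the number of truth variants (reference positions inside
#' the high-confidence territory other than gold-standard variants).
#'
#' @param results A [match_callset()] table.
#' @param qual_min QUAL threshold (default 0: everything with a numeric
#'   QUAL).
#' @param territory Optional [region_set()] for the TN universe.
#' @return A list of class `"confusion_counts"` with elements `tp`,
#'   `fp`, `fn`, `genotype_errors`, `n_truth`, `tn_universe`.
#' @export
confusion_counts <- function(results, qual_min = 0, territory = NULL) {
  pass <- !is.na(results$qual) & results$qual >= qual_min
  cat_ <- results$category
  tp <- sum(cat_ == "TP" & pass)
  fp <- sum(cat_ == "FP" & pass)
  ge <- sum(cat_ == "GENOTYPE_ERROR" & pass)
  n_truth <- sum(cat_ %in% c("TP", "FN", "GENOTYPE_ERROR"))
  # truth sites whose call failed the threshold become FN
  fn <- sum(cat_ == "FN") + sum(cat_ %in% c("TP", "GENOTYPE_ERROR") & !pass)
  tn_universe <- if (is.null(territory)) NA_integer_ else {
    covered_length(territory) - n_truth
  }
  structure(list(tp = tp, fp = fp, fn = fn, genotype_errors = ge,
                 n_truth = n_truth, tn_universe = tn_universe),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "<confusion_counts> TP=%d FP=%d FN=%d genotype_errors=%d (truth n=%d)\n",
    x$tp, x$fp, x$fn, x$genotype_errors, x$n_truth))
  invisible(x)
}
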