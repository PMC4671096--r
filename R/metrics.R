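# Performance metrics: precision and recall over genotype-aware
# confusion counts, QUAL-ranked precision-recall curves summarized by
# the area under the curve (APR), the aligner-vs-caller variance
# decomposition, IR/AR error probabilities, and the het/hom depth-ratio
# diagnostic.
#
# Genotype errors are the strictest consistent treatment of the
# genotype-aware TP definition: they count against precision (the call
# is wrong) and against recall (the truth genotype was not produced).

#' Precision of a confusion-count object
#'
#' `TP / (TP + FP + genotype errors)`; defined as 1.0 when no calls
#' survive (zero-call limit, so PR curves start at precision 1).
#'
#' @param c A [confusion_counts()] object.
#' @return A value in `[0, 1]`.
#' @export
precision <- function(c) {
  denom <- c$tp + c$fp + c$genotype_errors
  if (denom == 0L) return(1.0)
  c$tp / denom
}

#' Recall of a confusion-count object
#'
#' `TP / (TP + FN + genotype errors)`. Errors if the truth set is
#' empty (recall is undefined).
#'
#' @param c A [confusion_counts()] object.
#' @return A value in `[0, 1]`.
#' @export
recall <- function(c) {
  denom <- c$tp + c$fn + c$genotype_errors
  if (denom == 0L) stop("recall undefined: empty truth set", call. = FALSE)
  c$tp / denom
}

#' QUAL-ranked precision-recall curve
#'
#' Sorts calls by descending Phred-scaled QUAL and computes one
#' (recall, precision) point per distinct QUAL value, over the calls at
#' or above that threshold. Equal-QUAL calls are inseparable and enter
#' as one group; calls with missing QUAL form the final, loosest group.
#' Genotype errors count against both precision and recall.
#'
#' @param results A [match_callset()] table (optionally pre-filtered to
#'   one variant class).
#' @param truth_size Number of truth variants (recall denominator);
#'   defaults to the number of truth-backed rows in `results`.
#' @return An object of class `"pr_curve"`: list with `points` (a
#'   `data.table` with `qual`, cumulative `tp`, `fp`, `ge`, `precision`,
#'   `recall`), `truth_size`, and `apr`.
#' @export
pr_curve <- function(results, truth_size = NULL) {
  if (is.null(truth_size)) {
    truth_size <- sum(results$category %in% c("TP", "FN", "GENOTYPE_ERROR"))
  }
  if (truth_size == 0L) {
    stop("pr_curve: empty truth set", call. = FALSE)
  }
  calls <- as.data.table(results)[category %in% c("TP", "FP", "GENOTYPE_ERROR")]
  if (nrow(calls) == 0L) {
    pts <- data.table(qual = numeric(), tp = integer(), fp = integer(),
                      ge = integer(), precision = numeric(),
                      recall = numeric())
    out <- list(points = pts, truth_size = truth_size, apr = 0.0)
    class(out) <- "pr_curve"
    return(out)
  }
  setorder(calls, -qual, na.last = TRUE)
  grp_key <- ifelse(is.na(calls$qual), "NA", format(calls$qual, digits = 17))
  grp <- rleid(grp_key)
  pts <- calls[, .(qual = qual[1L],
                   tp = sum(category == "TP"),
                   fp = sum(category == "FP"),
                   ge = sum(category == "GENOTYPE_ERROR")),
               by = .(g = grp)]
  pts[, `:=`(tp = cumsum(tp), fp = cumsum(fp), ge = cumsum(ge))]
  pts[, g := NULL]
  pts[, precision := fifelse(tp + fp + ge == 0L, 1.0, tp / (tp + fp + ge))]
  pts[, recall := tp / truth_size]
  out <- list(points = pts, truth_size = truth_size,
              apr = .apr_from_points(pts, truth_size))
  class(out) <- "pr_curve"
  out
}

# step-wise average precision: sum over points of (R_i - R_{i-1}) * P_i,
# computed from integer TP increments so a perfect callset scores
# exactly 1.0
.apr_from_points <- function(pts, truth_size) {
  if (nrow(pts) == 0L) return(0.0)
  dtp <- diff(c(0L, pts$tp))
  a <- sum(dtp * pts$precision) / truth_size
  min(max(a, 0.0), 1.0)
}

#' Area under the precision-recall curve
#'
#' Step-wise average-precision integration (no linear interpolation
#' between PR points, which is known to overestimate in PR space):
#' `APR = sum_i (R_i - R_{i-1}) * P_i`, clamped to `[0, 1]`. A perfect
#' callset (all truth recovered, nothing else called) scores exactly
#' 1.0; an all-FP callset scores 0.
#'
#' @param curve A [pr_curve()] object.
#' @return APR in `[0, 1]`.
#' @export
apr <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"))
  .apr_from_points(curve$points, curve$truth_size)
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d threshold(s), truth n=%d, APR=%.4f\n",
              nrow(x$points), x$truth_size, x$apr))
  invisible(x)
}

#' Average APR standard deviation across aligners vs across callers
#'
#' Decomposes APR variation in a crossed (dataset x aligner x caller)
#' design: the mean over (dataset, caller) cells of the sample standard
#' deviation of APR across aligners, and the mean over (dataset,
#' aligner) cells of the sample standard deviation across callers. A
#' smaller first component than second means the variant caller has
#' more influence on performance than the read aligner.
#'
#' @param table A `data.frame`/`data.table` with columns `dataset_id`,
#'   `aligner_id`, `caller_id`, `apr` (and optionally `vclass`, treated
#'   as part of the dataset grouping).
#' @return Named numeric vector `c(sd_aligner_mean, sd_caller_mean)`
#'   (sample sd, n - 1 denominator). Groups with fewer than two members
#'   are skipped with a warning.
#' @export
aligner_caller_variation <- function(table) {
  dt <- as.data.table(table)
  extra <- intersect("vclass", names(dt))
  sd_over <- function(vary, fix) {
    g <- dt[, .(s = sd(apr), n = .N), by = c("dataset_id", fix, extra)]
    if (any(g$n < 2L)) {
      warning(sum(g$n < 2L), " group(s) with < 2 ", vary,
              " value(s) skipped", call. = FALSE)
      g <- g[n >= 2L]
    }
    if (nrow(g) == 0L) return(NA_real_)
    mean(g$s)
  }
  c(sd_aligner_mean = sd_over("aligner", "caller_id"),
    sd_caller_mean = sd_over("caller", "aligner_id"))
}

#' IR/AR error profile of a matched SNP callset
#'
#' Counts IR, AR and OTHER genotyping errors among classified SNP calls
#' with `qual >= qual_min`, and reports probabilities with denominator
#' `N` = all classified SNP calls at that threshold (TP + FP + genotype
#' errors). The raw counts are returned alongside so any alternative
#' denominator can be recomputed.
#'
#' @param results A [match_callset()] table.
#' @param qual_min QUAL threshold.
#' @return A list of class `"error_profile"`: `n_ir`, `n_ar`,
#'   `n_other`, `n_calls`, `p_ir`, `p_ar`.
#' @export
error_probabilities <- function(results, qual_min = 0) {
  snp <- as.data.table(results)[vclass == "SNP" &
                                  category %in% c("TP", "FP", "GENOTYPE_ERROR")]
  snp <- snp[!is.na(qual) & qual >= qual_min]
  n <- nrow(snp)
  if (n == 0L) stop("error_probabilities: no classified SNP calls",
                    call. = FALSE)
  n_ir <- sum(snp$error_class == "IR")
  n_ar <- sum(snp$error_class == "AR")
  n_other <- sum(snp$error_class == "OTHER")
  structure(list(n_ir = n_ir, n_ar = n_ar, n_other = n_other, n_calls = n,
                 p_ir = n_ir / n, p_ar = n_ar / n),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf(
    "<error_profile> IR=%d AR=%d other=%d of %d calls (p_ir=%.4f p_ar=%.4f)\n",
    x$n_ir, x$n_ar, x$n_other, x$n_calls, x$p_ir, x$p_ar))
  invisible(x)
}

#' Het/hom depth ratio of correctly called variants
#'
#' Mean read depth over true-positive heterozygous calls divided by the
#' mean depth over true-positive homozygous-alternate calls. Ratios
#' well below 1 flag datasets whose coverage is too shallow to sample
#' both alleles of heterozygous sites reliably.
#'
#' @param results A [match_callset()] table whose TP rows carry `depth`.
#' @return The depth ratio (positive numeric).
#' @export
het_hom_depth_ratio <- function(results) {
  tp <- as.data.table(results)[category == "TP" & !is.na(depth)]
  het <- tp[gt1 != gt2]
  hom <- tp[gt1 == gt2]
  if (nrow(het) == 0L || nrow(hom) == 0L) {
    stop("het_hom_depth_ratio: need TP calls with depth in both genotype ",
         "classes", call. = FALSE)
  }
  mean(het$depth) / mean(hom$depth)
}
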