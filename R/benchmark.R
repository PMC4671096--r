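# End-to-end orchestration: normalize -> restrict -> match -> metrics /
# error profile / concordance, for one truth set and any number of
# labeled query callsets.

restrict_class <- function(res, what) {
  switch(what,
         SNP = res[vclass == "SNP"],
         INDEL = res[vclass %in% c("INS", "DEL")],
         ALL = res)
}

#' Run the full benchmark for a set of query callsets
#'
#' For each query: decomposes calls and truth to allelic primitives,
#' restricts both to the evaluation territory (the intersection of the
#' high-confidence and capture regions when a capture set is given),
#' matches genotype-aware, and computes confusion counts at
#' `qual_min`, precision-recall curves and APR per variant class, the
#' IR/AR error profile, and the het/hom depth ratio. Across queries it
#' assembles the APR table, the aligner-vs-caller variance
#' decomposition (when the labels form a crossed design), and
#' per-dataset Venn concordance of callers after merging aligners.
#'
#' @param truth A [callset()] with the gold-standard genotypes.
#' @param queries Named list of [callset()]s; each should carry
#'   `caller_id` / `aligner_id` / `dataset_id` labels.
#' @param confident [region_set()] of high-confidence regions.
#' @param capture Optional [region_set()] of exome-capture regions.
#' @param qual_min QUAL threshold for counts, error profiles and
#'   concordance (default 20).
#' @param out_dir Optional directory; when given, a machine-readable
#'   `summary.json` plus per-query TSV match tables are written there.
#' @return A list of class `"benchmark_result"` with elements
#'   `per_query` (counts, curves, APRs, error profile, depth ratio,
#'   dropped-record accounting per query), `apr_table`, `variation`,
#'   `concordance`, `territory`.
#' @export
run_benchmark <- function(truth, queries, confident, capture = NULL,
                          qual_min = 20, out_dir = NULL) {
  stopifnot(length(queries) >= 1L)
  if (is.null(names(queries))) {
    names(queries) <- paste0("query", seq_along(queries))
  }
  territory <- if (is.null(capture)) confident else {
    intersect_regions(confident, capture, label = "territory")
  }
  truth_p <- restrict_variants(decompose(truth), territory)
  truth_drop <- attr(truth_p, "n_dropped")

  per_query <- lapply(names(queries), function(qn) {
    q <- queries[[qn]]
    q_p <- restrict_variants(decompose(q), territory)
    res <- match_callset(q_p, truth_p)
    counts <- lapply(c(SNP = "SNP", INDEL = "INDEL", ALL = "ALL"),
                     function(w) confusion_counts(restrict_class(res, w),
                                                  qual_min, territory))
    curves <- lapply(c(SNP = "SNP", INDEL = "INDEL", ALL = "ALL"),
                     function(w) {
                       r <- restrict_class(res, w)
                       if (sum(r$category %in%
                                 c("TP", "FN", "GENOTYPE_ERROR")) == 0L) {
                         return(NULL)
                       }
                       pr_curve(r)
                     })
    profile <- tryCatch(error_probabilities(res, qual_min),
                        error = function(e) NULL)
    ratio <- tryCatch(het_hom_depth_ratio(res), error = function(e) NA_real_)
    list(name = qn, results = res, counts = counts, curves = curves,
         apr = lapply(curves, function(cv) if (is.null(cv)) NA_real_ else cv$apr),
         error_profile = profile, het_hom_depth_ratio = ratio,
         labels = as.list(q[1L, .(caller_id, aligner_id, dataset_id)]),
         n_dropped_restrict = attr(q_p, "n_dropped"),
         n_skipped_read = attr(q, "n_skipped"))
  })
  names(per_query) <- names(queries)

  apr_table <- rbindlist(lapply(per_query, function(pq) {
    data.table(dataset_id = pq$labels$dataset_id,
               aligner_id = pq$labels$aligner_id,
               caller_id = pq$labels$caller_id,
               vclass = c("SNP", "INDEL", "ALL"),
               apr = unlist(pq$apr, use.names = FALSE))
  }))

  variation <- NULL
  design <- unique(apr_table[vclass == "ALL",
                             .(dataset_id, aligner_id, caller_id)])
  if (length(unique(design$aligner_id)) >= 2L &&
      length(unique(design$caller_id)) >= 2L) {
    variation <- suppressWarnings(
      lapply(c(SNP = "SNP", INDEL = "INDEL"), function(w) {
        tab <- apr_table[vclass == w & !is.na(apr)]
        if (nrow(tab) == 0L) return(NULL)
        aligner_caller_variation(tab)
      }))
  }

  concordance <- NULL
  meta <- rbindlist(lapply(per_query, function(pq) as.data.table(pq$labels)))
  meta[, name := names(per_query)]
  if (length(unique(meta$caller_id)) >= 2L) {
    venns <- lapply(split(meta, meta$dataset_id), function(m) {
      by_caller <- lapply(split(m$name, m$caller_id), function(nms) {
        merge_aligners(lapply(per_query[nms], function(pq) {
          as.data.table(pq$results)[category %in%
                                      c("TP", "FP", "GENOTYPE_ERROR")]
        }))
      })
      if (length(by_caller) < 2L) return(NULL)
      venn_concordance(by_caller, qual_min = qual_min)
    })
    venns <- Filter(Negate(is.null), venns)
    if (length(venns)) {
      concordance <- list(per_dataset = venns,
                          summary = concordance_summary(venns))
    }
  }

  out <- list(per_query = per_query, apr_table = apr_table,
              variation = variation, concordance = concordance,
              territory = territory, qual_min = qual_min)
  class(out) <- "benchmark_result"
  if (!is.null(out_dir)) write_benchmark(out, out_dir)
  out
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d query callset(s), qual_min=%g\n",
              length(x$per_query), x$qual_min))
  print(x$apr_table)
  invisible(x)
}

benchmark_summary_list <- function(x) {
  list(
    schema = "vcbench/summary/v1",
    qual_min = x$qual_min,
    territory_bases = covered_length(x$territory),
    per_query = lapply(x$per_query, function(pq) {
      cc <- pq$counts$ALL
      list(labels = pq$labels,
           tp = cc$tp, fp = cc$fp, fn = cc$fn,
           genotype_errors = cc$genotype_errors,
           precision = precision(cc), recall = recall(cc),
           apr_snp = pq$apr$SNP, apr_indel = pq$apr$INDEL,
           apr_all = pq$apr$ALL,
           p_ir = if (is.null(pq$error_profile)) NULL else
             pq$error_profile$p_ir,
           p_ar = if (is.null(pq$error_profile)) NULL else
             pq$error_profile$p_ar,
           het_hom_depth_ratio = pq$het_hom_depth_ratio,
           n_dropped_restrict = pq$n_dropped_restrict)
    }),
    variation = x$variation,
    concordance = if (is.null(x$concordance)) NULL else
      as.data.frame(x$concordance$summary)
  )
}

write_benchmark <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(benchmark_summary_list(x),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  for (qn in names(x$per_query)) {
    fwrite(x$per_query[[qn]]$results,
           file.path(out_dir, paste0("match_", qn, ".tsv")), sep = "\t")
  }
  fwrite(x$apr_table, file.path(out_dir, "apr_table.tsv"), sep = "\t")
  invisible(out_dir)
}

#' Simulate a benchmark scenario and write its files
#'
#' Wraps [simulate_truth()] and [simulate_callset()]: writes
#' `truth.vcf`, `confident.bed`, `capture.bed`, one query VCF per
#' caller profile, and the per-call label tables as TSV.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param profiles Named list (caller -> override list) passed to
#'   [simulate_callset()]; defaults to a single caller with the
#'   config's own rates.
#' @return Invisibly, a list with the written paths and the simulation
#'   objects.
#' @export
run_simulate <- function(cfg, out_dir, profiles = list(caller1 = list())) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_truth(cfg)
  paths <- list(
    truth = file.path(out_dir, "truth.vcf"),
    confident = file.path(out_dir, "confident.bed"),
    capture = file.path(out_dir, "capture.bed"))
  write_vcf(sim$truth, paths$truth, sample_name = "TRUTH")
  write_bed(sim$confident, paths$confident)
  write_bed(sim$capture, paths$capture)
  sims <- list()
  for (i in seq_along(profiles)) {
    cn <- names(profiles)[i]
    prof <- utils::modifyList(profiles[[i]], list(caller_id = cn))
    cs <- simulate_callset(sim, profile = prof, seed = cfg$seed + i)
    vp <- file.path(out_dir, paste0("query_", cn, ".vcf"))
    write_vcf(cs$calls, vp, sample_name = cn)
    fwrite(cs$labels, file.path(out_dir, paste0("labels_", cn, ".tsv")),
           sep = "\t")
    paths[[paste0("query_", cn)]] <- vp
    sims[[cn]] <- cs
  }
  invisible(list(paths = paths, truth_sim = sim, callsets = sims))
}
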