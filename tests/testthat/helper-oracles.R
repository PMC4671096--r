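# Independent oracles used to validate the package's computations.
# These deliberately re-derive each quantity by direct enumeration,
# without sharing code with the implementation.

library(data.table)

# --- average precision by direct threshold enumeration ----------------
# scores: numeric (NA = missing, ranks last); labels: logical, TRUE for
# a correct call; n_truth: recall denominator
oracle_average_precision <- function(scores, labels, n_truth = sum(labels)) {
  s <- ifelse(is.na(scores), -Inf, scores)
  thresholds <- sort(unique(s), decreasing = TRUE)
  ap <- 0
  prev_recall <- 0
  for (t in thresholds) {
    keep <- s >= t
    tp <- sum(labels & keep)
    p <- tp / sum(keep)
    r <- tp / n_truth
    ap <- ap + (r - prev_recall) * p
    prev_recall <- r
  }
  ap
}

# build a minimal match-results table from binary labels and scores,
# suitable for pr_curve()
labels_to_results <- function(scores, labels) {
  data.table(
    category = ifelse(labels, "TP", "FP"),
    qual = scores,
    vclass = "SNP"
  )
}

# --- haplotype reconstruction from primitives -------------------------
# Applies the primitives of one decomposed record to its REF string:
# SNPs substitute their base; left-anchored indels (ref[1] == alt[1])
# edit only the bases after their anchor; right-anchored indels (at the
# record start) edit only the bases before/under the following anchor.
oracle_reconstruct <- function(ref, pos0, prim) {
  chars <- strsplit(ref, "")[[1L]]
  n <- length(chars)
  subst <- chars
  keep <- rep(TRUE, n)
  ins_before <- vector("list", n + 1L)  # boundary b = before base b
  for (i in seq_len(nrow(prim))) {
    off <- prim$pos[i] - pos0 + 1L
    r <- prim$ref[i]; a <- prim$alt[i]
    lr <- nchar(r); la <- nchar(a)
    if (lr == 1L && la == 1L) {
      subst[off] <- a
    } else if (substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      if (la > lr) {
        ins_before[[off + 1L]] <- c(ins_before[[off + 1L]],
                                    substr(a, 2L, la))
      } else {
        keep[(off + 1L):(off + lr - 1L)] <- FALSE
      }
    } else {
      # right-anchored (gap opened the record)
      if (la > lr) {
        ins_before[[off]] <- c(ins_before[[off]], substr(a, 1L, la - 1L))
      } else {
        keep[off:(off + lr - 2L)] <- FALSE
      }
    }
  }
  out <- character(0L)
  for (b in seq_len(n + 1L)) {
    if (!is.null(ins_before[[b]])) out <- c(out, ins_before[[b]])
    if (b <= n && keep[b]) out <- c(out, subst[b])
  }
  paste(out, collapse = "")
}

# random REF/ALT pair sharing a first (anchor) base, as padded VCF
# records do; a small alphabet induces repeats that exercise
# left-alignment
random_complex_pair <- function(max_len = 30L, alphabet = c("A", "C", "G", "T")) {
  anchor <- sample(alphabet, 1L)
  lr <- sample.int(max_len, 1L)
  la <- sample.int(max_len, 1L)
  ref <- paste0(anchor, paste(sample(alphabet, lr - 1L, replace = TRUE),
                              collapse = ""))
  alt <- paste0(anchor, paste(sample(alphabet, la - 1L, replace = TRUE),
                              collapse = ""))
  if (ref == alt) return(random_complex_pair(max_len, alphabet))
  list(ref = ref, alt = alt)
}

# --- genotype enumeration over alleles {R, A, B} ----------------------
# all unordered diploid genotypes over a 3-allele site
enumerate_genotypes <- function(alleles = c("R", "A", "B")) {
  idx <- which(upper.tri(diag(length(alleles)), diag = TRUE), arr.ind = TRUE)
  lapply(seq_len(nrow(idx)), function(i) {
    sort(c(alleles[idx[i, 1L]], alleles[idx[i, 2L]]))
  })
}

# --- small simulated scenario shared by several tests -----------------
small_sim <- function(seed, ...) {
  cfg <- simulation_config(
    contig_length = 2e5, n_snp = 800, n_indel = 80, seed = seed, ...)
  simulate_truth(cfg)
}

# compare matchclass output with the simulator's label table; returns
# TRUE when every emitted call has the labeled category and class and
# the FN set equals the dropped truth sites
labels_recovered <- function(sim, cs) {
  truth_p <- restrict_variants(decompose(sim$truth), sim$territory)
  calls_p <- restrict_variants(decompose(cs$calls), sim$territory)
  res <- as.data.table(match_callset(calls_p, truth_p))
  m <- merge(res[category != "FN",
                 .(chrom, pos, ref, alt, category, error_class)],
             cs$labels, by = c("chrom", "pos", "ref", "alt"),
             suffixes = c("", ".lab"))
  nrow(m) == nrow(cs$labels) &&
    all(m$category == m$category.lab) &&
    all(m$error_class == m$error_class.lab) &&
    setequal(res[category == "FN", paste(chrom, pos, ref, alt, sep = ":")],
             cs$dropped)
}
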