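# Seeded synthetic-data generator: a diploid gold-standard callset of
# SNPs and short indels placed inside high-confidence and capture
# regions on a synthetic contig, plus degraded query callsets with
# controlled false-negative, false-positive and genotyping-error rates.
# The generator also emits a per-call label table, so classification
# can be checked against exact ground truth.

#' Simulation configuration
#'
#' Parameters of the synthetic truth set and of the degraded query
#' callsets derived from it. Defaults emulate a deeply sequenced human
#' exome benchmarked against a gold-standard callset: a few thousand
#' mostly-SNP truth variants with roughly 60 percent heterozygotes,
#' an evaluation territory that covers about half the contig, small
#' error rates, well-separated QUAL distributions for correct versus
#' erroneous calls (so a QUAL filter at 20 is meaningful), and a
#' het/hom depth ratio above 1 as seen in deep Illumina exomes.
#'
#' @param contig Contig name.
#' @param contig_length Contig length in bases.
#' @param n_snp,n_indel Number of SNP / indel truth variants
#'   (`n_snp + n_indel <= contig_length / 10`, which guarantees 10 bp
#'   site spacing).
#' @param het_fraction Probability that a truth genotype is
#'   heterozygous (otherwise hom-alt).
#' @param confident_fraction,capture_fraction Fraction of the contig
#'   covered by the high-confidence and exome-capture BEDs.
#' @param fn_rate Per-truth-site probability of not being called.
#' @param fp_rate Expected novel (false-positive) calls as a fraction
#'   of the truth count.
#' @param ir_rate Probability that an emitted heterozygous site is
#'   called hom-alt (IR error).
#' @param ar_rate Probability that an emitted hom-alt site is called
#'   het (AR error).
#' @param other_rate Probability that an emitted SNP site is called
#'   with a swapped alternative allele (OTHER error).
#'   `fn_rate + ir_rate + ar_rate + other_rate` must not exceed 1.
#' @param qual_true,qual_false Length-2 numeric `(mean, sd)` of the
#'   Phred QUAL distribution for faithful and for erroneous/novel
#'   calls; draws are truncated at 0.
#' @param depth_het_mean,depth_hom_mean Poisson means of the read depth
#'   at het and hom-alt calls.
#' @param seed Integer seed; every downstream draw is reproducible
#'   from it.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(contig = "chr1",
                              contig_length = 1e6,
                              n_snp = 3000, n_indel = 300,
                              het_fraction = 0.6,
                              confident_fraction = 0.8,
                              capture_fraction = 0.5,
                              fn_rate = 0.03, fp_rate = 0.05,
                              ir_rate = 0.02, ar_rate = 0.03,
                              other_rate = 0.005,
                              qual_true = c(45, 5),
                              qual_false = c(15, 5),
                              depth_het_mean = 49,
                              depth_hom_mean = 30,
                              seed = 1L) {
  cfg <- list(contig = contig, contig_length = as.integer(contig_length),
              n_snp = as.integer(n_snp), n_indel = as.integer(n_indel),
              het_fraction = het_fraction,
              confident_fraction = confident_fraction,
              capture_fraction = capture_fraction,
              fn_rate = fn_rate, fp_rate = fp_rate, ir_rate = ir_rate,
              ar_rate = ar_rate, other_rate = other_rate,
              qual_true = qual_true, qual_false = qual_false,
              depth_het_mean = depth_het_mean,
              depth_hom_mean = depth_hom_mean,
              seed = as.integer(seed))
  rates <- c(cfg$het_fraction, cfg$confident_fraction, cfg$capture_fraction,
             cfg$fn_rate, cfg$fp_rate, cfg$ir_rate, cfg$ar_rate,
             cfg$other_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("sim_config: all fractions/rates must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$fn_rate + cfg$ir_rate + cfg$ar_rate + cfg$other_rate > 1) {
    stop("sim_config: fn_rate + ir_rate + ar_rate + other_rate > 1",
         call. = FALSE)
  }
  if (cfg$n_snp + cfg$n_indel > cfg$contig_length / 10) {
    stop("sim_config: too many sites for the contig (need ",
         "n_snp + n_indel <= contig_length / 10)", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

BASES <- c("A", "C", "G", "T")

rand_bases <- function(n) sample(BASES, n, replace = TRUE)

other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(BASES, x), 1L), character(1L),
         USE.NAMES = FALSE)
}

# a base differing from both the reference and the current alt
third_base <- function(ref, alt) {
  mapply(function(r, a) sample(setdiff(BASES, c(r, a)), 1L), ref, alt,
         USE.NAMES = FALSE)
}

trunc_normal <- function(n, mu, sigma) pmax(rnorm(n, mu, sigma), 0)

# blocks of this size are switched on/off to build the BED tracks
SIM_BLOCK <- 2000L

sim_regions <- function(contig, contig_length, fraction) {
  n_blocks <- max(1L, contig_length %/% SIM_BLOCK)
  n_on <- round(fraction * n_blocks)
  if (n_on == 0L) return(region_set(label = "simulated"))
  on <- sort(sample.int(n_blocks, n_on))
  region_set(chrom = contig, start = (on - 1L) * SIM_BLOCK,
             end = pmin(on * SIM_BLOCK, contig_length), label = "simulated")
}

#' Simulate a gold-standard truth set
#'
#' Places `n_snp + n_indel` truth variants on a 10 bp grid (so sites
#' are at least 10 bp apart) inside the intersection of simulated
#' high-confidence and capture regions. Genotypes are heterozygous with
#' probability `het_fraction` and hom-alt otherwise; indels have
#' ref/alt lengths 1-5 with a one-base anchor. Reference bases are
#' drawn uniformly from `{A,C,G,T}` per site, so no external genome is
#' needed. Deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `"truth_sim"`: `truth` (a [callset()]),
#'   `confident`, `capture`, `territory` ([region_set()]s), `free_pos`
#'   (unused grid positions available for false-positive placement) and
#'   `cfg`.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  confident <- sim_regions(cfg$contig, cfg$contig_length,
                           cfg$confident_fraction)
  capture <- sim_regions(cfg$contig, cfg$contig_length,
                         cfg$capture_fraction)
  territory <- intersect_regions(confident, capture, label = "territory")
  n_sites <- cfg$n_snp + cfg$n_indel
  # candidate positions: 10 bp lattice, 6 bp margin so a 5-base ref
  # span is always fully contained in its interval
  cand <- unlist(lapply(seq_len(nrow(territory)), function(i) {
    s <- territory$start[i] + 1L   # 1-based
    e <- territory$end[i] - 5L
    if (e < s) return(integer())
    seq.int(s, e, by = 10L)
  }))
  if (length(cand) < n_sites) {
    stop("simulate_truth: infeasible site count (", n_sites,
         " sites, ", length(cand), " candidate positions); increase ",
         "contig_length or region fractions", call. = FALSE)
  }
  take <- sort(sample(cand, n_sites))
  is_indel <- rep(FALSE, n_sites)
  if (cfg$n_indel > 0L) {
    is_indel[sample.int(n_sites, cfg$n_indel)] <- TRUE
  }
  anchor <- rand_bases(n_sites)
  ref <- anchor
  alt <- character(n_sites)
  # SNPs
  snp_i <- which(!is_indel)
  alt[snp_i] <- other_base(anchor[snp_i])
  # indels: half insertions, half deletions, tail lengths 1-4
  ind_i <- which(is_indel)
  if (length(ind_i)) {
    is_ins <- runif(length(ind_i)) < 0.5
    tail_len <- sample.int(4L, length(ind_i), replace = TRUE)
    tails <- vapply(tail_len, function(k) paste(rand_bases(k), collapse = ""),
                    character(1L))
    ref[ind_i] <- ifelse(is_ins, anchor[ind_i],
                         paste0(anchor[ind_i], tails))
    alt[ind_i] <- ifelse(is_ins, paste0(anchor[ind_i], tails),
                         anchor[ind_i])
  }
  het <- runif(n_sites) < cfg$het_fraction
  qual <- trunc_normal(n_sites, cfg$qual_true[1L], cfg$qual_true[2L])
  depth <- rpois(n_sites, ifelse(het, cfg$depth_het_mean,
                                 cfg$depth_hom_mean))
  truth <- callset(
    chrom = cfg$contig, pos = take, ref = ref, alt = alt,
    gt1 = ifelse(het, 0L, 1L), gt2 = 1L,
    qual = qual, depth = depth, dataset_id = "simulated_truth")
  out <- list(truth = truth, confident = confident, capture = capture,
              territory = territory,
              free_pos = setdiff(cand, take), cfg = cfg)
  class(out) <- "truth_sim"
  out
}

#' Simulate a degraded query callset
#'
#' Derives a query callset from a simulated truth set: each truth site
#' is independently dropped with probability `fn_rate`; emitted
#' heterozygous sites are mis-called hom-alt with probability `ir_rate`
#' (IR), emitted hom-alt sites are mis-called het with probability
#' `ar_rate` (AR), and emitted SNP sites have their alternative allele
#' swapped with probability `other_rate` (OTHER). Indel genotype flips
#' are injected at the same rates but labeled OTHER, since the IR/AR
#' typology applies to SNPs. `round(fp_rate * n_truth)` novel SNP calls
#' are placed at unused grid positions inside the territory. Faithful
#' calls draw QUAL from `qual_true`, erroneous and novel calls from
#' `qual_false`; depth is Poisson with the mean chosen by the emitted
#' genotype. Deterministic given `seed`.
#'
#' @param sim A `"truth_sim"` from [simulate_truth()].
#' @param profile Named list of [simulation_config()] overrides (e.g. a
#'   caller-specific `ir_rate`), plus optional `caller_id`,
#'   `aligner_id`, `dataset_id` labels.
#' @param seed Seed for this callset; defaults to `cfg$seed + 1`.
#' @return A list of class `"callset_sim"`: `calls` (a [callset()]),
#'   `labels` (one row per emitted call: key fields, true `category`
#'   of `TP`, `FP` or `GENOTYPE_ERROR`, and injected `error_class`),
#'   and `dropped` (keys of truth sites withheld as FN).
#' @export
simulate_callset <- function(sim, profile = list(), seed = NULL) {
  stopifnot(inherits(sim, "truth_sim"))
  labels_in <- profile[intersect(names(profile),
                                 c("caller_id", "aligner_id", "dataset_id"))]
  overrides <- profile[setdiff(names(profile),
                               c("caller_id", "aligner_id", "dataset_id"))]
  cfg <- sim$cfg
  if (length(overrides)) {
    cfg <- do.call(simulation_config,
                   utils::modifyList(unclass(cfg), overrides))
  }
  if (is.null(seed)) seed <- cfg$seed + 1L
  set.seed(seed)
  tr <- as.data.table(sim$truth)
  n <- nrow(tr)
  het <- tr$gt1 != tr$gt2
  is_snp <- nchar(tr$ref) == 1L & nchar(tr$alt) == 1L

  drop <- runif(n) < cfg$fn_rate
  v <- runif(n)
  flip_rate <- ifelse(het, cfg$ir_rate, cfg$ar_rate)
  flip <- v < flip_rate
  swap <- !flip & is_snp & v < flip_rate + cfg$other_rate
  # pre-draw per-site randomness before FP generation so that changing
  # fp_rate leaves the truth-derived calls untouched
  swap_alt <- third_base(substr(tr$ref, 1L, 1L), substr(tr$alt, 1L, 1L))

  emit <- !drop
  calls <- tr[emit]
  e_het <- het[emit]; e_flip <- flip[emit]; e_swap <- swap[emit]
  e_snp <- is_snp[emit]
  # genotype flips
  calls[e_flip & e_het, `:=`(gt1 = 1L, gt2 = 1L)]
  calls[e_flip & !e_het, `:=`(gt1 = 0L, gt2 = 1L)]
  # alt swaps (SNPs only)
  calls[e_swap, alt := swap_alt[emit][e_swap]]
  err <- e_flip | e_swap
  ne <- nrow(calls)
  calls[, qual := fifelse(err,
                          trunc_normal(ne, cfg$qual_false[1L],
                                       cfg$qual_false[2L]),
                          trunc_normal(ne, cfg$qual_true[1L],
                                       cfg$qual_true[2L]))]
  now_het <- calls$gt1 != calls$gt2
  calls[, depth := rpois(ne, fifelse(now_het, cfg$depth_het_mean,
                                     cfg$depth_hom_mean))]
  label_cls <- rep("NONE", ne)
  label_cls[e_flip & e_snp & e_het] <- "IR"
  label_cls[e_flip & e_snp & !e_het] <- "AR"
  label_cls[e_swap | (e_flip & !e_snp)] <- "OTHER"
  label_cat <- ifelse(err, "GENOTYPE_ERROR", "TP")

  # novel false-positive SNP calls on unused grid positions; the whole
  # pool is drawn up front so that FP sets are nested in fp_rate (a
  # larger rate adds calls without redrawing the existing ones), which
  # makes APR deterministically non-increasing along an fp_rate sweep
  n_fp <- round(cfg$fp_rate * n)
  if (n_fp > length(sim$free_pos)) {
    stop("simulate_callset: not enough free positions for ", n_fp,
         " false-positive calls", call. = FALSE)
  }
  npool <- length(sim$free_pos)
  pool_pos <- sample(sim$free_pos)
  pool_ref <- rand_bases(npool)
  pool_het <- runif(npool) < cfg$het_fraction
  pool_alt <- other_base(pool_ref)
  pool_qual <- trunc_normal(npool, cfg$qual_false[1L], cfg$qual_false[2L])
  pool_depth <- rpois(npool, ifelse(pool_het, cfg$depth_het_mean,
                                    cfg$depth_hom_mean))
  if (n_fp > 0L) {
    sel <- seq_len(n_fp)
    fp_calls <- data.table(
      chrom = cfg$contig, pos = pool_pos[sel], ref = pool_ref[sel],
      alt = pool_alt[sel],
      gt1 = ifelse(pool_het[sel], 0L, 1L), gt2 = 1L,
      qual = pool_qual[sel], depth = pool_depth[sel],
      filter = "PASS", caller_id = NA_character_,
      aligner_id = NA_character_, dataset_id = NA_character_)
    calls <- rbind(calls, fp_calls, use.names = TRUE)
    label_cat <- c(label_cat, rep("FP", n_fp))
    label_cls <- c(label_cls, rep("NONE", n_fp))
  }
  for (nm in names(labels_in)) set(calls, j = nm, value = labels_in[[nm]])
  ord <- order(calls$pos)
  calls <- calls[ord]
  label_cat <- label_cat[ord]
  label_cls <- label_cls[ord]
  labels <- data.table(chrom = calls$chrom, pos = calls$pos,
                       ref = calls$ref, alt = calls$alt,
                       gt1 = calls$gt1, gt2 = calls$gt2,
                       category = label_cat, error_class = label_cls)
  out <- list(calls = as_callset(calls), labels = labels,
              dropped = tr[drop, paste(chrom, pos, ref, alt, sep = ":")])
  class(out) <- "callset_sim"
  out
}
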