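---
title: "Genotype-aware benchmarking of variant callsets: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-aware benchmarking of variant callsets: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcbench)
library(data.table)
```

## The problem

Different variant-calling pipelines applied to the same sequencing data
disagree substantially, both in which sites they call and in the
genotypes they assign. Benchmarking a pipeline therefore needs (i) a
gold-standard set of diploid genotypes believed correct inside
well-defined high-confidence regions, (ii) a canonical representation of
variants so that the same underlying event is comparable across callers,
and (iii) scoring that is *genotype-aware*: calling the right alternate
allele with the wrong zygosity is not a true positive.

`vcbench` implements this evaluation for single-sample callsets: VCF and
BED ingestion, decomposition into allelic primitives, restriction to an
evaluation territory, genotype-aware classification, QUAL-ranked
precision-recall summaries, SNP genotyping-error typology, and
multi-caller concordance. A seeded simulator generates truth sets and
degraded callsets with known error structure, so every classification
the package makes can be checked against exact ground truth.

## Classification model

After normalization and restriction, calls and truth variants are joined
on the key `(chrom, pos, ref, alt)`:

* **TP** — same key and the same unordered diploid genotype;
* **genotype error** — same key, different genotype; or a SNP call at a
  truth SNP site with a different alternative allele;
* **FP** — a call with no truth counterpart;
* **FN** — a truth variant with no (surviving) call;
* **TN** — implicitly, every covered reference base of the territory
  that is not a truth site (`tn_universe` in `confusion_counts()`).

Genotypes are unordered: phase separators are discarded on ingestion
because the error typology below is phase-free.

SNP genotype errors are typed over the alleles `{R}` (reference) and
alternatives:

| error class | call | truth |
|---|---|---|
| IR (ignoring the reference allele) | `A/A` | `R/A` |
| AR (adding the reference allele)   | `R/A` | `A/A` |
| OTHER | any other discordant pair (`A/A` vs `A/B`, `A/B` vs `A/A`, `R/A` vs `R/B`, ...) |

The three classes are exhaustive and mutually exclusive over all unequal
diploid genotype pairs, which the test suite verifies by enumeration
over a three-allele site. Indel genotype mismatches count as genotype
errors but are always typed OTHER: the IR/AR typology is a SNP concept.

A deliberate design choice is the treatment of genotype errors in the
metrics. They count against **both** precision (the emitted call is
wrong) and recall (the truth genotype was not produced). This is the
strictest convention consistent with the genotype-aware TP definition;
the counts are reported separately so a site-level analysis can be
reconstructed.

## Normalization to allelic primitives

The same indel or clustered variant can be written many ways in VCF.
`decompose()` regularizes records in three steps:

1. multi-allelic records are split into one biallelic record per ALT
   allele carried by the genotype (an uncalled ALT is dropped, a `0/0`
   record vanishes);
2. each REF/ALT pair is globally aligned (match +1, mismatch −1, a gap
   of length L costs 1 + L); aligned mismatches become SNP primitives
   and gap runs become simple indels;
3. indels are left-aligned within the record's own REF window and
   anchored on the preceding reference base, so no external genome is
   required.

Two numerical details matter. First, when a gap opens the record there
is no left anchor; the primitive is then anchored on the *following*
reference base (`ref = "GCA", alt = "A"` style), which keeps the
reconstruction property intact. Second, left-alignment shifts are
bounded so that a shifted indel never crosses a reference base already
claimed by an earlier primitive of the same record; unbounded shifting
can make the primitive set non-reconstructible (the brute-force oracle
in the test suite finds such cases, e.g. `AAA -> GA`).

The alignment tie-break among equally scoring alignments is the
deterministic one of the underlying pairwise aligner. Any optimal
alignment yields primitives that reconstruct the ALT exactly — the
invariant the tests enforce on random complex alleles — so tie-breaking
affects at most the representation of pathological records, never
correctness, and is stable run to run.

The decomposition is idempotent; primitives pass through unchanged.

## Territory restriction

Coordinates are held 0-based half-open internally (BED-native), with
VCF's 1-based POS converted at ingestion. The evaluation territory is
the exact interval intersection of the high-confidence regions with the
exome-capture regions. A variant is kept iff its reference span is
*fully contained* in a single territory interval: mere overlap would let
a deletion half-inside a region edge be scored against truth that was
clipped at the same edge. Dropped-record counts are attached to every
restriction so denominators remain auditable.

## Precision-recall curves and APR

Calls are sorted by descending Phred QUAL; each distinct QUAL value is
one threshold, and equal-QUAL calls enter as one inseparable group (any
within-tie ordering would be arbitrary and irreproducible). A missing
QUAL sorts below every numeric value and fails every numeric threshold.
At each threshold, precision and recall are computed over the calls at
or above it. The area under the precision-recall curve is the step-wise
average-precision sum

$$\mathrm{APR} = \sum_i (R_i - R_{i-1})\, P_i ,$$

without linear interpolation between PR points (interpolating in PR
space is known to overestimate). The zero-call limit defines precision
as 1, so curves start at (0, 1); this matters for APR on tiny inputs
and is stated explicitly for that reason. The integration uses integer
true-positive increments, so a callset identical to the truth scores
exactly 1.0, not 1 − ε.

The per-pipeline APRs feed a variance decomposition: the mean over
(dataset, caller) cells of the sample standard deviation of APR across
aligners, versus the mean over (dataset, aligner) cells of the standard
deviation across callers (n − 1 denominator). Comparing the two says
whether the aligner or the caller dominates performance variation.

## Concordance

For each caller, callsets from different aligners are merged by union
over the identity `(chrom, pos, ref, alt, genotype)`, keeping the
maximum QUAL for colliding identities. After filtering at
`qual >= 20`, every surviving identity is assigned to exactly one Venn
region — the exact subset of callers containing it — and region sizes
are reported as percentages of the union (they sum to 100 by
construction). Because the denominator convention for such percentages
is not standardized, per-caller-relative percentages are attached as an
attribute. Concordance identity includes the genotype by default, for
consistency with the genotype-aware TP definition; `genotype_aware =
FALSE` gives site-level identity.

One subtlety: *exclusive* Venn regions are not monotone in the QUAL
threshold (an identity can move from the triple intersection to a
single-caller region when one caller's copy falls below the cut); the
monotone quantities are the closed intersections and the union, and the
tests assert exactly those.

## The simulator

`simulate_truth()` and `simulate_callset()` emulate the structure of a
gold-standard exome benchmark, not any particular sequencing chemistry:

* a single synthetic contig (1 Mb by default) with high-confidence and
  capture tracks built from 2 kb blocks covering 80% and 50% of the
  contig;
* 3,000 SNP and 300 indel truth sites on a 10 bp lattice inside the
  territory (exome-scale SNP:indel ratio), heterozygous with
  probability 0.6; indel lengths 1–5 with a one-base anchor; reference
  bases drawn uniformly, so no external genome is needed;
* per-site degradation: drop (`fn_rate` 0.03), het→hom flips
  (`ir_rate` 0.02), hom→het flips (`ar_rate` 0.03), alternative-allele
  swaps (`other_rate` 0.005), plus `fp_rate · n` novel calls (0.05) at
  unused lattice positions;
* QUAL ~ Normal(45, 5) for faithful calls and Normal(15, 5) for
  erroneous/novel calls, truncated at 0 — well separated, so the
  QUAL ≥ 20 filter and the PR ranking are meaningful;
* depth ~ Poisson with means 49 (het) and 30 (hom), echoing the
  het/hom coverage ratio around 1.6 seen in deep Illumina exomes (tests
  of the shallow-coverage regime override these with 15/30, where the
  ratio 0.5 flags under-sampled heterozygotes).

Every emitted call carries a ground-truth label (TP, FP, or a genotype
error with its injected class), and the whole pipeline is required to
reproduce those labels *exactly* over randomized configurations. Rates
are recovered within three binomial standard errors at 2 × 10⁴ sites;
note that the Fig-4-style probability `p_ir` (denominator: all
classified SNP calls) estimates `ir_rate × het_fraction`, so rate
recovery uses the eligible-site denominators the `ErrorProfile` counts
expose.

What the simulator deliberately does **not** model: read-level errors
and alignment artifacts, platform-specific error spectra (e.g.
homopolymer indel bias of semiconductor sequencing), clustered or
complex truth variants spanning region edges, multi-sample semantics,
and correlation between QUAL and depth. Passing tests therefore show
the *evaluation machinery* is correct; they do not certify any claim
about real callers on real data.

## Problem sizes and determinism

All randomness flows through integer seeds (`simulation_config(seed =)`
and the `seed` argument of `simulate_callset()`); identical seeds give
byte-identical VCF/BED output. The shipped validation suite uses
simulations of a few hundred to 2 × 10⁴ truth sites, 1,000 random
score lists for the average-precision cross-check, and 1,000 random
complex alleles (≤ 30 bp) for the reconstruction property — sizes
chosen to exercise the asymptotics the methods rely on while keeping a
full run in the minutes range on one core.

## Worked example

```{r example}
cfg <- simulation_config(n_snp = 800, n_indel = 80,
                         contig_length = 2e5, seed = 7)
sim <- simulate_truth(cfg)
q <- simulate_callset(sim, profile = list(caller_id = "callerA",
                                          aligner_id = "alignerX",
                                          dataset_id = "d1"))
bm <- run_benchmark(sim$truth, list(callerA = q$calls),
                    sim$confident, sim$capture)
bm$per_query$callerA$counts$ALL
bm$per_query$callerA$apr
bm$per_query$callerA$error_profile
```

## Known limitations

* Matching is by exact normalized representation; there is no
  vcfeval-style haplotype-aware comparison and no positional slop for
  indels, so representationally ambiguous indels that normalization
  cannot reconcile will score as FP + FN.
* Left-alignment is bounded by the record window; cross-record MNP
  merging and genome-wide normalization are out of scope.
* FILTER semantics are binary (PASS/`.` pass, everything else excluded
  unless `keep_filtered = TRUE`); the package does not interpret
  tranche or soft-filter annotations.
* Contig names match as exact strings; `chr1` and `1` are different
  contigs by design, and any renaming must happen upstream.
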