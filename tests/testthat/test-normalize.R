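# Allelic-primitive decomposition: multi-allelic splitting, alignment
# into SNP/indel primitives, left-alignment, and reconstruction.

test_that("split_multiallelic emits one record per carried alt and remaps genotypes", {
  x <- callset(chrom = "chr1", pos = 10L, ref = "A", alt = "G,T",
               gt1 = 1L, gt2 = 2L, qual = 30)
  s <- split_multiallelic(x)
  expect_equal(s$alt, c("G", "T"))
  expect_equal(s$gt1, c(0L, 0L))
  expect_equal(s$gt2, c(1L, 1L))

  # uncalled alt dropped
  x2 <- callset(chrom = "chr1", pos = 10L, ref = "A", alt = "G,T",
                gt1 = 0L, gt2 = 2L)
  s2 <- split_multiallelic(x2)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2[, c(alt, gt1, gt2)], c("T", "0", "1"))

  # biallelic record passes through unchanged
  x3 <- callset(chrom = "chr1", pos = 10L, ref = "A", alt = "G",
                gt1 = 1L, gt2 = 1L, qual = 12)
  expect_equal(as.data.frame(split_multiallelic(x3)), as.data.frame(x3))
})

test_that("decompose handles simple, complex and left-alignable records", {
  # already primitive: deletion passes through
  d1 <- decompose(callset(chrom = "c", pos = 100L, ref = "AT", alt = "A",
                          gt1 = 0L, gt2 = 1L, qual = 5))
  expect_equal(as.data.frame(d1[, .(pos, ref, alt, vclass, gt1, gt2)]),
               data.frame(pos = 100L, ref = "AT", alt = "A",
                          vclass = "DEL", gt1 = 0L, gt2 = 1L))

  # MNP decomposes to SNPs carrying the parent genotype and qual
  d2 <- decompose(callset(chrom = "c", pos = 200L, ref = "ATT", alt = "GTC",
                          gt1 = 1L, gt2 = 1L, qual = 44))
  expect_equal(as.data.frame(d2[, .(pos, ref, alt, vclass)]),
               data.frame(pos = c(200L, 202L), ref = c("A", "T"),
                          alt = c("G", "C"), vclass = c("SNP", "SNP")))
  expect_equal(d2$gt1, c(1L, 1L))
  expect_equal(d2$qual, c(44, 44))

  # deletion is left-aligned inside the record window
  d3 <- decompose(callset(chrom = "c", pos = 300L, ref = "ACGTA",
                          alt = "AGTA", gt1 = 0L, gt2 = 1L))
  expect_equal(as.data.frame(d3[, .(pos, ref, alt, vclass)]),
               data.frame(pos = 300L, ref = "AC", alt = "A",
                          vclass = "DEL"))

  # homopolymer deletion shifts to the leftmost equivalent placement
  d4 <- decompose(callset(chrom = "c", pos = 500L, ref = "CAAAT",
                          alt = "CAAT", gt1 = 0L, gt2 = 1L))
  expect_equal(as.data.frame(d4[, .(pos, ref, alt)]),
               data.frame(pos = 500L, ref = "CA", alt = "C"))

  # REF == ALT is a no-op with a warning
  expect_warning(
    d5 <- decompose(callset(chrom = "c", pos = 1L, ref = "A", alt = "A",
                            gt1 = 0L, gt2 = 1L)),
    "REF == ALT")
  expect_equal(nrow(d5), 0L)
})

test_that("left-aligned placement agrees with a brute-force shift oracle", {
  # brute force: try every deletion placement in the window and keep
  # placements whose edited string equals the alt; leftmost must match
  set.seed(31)
  for (i in 1:50) {
    w <- paste(sample(c("A", "C"), 12, replace = TRUE), collapse = "")
    k <- sample.int(3, 1L)          # deleted length
    s0 <- sample(2:(12 - k), 1L)    # 1-based start of deleted run
    ref <- w
    alt <- paste0(substr(w, 1, s0 - 1), substr(w, s0 + k, 12))
    if (alt == ref) next
    d <- decompose(callset(chrom = "c", pos = 1000L, ref = ref, alt = alt,
                           gt1 = 0L, gt2 = 1L))
    equivalent <- Filter(function(s) {
      paste0(substr(w, 1, s - 1), substr(w, s + k, 12)) == alt
    }, seq_len(12 - k + 1))
    leftmost <- min(unlist(equivalent))
    expect_equal(nrow(d), 1L)
    expect_equal(d$vclass, "DEL")
    if (leftmost >= 2L) {
      # anchored immediately before the leftmost placement
      expect_equal(d$pos, 1000L + leftmost - 2L)
      expect_equal(d$ref, substr(w, leftmost - 1L, leftmost + k - 1L))
    } else {
      # deletion at the window start: anchored on the following base
      expect_equal(d$pos, 1000L)
      expect_equal(nchar(d$ref), k + 1L)
    }
    expect_equal(oracle_reconstruct(ref, 1000L, d), alt)
  }
})

test_that("applying primitives to REF reconstructs ALT for random complex alleles", {
  set.seed(97)
  for (i in 1:200) {
    pair <- random_complex_pair(max_len = 18L,
                                alphabet = sample(list(c("A", "C"),
                                                       c("A", "C", "G", "T")),
                                                  1L)[[1L]])
    x <- callset(chrom = "c", pos = 5000L, ref = pair$ref, alt = pair$alt,
                 gt1 = 0L, gt2 = 1L, qual = 10)
    d <- decompose(x)
    expect_equal(oracle_reconstruct(pair$ref, 5000L, d), pair$alt,
                 info = paste(pair$ref, ">", pair$alt))
  }
})

test_that("decompose is idempotent and leaves biallelic SNPs untouched", {
  set.seed(13)
  for (i in 1:40) {
    pair <- random_complex_pair(max_len = 15L)
    x <- callset(chrom = "c", pos = 100L, ref = pair$ref, alt = pair$alt,
                 gt1 = sample(0:1, 1L), gt2 = 1L, qual = 33)
    d1 <- decompose(x)
    d2 <- decompose(d1)
    cols <- c("chrom", "pos", "ref", "alt", "gt1", "gt2", "qual", "vclass")
    expect_equal(as.data.frame(d1[, cols, with = FALSE]),
                 as.data.frame(d2[, cols, with = FALSE]))
  }
  snp <- callset(chrom = "chr9", pos = 77L, ref = "T", alt = "C",
                 gt1 = 1L, gt2 = 1L, qual = 18)
  expect_equal(as.data.frame(decompose(snp)[, .(chrom, pos, ref, alt)]),
               data.frame(chrom = "chr9", pos = 77L, ref = "T", alt = "C"))
})
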