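# Genotype-aware matching against the gold standard and the IR/AR/OTHER
# error typology.

prim <- function(pos, ref, alt, gt1, gt2, qual = 50, depth = NA_integer_,
                 filter = "PASS") {
  decompose(callset(chrom = "chr1", pos = as.integer(pos), ref = ref,
                    alt = alt, gt1 = as.integer(gt1), gt2 = as.integer(gt2),
                    qual = qual, depth = depth, filter = filter))
}

test_that("calls are partitioned into TP, FP, FN and genotype errors", {
  truth <- prim(c(100L, 300L, 400L),
                c("A", "G", "A"), c("G", "A", "G"),
                c(0L, 1L, 0L), c(1L, 1L, 1L))
  calls <- prim(c(100L, 200L, 400L),
                c("A", "C", "A"), c("G", "T", "G"),
                c(0L, 0L, 1L), c(1L, 1L, 1L))
  res <- as.data.table(match_callset(calls, truth))
  expect_equal(res[pos == 100L, category], "TP")
  expect_equal(res[pos == 200L, category], "FP")
  expect_equal(res[pos == 300L, category], "FN")
  # hom-alt call at a het truth site: genotype error, typed IR
  expect_equal(res[pos == 400L, c(category, error_class)],
               c("GENOTYPE_ERROR", "IR"))
  # every call and truth variant appears exactly once
  expect_equal(nrow(res), 4L)
  expect_equal(sum(res$category %in% c("TP", "FP", "GENOTYPE_ERROR")), 3L)
  expect_equal(sum(res$category %in% c("TP", "FN", "GENOTYPE_ERROR")), 3L)
})

test_that("same-site different-alt SNPs become OTHER genotype errors, not FP+FN", {
  truth <- prim(500L, "A", "G", 0L, 1L)
  calls <- prim(500L, "A", "T", 0L, 1L)   # het with the wrong alt (RA vs RB)
  res <- as.data.table(match_callset(calls, truth))
  expect_equal(nrow(res), 1L)
  expect_equal(res$category, "GENOTYPE_ERROR")
  expect_equal(res$error_class, "OTHER")
})

test_that("indel genotype mismatches are genotype errors but never IR/AR", {
  truth <- prim(100L, "AT", "A", 0L, 1L)
  calls <- prim(100L, "AT", "A", 1L, 1L)
  res <- as.data.table(match_callset(calls, truth))
  expect_equal(res$category, "GENOTYPE_ERROR")
  expect_equal(res$error_class, "OTHER")
})

test_that("duplicate call keys keep the highest-QUAL record", {
  truth <- prim(100L, "A", "G", 0L, 1L)
  calls <- rbind(prim(100L, "A", "G", 0L, 1L, qual = 10),
                 prim(100L, "A", "G", 0L, 1L, qual = 60))
  expect_warning(res <- match_callset(calls, truth), "duplicate")
  expect_equal(nrow(res), 1L)
  expect_equal(res$qual, 60)
})

test_that("FILTER-failing calls are excluded unless requested", {
  truth <- prim(100L, "A", "G", 0L, 1L)
  calls <- prim(100L, "A", "G", 0L, 1L, filter = "q10")
  res <- as.data.table(match_callset(calls, truth))
  expect_equal(res$category, "FN")
  res2 <- as.data.table(match_callset(calls, truth, keep_filtered = TRUE))
  expect_equal(res2$category, "TP")
})

test_that("classify_error reproduces the canonical IR/AR/OTHER examples", {
  # call hom-alt vs truth het ref/alt: ignoring the reference allele
  expect_equal(classify_error(c("A", "A"), c("R", "A"), ref = "R"), "IR")
  # call het ref/alt vs truth hom-alt: adding the reference allele
  expect_equal(classify_error(c("R", "A"), c("A", "A"), ref = "R"), "AR")
  expect_equal(classify_error(c("A", "A"), c("A", "B"), ref = "R"), "OTHER")
  expect_equal(classify_error(c("A", "B"), c("A", "A"), ref = "R"), "OTHER")
  expect_equal(classify_error(c("R", "A"), c("R", "B"), ref = "R"), "OTHER")
  # IR/AR require the same alternative allele
  expect_equal(classify_error(c("A", "A"), c("R", "B"), ref = "R"), "OTHER")
  expect_error(classify_error(c("R", "A"), c("R", "A"), ref = "R"),
               "identical")
})

test_that("IR and AR are dual under swapping call and truth", {
  gts <- enumerate_genotypes()
  for (cg in gts) for (tg in gts) {
    if (identical(cg, tg)) next
    fwd <- classify_error(cg, tg, ref = "R")
    rev <- classify_error(tg, cg, ref = "R")
    expect_identical(fwd == "IR", rev == "AR")
    expect_identical(fwd == "OTHER", rev == "OTHER")
  }
})

test_that("confusion counts respect the QUAL threshold and the TN universe", {
  truth <- prim(c(100L, 200L, 300L, 400L),
                rep("A", 4), rep("G", 4), rep(0L, 4), rep(1L, 4))
  calls <- rbind(
    prim(c(100L, 200L, 300L), rep("A", 3), rep("G", 3),
         rep(0L, 3), rep(1L, 3), qual = c(50, 45, 30)),
    prim(500L, "C", "T", 0L, 1L, qual = 10))  # low-QUAL FP
  res <- match_callset(calls, truth)
  territory <- region_set("chr1", 0L, 1000L)
  cc <- confusion_counts(res, qual_min = 20, territory = territory)
  expect_equal(cc$tp, 3L)
  expect_equal(cc$fp, 0L)
  expect_equal(cc$fn, 1L)
  expect_equal(cc$tn_universe, 1000L - 4L)
  cc0 <- confusion_counts(res, qual_min = 0, territory = territory)
  expect_equal(cc0$fp, 1L)
  # a TP whose QUAL fails the threshold turns into a FN
  cc40 <- confusion_counts(res, qual_min = 40)
  expect_equal(cc40$tp, 2L)
  expect_equal(cc40$fn, 2L)
  # truth-partition invariant at every threshold
  for (q in c(0, 20, 40, 60)) {
    cq <- confusion_counts(res, q)
    expect_equal(cq$tp + cq$fn + cq$genotype_errors, cq$n_truth)
  }
})
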