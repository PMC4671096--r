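# Precision/recall, PR curves, APR, variance decomposition, error
# probabilities and the depth-ratio diagnostic.

cc <- function(tp, fp, fn, ge = 0L) {
  structure(list(tp = tp, fp = fp, fn = fn, genotype_errors = ge,
                 n_truth = tp + fn + ge, tn_universe = NA_integer_),
            class = "confusion_counts")
}

test_that("precision and recall follow their definitions and limits", {
  expect_equal(precision(cc(3L, 1L, 1L)), 0.75)
  expect_equal(recall(cc(3L, 1L, 1L)), 0.75)
  expect_equal(precision(cc(0L, 0L, 5L)), 1.0)  # zero-call convention
  expect_equal(precision(cc(5L, 0L, 0L)), 1.0)
  expect_equal(recall(cc(5L, 0L, 0L)), 1.0)
  expect_error(recall(cc(0L, 3L, 0L)), "empty truth")
  # genotype errors count against both precision and recall
  expect_equal(precision(cc(3L, 0L, 0L, ge = 1L)), 0.75)
  expect_equal(recall(cc(3L, 0L, 0L, ge = 1L)), 0.75)
})

test_that("pr_curve enumerates distinct-QUAL thresholds with tie grouping", {
  res <- data.table(category = c("TP", "FP", "TP"), qual = c(50, 40, 30))
  cv <- pr_curve(res, truth_size = 2L)
  expect_equal(cv$points$recall, c(0.5, 0.5, 1.0))
  expect_equal(cv$points$precision, c(1.0, 0.5, 2 / 3))
  expect_equal(cv$apr, 0.5 * 1.0 + 0.5 * (2 / 3))

  # equal-QUAL calls are inseparable: one point for the tied group
  tie <- data.table(category = c("TP", "FP"), qual = c(40, 40))
  cvt <- pr_curve(tie, truth_size = 1L)
  expect_equal(nrow(cvt$points), 1L)
  expect_equal(cvt$points$recall, 1.0)
  expect_equal(cvt$points$precision, 0.5)

  # all-TP callset recovering the whole truth ends at (1, 1)
  perfect <- data.table(category = rep("TP", 4L), qual = c(9, 8, 7, 6))
  cvp <- pr_curve(perfect, truth_size = 4L)
  expect_equal(tail(cvp$points$recall, 1L), 1.0)
  expect_equal(tail(cvp$points$precision, 1L), 1.0)
  expect_identical(cvp$apr, 1.0)
  expect_error(pr_curve(res, truth_size = 0L), "empty truth")
})

test_that("apr equals the independent average-precision oracle on random lists", {
  set.seed(19)
  for (i in 1:30) {
    n <- sample(5:400, 1L)
    scores <- round(runif(n, 0, 60), 1)  # ties on purpose
    labels <- runif(n) < runif(1, 0.2, 0.9)
    if (!any(labels)) labels[1L] <- TRUE
    cv <- pr_curve(labels_to_results(scores, labels),
                   truth_size = sum(labels))
    expect_equal(cv$apr, oracle_average_precision(scores, labels),
                 tolerance = 1e-12)
    expect_equal(apr(cv), cv$apr)
  }
})

test_that("pr_curve recall at the loosest threshold matches the unthresholded counts", {
  set.seed(23)
  res <- data.table(
    category = sample(c("TP", "FP", "GENOTYPE_ERROR", "FN"), 300,
                      replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1)),
    qual = round(runif(300, 1, 60), 1))
  res[category == "FN", qual := NA_real_]
  cv <- pr_curve(res)
  expect_equal(tail(cv$points$recall, 1L),
               recall(confusion_counts(res, qual_min = 0)))
})

test_that("an all-FP callset has APR zero", {
  res <- data.table(category = c(rep("FP", 10L), "FN"),
                    qual = c(round(runif(10, 1, 60), 1), NA))
  expect_equal(pr_curve(res)$apr, 0.0)
})

test_that("aligner and caller APR variation use the sample sd over crossed cells", {
  tab <- CJ(dataset_id = "d1", aligner_id = c("a1", "a2"),
            caller_id = c("c1", "c2"))
  tab[, apr := fifelse(aligner_id == "a1", 0.8, 0.9)]
  v <- aligner_caller_variation(tab)
  expect_equal(unname(v["sd_aligner_mean"]), sd(c(0.8, 0.9)))
  expect_equal(unname(v["sd_caller_mean"]), 0)
  # permutation invariance
  v2 <- aligner_caller_variation(tab[sample.int(nrow(tab))])
  expect_equal(v, v2)
  # all equal -> (0, 0)
  tab[, apr := 0.5]
  expect_equal(unname(aligner_caller_variation(tab)), c(0, 0))
  # degenerate group warns and is skipped
  expect_warning(aligner_caller_variation(tab[aligner_id == "a1"]),
                 "skipped")
})

test_that("error probabilities use all classified SNP calls as denominator", {
  res <- data.table(
    category = c(rep("TP", 8L), "GENOTYPE_ERROR", "GENOTYPE_ERROR"),
    error_class = c(rep("NONE", 8L), "IR", "AR"),
    vclass = "SNP", qual = 50)
  ep <- error_probabilities(res)
  expect_equal(ep$n_calls, 10L)
  expect_equal(ep$p_ir, 0.1)
  expect_equal(ep$p_ar, 0.1)
  res2 <- res[error_class == "NONE"]
  ep2 <- error_probabilities(res2)
  expect_equal(c(ep2$p_ir, ep2$p_ar), c(0, 0))
  expect_error(error_probabilities(res[0L]), "no classified")
})

test_that("het/hom depth ratio averages TP depths per genotype class", {
  res <- data.table(
    category = "TP", vclass = "SNP",
    gt1 = c(0L, 0L, 1L), gt2 = 1L,
    depth = c(10L, 20L, 30L), qual = 50)
  expect_equal(het_hom_depth_ratio(res), 0.5)
  res_eq <- copy(res)[, depth := 15L]
  expect_equal(het_hom_depth_ratio(res_eq), 1.0)
  expect_error(het_hom_depth_ratio(res[gt1 == 1L]), "both genotype")
})
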