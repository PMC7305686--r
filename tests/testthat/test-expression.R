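toy_pe <- function(d, h, tissues = paste0("t", seq_len(ncol(d)))) {
  n <- nrow(d)
  pairs <- data.frame(pair_id = sprintf("p%02d", seq_len(n)),
                      diploid_gene_id = sprintf("d%02d", seq_len(n)),
                      hexaploid_gene_id = sprintf("h%02d", seq_len(n)))
  colnames(d) <- colnames(h) <- tissues
  rownames(d) <- rownames(h) <- pairs$pair_id
  design <- data.frame(sample = tissues, tissue = tissues)
  PairedExpression(pairs, d, h, design)
}

test_that("replicate aggregation is the per-tissue arithmetic mean and rejects bad input", {
  tpm <- matrix(c(1, 2, 3, 10, 20, 30), nrow = 1,
                dimnames = list("g1", c("a1", "a2", "a3", "b1", "b2", "b3")))
  design <- data.frame(sample = colnames(tpm),
                       tissue = rep(c("leaf", "root"), each = 3))
  out <- aggregateReplicates(tpm, design)
  expect_equal(out["g1", "leaf"], 2)
  expect_equal(out["g1", "root"], 20)
  single <- aggregateReplicates(tpm[, "a1", drop = FALSE],
                                data.frame(sample = "a1", tissue = "leaf"))
  expect_equal(unname(single[1, 1]), 1)
  tpm[1, 2] <- NaN
  expect_error(aggregateReplicates(tpm, design), "NA/NaN")
  expect_error(aggregateReplicates(tpm[, 1:3, drop = FALSE], design), "missing")
})

test_that("a pair is expressed when either genome reaches the threshold anywhere", {
  # 4-case enumeration of the either-genome rule, including the inclusive edge
  d <- matrix(c(5, 0, 1.0, 0), ncol = 1)
  h <- matrix(c(0, 5, 0, 0.4), ncol = 1)
  pe <- flagExpressed(toy_pe(d, h))
  expect_equal(unname(SummarizedExperiment::rowData(pe)$expressed),
               c(TRUE, TRUE, TRUE, FALSE))
  # threshold is >=: exactly 1.0 TPM counts as expressed
  expect_true(SummarizedExperiment::rowData(pe)$expressed[3])
})

test_that("median-ratio factor matches construction and fixed mode returns the constant", {
  d <- matrix(rep(10, 24), ncol = 2)
  pe <- flagExpressed(toy_pe(d, d))
  expect_equal(computeNormalizationFactor(pe)$factor, 1.0)
  pe2 <- flagExpressed(toy_pe(d, d / 2))
  expect_equal(computeNormalizationFactor(pe2)$factor, 2.0, tolerance = 1e-3)
  expect_equal(computeNormalizationFactor(pe2, method = "fixed")$factor, 1.7604)
  few <- flagExpressed(toy_pe(matrix(10, 2, 1), matrix(10, 2, 1)))
  expect_error(computeNormalizationFactor(few), ">= 10 expressed pairs")
})

test_that("fold-change classification honours the inclusive 4-fold boundary", {
  # scaled ratios: 5.0, exactly 4.0, 3.9, exactly 0.25, 0.26 -> with factor 1
  d <- matrix(c(10, 10, 10, 40, 100), ncol = 1)
  h <- matrix(c(50, 40, 39, 10, 26), ncol = 1)
  pe <- flagExpressed(toy_pe(d, h))
  pe <- classifyPairs(pe, norm = 1, fold = 4, eps = 0)
  cls <- pairClasses(pe)[, 1]
  expect_equal(unname(cls),
               c("deg_up_hexaploid", "deg_up_hexaploid", "balanced",
                 "deg_up_diploid", "balanced"))
  expect_equal(unname(overallClass(pe)),
               c("deg", "deg", "balanced", "deg", "balanced"))
  expect_error(classifyPairs(pe, norm = 1, fold = 1), "fold")
  expect_error(classifyPairs(pe, norm = -2), "factor")
})

test_that("expressed pairs partition into balanced and DEG", {
  cfg <- generatorConfig(seed = 31, n_genes = 300, chrom_len = 4e6)
  m <- generateGeneModels(cfg)
  e <- generateExpression(cfg, m$pairs)
  pe <- flagExpressed(PairedExpression(m$pairs, e$tpm_diploid,
                                       e$tpm_hexaploid, e$design))
  pe <- classifyPairs(pe, computeNormalizationFactor(pe))
  rd <- SummarizedExperiment::rowData(pe)
  cls <- overallClass(pe)
  expect_true(all(cls[rd$expressed] %in% c("balanced", "deg")))
  expect_true(all(cls[!rd$expressed] == "not_expressed"))
  expect_equal(sum(cls == "balanced") + sum(cls == "deg"), sum(rd$expressed))
})

test_that("classification is invariant to rescaling one genome under median-ratio normalization", {
  cfg <- generatorConfig(seed = 32, n_genes = 200, chrom_len = 2.6e6)
  m <- generateGeneModels(cfg)
  e <- generateExpression(cfg, m$pairs)
  classify <- function(hex_scale) {
    pe <- flagExpressed(PairedExpression(m$pairs, e$tpm_diploid,
                                         e$tpm_hexaploid * hex_scale, e$design),
                        tpm_min = 0.001)  # keep the expressed set fixed too
    pe <- classifyPairs(pe, computeNormalizationFactor(pe, tpm_min = 0.001, eps = 0),
                        eps = 0, tpm_min = 0.001)
    overallClass(pe)
  }
  expect_identical(classify(1), classify(7.3))
  expect_identical(classify(1), classify(0.02))
})

test_that("conserved DEGs require the same direction in every comparison", {
  a <- data.frame(pair_id = c("p1", "p2", "p3"),
                  direction = c("up_hexaploid", "up_diploid", "up_hexaploid"))
  b <- data.frame(pair_id = c("p1", "p2", "p4"),
                  direction = c("up_hexaploid", "up_hexaploid", "up_diploid"))
  out <- conservedDegs(list(a, b))
  expect_equal(out$pair_id, "p1")           # p2 flips direction -> excluded
  expect_equal(out$direction, "up_hexaploid")
  expect_equal(nrow(conservedDegs(list(a, a, a))), 3L)
  disj <- data.frame(pair_id = "p9", direction = "up_diploid")
  expect_equal(nrow(conservedDegs(list(a, disj))), 0L)
  expect_error(conservedDegs(list(a)), ">= 2")
})

test_that("per-tissue tallies are exact and conserve the DEG count", {
  d <- matrix(c(10, 10, 10), ncol = 1)
  h <- matrix(c(50, 1, 10), ncol = 1)
  pe <- classifyPairs(flagExpressed(toy_pe(d, h)), norm = 1, eps = 0)
  s <- stageSpecificSummary(pe)
  expect_equal(s$deg_up_hexaploid, 1L)
  expect_equal(s$deg_up_diploid, 1L)
  expect_equal(s$balanced, 1L)
  expect_equal(s$deg_up_hexaploid + s$deg_up_diploid + s$balanced +
                 s$not_expressed, nrow(pe))
})
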