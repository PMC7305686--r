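test_that("context calling follows the CG/CHG/CHH definitions on both strands", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACAGTACATT"))
  # + strand: C at 2 -> CG; C at 6 (C,A,G) -> CHG; C at 11 (C,A,T) -> CHH
  expect_equal(callContext(ref, "chr1", 2, "+"), "CpG")
  expect_equal(callContext(ref, "chr1", 6, "+"), "CHG")
  expect_equal(callContext(ref, "chr1", 11, "+"), "CHH")
  # - strand is read on the reverse complement; base must be G on the reference
  ref2 <- Biostrings::DNAStringSet(c(c2 = "AACCGG"))
  expect_equal(callContext(ref2, "c2", 5, "-"), "CpG")   # revcomp(CCG) = CGG
  expect_equal(callContext(ref2, "c2", 6, "-"), "CHG")   # revcomp(CGG) = CCG
  expect_error(callContext(ref, "chr1", 11, "-"), "not C")
  expect_error(callContext(ref, "chr1", 1, "+"), "not C")
  # within 2 bp of the contig end: context undeterminable, NA with warning
  ref3 <- Biostrings::DNAStringSet(c(c3 = "AAAC"))
  expect_warning(out <- callContext(ref3, "c3", 4, "+"), "skipped")
  expect_true(is.na(out))
})

test_that("weighted methylation is read-weighted and split-invariant", {
  s <- make_sites(c(10, 20, 30), c(5, 0, 10), c(10, 10, 10))
  expect_equal(weightedMethylation(s), 0.5)   # 15/30
  expect_equal(weightedMethylation(make_sites(1:4, 7, 7)), 1.0)
  # splitting one site's reads across two entries changes nothing
  split1 <- make_sites(c(10, 10, 20, 30), c(2, 3, 0, 10), c(4, 6, 10, 10))
  expect_equal(weightedMethylation(split1), weightedMethylation(s))
  # zero-coverage sites are ignored, not counted as zeros
  s0 <- c(s, make_sites(40, 0, 0))
  expect_equal(weightedMethylation(s0), 0.5)
})

test_that("region aggregation enforces the 5-methylated-cytosine and coverage filters", {
  genes <- make_genes(1000, 3000)
  reg <- regionsForGenes(genes, "gene_body")
  mk <- function(n, meth, cov) make_sites(seq(1100, by = 50, length.out = n), meth, cov)
  # 4 qualifying sites: region not reported
  expect_equal(nrow(aggregateRegions(mk(4, 5, 10), reg, min_cov = 5)), 0L)
  # 5 fully methylated sites at the coverage cutoff: level 1.0
  out <- aggregateRegions(mk(5, 5, 5), reg, min_cov = 5)
  expect_equal(out$level, 1.0)
  expect_equal(out$n_sites, 5L)
  # a site at min_cov - 1 is excluded from both the count and the level
  s <- c(mk(5, 5, 5), make_sites(2500, 0, 4))
  out2 <- aggregateRegions(s, reg, min_cov = 5)
  expect_equal(out2$n_sites, 5L)
  expect_equal(out2$level, 1.0)
  # unmethylated covered sites are not "methylated cytosines"
  s3 <- c(mk(4, 5, 10), make_sites(2600, 0, 50))
  expect_equal(nrow(aggregateRegions(s3, reg, min_cov = 5)), 0L)
})

test_that("metaprofile bins are strand-aware and saturate at fully methylated input", {
  genes <- make_genes(5000, 8999)            # width 4000
  pos <- seq(2000, 12000, by = 25)
  sites <- make_sites(pos, 10, 10)
  prof <- metaprofile(sites, genes, expressed_ids = genes$gene_id, "CpG")
  b <- binMeans(prof$expressed)
  expect_true(all(b[prof$expressed@bin_counts > 0] == 1))
  expect_equal(sum(prof$non_expressed@bin_counts), 0L)
  # a site exactly at the TSS lands in the first gene-body bin
  one <- metaprofile(make_sites(5000, 1, 2), genes, genes$gene_id, "CpG")
  expect_equal(which(one$expressed@bin_counts > 0), 51L)
  # mirrored minus-strand gene with mirrored sites gives the same profile
  L <- 14000
  genes_m <- make_genes(L - 8999, L - 5000, strand = "-")
  sites_m <- make_sites(L - pos, 10, 10)
  prof_m <- metaprofile(sites_m, genes_m, genes_m$gene_id, "CpG")
  expect_equal(prof_m$expressed@bin_counts, prof$expressed@bin_counts)
  expect_equal(binMeans(prof_m$expressed), b)
})

test_that("TSS-window test has 80 df at full coverage and detects a planted shift", {
  n <- 30
  genes <- make_genes(seq(10000, by = 5000, length.out = n),
                      seq(12000, by = 5000, length.out = n))
  tss <- tssPositions(genes)
  expressed <- genes$gene_id[1:(n / 2)]
  mk_sites <- function(level) {
    pos <- as.vector(outer(-20:20, tss, `+`))
    gid <- rep(genes$gene_id, each = 41)
    meth <- ifelse(gid %in% expressed, round(level[1] * 10), round(level[2] * 10))
    make_sites(pos, meth, 10)
  }
  s <- mk_sites(c(0.2, 0.8))
  out <- tssWindowTest(s, genes, expressed)
  expect_equal(out$df, 80)
  expect_equal(out$n_positions, 41L)
  expect_lt(out$t, 0)          # expressed lower
  expect_lt(out$p, 1e-6)
  # identical groups: t = 0
  same <- tssWindowTest(mk_sites(c(0.5, 0.5)), genes, expressed)
  expect_equal(same$t, 0)
  # dropping one covered position shrinks the df symmetrically
  drop_pos <- unlist(lapply(tss[1:(n / 2)], function(t) t + 20))
  s3 <- s[!(GenomicRanges::start(s) %in% drop_pos)]
  expect_message(out3 <- tssWindowTest(s3, genes, expressed), "1 position")
  expect_equal(out3$df, 78)
})

test_that("DMR calls combine the q-value with context-specific deltas", {
  mkreg <- function(gene, kind, cx, meth, tot)
    data.frame(gene_id = gene, region_kind = kind, context = cx,
               n_sites = 10L, meth_reads = meth, total_reads = tot,
               level = meth / tot)
  d <- rbind(mkreg("g1", "gene_body", "CpG", 100, 1000),   # 10%
             mkreg("g2", "gene_body", "CpG", 100, 1000),
             mkreg("g3", "gene_body", "CHH", 40, 1000),    # 4%
             mkreg("g4", "gene_body", "CHG", 500, 1000))
  h <- rbind(mkreg("g1", "gene_body", "CpG", 700, 1000),   # +60 pts
             mkreg("g2", "gene_body", "CpG", 500, 1000),   # +40 pts
             mkreg("g3", "gene_body", "CHH", 160, 1000),   # +12 pts
             mkreg("g4", "gene_body", "CHG", 500, 1000))   # equal
  out <- callDmrs(d, h)
  expect_equal(out$is_dmr[out$pair_id == "g1"], TRUE)
  expect_equal(out$is_dmr[out$pair_id == "g2"], FALSE)  # q tiny but < 50 pts
  expect_lt(out$q[out$pair_id == "g2"], 0.05)
  expect_equal(out$is_dmr[out$pair_id == "g3"], TRUE)   # CHH threshold is 10
  expect_equal(out$is_dmr[out$pair_id == "g4"], FALSE)
  expect_equal(out$delta[out$pair_id == "g1"], 60)
  # identical inputs on both sides: zero DMRs at any positive threshold
  none <- callDmrs(d, d)
  expect_equal(sum(none$is_dmr), 0L)
  expect_true(all(none$delta == 0))
  # unmatched or zero-total regions are skipped
  h0 <- mkreg("g9", "gene_body", "CpG", 0, 0)
  expect_equal(nrow(callDmrs(d, h0)), 0L)
})

test_that("DMR-DEG overlap proportions count pair membership per stratum", {
  dm <- data.frame(pair_id = sprintf("p%d", 1:8), region_kind = "gene_body",
                   context = "CpG", is_dmr = TRUE)
  out <- dmrDegOverlap(dm, c("p1", "p2"))
  row <- out[out$context == "CpG" & out$region_kind == "gene_body", ]
  expect_equal(row$n_dmr, 8L)
  expect_equal(row$n_overlap, 2L)
  expect_equal(row$proportion, 0.25)
  expect_equal(dmrDegOverlap(dm, "none")$n_overlap, rep(0L, 6))
  all_in <- dmrDegOverlap(dm, dm$pair_id)
  expect_equal(all_in$proportion[all_in$context == "CpG" &
                                 all_in$region_kind == "gene_body"], 1.0)
})

test_that("pseudogene comparison recovers a constructed offset exactly", {
  genes <- make_genes(c(100, 300, 500, 700), c(200, 400, 600, 800),
                      biotype = c("gene", "gene", "pseudogene", "pseudogene"))
  reg <- data.frame(gene_id = genes$gene_id, region_kind = "gene_body",
                    context = "CpG", n_sites = 10L,
                    meth_reads = c(500, 500, 632, 632),
                    total_reads = 1000,
                    level = c(0.5, 0.5, 0.632, 0.632))
  out <- pseudogeneComparison(reg, genes)
  expect_equal(out$difference, 0.132)
  eq <- reg; eq$level <- 0.5
  expect_equal(pseudogeneComparison(eq, genes)$difference, 0)
})

test_that("the planted pseudogene elevation is recovered from the full generator", {
  cfg <- generatorConfig(seed = 17, n_genes = 120, chrom_len = 1.6e6,
                         pseudogene_fraction = 0.25, coverage_mean = 20,
                         tss_dip = c(0, 0), dmr_fraction = 0)
  m <- generateGeneModels(cfg)
  sm <- suppressWarnings(generateMethylation(cfg, m$diploid, "diploid"))
  reg <- aggregateRegions(sm$sites, regionsForGenes(m$diploid), min_cov = 5)
  out <- pseudogeneComparison(reg, m$diploid)
  # CpG clips at 1 (0.871 + 0.132), so compare CHG against its configured offset
  chg <- out$difference[out$context == "CHG"]
  # gene-level Beta spread (conc 20) at ~30 pseudogenes: sd of the mean ~ 0.02
  expect_lt(abs(chg - 0.126), 3 * 0.025)
})
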