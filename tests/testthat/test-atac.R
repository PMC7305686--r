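test_that("Tn5 shifting moves +4 forward, -5 reverse, preserving widths", {
  reads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 100), width = 50),
                                  strand = c("+", "-"))
  out <- shiftReads(reads)
  expect_equal(GenomicRanges::start(out), c(104, 95))
  expect_equal(GenomicRanges::end(out), c(153, 144))
  expect_equal(GenomicRanges::width(out), c(50, 50))
  # the correction is asymmetric: flipping strand and re-shifting is not inverse
  flip <- out
  GenomicRanges::strand(flip) <- c("-", "+")
  back <- shiftReads(flip)
  expect_false(identical(GenomicRanges::start(back), GenomicRanges::start(reads)))
  expect_warning(shiftReads(GenomicRanges::GRanges("c", IRanges::IRanges(3, 30),
                                                   strand = "-")), "clipped")
})

test_that("reproducible peaks equal the per-base intersection oracle", {
  # worked example: [1,10], [6,15], [9,20] -> [9,10]
  reps <- list(make_peaks(1, 10), make_peaks(6, 15), make_peaks(9, 20))
  out <- reproduciblePeaks(reps)
  expect_equal(GenomicRanges::start(out), 9)
  expect_equal(GenomicRanges::end(out), 10)
  # identical replicates -> identity; disjoint -> empty
  same <- list(make_peaks(c(5, 50), c(20, 70)), make_peaks(c(5, 50), c(20, 70)))
  expect_equal(as.data.frame(reproduciblePeaks(same))[, 1:3],
               as.data.frame(same[[1]])[, 1:3])
  expect_equal(length(reproduciblePeaks(list(make_peaks(1, 10),
                                             make_peaks(20, 30)))), 0L)
  expect_equal(length(reproduciblePeaks(list(make_peaks(1, 10),
                                             GenomicRanges::GRanges()))), 0L)
  # randomized instances <= 10 kb against the brute-force boolean AND
  withr::with_seed(99, {
    for (case in 1:15) {
      reps <- lapply(1:3, function(r) {
        n <- sample(1:8, 1)
        s <- sample(1:9500, n)
        make_peaks(s, pmin(10000, s + sample(1:500, n, replace = TRUE)))
      })
      got <- reproduciblePeaks(reps)
      want <- runs_from_logical(brute_intersect(reps, 10000))
      expect_equal(GenomicRanges::start(got), unname(want[, "start"]))
      expect_equal(GenomicRanges::end(got), unname(want[, "end"]))
    }
  })
})

test_that("peak merging uses an exclusive 10 bp gap rule, transitively and idempotently", {
  # 1-based equivalents of gap-9 and gap-10 pairs
  m1 <- mergeClosePeaks(make_peaks(c(1, 20), c(10, 30)))   # gap 9 -> merge
  expect_equal(length(m1), 1L)
  expect_equal(GenomicRanges::end(m1), 30)
  m2 <- mergeClosePeaks(make_peaks(c(1, 21), c(10, 30)))   # gap 10 -> keep
  expect_equal(length(m2), 2L)
  chain <- mergeClosePeaks(make_peaks(c(1, 16, 31), c(10, 25, 40)))  # gaps 5,5
  expect_equal(length(chain), 1L)
  expect_equal(GenomicRanges::end(chain), 40)
  # idempotence + all output gaps >= max_gap, against the brute oracle
  withr::with_seed(7, {
    for (case in 1:10) {
      n <- sample(2:12, 1)
      s <- sort(sample(1:5000, n))
      p <- make_peaks(s, s + sample(1:300, n, replace = TRUE))
      got <- mergeClosePeaks(p)
      expect_identical(as.data.frame(mergeClosePeaks(got)), as.data.frame(got))
      want <- brute_merge(GenomicRanges::start(p), GenomicRanges::end(p), 10L)
      expect_equal(cbind(GenomicRanges::start(got), GenomicRanges::end(got)),
                   unname(want))
      gaps <- GenomicRanges::start(got)[-1] - GenomicRanges::end(got)[-length(got)] - 1L
      expect_true(all(gaps >= 10L))
    }
  })
})

test_that("peak annotation classifies by strand-aware windows with promoter precedence", {
  # + gene: ATG 10150, CDS end 11850, TTS 12000
  g <- make_genes(10000, 12000, gene_id = "gA")
  ann <- function(s, e) annotatePeaks(make_peaks(s, e), g)$region_class
  expect_equal(ann(9000, 9100), "promoter5utr")      # 1 kb upstream of ATG
  expect_equal(ann(11000, 11100), "cds_intron")
  expect_equal(ann(13000, 13100), "utr3_downstream") # < 2 kb past TTS
  expect_equal(ann(20000, 20100), "intergenic")      # > 2 kb from the gene
  expect_equal(ann(10100, 10300), "promoter5utr")    # straddles promoter + CDS
  expect_equal(ann(11800, 12100), "cds_intron")      # straddles CDS + downstream
  # mirrored - strand gene: classes are unchanged under coordinate reflection
  L <- 30000
  gm <- make_genes(L - 12000, L - 10000, strand = "-", gene_id = "gA")
  annm <- function(s, e) annotatePeaks(make_peaks(L - e, L - s), gm)$region_class
  for (w in list(c(9000, 9100), c(11000, 11100), c(13000, 13100),
                 c(20000, 20100), c(10100, 10300)))
    expect_equal(annm(w[1], w[2]), ann(w[1], w[2]))
  # multi-gene overlap resolves to the nearest TSS
  g2 <- make_genes(c(10000, 14000), c(12000, 16000), gene_id = c("gA", "gB"))
  two <- annotatePeaks(make_peaks(13780, 13820), g2)
  expect_equal(two$gene_id, "gB")
  expect_error(annotatePeaks(make_peaks(1, 10, chrom = "chrZ"), g),
               "absent from the annotation")
})

test_that("every peak gets exactly one region class and a signed TSS distance", {
  cfg <- generatorConfig(seed = 23, n_genes = 40, chrom_len = 6e5)
  m <- generateGeneModels(cfg)
  a <- generateAtac(cfg, m$diploid, "diploid")
  peaks <- mergeClosePeaks(reproduciblePeaks(a$replicate_peaks))
  ann <- annotatePeaks(peaks, m$diploid)
  expect_true(all(ann$region_class %in%
    c("promoter5utr", "cds_intron", "utr3_downstream", "intergenic")))
  expect_true(all(is.na(ann$gene_id[ann$region_class == "intergenic"])))
  expect_true(all(!is.na(ann$gene_id[ann$region_class != "intergenic"])))
  expect_true(all(is.finite(ann$tss_distance)))
})

test_that("TSS-distance CDF counts thresholds inclusively and is monotone", {
  pk <- make_peaks(c(1, 2, 3, 4), c(100, 100, 100, 100))
  pk$tss_distance <- c(1000, -2000, 50000, 200000)
  cdf <- tssDistanceCdf(pk)
  expect_equal(unname(cdf[1]), 0.5)
  expect_equal(unname(cdf[2]), 0.75)
  pk$tss_distance <- rep(0, 4)
  expect_equal(unname(tssDistanceCdf(pk)), c(1, 1))
  withr::with_seed(1, {
    pk2 <- pk
    pk2$tss_distance <- runif(4, 0, 3e5)
    many <- tssDistanceCdf(pk2, thresholds = c(1e3, 1e4, 1e5, 3e5))
    expect_true(all(diff(many) >= 0))
  })
})

test_that("fragment periodicity finds planted combs and rejects flat histograms", {
  comb_sample <- function(period, n = 50000, seed = 3) withr::with_seed(seed, {
    len <- round(rnorm(4 * n, 200, 60))
    len <- len[len >= 50 & len <= 450]
    keep <- runif(length(len)) < (1 + 0.5 * cos(2 * pi * len / period)) / 1.5
    len[keep][1:n]
  })
  p105 <- fragmentPeriodicity(comb_sample(10.5))
  expect_lt(abs(p105$period - 10.5), 0.5)
  expect_true(p105$significant)
  p7 <- fragmentPeriodicity(comb_sample(7))
  expect_lt(abs(p7$period - 7), 0.5)
  flat <- withr::with_seed(4, sample(50:450, 50000, replace = TRUE))
  expect_false(fragmentPeriodicity(flat)$significant)
  expect_warning(fragmentPeriodicity(comb_sample(10.5)[1:500]), "low-confidence")
})

test_that("gene accessibility totals are conserved under peak splitting", {
  g <- make_genes(10000, 12000, gene_id = "gA")
  pk <- make_peaks(c(9000, 9500), c(9099, 9549))  # two promoter peaks 100+50 bp
  acc <- geneAccessibility(annotatePeaks(pk, g), g)
  prom <- acc[acc$region_class == "promoter5utr", ]
  expect_equal(prom$n_peaks, 2L)
  expect_equal(prom$total_bp, 150)
  expect_equal(acc$total_bp[acc$region_class == "any"], 150)
  # splitting a peak at an interior point conserves total bp
  split_pk <- make_peaks(c(9000, 9050, 9500), c(9049, 9099, 9549))
  acc2 <- geneAccessibility(annotatePeaks(split_pk, g), g)
  expect_equal(acc2$total_bp[acc2$region_class == "promoter5utr"], 150)
  # a gene with no peaks reports zeros
  g2 <- make_genes(c(10000, 50000), c(12000, 52000), gene_id = c("gA", "gB"))
  acc3 <- geneAccessibility(annotatePeaks(pk, g2), g2)
  expect_true(all(acc3$total_bp[acc3$gene_id == "gB"] == 0))
})

test_that("differential accessibility needs presence change or fold + absolute difference", {
  acc <- function(bp) data.frame(gene_id = "gX", region_class =
    c("promoter5utr", "cds_intron", "utr3_downstream", "any"),
    n_peaks = as.integer(bp > 0), total_bp = bp)
  pairs <- data.frame(pair_id = "p1", diploid_gene_id = "gX",
                      hexaploid_gene_id = "gX")
  run <- function(bp_d, bp_h)
    differentialAccessibility(acc(bp_d), acc(bp_h), pairs)
  only_d <- run(c(120, 0, 0, 120), c(0, 0, 0, 0))
  expect_true(only_d$differential[only_d$region_class == "promoter5utr"])
  expect_equal(sum(run(c(100, 0, 0, 100), c(60, 0, 0, 60))$differential), 0L)  # 1.67x
  expect_equal(sum(run(c(100, 0, 0, 100), c(100, 0, 0, 100))$differential), 0L)
  big <- run(c(250, 0, 0, 250), c(100, 0, 0, 100))  # 2.5x and 150 bp
  expect_true(big$differential[big$region_class == "promoter5utr"])
  # 2.5-fold but < 50 bp absolute: not flagged
  expect_equal(sum(run(c(25, 0, 0, 25), c(10, 0, 0, 10))$differential), 0L)
  # unmatched genes are skipped with a message
  p2 <- rbind(pairs, data.frame(pair_id = "p2", diploid_gene_id = "gY",
                                hexaploid_gene_id = "gY"))
  expect_message(out <- differentialAccessibility(acc(100), acc(100), p2),
                 "skipped 1")
  expect_equal(unique(out$pair_id), "p1")
})

test_that("DEG/differential-peak overlap tallies match hand counts", {
  da <- data.frame(pair_id = sprintf("p%d", 1:10), region_class = "promoter5utr",
                   bp_diploid = 1, bp_hexaploid = 0, differential = TRUE)
  degs <- sprintf("p%d", 1:10)
  out <- degAtacOverlap(da, degs[1:10][c(1:7)])
  expect_equal(out$n_overlap, 7L)
  expect_equal(out$fraction_deg_with_diff, 1.0)   # all 7 DEGs have diff peaks
  out2 <- degAtacOverlap(da, c("q1", "q2"))
  expect_equal(out2$n_overlap, 0L)
  expect_equal(out2$fraction_deg_with_diff, 0)
  out3 <- degAtacOverlap(da, degs)
  expect_equal(out3$fraction_deg_with_diff, 1.0)
  expect_equal(out3$by_class[["promoter5utr"]], 10L)
})
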