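#' Tn5 insertion-offset correction of ATAC reads
#'
#' Shifts whole reads to centre them on the transposase insertion point:
#' forward-strand reads move +4 bp, reverse-strand reads move -5 bp. The
#' correction is deliberately asymmetric (a forward/reverse round trip is not
#' the identity); read lengths are preserved.
#'
#' @param reads stranded `GRanges`.
#' @return shifted `GRanges`; reads pushed below position 1 are clipped with a
#'   warning.
#' @export
shiftReads <- function(reads) {
  offs <- ifelse(as.character(GenomicRanges::strand(reads)) == "-", -5L, 4L)
  out <- GenomicRanges::shift(reads, offs)
  low <- GenomicRanges::start(out) < 1L
  if (any(low)) {
    warning(sum(low), " read(s) clipped at position 1 after shifting")
    GenomicRanges::start(out)[low] <- 1L
  }
  out
}

#' Peak regions reproducible across all replicates
#'
#' Returns the maximal genomic intervals in which every replicate has peak
#' coverage — the strict per-base reading of "only peak areas generated in
#' all independent experiments". With `mode = "any_overlap"` the union of
#' replicate-1-anchored peaks overlapping a peak in every other replicate is
#' returned instead.
#'
#' @param replicates list (length >= 2) of peak `GRanges`.
#' @param mode `"per_base"` (default) or `"any_overlap"`.
#' @return unstranded `GRanges` of reproducible peak regions.
#' @export
reproduciblePeaks <- function(replicates, mode = c("per_base", "any_overlap")) {
  mode <- match.arg(mode)
  if (length(replicates) < 2L) stop("need >= 2 replicate peak sets")
  if (any(vapply(replicates, length, 1L) == 0L))
    return(GenomicRanges::GRanges())
  lvls <- Reduce(union, lapply(replicates, GenomeInfoDb::seqlevels))
  replicates <- lapply(replicates, function(g) {
    GenomeInfoDb::seqlevels(g) <- lvls
    GenomicRanges::reduce(g, ignore.strand = TRUE)
  })
  if (mode == "any_overlap") {
    base <- replicates[[1]]
    for (r in replicates[-1])
      base <- base[IRanges::overlapsAny(base, r)]
    return(base)
  }
  # common per-contig width so the per-base AND is aligned across replicates
  wd <- setNames(rep(0L, length(lvls)), lvls)
  for (g in replicates) {
    e <- tapply(GenomicRanges::end(g), as.character(GenomicRanges::seqnames(g)), max)
    wd[names(e)] <- pmax(wd[names(e)], e)
  }
  covs <- lapply(replicates,
                 function(g) GenomicRanges::coverage(g, width = wd) > 0L)
  all_cov <- Reduce(`&`, covs)
  gr <- methods::as(all_cov, "GRanges")
  gr <- gr[gr$score]
  S4Vectors::mcols(gr) <- NULL
  gr
}

#' Merge peaks separated by small gaps
#'
#' Peaks whose proximal ends are closer than `max_gap` bp are merged
#' (transitively); the result is sorted and non-overlapping, and the operation
#' is idempotent.
#'
#' @param peaks `GRanges`.
#' @param max_gap exclusive gap threshold in bp (default 10: gaps of 9 bp or
#'   fewer are merged, a 10 bp gap is preserved).
#' @return merged `GRanges`.
#' @export
mergeClosePeaks <- function(peaks, max_gap = 10L) {
  GenomicRanges::reduce(peaks, min.gapwidth = max_gap, ignore.strand = TRUE)
}

#' Annotate peaks with gene region classes
#'
#' Classifies each peak into one of four classes by overlap with strand-aware
#' gene windows: `promoter5utr` (from the start codon to `promoter_upstream`
#' bp upstream), `cds_intron` (start codon to the end of the coding region,
#' introns included), `utr3_downstream` (past the coding region to
#' `downstream` bp beyond the TTS), or `intergenic` (no overlap with any
#' window, i.e. farther than the window widths from genes). Peaks touching
#' several classes take the highest-precedence one (promoter > CDS >
#' downstream); peaks touching windows of several genes are assigned to the
#' gene with the nearest TSS. Models without a start codon (pseudogenes) fall
#' back to TSS/TTS anchoring for their windows.
#'
#' @param peaks `GRanges`.
#' @param genes gene-model `GRanges` (needs `atg`, `cds_end`).
#' @param promoter_upstream,downstream window sizes in bp (default 2000).
#' @return `peaks` with added metadata columns `region_class`, `gene_id`
#'   (`NA` for intergenic) and `tss_distance` (peak midpoint minus nearest
#'   TSS, in gene orientation: positive downstream of the TSS).
#' @export
annotatePeaks <- function(peaks, genes, promoter_upstream = 2000,
                          downstream = 2000) {
  chrom_ok <- as.character(GenomicRanges::seqnames(peaks)) %in%
    as.character(GenomicRanges::seqnames(genes))
  if (!all(chrom_ok))
    stop("peak(s) on contig(s) absent from the annotation: ",
         paste(unique(as.character(GenomicRanges::seqnames(peaks))[!chrom_ok]),
               collapse = ", "))
  strand <- as.character(GenomicRanges::strand(genes))
  chrom <- as.character(GenomicRanges::seqnames(genes))
  tss <- tssPositions(genes); tts <- ttsPositions(genes)
  atg <- ifelse(is.na(genes$atg), tss, genes$atg)
  cend <- ifelse(is.na(genes$cds_end), tts, genes$cds_end)
  mkwin <- function(s, e) {
    s2 <- pmin(s, e); e2 <- pmax(s, e)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(pmax(1, s2), e2))
  }
  minus <- strand == "-"
  win <- list(
    promoter5utr = mkwin(ifelse(minus, atg + 1, atg - promoter_upstream),
                         ifelse(minus, atg + promoter_upstream, atg - 1)),
    cds_intron = mkwin(atg, cend),
    utr3_downstream = mkwin(ifelse(minus, tts - downstream, cend + 1),
                            ifelse(minus, cend - 1, tts + downstream))
  )
  n <- length(peaks)
  cls <- rep("intergenic", n)
  gid <- rep(NA_character_, n)
  mid <- (GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) %/% 2L
  for (w in names(win)) {
    hits <- GenomicRanges::findOverlaps(peaks, win[[w]], ignore.strand = TRUE)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    open <- cls[qh] == "intergenic"  # precedence: first class to claim wins
    if (!any(open)) next
    qh <- qh[open]; sh <- sh[open]
    # nearest-TSS tie-break among candidate genes for the same peak
    dtss <- abs(mid[qh] - tss[sh])
    ord <- order(qh, dtss)
    first <- !duplicated(qh[ord])
    qs <- qh[ord][first]; ss <- sh[ord][first]
    cls[qs] <- w
    gid[qs] <- genes$gene_id[ss]
  }
  # signed distance to the nearest TSS (any gene, intergenic included)
  tssgr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(tss, width = 1L))
  midgr <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                  IRanges::IRanges(mid, width = 1L))
  nst <- GenomicRanges::nearest(midgr, tssgr)
  tssd <- ifelse(minus[nst], tss[nst] - mid, mid - tss[nst])
  peaks$region_class <- cls
  peaks$gene_id <- gid
  peaks$tss_distance <- tssd
  peaks
}

#' Fraction of peaks within given distances of a TSS
#'
#' @param annotated_peaks output of [annotatePeaks()].
#' @param thresholds distances in bp (default 3 kb and 100 kb).
#' @return named numeric vector of fractions of peaks with
#'   `|tss_distance| <= threshold`; nondecreasing in the threshold.
#' @export
tssDistanceCdf <- function(annotated_peaks, thresholds = c(3000, 100000)) {
  d <- abs(annotated_peaks$tss_distance)
  setNames(vapply(thresholds, function(t) mean(d <= t), numeric(1)),
           paste0("within_", thresholds, "bp"))
}

#' Dominant periodicity of the fragment-length distribution
#'
#' Builds the integer-bp length histogram, removes the slowly varying
#' envelope with a centred moving average, and scans the detrended signal's
#' spectral power over a fine period grid inside `band`, returning the
#' dominant period. The ~10.5 bp comb in ATAC fragment lengths reflects
#' single-helical-turn access of the transposase to the nucleosome-bound DNA
#' helix.
#'
#' @param fragment_lengths integer vector of fragment lengths in bp.
#' @param band numeric length-2 period search band in bp (default 5-15).
#' @param detrend_window moving-average window (odd, bp) for envelope
#'   removal.
#' @return list with `period` (bp), `amplitude` (power at the peak relative
#'   to the in-band median), `significant` (amplitude >= 15, conservative
#'   against the extreme-value inflation of a white-noise spectrum), and
#'   `low_confidence` (fewer than 1000 fragments, with a warning).
#' @export
fragmentPeriodicity <- function(fragment_lengths, band = c(5, 15),
                                detrend_window = 21L) {
  low_conf <- length(fragment_lengths) < 1000L
  if (low_conf)
    warning("fewer than 1000 fragments; periodicity estimate is low-confidence")
  rng <- range(fragment_lengths)
  lens <- rng[1]:rng[2]
  h <- tabulate(fragment_lengths - rng[1] + 1L, nbins = length(lens))
  k <- detrend_window
  env <- stats::filter(h, rep(1 / k, k), sides = 2)
  d <- h - env
  keep <- !is.na(d)
  d <- d[keep]; x <- lens[keep]
  periods <- seq(band[1], band[2], by = 0.05)
  power <- vapply(periods, function(T)
    Mod(sum(d * exp(-2i * pi * x / T)))^2, numeric(1))
  i <- which.max(power)
  amp <- power[i] / stats::median(power)
  list(period = periods[i], amplitude = amp, significant = amp >= 15,
       low_confidence = low_conf)
}

#' Per-gene accessible-chromatin summaries
#'
#' @param annotated_peaks output of [annotatePeaks()].
#' @param genes gene-model `GRanges`.
#' @return data.frame with one row per gene x region class (the three genic
#'   classes), giving `n_peaks` and `total_bp` of the peaks assigned to that
#'   gene and class, plus an `any` class row aggregating the three.
#' @export
geneAccessibility <- function(annotated_peaks, genes) {
  classes <- c("promoter5utr", "cds_intron", "utr3_downstream")
  pk <- annotated_peaks[!is.na(annotated_peaks$gene_id)]
  grid <- expand.grid(gene_id = genes$gene_id, region_class = c(classes, "any"),
                      stringsAsFactors = FALSE)
  grid$n_peaks <- 0L; grid$total_bp <- 0
  key <- paste(grid$gene_id, grid$region_class)
  if (length(pk)) {
    tab_n <- table(paste(pk$gene_id, pk$region_class))
    tab_bp <- tapply(GenomicRanges::width(pk),
                     paste(pk$gene_id, pk$region_class), sum)
    m <- match(key, names(tab_n))
    grid$n_peaks <- ifelse(is.na(m), 0L, as.integer(tab_n[m]))
    grid$total_bp <- ifelse(is.na(m), 0, as.numeric(tab_bp[names(tab_n)[m]]))
    grid$total_bp[is.na(grid$total_bp)] <- 0
    any_n <- tapply(pk$gene_id, pk$gene_id, length)
    any_bp <- tapply(GenomicRanges::width(pk), pk$gene_id, sum)
    ka <- grid$region_class == "any"
    ma <- match(grid$gene_id[ka], names(any_n))
    grid$n_peaks[ka] <- ifelse(is.na(ma), 0L, as.integer(any_n[ma]))
    grid$total_bp[ka] <- ifelse(is.na(ma), 0, as.numeric(any_bp[ma]))
  }
  grid
}

#' Genes with differential chromatin accessibility between genomes
#'
#' A gene pair is flagged in a region class when peak presence/absence
#' differs between genomes there, or when both genomes have peaks but the
#' total peak bp differs by at least `min_fold`-fold and `min_abs` bp. The
#' fold/absolute double condition keeps small fluctuations on short peaks
#' from being called.
#'
#' @param acc_diploid,acc_hexaploid outputs of [geneAccessibility()].
#' @param pairs pair table (`pair_id`, `diploid_gene_id`,
#'   `hexaploid_gene_id`); pairs with a gene missing from either
#'   accessibility table are skipped with a message.
#' @param min_fold minimum fold difference (default 2).
#' @param min_abs minimum absolute difference in bp (default 50).
#' @return data.frame per pair x genic region class: per-genome `total_bp`,
#'   `differential` flag; attribute-free, one row per (pair, class).
#' @export
differentialAccessibility <- function(acc_diploid, acc_hexaploid, pairs,
                                      min_fold = 2, min_abs = 50) {
  classes <- c("promoter5utr", "cds_intron", "utr3_downstream")
  have_d <- pairs$diploid_gene_id %in% acc_diploid$gene_id
  have_h <- pairs$hexaploid_gene_id %in% acc_hexaploid$gene_id
  skip <- !(have_d & have_h)
  if (any(skip))
    message("differentialAccessibility: skipped ", sum(skip),
            " pair(s) absent from one genome's annotation")
  pr <- pairs[!skip, , drop = FALSE]
  rows <- list()
  for (cl in classes) {
    d <- acc_diploid[acc_diploid$region_class == cl, ]
    h <- acc_hexaploid[acc_hexaploid$region_class == cl, ]
    bp_d <- d$total_bp[match(pr$diploid_gene_id, d$gene_id)]
    bp_h <- h$total_bp[match(pr$hexaploid_gene_id, h$gene_id)]
    presence_diff <- (bp_d > 0) != (bp_h > 0)
    both <- bp_d > 0 & bp_h > 0
    fold <- pmax(bp_d, bp_h) / pmin(bp_d, bp_h)
    quant_diff <- both & fold >= min_fold & abs(bp_d - bp_h) >= min_abs
    rows[[cl]] <- data.frame(
      pair_id = pr$pair_id, region_class = cl,
      bp_diploid = bp_d, bp_hexaploid = bp_h,
      differential = presence_diff | quant_diff,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap between differentially accessible genes and DEGs
#'
#' @param diff_acc output of [differentialAccessibility()].
#' @param deg_ids pair ids differentially expressed in the matched tissue.
#' @return list with `n_differential` (pairs differential in any class),
#'   `n_deg`, `n_overlap`, `fraction_deg_with_diff` and `by_class` counts of
#'   overlapping pairs per region class.
#' @export
degAtacOverlap <- function(diff_acc, deg_ids) {
  diff_pairs <- unique(diff_acc$pair_id[diff_acc$differential])
  overlap <- intersect(diff_pairs, deg_ids)
  by_class <- vapply(split(diff_acc, diff_acc$region_class), function(d)
    length(intersect(unique(d$pair_id[d$differential]), deg_ids)), integer(1))
  list(n_differential = length(diff_pairs),
       n_deg = length(deg_ids),
       n_overlap = length(overlap),
       fraction_deg_with_diff =
         if (length(deg_ids)) length(overlap) / length(deg_ids) else NA_real_,
       by_class = by_class)
}
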