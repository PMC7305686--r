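# Fixtures and independent brute-force oracles used across the suite.

# gene-model GRanges from a compact spec; defaults give a plain single-exon
# protein-coding gene with 150 bp UTRs
make_genes <- function(start, end, strand = "+", chrom = "chrA",
                       gene_id = sprintf("g%03d", seq_along(start)),
                       biotype = "gene", atg = NULL, cds_end = NULL) {
  n <- length(start)
  strand <- rep_len(strand, n); biotype <- rep_len(biotype, n)
  if (is.null(atg))
    atg <- ifelse(strand == "-", end - 150, start + 150)
  if (is.null(cds_end))
    cds_end <- ifelse(strand == "-", start + 150, end - 150)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = gene_id, biotype = biotype, atg = atg, cds_end = cds_end,
    exons = IRanges::IRangesList(lapply(seq_len(n), function(i)
      IRanges::IRanges(start[i], end[i]))))
  names(gr) <- gene_id
  gr
}

make_sites <- function(pos, n_meth, n_total, context = "CpG",
                       chrom = "chrA", strand = "+") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               strand = rep_len(strand, length(pos)))
  gr$context <- rep_len(context, length(pos))
  gr$n_meth <- as.integer(rep_len(n_meth, length(pos)))
  gr$n_total <- as.integer(rep_len(n_total, length(pos)))
  gr
}

make_peaks <- function(start, end, chrom = "chrA") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

# per-base boolean oracle for replicate intersection (1-based closed)
brute_intersect <- function(replicates, max_pos) {
  covered <- rep(TRUE, max_pos)
  for (g in replicates) {
    c1 <- rep(FALSE, max_pos)
    for (i in seq_along(g))
      c1[GenomicRanges::start(g)[i]:GenomicRanges::end(g)[i]] <- TRUE
    covered <- covered & c1
  }
  covered
}

# turn a per-base logical vector into (start, end) runs
runs_from_logical <- function(covered) {
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# brute-force merge of sorted peaks: gaps < max_gap coalesce transitively
brute_merge <- function(starts, ends, max_gap) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out <- NULL
  for (i in seq_along(starts)[-1]) {
    gap <- starts[i] - me - 1L
    if (gap < max_gap) me <- max(me, ends[i])
    else { out <- rbind(out, c(ms, me)); ms <- starts[i]; me <- ends[i] }
  }
  rbind(out, c(ms, me))
}

# Needleman-Wunsch optimal global alignment score (linear gap penalty)
nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- (0:n) * gap; S[1, ] <- (0:m) * gap
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(
      S[i, j] + if (a[i] == b[j]) match else mismatch,
      S[i, j + 1] + gap,
      S[i + 1, j] + gap)
  }
  S[n + 1, m + 1]
}

# exhaustive hypergeometric upper tail: P(|draw of size nb from universe| has
# >= k elements of A), enumerating all draws
brute_hyper <- function(N, A_idx, nb, k_obs) {
  draws <- utils::combn(N, nb)
  hits <- apply(draws, 2, function(d) sum(d %in% A_idx))
  mean(hits >= k_obs)
}
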