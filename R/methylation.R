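#' Call the sequence context of a cytosine
#'
#' Classifies cytosines into the plant methylation contexts: `CpG` (CG),
#' `CHG` (C-H-G) and `CHH` (C-H-H), with H any of A/C/T. Minus-strand sites
#' are evaluated on the reverse complement (the base at `pos` must then be a
#' G on the reference).
#'
#' @param reference a [Biostrings::DNAStringSet] named by contig, or a FASTA
#'   path.
#' @param chrom contig name(s).
#' @param pos 1-based position(s).
#' @param strand `"+"` or `"-"`, recycled.
#' @return character vector of contexts; positions within 2 bp of the contig
#'   end return `NA` with a warning (context undeterminable).
#' @export
callContext <- function(reference, chrom, pos, strand = "+") {
  if (is.character(reference) && length(reference) == 1L && file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  n <- length(pos)
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  out <- rep(NA_character_, n)
  seqs <- lapply(setNames(nm = unique(chrom)),
                 function(cn) as.character(reference[[cn]]))
  for (i in seq_len(n)) {
    s <- seqs[[chrom[i]]]
    L <- nchar(s)
    if (strand[i] == "+") {
      if (substr(s, pos[i], pos[i]) != "C")
        stop("base at ", chrom[i], ":", pos[i], " (+) is not C")
      if (pos[i] + 2L > L) next  # undeterminable, left NA
      tri <- substr(s, pos[i], pos[i] + 2L)
    } else {
      if (substr(s, pos[i], pos[i]) != "G")
        stop("base at ", chrom[i], ":", pos[i], " (-) is not C")
      if (pos[i] - 2L < 1L) next
      tri <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(s, pos[i] - 2L, pos[i]))))
    }
    b2 <- substr(tri, 2, 2); b3 <- substr(tri, 3, 3)
    out[i] <- if (b2 == "G") "CpG" else if (b3 == "G") "CHG" else "CHH"
  }
  if (anyNA(out))
    warning(sum(is.na(out)), " site(s) within 2 bp of a contig end skipped")
  out
}

#' Weighted methylation level of a set of cytosines
#'
#' The read-weighted level: total methylated reads divided by total reads
#' over all sites with coverage. Invariant to splitting one site's reads
#' across duplicate entries.
#'
#' @param sites cytosine-site `GRanges` (needs `n_meth`, `n_total`).
#' @return proportion in `[0, 1]` (`NaN` when nothing is covered).
#' @export
weightedMethylation <- function(sites) {
  .check_sites(sites)
  keep <- sites$n_total > 0L
  sum(sites$n_meth[keep]) / sum(sites$n_total[keep])
}

#' Promoter and gene-body regions for a gene set
#'
#' @param genes gene-model `GRanges`.
#' @param kind `"promoter"`, `"gene_body"`, or both.
#' @param promoter_upstream promoter length upstream of the anchor, bp.
#' @param anchor `"tss"` (default, used by the methylation analyses) or
#'   `"atg"` (used by the ATAC region classes); `atg`-anchored promoters fall
#'   back to the TSS for models without a start codon.
#' @return `GRanges` with `gene_id` and `region_kind` columns; strand-aware
#'   (upstream of a "-" gene extends to larger coordinates).
#' @export
regionsForGenes <- function(genes, kind = c("promoter", "gene_body"),
                            promoter_upstream = 2000, anchor = c("tss", "atg")) {
  kind <- match.arg(kind, several.ok = TRUE)
  anchor <- match.arg(anchor)
  strand <- as.character(GenomicRanges::strand(genes))
  chrom <- as.character(GenomicRanges::seqnames(genes))
  out <- list()
  if ("promoter" %in% kind) {
    a <- if (anchor == "atg") ifelse(is.na(genes$atg), tssPositions(genes),
                                     genes$atg)
         else tssPositions(genes)
    s <- ifelse(strand == "-", a + 1, pmax(1, a - promoter_upstream))
    e <- ifelse(strand == "-", a + promoter_upstream, a - 1)
    keep <- e >= s
    gr <- GenomicRanges::GRanges(chrom[keep], IRanges::IRanges(s[keep], e[keep]),
                                 strand = strand[keep])
    gr$gene_id <- genes$gene_id[keep]; gr$region_kind <- "promoter"
    out$promoter <- gr
  }
  if ("gene_body" %in% kind) {
    gr <- GenomicRanges::granges(genes)
    S4Vectors::mcols(gr) <- NULL
    gr$gene_id <- genes$gene_id; gr$region_kind <- "gene_body"
    out$gene_body <- gr
  }
  res <- unname(out)
  do.call(c, res)
}

#' Filtered region-level methylation aggregates
#'
#' A site qualifies for a region when it matches the context, has coverage
#' `>= min_cov` and carries at least one methylated read (the literal
#' "methylated cytosine" reading). A region is reported only when it contains
#' at least `min_sites` qualifying sites; its level is the read-weighted mean
#' over those sites.
#'
#' @param sites cytosine-site `GRanges`.
#' @param regions region `GRanges` from [regionsForGenes()].
#' @param contexts contexts to aggregate (default all three).
#' @param min_sites minimum qualifying sites per region (default 5).
#' @param min_cov minimum per-site coverage (the study used 5x for the
#'   diploid capture data and 10x for the deeper hexaploid data).
#' @return data.frame `gene_id`, `region_kind`, `context`, `n_sites`,
#'   `meth_reads`, `total_reads`, `level`.
#' @export
aggregateRegions <- function(sites, regions, contexts = c("CpG", "CHG", "CHH"),
                             min_sites = 5L, min_cov = 5L) {
  .check_sites(sites)
  hits <- GenomicRanges::findOverlaps(regions, sites, ignore.strand = TRUE)
  ri <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  qual <- sites$n_total[si] >= min_cov & sites$n_meth[si] >= 1L
  rows <- list()
  for (cx in contexts) {
    k <- qual & sites$context[si] == cx
    if (!any(k)) next
    f <- factor(ri[k], levels = seq_along(regions))
    n_sites <- tabulate(f, nbins = length(regions))
    meth <- vapply(split(sites$n_meth[si[k]], f), sum, numeric(1))
    tot <- vapply(split(sites$n_total[si[k]], f), sum, numeric(1))
    keep <- n_sites >= min_sites
    if (!any(keep)) next
    rows[[cx]] <- data.frame(
      gene_id = regions$gene_id[keep],
      region_kind = regions$region_kind[keep],
      context = cx,
      n_sites = n_sites[keep],
      meth_reads = unname(meth[keep]),
      total_reads = unname(tot[keep]),
      level = unname(meth[keep] / tot[keep]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), region_kind = character(),
                      context = character(), n_sites = integer(),
                      meth_reads = numeric(), total_reads = numeric(),
                      level = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Methylation metaprofile over scaled gene bodies
#'
#' Strand-aware assignment of sites to fixed-width upstream bins, normalized
#' gene-body bins and fixed-width downstream bins, separately for expressed
#' and non-expressed genes; each bin is the read-weighted methylation of its
#' assigned sites. A site falling on several genes' windows contributes to
#' each.
#'
#' @param sites cytosine-site `GRanges`.
#' @param genes gene-model `GRanges`.
#' @param expressed_ids character vector of expressed gene ids.
#' @param context single context.
#' @param bins integer triple: upstream, body, downstream bin counts.
#' @param flank flank width in bp (profiles cover `flank` bp beyond the TSS
#'   and TTS).
#' @return list of two `MethylationMetaprofile` objects: `expressed` and
#'   `non_expressed`.
#' @export
metaprofile <- function(sites, genes, expressed_ids, context = "CpG",
                        bins = c(50L, 40L, 50L), flank = 3000) {
  .check_sites(sites)
  sites <- sites[sites$context == context & sites$n_total > 0L]
  strand <- as.character(GenomicRanges::strand(genes))
  tss <- tssPositions(genes); tts <- ttsPositions(genes)
  width <- GenomicRanges::width(genes)
  span <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(GenomicRanges::start(genes) - flank,
                     GenomicRanges::end(genes) + flank))
  hits <- GenomicRanges::findOverlaps(span, sites, ignore.strand = TRUE)
  gi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  pos <- GenomicRanges::start(sites)[si]
  # oriented distance from the TSS, positive into the gene body
  d5 <- ifelse(strand[gi] == "-", tss[gi] - pos, pos - tss[gi])
  nb <- sum(bins)
  bin <- integer(length(gi))
  in_body <- d5 >= 0 & d5 <= width[gi] - 1L
  upstream <- d5 < 0
  downstream <- d5 > width[gi] - 1L
  bin[upstream] <- pmax(1L, bins[1] + 1L + floor(d5[upstream] / (flank / bins[1])))
  frac <- d5[in_body] / pmax(width[gi][in_body], 2L)
  bin[in_body] <- bins[1] + pmin(bins[2], floor(frac * bins[2]) + 1L)
  d3 <- d5[downstream] - width[gi][downstream]
  bin[downstream] <- bins[1] + bins[2] +
    pmin(bins[3], floor(d3 / (flank / bins[3])) + 1L)

  grp <- ifelse(genes$gene_id[gi] %in% expressed_ids, "expressed", "non_expressed")
  mk <- function(g) {
    k <- grp == g
    f <- factor(bin[k], levels = seq_len(nb))
    meth <- vapply(split(sites$n_meth[si[k]], f), sum, numeric(1))
    tot <- vapply(split(sites$n_total[si[k]], f), sum, numeric(1))
    cnt <- tabulate(f, nbins = nb)
    methods::new("MethylationMetaprofile", context = context, group = g,
                 bins = unname(meth / tot), bin_counts = cnt,
                 layout = as.integer(bins), flank = flank)
  }
  list(expressed = mk("expressed"), non_expressed = mk("non_expressed"))
}

#' @rdname binMeans
#' @param x a `MethylationMetaprofile` object.
#' @return numeric vector of per-bin weighted methylation means.
#' @export
setMethod("binMeans", "MethylationMetaprofile", function(x) x@bins)

#' Expressed versus non-expressed methylation at the TSS window
#'
#' For every position of the TSS +/- `window` interval (strand-aware), the
#' read-weighted methylation across genes is computed separately for the
#' expressed and non-expressed groups, and the two per-position vectors are
#' compared with a pooled-variance two-sample t-test. With a +/-20 bp window
#' and every position covered in both groups this gives 41 + 41 - 2 = 80
#' degrees of freedom; positions lacking coverage in either group are dropped
#' from both vectors and the df shrink accordingly.
#'
#' @param sites cytosine-site `GRanges`.
#' @param genes gene-model `GRanges`.
#' @param expressed_ids expressed gene ids.
#' @param window half-width in bp (default 20).
#' @param context optional single context to restrict to (default: all sites).
#' @return list with `t`, `df`, `p`, `n_positions` (positions retained), and
#'   the two per-position mean vectors.
#' @export
tssWindowTest <- function(sites, genes, expressed_ids, window = 20L,
                          context = NULL) {
  .check_sites(sites)
  if (!is.null(context)) sites <- sites[sites$context == context]
  sites <- sites[sites$n_total > 0L]
  strand <- as.character(GenomicRanges::strand(genes))
  tss <- tssPositions(genes)
  win <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                IRanges::IRanges(tss - window, tss + window))
  hits <- GenomicRanges::findOverlaps(win, sites, ignore.strand = TRUE)
  gi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  pos <- GenomicRanges::start(sites)[si]
  off <- ifelse(strand[gi] == "-", tss[gi] - pos, pos - tss[gi])
  grp <- ifelse(genes$gene_id[gi] %in% expressed_ids, "expressed", "non_expressed")

  lev <- function(g) {
    k <- grp == g
    f <- factor(off[k], levels = -window:window)
    meth <- vapply(split(sites$n_meth[si[k]], f), sum, numeric(1))
    tot <- vapply(split(sites$n_total[si[k]], f), sum, numeric(1))
    ifelse(tot > 0, meth / tot, NA_real_)
  }
  e <- lev("expressed"); ne <- lev("non_expressed")
  keep <- !is.na(e) & !is.na(ne)
  if (sum(keep) < length(keep))
    message("tssWindowTest: ", sum(!keep), " position(s) uncovered, dropped")
  if (sum(keep) < 3L) stop("too few covered positions for a t-test")
  a <- e[keep]; b <- ne[keep]
  if (sd(a) == 0 && sd(b) == 0) {
    # degenerate: both per-position vectors constant; t is 0 (equal) or
    # unbounded (different), with the same pooled df either way
    dlt <- mean(a) - mean(b)
    tt <- list(statistic = if (dlt == 0) 0 else sign(dlt) * Inf,
               parameter = length(a) + length(b) - 2,
               p.value = if (dlt == 0) 1 else 0)
  } else {
    tt <- t.test(a, b, var.equal = TRUE)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       n_positions = sum(keep), expressed = a, non_expressed = b)
}

#' Call differentially methylated regions between genomes
#'
#' Regions are matched across genomes by (pair, region kind, context); the
#' per-region p-value comes from a two-sided two-proportion test with
#' continuity correction on the pooled (methylated, total) read counts, with
#' Benjamini-Hochberg adjustment within each context. A region is a DMR when
#' `q < q_cutoff` and the methylation difference (hexaploid - diploid, in
#' percentage points) meets the context threshold: 50 for CpG, 25 for CHG,
#' 10 for CHH by default.
#'
#' @param regions_diploid,regions_hexaploid outputs of [aggregateRegions()]
#'   for the two genomes.
#' @param pairs optional pair table (`pair_id`, `diploid_gene_id`,
#'   `hexaploid_gene_id`) used to match regions across genomes; without it,
#'   matching is on identical `gene_id`.
#' @param thresholds named vector of context thresholds in percentage points.
#' @param q_cutoff BH-adjusted significance cutoff (default 0.05).
#' @return data.frame with one row per matched region: ids, `level_diploid`,
#'   `level_hexaploid`, `delta` (percentage points), `p`, `q`, `is_dmr`.
#' @export
callDmrs <- function(regions_diploid, regions_hexaploid, pairs = NULL,
                     thresholds = c(CpG = 50, CHG = 25, CHH = 10),
                     q_cutoff = 0.05) {
  d <- regions_diploid; h <- regions_hexaploid
  if (!is.null(pairs)) {
    d$pair_id <- pairs$pair_id[match(d$gene_id, pairs$diploid_gene_id)]
    h$pair_id <- pairs$pair_id[match(h$gene_id, pairs$hexaploid_gene_id)]
  } else {
    d$pair_id <- d$gene_id; h$pair_id <- h$gene_id
  }
  d <- d[!is.na(d$pair_id) & d$total_reads > 0, ]
  h <- h[!is.na(h$pair_id) & h$total_reads > 0, ]
  key <- function(x) paste(x$pair_id, x$region_kind, x$context, sep = "|")
  m <- match(key(d), key(h))
  keep <- !is.na(m)
  d <- d[keep, ]; h <- h[m[keep], ]
  if (!nrow(d))
    return(data.frame(pair_id = character(), region_kind = character(),
                      context = character(), level_diploid = numeric(),
                      level_hexaploid = numeric(), delta = numeric(),
                      p = numeric(), q = numeric(), is_dmr = logical()))
  p <- vapply(seq_len(nrow(d)), function(i) {
    suppressWarnings(prop.test(
      x = c(h$meth_reads[i], d$meth_reads[i]),
      n = c(h$total_reads[i], d$total_reads[i])))$p.value
  }, numeric(1))
  out <- data.frame(
    pair_id = d$pair_id,
    diploid_gene_id = d$gene_id,
    hexaploid_gene_id = h$gene_id,
    region_kind = d$region_kind,
    context = d$context,
    level_diploid = d$level,
    level_hexaploid = h$level,
    delta = 100 * (h$level - d$level),
    p = p,
    stringsAsFactors = FALSE)
  out$q <- NA_real_
  for (cx in unique(out$context))
    out$q[out$context == cx] <- p.adjust(out$p[out$context == cx], "BH")
  out$is_dmr <- out$q < q_cutoff &
    abs(out$delta) >= thresholds[out$context]
  rownames(out) <- NULL
  out
}

#' Cross-tabulate DMRs against differentially expressed genes
#'
#' @param dmrs output of [callDmrs()].
#' @param deg_ids pair ids called DEG.
#' @return data.frame per (context, region_kind): `n_dmr`, `n_overlap`,
#'   `proportion` of DMRs whose pair is a DEG.
#' @export
dmrDegOverlap <- function(dmrs, deg_ids) {
  dm <- dmrs[dmrs$is_dmr, ]
  grid <- expand.grid(context = c("CpG", "CHG", "CHH"),
                      region_kind = c("gene_body", "promoter"),
                      stringsAsFactors = FALSE)
  grid$n_dmr <- grid$n_overlap <- 0L
  for (i in seq_len(nrow(grid))) {
    k <- dm$context == grid$context[i] & dm$region_kind == grid$region_kind[i]
    grid$n_dmr[i] <- sum(k)
    grid$n_overlap[i] <- sum(dm$pair_id[k] %in% deg_ids)
  }
  grid$proportion <- ifelse(grid$n_dmr > 0, grid$n_overlap / grid$n_dmr, NA_real_)
  grid
}

#' Pseudogene methylation elevation
#'
#' Difference of unweighted means of region methylation levels between
#' pseudogenes and ordinary genes, per context.
#'
#' @param regions output of [aggregateRegions()].
#' @param genes gene-model `GRanges` carrying `biotype`.
#' @param region_kind which region kind to compare (default gene bodies).
#' @return data.frame `context`, `mean_pseudogene`, `mean_gene`,
#'   `difference` (pseudogene - gene, proportion).
#' @export
pseudogeneComparison <- function(regions, genes, region_kind = "gene_body") {
  bio <- setNames(genes$biotype, genes$gene_id)
  r <- regions[regions$region_kind == region_kind, ]
  r$biotype <- bio[r$gene_id]
  res <- lapply(unique(r$context), function(cx) {
    k <- r$context == cx
    mp <- mean(r$level[k & r$biotype == "pseudogene"])
    mg <- mean(r$level[k & r$biotype == "gene"])
    data.frame(context = cx, mean_pseudogene = mp, mean_gene = mg,
               difference = mp - mg, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
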