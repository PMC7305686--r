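#' Hypergeometric test for gene-set overlap
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between two gene sets drawn from a common universe.
#'
#' @param universe character vector of all eligible ids.
#' @param setA,setB character vectors, subsets of `universe`.
#' @return list with `n_universe`, `n_setA`, `n_setB`, `n_overlap`, `p_hyper`.
#' @export
hypergeometricOverlap <- function(universe, setA, setB) {
  universe <- unique(universe)
  setA <- unique(intersect(setA, universe))
  setB <- unique(intersect(setB, universe))
  k <- length(intersect(setA, setB))
  N <- length(universe)
  p <- phyper(k - 1, length(setA), N - length(setA), length(setB),
              lower.tail = FALSE)
  list(n_universe = N, n_setA = length(setA), n_setB = length(setB),
       n_overlap = k, p_hyper = p)
}

#' One-way ANOVA on peak lengths
#'
#' Fixed-effects one-way analysis of variance on raw lengths across named
#' groups (e.g. diploid vs hexaploid promoter peaks).
#'
#' @param groups named list of numeric length vectors.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
peakLengthAnova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  df <- data.frame(
    length = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L))))
  a <- anova(lm(length ~ group, data = df))
  list(F = a[["F value"]][1], df1 = a$Df[1], df2 = a$Df[2],
       p = a[["Pr(>F)"]][1])
}

#' Spearman correlation of positionally binned values
#'
#' Averages values within fixed-width positional bins along the chromosome
#' arm and correlates the bin index with the bin mean (Spearman, average
#' ranks for ties) — the summary used for chromosome-scale trends such as
#' sequence-similarity decay towards the telomere.
#'
#' @param positions genomic positions in bp.
#' @param values values attached to the positions (e.g. percent identity of
#'   the pair at that position).
#' @param bin bin width in bp (default 8 Mb).
#' @return list with `rho`, `p`, `n_bins`, `bin_means`, and `defined`
#'   (`FALSE`, with `rho = NA`, when fewer than 3 non-empty bins or constant
#'   bin means make the correlation undefined).
#' @export
binnedPositionCorrelation <- function(positions, values, bin = 8e6) {
  stopifnot(length(positions) == length(values))
  idx <- floor(positions / bin)
  means <- tapply(values, idx, mean)
  bins <- as.numeric(names(means))
  if (length(means) < 3L || sd(means) == 0 || is.na(sd(means))) {
    warning("binned correlation undefined (too few bins or constant values)")
    return(list(rho = NA_real_, p = NA_real_, n_bins = length(means),
                bin_means = means, defined = FALSE))
  }
  ct <- suppressWarnings(cor.test(bins, as.numeric(means), method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n_bins = length(means),
       bin_means = means, defined = TRUE)
}

#' Percent identity of two sequences under global alignment
#'
#' Needleman-Wunsch global alignment (defaults: match +1, mismatch -1, gap
#' -2 per position) followed by identity = matches / alignment columns x 100.
#'
#' @param seqA,seqB DNA sequences (character or `DNAString`).
#' @param match,mismatch,gap alignment scores (gap is per gapped column).
#' @return percent identity in `[0, 100]`.
#' @export
pairwiseIdentity <- function(seqA, seqB, match = 1, mismatch = -1, gap = -2) {
  seqA <- as.character(seqA); seqB <- as.character(seqB)
  if (nchar(seqA) == 0L || nchar(seqB) == 0L)
    stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seqA), Biostrings::DNAString(seqB),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = TRUE),
    gapOpening = 0, gapExtension = -gap)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(a == b & a != "-") / length(a)
}

#' Promoter k-mer enrichment by presence/absence
#'
#' For each k-mer observed in any promoter, counts the promoters containing
#' it at least once in the target and background sets, computes an upper-tail
#' hypergeometric p-value for over-representation among targets, and adjusts
#' across k-mers with Benjamini-Hochberg. A deliberately simple motif-screen
#' surrogate: presence/absence avoids length confounding between promoter
#' sets.
#'
#' @param target_promoters,background_promoters character vectors or
#'   `DNAStringSet` of promoter sequences.
#' @param k k-mer length (default 6).
#' @return data.frame `kmer`, `n_target`, `n_background`, `p`, `q`, ordered
#'   by `p`.
#' @export
kmerPromoterEnrichment <- function(target_promoters, background_promoters,
                                   k = 6L) {
  kmer_set <- function(s) {
    s <- toupper(as.character(s))
    if (nchar(s) < k) return(character(0))
    unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  }
  tk <- lapply(as.character(target_promoters), kmer_set)
  bk <- lapply(as.character(background_promoters), kmer_set)
  all_k <- unique(unlist(c(tk, bk)))
  if (!length(all_k))
    return(data.frame(kmer = character(), n_target = integer(),
                      n_background = integer(), p = numeric(), q = numeric()))
  nt <- length(tk); nb <- length(bk)
  cnt_t <- table(factor(unlist(tk), levels = all_k))
  cnt_b <- table(factor(unlist(bk), levels = all_k))
  p <- phyper(as.integer(cnt_t) - 1, as.integer(cnt_t) + as.integer(cnt_b),
              nt + nb - as.integer(cnt_t) - as.integer(cnt_b), nt,
              lower.tail = FALSE)
  out <- data.frame(kmer = all_k,
                    n_target = as.integer(cnt_t),
                    n_background = as.integer(cnt_b),
                    p = p, q = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out[order(out$p, out$kmer), ]
}
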