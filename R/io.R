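#' Read gene models from a GFF3 file
#'
#' Imports `gene`/`pseudogene` features together with their `mRNA`, `exon` and
#' `CDS` children and returns one [GenomicRanges::GRanges] row per gene.
#' Coordinates stay in the GFF3 (1-based, closed) convention used throughout
#' the package. The transcription start site is the strand-aware 5' end of the
#' gene; the start-codon position (`atg`) and the end of the coding region
#' (`cds_end`) are derived from the CDS features, strand-aware.
#'
#' Pseudogenes are recognised either by feature type `pseudogene` or by a
#' `biotype=pseudogene` attribute: gene-like models with conserved exon-intron
#' structure but no translatable coding sequence. A `gene`-biotype model
#' without any CDS feature is kept but flagged with `atg = NA` and a warning,
#' since its promoter windows can then only be anchored at the TSS.
#'
#' @param path path to a GFF3 file.
#' @return `GRanges` with metadata columns `gene_id`, `biotype`
#'   (`"gene"`/`"pseudogene"`), `atg`, `cds_end` and `exons`
#'   (an [IRanges::IRangesList], sorted and non-overlapping per gene).
#' @seealso [tssPositions()], [writeGeneModels()]
#' @export
readGeneModels <- function(path) {
  .validate_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  is_gene <- as.character(gr$type) %in% c("gene", "pseudogene")
  genes <- gr[is_gene]
  if (length(genes) == 0L) stop("no gene/pseudogene features in ", path)
  gene_id <- genes$ID
  if (is.null(gene_id) || anyNA(gene_id))
    stop("gene features must carry an ID attribute")

  biotype <- ifelse(as.character(genes$type) == "pseudogene", "pseudogene", "gene")
  if (!is.null(genes$biotype))
    biotype[!is.na(genes$biotype) & genes$biotype == "pseudogene"] <- "pseudogene"

  # map child features up to their gene
  parent_of <- function(x) as.character(S4Vectors::unstrsplit(x$Parent, ","))
  mrna <- gr[as.character(gr$type) == "mRNA"]
  mrna_gene <- structure(parent_of(mrna), names = as.character(mrna$ID))
  to_gene <- function(child) {
    p <- parent_of(child)
    ifelse(p %in% names(mrna_gene), unname(mrna_gene[p]), p)
  }

  exon <- gr[as.character(gr$type) == "exon"]
  exon_gene <- to_gene(exon)
  cds <- gr[as.character(gr$type) == "CDS"]
  cds_gene <- to_gene(cds)

  exons <- IRanges::IRangesList(lapply(gene_id, function(g) {
    e <- IRanges::ranges(exon[exon_gene == g])
    e <- e[order(IRanges::start(e))]
    if (length(e) > 1L && any(IRanges::start(e)[-1] <= IRanges::end(e)[-length(e)]))
      stop("overlapping exons for gene ", g)
    e
  }))

  atg <- cds_end <- rep(NA_real_, length(genes))
  strand_chr <- as.character(GenomicRanges::strand(genes))
  for (i in seq_along(genes)) {
    cr <- IRanges::ranges(cds[cds_gene == gene_id[i]])
    if (length(cr) == 0L) next
    if (strand_chr[i] == "-") {
      atg[i] <- max(IRanges::end(cr))
      cds_end[i] <- min(IRanges::start(cr))
    } else {
      atg[i] <- min(IRanges::start(cr))
      cds_end[i] <- max(IRanges::end(cr))
    }
  }
  if (any(is.na(atg) & biotype == "gene"))
    warning(sum(is.na(atg) & biotype == "gene"),
            " gene model(s) without CDS features; atg set to NA")

  out <- GenomicRanges::granges(genes)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = gene_id, biotype = biotype, atg = atg, cds_end = cds_end,
    exons = exons
  )
  names(out) <- gene_id
  out
}

# minimal structural validation so malformed lines fail with a line number
.validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("GFF3 parse error at line ", i, ": expected 9 tab-separated fields")
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e))
      stop("GFF3 parse error at line ", i, ": non-integer coordinates")
    if (e < s)
      stop("GFF3 parse error at line ", i, ": end < start")
  }
  invisible(TRUE)
}

#' Write gene models to GFF3
#'
#' Inverse of [readGeneModels()]: emits `gene` (or `pseudogene`), `mRNA`,
#' `exon` and `CDS` features so that re-reading recovers the gene coordinates,
#' strand, biotype, exon structure, `atg` and `cds_end` exactly.
#'
#' @param genes `GRanges` as returned by [readGeneModels()] or
#'   [generateGeneModels()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  rows <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    gid <- g$gene_id
    ptype <- if (g$biotype == "pseudogene") "pseudogene" else "gene"
    chrom <- as.character(GenomicRanges::seqnames(g))
    strand <- as.character(GenomicRanges::strand(g))
    add <- function(type, s, e, id = NA, parent = NA) {
      S4Vectors::DataFrame(chrom = chrom, start = s, end = e, strand = strand,
                           type = type, id = id, parent = parent)
    }
    rows[[length(rows) + 1L]] <- add(ptype, GenomicRanges::start(g),
                                     GenomicRanges::end(g), id = gid)
    mid <- paste0(gid, ".1")
    rows[[length(rows) + 1L]] <- add("mRNA", GenomicRanges::start(g),
                                     GenomicRanges::end(g), id = mid, parent = gid)
    ex <- g$exons[[1]]
    for (j in seq_along(ex))
      rows[[length(rows) + 1L]] <- add("exon", IRanges::start(ex)[j],
                                       IRanges::end(ex)[j], parent = mid)
    if (!is.na(g$atg)) {
      cds_lo <- min(g$atg, g$cds_end); cds_hi <- max(g$atg, g$cds_end)
      for (j in seq_along(ex)) {
        s <- max(IRanges::start(ex)[j], cds_lo)
        e <- min(IRanges::end(ex)[j], cds_hi)
        if (s <= e)
          rows[[length(rows) + 1L]] <- add("CDS", s, e, parent = mid)
      }
    }
  }
  tab <- do.call(rbind, rows)
  out <- GenomicRanges::GRanges(tab$chrom,
                                IRanges::IRanges(tab$start, tab$end),
                                strand = tab$strand)
  out$type <- tab$type
  out$ID <- ifelse(is.na(tab$id), NA_character_, tab$id)
  out$Parent <- ifelse(is.na(tab$parent), NA_character_, tab$parent)
  out$phase <- ifelse(tab$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Strand-aware gene anchors
#'
#' `tssPositions()` returns the transcription start site of each gene (the 5'
#' end in gene orientation: `start` on "+", `end` on "-"); `ttsPositions()`
#' the transcription termination site.
#'
#' @param genes gene-model `GRanges`.
#' @return numeric vector of genomic positions, named by `gene_id` when
#'   available.
#' @export
tssPositions <- function(genes) {
  p <- ifelse(as.character(GenomicRanges::strand(genes)) == "-",
              GenomicRanges::end(genes), GenomicRanges::start(genes))
  if (!is.null(genes$gene_id)) names(p) <- genes$gene_id
  p
}

#' @rdname tssPositions
#' @export
ttsPositions <- function(genes) {
  p <- ifelse(as.character(GenomicRanges::strand(genes)) == "-",
              GenomicRanges::start(genes), GenomicRanges::end(genes))
  if (!is.null(genes$gene_id)) names(p) <- genes$gene_id
  p
}

#' Read a per-cytosine bisulphite report
#'
#' Reads the Bismark-style cytosine report: tab-delimited columns
#' `chrom, pos (1-based), strand, count_methylated, count_unmethylated,
#' context` (a seventh trinucleotide column, if present, is ignored). Counts
#' are preserved exactly; sites with zero coverage are retained (downstream
#' filters decide their fate).
#'
#' @param path path to the report.
#' @return `GRanges` of width-1 sites with metadata columns `context`
#'   (`"CpG"`, `"CHG"`, `"CHH"`), `n_meth` and `n_total`.
#' @export
readCytosineReport <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 6L) stop("cytosine report needs at least 6 columns")
  names(dt)[1:6] <- c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context")
  if (!is.numeric(dt$pos) || any(dt$pos != floor(dt$pos)))
    stop("cytosine report: non-integer positions")
  if (!is.numeric(dt$n_meth) || !is.numeric(dt$n_unmeth) ||
      any(dt$n_meth < 0) || any(dt$n_unmeth < 0))
    stop("cytosine report: counts must be non-negative integers")
  bad <- !dt$context %in% c("CpG", "CG", "CHG", "CHH")
  if (any(bad))
    stop("cytosine report: unknown context string(s): ",
         paste(unique(dt$context[bad]), collapse = ", "))
  ctx <- ifelse(dt$context == "CG", "CpG", dt$context)
  gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, width = 1L),
                               strand = dt$strand)
  gr$context <- ctx
  gr$n_meth <- as.integer(dt$n_meth)
  gr$n_total <- as.integer(dt$n_meth + dt$n_unmeth)
  gr
}

#' @rdname readCytosineReport
#' @param sites cytosine-site `GRanges` as returned by [readCytosineReport()]
#'   or [generateMethylation()].
#' @export
writeCytosineReport <- function(sites, path) {
  .check_sites(sites)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    pos = GenomicRanges::start(sites),
    strand = as.character(GenomicRanges::strand(sites)),
    n_meth = sites$n_meth,
    n_unmeth = sites$n_total - sites$n_meth,
    context = sites$context
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

.check_sites <- function(sites) {
  need <- c("context", "n_meth", "n_total")
  miss <- setdiff(need, colnames(S4Vectors::mcols(sites)))
  if (length(miss))
    stop("cytosine sites lack required column(s): ", paste(miss, collapse = ", "))
  if (any(sites$n_meth > sites$n_total) || any(sites$n_meth < 0))
    stop("cytosine sites violate 0 <= n_meth <= n_total")
  invisible(TRUE)
}

#' Read or write BED intervals
#'
#' Thin wrappers around `rtracklayer::import()`/`rtracklayer::export()` that keep
#' the package on a single interval representation: BED's 0-based half-open
#' coordinates are converted to `GRanges` (1-based closed) on input and back
#' on output, so a read-write-read round trip is the identity.
#'
#' @param path BED file path.
#' @return `readBed()`: a `GRanges` (with `name`/`score` columns when present
#'   in the file). `writeBed()`: `path`, invisibly.
#' @export
readBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (any(GenomicRanges::width(gr) < 1L))
    stop("BED intervals must satisfy start < end")
  gr
}

#' @rdname readBed
#' @param intervals `GRanges` to write.
#' @export
writeBed <- function(intervals, path) {
  if (any(GenomicRanges::width(intervals) < 1L))
    stop("BED intervals must satisfy start < end")
  rtracklayer::export(intervals, path, format = "bed")
  invisible(path)
}

#' Drop reads or intervals on organelle contigs
#'
#' Organelle (mitochondrial/chloroplast) material is removed by contig name
#' against a configurable list, since alignment happens upstream of this
#' package.
#'
#' @param x `GRanges`.
#' @param organelle_contigs character vector of contig names to drop.
#' @return `x` without ranges on the listed contigs; a message reports the
#'   input/output counts.
#' @export
filterOrganelle <- function(x, organelle_contigs) {
  keep <- !as.character(GenomicRanges::seqnames(x)) %in% organelle_contigs
  message("filterOrganelle: kept ", sum(keep), "/", length(x), " ranges")
  x[keep]
}
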