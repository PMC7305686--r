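#' Pipeline configuration
#'
#' Bundles the generator settings and every stage threshold (all defaulting
#' to the values the package is calibrated around) into one serializable
#' object.
#'
#' @param cfg a [generatorConfig()] (its seed drives every stochastic stage).
#' @param input_dir optional directory produced by [writeSyntheticDataset()]
#'   (or real data in the same layout); when given, inputs are read from disk
#'   instead of generated in memory.
#' @param tpm_min expression threshold in TPM.
#' @param fold DEG fold-change threshold.
#' @param eps TPM pseudocount.
#' @param norm_method `"median_ratio"` or `"fixed"`.
#' @param fixed_factor factor for `norm_method = "fixed"`.
#' @param min_sites minimum qualifying cytosines per region.
#' @param min_cov named per-genome minimum site coverage (diploid 5x,
#'   hexaploid 10x by default, mirroring the unequal sequencing depths).
#' @param dmr_thresholds per-context DMR thresholds in percentage points.
#' @param q_cutoff DMR significance cutoff.
#' @param atac_min_fold,atac_min_abs differential-accessibility thresholds.
#' @param tss_thresholds TSS-distance CDF thresholds in bp.
#' @param outdir optional output directory for the TSV/JSON report.
#' @return classed list.
#' @export
pipelineConfig <- function(cfg = generatorConfig(),
                           input_dir = NULL,
                           tpm_min = 1, fold = 4, eps = 0.01,
                           norm_method = "median_ratio", fixed_factor = 1.7604,
                           min_sites = 5L,
                           min_cov = c(diploid = 5L, hexaploid = 10L),
                           dmr_thresholds = c(CpG = 50, CHG = 25, CHH = 10),
                           q_cutoff = 0.05,
                           atac_min_fold = 2, atac_min_abs = 50,
                           tss_thresholds = c(3000, 100000),
                           outdir = NULL) {
  out <- as.list(environment())
  class(out) <- "pipeline_config"
  out
}

#' Run the full arm-comparison pipeline
#'
#' Orchestrates generation (or loading) of the inputs, expression
#' classification, methylation region aggregation and DMR calling, ATAC peak
#' post-processing, and the integration statistics, returning a consolidated
#' report. Every filter logs its input/output counts. Reruns with the same
#' configuration are identical.
#'
#' @param config a [pipelineConfig()].
#' @return a list report (see the worked example in the package README);
#'   written as `report.json` plus per-stage TSVs when `config$outdir` is
#'   set.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$cfg

  if (!is.null(config$input_dir)) {
    dirp <- config$input_dir
    need <- c("diploid.gff3", "hexaploid.gff3", "tpm_diploid.tsv",
              "tpm_hexaploid.tsv", "design.tsv", "pairs.tsv",
              "cx_diploid.txt", "cx_hexaploid.txt")
    missing <- need[!file.exists(file.path(dirp, need))]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    models <- list(diploid = readGeneModels(file.path(dirp, "diploid.gff3")),
                   hexaploid = readGeneModels(file.path(dirp, "hexaploid.gff3")),
                   pairs = as.data.frame(data.table::fread(file.path(dirp, "pairs.tsv"))))
    rdm <- function(f) {
      dt <- data.table::fread(file.path(dirp, f))
      m <- as.matrix(dt[, -1]); rownames(m) <- dt[[1]]; m
    }
    expr <- list(tpm_diploid = rdm("tpm_diploid.tsv"),
                 tpm_hexaploid = rdm("tpm_hexaploid.tsv"),
                 design = as.data.frame(data.table::fread(file.path(dirp, "design.tsv"))),
                 accessions = list())
    meth <- list(diploid = list(sites = readCytosineReport(file.path(dirp, "cx_diploid.txt"))),
                 hexaploid = list(sites = readCytosineReport(file.path(dirp, "cx_hexaploid.txt"))))
    atac <- lapply(c(diploid = "diploid", hexaploid = "hexaploid"), function(g) {
      beds <- Sys.glob(file.path(dirp, sprintf("atac_%s_rep*.bed", g)))
      fl <- file.path(dirp, sprintf("fragments_%s.tsv", g))
      list(replicate_peaks = lapply(beds, readBed),
           fragments = if (file.exists(fl)) data.table::fread(fl)$length else integer(0))
    })
  } else {
    models <- generateGeneModels(cfg)
    expr <- generateExpression(cfg, models$pairs)
    atac <- list(diploid = generateAtac(cfg, models$diploid, "diploid"),
                 hexaploid = generateAtac(cfg, models$hexaploid, "hexaploid"))
    meth <- NULL  # generated below, after expression defines expressed ids
  }

  ## --- expression ---
  pe <- PairedExpression(models$pairs, expr$tpm_diploid, expr$tpm_hexaploid,
                         expr$design)
  pe <- flagExpressed(pe, tpm_min = config$tpm_min)
  norm <- computeNormalizationFactor(pe, method = config$norm_method,
                                     fixed_factor = config$fixed_factor,
                                     eps = config$eps, tpm_min = config$tpm_min)
  pe <- classifyPairs(pe, norm, fold = config$fold, eps = config$eps,
                      tpm_min = config$tpm_min)
  rd <- SummarizedExperiment::rowData(pe)
  expressed <- rd$expressed
  cls <- overallClass(pe)
  bal <- cls == "balanced"
  message("expression: ", sum(expressed), "/", length(expressed),
          " pairs expressed; ", sum(cls == "deg"), " DEGs")
  deg_by_tissue <- stageSpecificSummary(pe)
  leaf_cls <- pairClasses(pe)[, "leaf"]
  leaf_degs <- rownames(pe)[leaf_cls %in% c("deg_up_hexaploid", "deg_up_diploid")]

  conserved <- NULL
  if (length(expr$accessions)) {
    deg_sets <- lapply(c(list(primary = expr$tpm_diploid), expr$accessions),
                       function(m) {
      pa <- PairedExpression(models$pairs, m, expr$tpm_hexaploid, expr$design)
      pa <- flagExpressed(pa, tpm_min = config$tpm_min)
      na <- computeNormalizationFactor(pa, method = config$norm_method,
                                       eps = config$eps, tpm_min = config$tpm_min)
      pa <- classifyPairs(pa, na, fold = config$fold, eps = config$eps,
                          tpm_min = config$tpm_min)
      lc <- pairClasses(pa)[, "leaf"]
      keep <- lc %in% c("deg_up_hexaploid", "deg_up_diploid")
      data.frame(pair_id = rownames(pa)[keep],
                 direction = ifelse(lc[keep] == "deg_up_hexaploid",
                                    "up_hexaploid", "up_diploid"))
    })
    conserved <- conservedDegs(deg_sets)
  }

  expressed_ids <- list(
    diploid = rd$diploid_gene_id[apply(diploidTPM(pe), 1, max) >= config$tpm_min],
    hexaploid = rd$hexaploid_gene_id[apply(hexaploidTPM(pe), 1, max) >= config$tpm_min])

  ## --- methylation ---
  if (is.null(meth))
    meth <- generateMethylationPair(cfg, models, expressed_ids = expressed_ids)
  regions <- lapply(c(diploid = "diploid", hexaploid = "hexaploid"), function(g)
    aggregateRegions(meth[[g]]$sites, regionsForGenes(models[[g]]),
                     min_sites = config$min_sites,
                     min_cov = config$min_cov[[g]]))
  message("methylation: ", nrow(regions$diploid), " diploid and ",
          nrow(regions$hexaploid), " hexaploid regions pass the filters")
  dmrs <- callDmrs(regions$diploid, regions$hexaploid, pairs = models$pairs,
                   thresholds = config$dmr_thresholds, q_cutoff = config$q_cutoff)
  deg_ids <- rownames(pe)[cls == "deg"]
  dmr_deg <- dmrDegOverlap(dmrs, deg_ids)
  pseudo_cmp <- lapply(c(diploid = "diploid", hexaploid = "hexaploid"),
                       function(g) pseudogeneComparison(regions[[g]], models[[g]]))
  meth_levels <- lapply(c(diploid = "diploid", hexaploid = "hexaploid"),
                        function(g) {
    s <- meth[[g]]$sites
    vapply(c(CpG = "CpG", CHG = "CHG", CHH = "CHH"), function(cx)
      weightedMethylation(s[s$context == cx]), numeric(1))
  })
  tss_test <- tryCatch(
    tssWindowTest(meth$hexaploid$sites, models$hexaploid,
                  expressed_ids$hexaploid, context = "CpG"),
    error = function(e) {
      # e.g. one expression group too small to cover the window
      message("tssWindowTest skipped: ", conditionMessage(e))
      list(t = NA_real_, df = NA_real_, p = NA_real_)
    })

  ## --- ATAC ---
  atac_res <- lapply(c(diploid = "diploid", hexaploid = "hexaploid"),
                     function(g) {
    a <- atac[[g]]
    rp <- reproduciblePeaks(a$replicate_peaks)
    merged <- mergeClosePeaks(rp)
    message("atac/", g, ": ", sum(vapply(a$replicate_peaks, length, 1L)),
            " replicate peaks -> ", length(rp), " reproducible -> ",
            length(merged), " merged")
    ann <- annotatePeaks(merged, models[[g]])
    acc <- geneAccessibility(ann, models[[g]])
    list(peaks = ann, acc = acc,
         class_counts = table(ann$region_class),
         tss_cdf = tssDistanceCdf(ann, config$tss_thresholds),
         periodicity = if (length(a$fragments))
           fragmentPeriodicity(a$fragments) else NULL)
  })
  diff_acc <- differentialAccessibility(atac_res$diploid$acc,
                                        atac_res$hexaploid$acc, models$pairs,
                                        min_fold = config$atac_min_fold,
                                        min_abs = config$atac_min_abs)
  atac_deg <- degAtacOverlap(diff_acc, leaf_degs)
  overlap_test <- hypergeometricOverlap(
    rownames(pe), unique(diff_acc$pair_id[diff_acc$differential]), leaf_degs)
  prom_lengths <- lapply(atac_res, function(a)
    GenomicRanges::width(a$peaks[a$peaks$region_class == "promoter5utr"]))
  anova_prom <- if (all(vapply(prom_lengths, length, 1L) > 1))
    peakLengthAnova(prom_lengths) else NULL

  report <- list(
    n_pairs = length(expressed),
    expressed = list(n = sum(expressed), fraction = mean(expressed)),
    normalization = norm,
    balanced = list(
      n = sum(bal),
      fraction_of_expressed = sum(bal) / sum(expressed),
      median_ratio = median(rd$ratio_hexdip[bal])),
    deg = list(n = sum(cls == "deg"), by_tissue = deg_by_tissue),
    conserved_degs = if (!is.null(conserved)) nrow(conserved) else NA_integer_,
    methylation = list(weighted_levels = meth_levels,
                       n_dmr = sum(dmrs$is_dmr),
                       dmr_deg_table = dmr_deg,
                       pseudogene = pseudo_cmp,
                       tss_window_test = tss_test[c("t", "df", "p")]),
    atac = list(
      class_counts = lapply(atac_res, `[[`, "class_counts"),
      tss_cdf = lapply(atac_res, `[[`, "tss_cdf"),
      periodicity = lapply(atac_res, function(a)
        if (is.null(a$periodicity)) NULL else a$periodicity$period),
      n_differential = atac_deg$n_differential,
      deg_overlap = atac_deg,
      overlap_p = overlap_test$p_hyper,
      promoter_length_anova = anova_prom)
  )

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      report, file.path(config$outdir, "report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE, na = "null")
    data.table::fwrite(as.data.frame(rd),
                       file.path(config$outdir, "pair_classes.tsv"), sep = "\t")
    data.table::fwrite(dmrs, file.path(config$outdir, "dmrs.tsv"), sep = "\t")
    data.table::fwrite(diff_acc,
                       file.path(config$outdir, "differential_accessibility.tsv"),
                       sep = "\t")
  }
  report
}
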