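#' Configuration for the synthetic arm-pair generator
#'
#' Builds the parameter list consumed by [generateGeneModels()],
#' [generateExpression()], [generateMethylation()] and [generateAtac()]. The
#' defaults are the study conditions the package is calibrated against: ~70%
#' of expressed syntenic pairs proportionately reduced to ~40% of the diploid
#' TPM, ~30% differentially expressed at >= 4-fold after normalization;
#' genome-wide weighted methylation near 89.9/59.4/3.8% (CpG/CHG/CHH) for the
#' hexaploid and 87.1/53.4/3.4% for the diploid, with pseudogene CpG/CHG
#' elevation of +13.2/+12.6 points; ATAC peaks concentrated near TSSs, tighter
#' and narrower in the hexaploid, and fragment lengths carrying a ~10.5 bp
#' periodicity from helical-face Tn5 cleavage.
#'
#' @param seed integer; fully determines all generator output.
#' @param n_genes number of syntenic gene pairs per arm.
#' @param chrom_len arm length in bp for both synthetic arms.
#' @param pseudogene_fraction fraction of pairs flagged as pseudogenes.
#' @param balanced_fraction fraction of pairs with proportionately reduced
#'   expression.
#' @param balanced_ratio hexaploid/diploid TPM ratio for balanced pairs.
#' @param deg_min_fold minimum DEG fold change after the implied
#'   normalization; DEG effect sizes are drawn log-uniform in
#'   `[deg_min_fold, 4 * deg_min_fold]`.
#' @param tpm_noise_sd log-scale SD of pair-level and replicate-level TPM
#'   noise.
#' @param tissue_sd log-scale SD of shared tissue effects.
#' @param base_meanlog,base_sdlog log-normal parameters of the diploid base
#'   TPM.
#' @param tissues tissue names.
#' @param replicates RNA replicates per tissue.
#' @param n_accessions number of diploid accessions (1 primary plus
#'   `n_accessions - 1` divergent lines for the conserved-DEG intersection).
#' @param accession_sd log-scale SD of pair-level accession effects.
#' @param meth_rates per-genome named context rates (CpG, CHG, CHH).
#' @param meth_concentration Beta concentration of per-gene-region rate
#'   heterogeneity around the context mean.
#' @param pseudogene_offset additive methylation elevation (proportion) for
#'   pseudogene regions, per context.
#' @param coverage_mean mean Poisson bisulphite coverage per site.
#' @param meth_site_density expected cytosine sites per bp, per context.
#' @param tss_window half-width (bp) of the densely covered window around each
#'   TSS in the methylation generator.
#' @param tss_dip fractional TSS methylation dip for expressed (first element)
#'   and non-expressed (second) genes.
#' @param dmr_fraction fraction of (gene, region, context) units planted as
#'   true DMRs in [generateMethylationPair()].
#' @param dmr_delta planted DMR effect in proportion points, per context.
#' @param atac_peak_rate per-genome probability that a gene carries an
#'   accessible-promoter latent peak.
#' @param atac_width_meanlog,atac_width_sdlog per-genome log-normal peak-width
#'   parameters.
#' @param atac_tss_scale per-genome Laplace scale (bp) of latent peak distance
#'   from the TSS.
#' @param atac_jitter_sd SD (bp) of replicate-specific jitter on latent peak
#'   edges.
#' @param atac_noise_rate expected replicate-specific spurious peaks per gene.
#' @param atac_replicates ATAC replicates.
#' @param fragment_period comb period (bp) in the fragment-length law.
#' @param fragment_comb_amp amplitude of the multiplicative comb in `[0, 1)`.
#' @param n_fragments fragments drawn per genome.
#' @return a classed list of generator settings.
#' @export
generatorConfig <- function(seed = 1L,
                            n_genes = 300L,
                            chrom_len = 6e6,
                            pseudogene_fraction = 0.05,
                            balanced_fraction = 0.70,
                            balanced_ratio = 0.40,
                            deg_min_fold = 4,
                            tpm_noise_sd = 0.2,
                            tissue_sd = 0.5,
                            base_meanlog = 2.5,
                            base_sdlog = 1,
                            tissues = c("leaf", "root", "seedling",
                                        "grain10", "grain27"),
                            replicates = 3L,
                            n_accessions = 3L,
                            accession_sd = 0.1,
                            meth_rates = list(
                              hexaploid = c(CpG = 0.899, CHG = 0.594, CHH = 0.038),
                              diploid   = c(CpG = 0.871, CHG = 0.534, CHH = 0.034)),
                            meth_concentration = 20,
                            pseudogene_offset = c(CpG = 0.132, CHG = 0.126, CHH = 0),
                            coverage_mean = 10,
                            meth_site_density = c(CpG = 0.01, CHG = 0.01, CHH = 0.03),
                            tss_window = 20L,
                            tss_dip = c(expressed = 0.7, non_expressed = 0.2),
                            dmr_fraction = 0.10,
                            dmr_delta = c(CpG = 0.60, CHG = 0.35, CHH = 0.20),
                            atac_peak_rate = c(diploid = 0.6, hexaploid = 0.4),
                            atac_width_meanlog = c(diploid = log(450),
                                                   hexaploid = log(280)),
                            atac_width_sdlog = 0.4,
                            atac_tss_scale = c(diploid = 80000, hexaploid = 4300),
                            atac_jitter_sd = 15,
                            atac_noise_rate = 0.15,
                            atac_replicates = 3L,
                            fragment_period = 10.5,
                            fragment_comb_amp = 0.4,
                            n_fragments = 20000L) {
  deg_fraction <- 1 - balanced_fraction
  props <- c(pseudogene_fraction, balanced_fraction, balanced_ratio, deg_fraction,
             dmr_fraction, fragment_comb_amp,
             unlist(meth_rates), pseudogene_offset)
  if (any(props < 0 | props > 1))
    stop("all proportion parameters must lie in [0, 1]")
  if (deg_min_fold <= 1) stop("deg_min_fold must exceed 1")
  cfg <- as.list(environment())
  cfg$deg_fraction <- deg_fraction
  cfg$seed <- as.integer(seed)
  class(cfg) <- "generator_config"
  cfg
}

# stage-scoped deterministic seeds derived from the master seed
.stage_seed <- function(cfg, stage) {
  offs <- c(models = 101L, expression = 211L, methylation = 307L,
            atac_diploid = 401L, atac_hexaploid = 409L, sites = 503L)
  (cfg$seed %% 2000000000L) + offs[[stage]]
}

#' Generate collinear gene models for both arms
#'
#' Places `n_genes` genes at collinear positions along one synthetic diploid
#' arm and one hexaploid arm (constant offset and small positional jitter, so
#' pairs sorted by diploid position are also sorted by hexaploid position).
#' A configurable fraction of pairs is flagged as pseudogenes on both arms.
#' Each gene has 1-4 exons, a short 5'/3' UTR, and hence a TSS, start codon
#' and coding-region end.
#'
#' @param cfg a [generatorConfig()].
#' @return list with elements `diploid` and `hexaploid` (gene-model `GRanges`
#'   as from [readGeneModels()], seqnames `chr3L_dip` / `chr3DL_hex`) and
#'   `pairs` (data.frame `pair_id`, `diploid_gene_id`, `hexaploid_gene_id`,
#'   `pseudogene`).
#' @export
generateGeneModels <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_genes < 10L) stop("n_genes must be >= 10")
  min_span <- 12000  # gene body + flanks; keeps promoter/flank windows disjoint
  if (cfg$chrom_len < cfg$n_genes * min_span)
    stop("chrom_len too small for n_genes at minimum spacing")
  withr::with_seed(.stage_seed(cfg, "models"), {
    n <- cfg$n_genes
    slot_w <- floor(cfg$chrom_len / n)
    widths <- round(exp(runif(n, log(1500), log(4000))))
    starts <- (seq_len(n) - 1L) * slot_w + 4000 +
      round(runif(n, 0, slot_w - 8000 - max(widths)))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    pseudo <- rep(FALSE, n)
    n_pseudo <- round(cfg$pseudogene_fraction * n)
    if (n_pseudo > 0) pseudo[sample.int(n, n_pseudo)] <- TRUE

    build <- function(prefix, chrom, shift_jitter) {
      s <- starts + shift_jitter
      e <- s + widths - 1L
      gid <- sprintf("%s_g%04d", prefix, seq_len(n))
      gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e), strand = strand)
      utr5 <- round(runif(n, 100, 300)); utr3 <- round(runif(n, 100, 300))
      atg <- ifelse(strand == "-", e - utr5, s + utr5)
      cds_end <- ifelse(strand == "-", s + utr3, e - utr3)
      atg[pseudo] <- NA_real_; cds_end[pseudo] <- NA_real_
      n_ex <- sample(1:4, n, replace = TRUE)
      exons <- IRanges::IRangesList(lapply(seq_len(n), function(i) {
        if (n_ex[i] == 1L) return(IRanges::IRanges(s[i], e[i]))
        # keep UTR anchors inside the terminal exons (atg/cds_end round-trip)
        cuts <- sort(sample(seq(s[i] + 350, e[i] - 350, by = 10), 2 * (n_ex[i] - 1L)))
        IRanges::IRanges(c(s[i], cuts[seq(2, length(cuts), 2)]),
                         c(cuts[seq(1, length(cuts), 2)], e[i]))
      }))
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        gene_id = gid,
        biotype = ifelse(pseudo, "pseudogene", "gene"),
        atg = atg, cds_end = cds_end, exons = exons)
      names(gr) <- gid
      gr
    }
    dip <- build("dip", "chr3L_dip", 0L)
    hex <- build("hex", "chr3DL_hex", round(rnorm(1, 0, 200)))
    pairs <- data.frame(
      pair_id = sprintf("pair%04d", seq_len(n)),
      diploid_gene_id = dip$gene_id,
      hexaploid_gene_id = hex$gene_id,
      pseudogene = pseudo,
      stringsAsFactors = FALSE)
    list(diploid = dip, hexaploid = hex, pairs = pairs)
  })
}

#' Generate replicate-level TPM tables for syntenic pairs
#'
#' Diploid base TPM is log-normal per pair; shared multiplicative tissue
#' effects apply to both genomes. A fixed `balanced_fraction` of pairs gets a
#' hexaploid mean of `balanced_ratio * diploid * exp(N(0, tpm_noise_sd))`; the
#' remaining pairs are true DEGs whose post-normalization fold change is drawn
#' log-uniform in `[deg_min_fold, 4 * deg_min_fold]` with random direction.
#' Independent log-normal replicate noise is added on top. Truth labels are
#' returned alongside and are never consumed by the analysis stages.
#'
#' @param cfg a [generatorConfig()].
#' @param pairs the `pairs` data.frame from [generateGeneModels()].
#' @return list with `tpm_diploid`, `tpm_hexaploid` (matrices pair x
#'   tissue:replicate), `design` (data.frame `sample`, `tissue`) and `truth`
#'   (data.frame `pair_id`, `class` in `balanced`/`deg`, `true_ratio`,
#'   `deg_direction`).
#' @export
generateExpression <- function(cfg, pairs) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(.stage_seed(cfg, "expression"), {
    n <- nrow(pairs)
    n_bal <- round(cfg$balanced_fraction * n)
    cls <- sample(c(rep("balanced", n_bal), rep("deg", n - n_bal)))
    base <- rlnorm(n, cfg$base_meanlog, cfg$base_sdlog)

    ratio <- numeric(n)
    direction <- rep(NA_character_, n)
    bal <- cls == "balanced"
    ratio[bal] <- cfg$balanced_ratio * exp(rnorm(sum(bal), 0, cfg$tpm_noise_sd))
    if (any(!bal)) {
      fold <- exp(runif(sum(!bal), log(cfg$deg_min_fold), log(4 * cfg$deg_min_fold)))
      dirn <- sample(c(1, -1), sum(!bal), replace = TRUE)
      ratio[!bal] <- cfg$balanced_ratio * fold^dirn
      direction[!bal] <- ifelse(dirn > 0, "up_hexaploid", "up_diploid")
    }

    tiss <- cfg$tissues; reps <- cfg$replicates
    samples <- as.vector(outer(tiss, seq_len(reps),
                               function(t, r) paste0(t, "_rep", r)))
    design <- data.frame(sample = samples,
                         tissue = rep(tiss, times = reps),
                         stringsAsFactors = FALSE)
    t_eff <- matrix(exp(rnorm(n * length(tiss), 0, cfg$tissue_sd)),
                    nrow = n, dimnames = list(pairs$pair_id, tiss))
    mk <- function(mean_pair) {
      m <- matrix(0, n, length(samples),
                  dimnames = list(pairs$pair_id, samples))
      for (j in seq_along(samples)) {
        mu <- mean_pair * t_eff[, design$tissue[j]]
        m[, j] <- mu * exp(rnorm(n, 0, cfg$tpm_noise_sd))
      }
      m
    }
    tpm_dip <- mk(base)
    tpm_hex <- mk(base * ratio)
    # further diploid accessions: small pair-level accession effects on the
    # same expression programme, fresh replicate noise
    accessions <- list()
    if (cfg$n_accessions > 1L) {
      for (a in seq_len(cfg$n_accessions - 1L)) {
        eff <- exp(rnorm(n, 0, cfg$accession_sd))
        accessions[[paste0("accession", a + 1L)]] <- mk(base * eff)
      }
    }
    list(tpm_diploid = tpm_dip, tpm_hexaploid = tpm_hex, design = design,
         accessions = accessions,
         truth = data.frame(pair_id = pairs$pair_id, class = cls,
                            true_ratio = ratio, deg_direction = direction,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate independent cytosine sites at a fixed context rate
#'
#' Draws per-site methylation probabilities from a Beta distribution with the
#' given mean and concentration (real methylation is overdispersed across
#' sites), Poisson coverage, and binomial methylated-read counts.
#'
#' @param n number of sites.
#' @param rate mean methylation proportion.
#' @param coverage_mean Poisson mean coverage.
#' @param concentration Beta concentration (`Inf` for no overdispersion).
#' @param context context label stored on the sites.
#' @param seed integer seed.
#' @return cytosine-site `GRanges` (positions on one synthetic contig).
#' @export
simulateCytosineSites <- function(n, rate, coverage_mean = 10,
                                  concentration = 20, context = "CpG",
                                  seed = 1L) {
  withr::with_seed(as.integer(seed), {
    p <- if (is.finite(concentration))
      stats::rbeta(n, rate * concentration, (1 - rate) * concentration)
    else rep(rate, n)
    cov <- rpois(n, coverage_mean)
    m <- rbinom(n, cov, p)
    gr <- GenomicRanges::GRanges("sim", IRanges::IRanges(seq_len(n) * 2L, width = 1L),
                                 strand = "+")
    gr$context <- context
    gr$n_meth <- m
    gr$n_total <- cov
    gr
  })
}

# per-(gene, region, context) true rates for one genome; shared_base lets the
# paired generator reuse the diploid draw for null regions
.region_rates <- function(cfg, genes, genome) {
  rates <- cfg$meth_rates[[genome]]
  ctxs <- names(rates)
  grid <- expand.grid(gene_id = genes$gene_id,
                      region_kind = c("promoter", "gene_body"),
                      context = ctxs, stringsAsFactors = FALSE)
  bio <- setNames(genes$biotype, genes$gene_id)
  mu <- rates[grid$context] +
    ifelse(bio[grid$gene_id] == "pseudogene",
           cfg$pseudogene_offset[grid$context], 0)
  clip <- mu < 0 | mu > 1
  if (any(clip)) warning("methylation rate clipped to [0,1] after pseudogene offset")
  mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
  k <- cfg$meth_concentration
  grid$rate <- stats::rbeta(nrow(grid), mu * k, (1 - mu) * k)
  grid
}

#' Generate a per-cytosine report for one genome
#'
#' Sites are placed at context-specific densities across each gene's promoter
#' (2 kb upstream of the TSS), gene body and 2 kb downstream flank, plus one
#' site at every position of the TSS +/- `tss_window` window (cytosine-dense
#' TSS neighbourhoods make the TSS-window test well defined). Each
#' (gene, region, context) unit carries a Beta-distributed true rate around
#' the genome's context mean, elevated for pseudogenes; expressed genes get a
#' multiplicative methylation dip at the TSS. Coverage is Poisson, methylated
#' counts binomial.
#'
#' @param cfg a [generatorConfig()].
#' @param genes gene-model `GRanges` for one arm.
#' @param genome `"diploid"` or `"hexaploid"`.
#' @param expressed_ids gene ids treated as expressed (for the TSS dip).
#' @param region_rates optional precomputed rate table (used by
#'   [generateMethylationPair()] to share null rates across genomes).
#' @param seed_offset integer added to the stage seed (distinct genomes).
#' @return list with `sites` (cytosine `GRanges` with a `gene_id` column) and
#'   `rates` (the true per-unit rate table).
#' @export
generateMethylation <- function(cfg, genes, genome = c("hexaploid", "diploid"),
                                expressed_ids = character(),
                                region_rates = NULL, seed_offset = 0L) {
  stopifnot(inherits(cfg, "generator_config"))
  genome <- match.arg(genome)
  withr::with_seed(.stage_seed(cfg, "methylation") + as.integer(seed_offset), {
    if (is.null(region_rates)) region_rates <- .region_rates(cfg, genes, genome)
    key <- with(region_rates, paste(gene_id, region_kind, context, sep = "|"))
    rate_of <- setNames(region_rates$rate, key)

    tss <- tssPositions(genes)
    tts <- ttsPositions(genes)
    strand <- as.character(GenomicRanges::strand(genes))
    chrom <- as.character(GenomicRanges::seqnames(genes))
    dens <- cfg$meth_site_density
    ctxs <- names(dens)
    out <- vector("list", length(genes))

    for (i in seq_along(genes)) {
      gid <- genes$gene_id[i]
      up <- if (strand[i] == "-") (tss[i] + 1):(tss[i] + 2000)
            else (tss[i] - 2000):(tss[i] - 1)
      body <- GenomicRanges::start(genes)[i]:GenomicRanges::end(genes)[i]
      down <- if (strand[i] == "-") (tts[i] - 2000):(tts[i] - 1)
              else (tts[i] + 1):(tts[i] + 2000)
      win <- (tss[i] - cfg$tss_window):(tss[i] + cfg$tss_window)

      pos <- ctx <- kind <- list()
      for (cx in ctxs) {
        n_up <- rpois(1, dens[[cx]] * length(up))
        n_bd <- rpois(1, dens[[cx]] * length(body))
        n_dn <- rpois(1, dens[[cx]] * length(down))
        pos[[cx]] <- c(sample(up, min(n_up, length(up))),
                       sample(body, min(n_bd, length(body))),
                       sample(down, min(n_dn, length(down))))
        kind[[cx]] <- rep(c("promoter", "gene_body", "gene_body"),
                          c(min(n_up, length(up)), min(n_bd, length(body)),
                            min(n_dn, length(down))))
      }
      # dense TSS window: one site per position, contexts mixed
      win_ctx <- sample(ctxs, length(win), replace = TRUE,
                        prob = c(0.3, 0.3, 0.4))
      all_pos <- c(unlist(pos, use.names = FALSE), win)
      all_ctx <- c(rep(ctxs, vapply(pos, length, 1L)), win_ctx)
      all_kind <- c(unlist(kind, use.names = FALSE),
                    rep("gene_body", length(win)))
      all_kind[seq_along(all_pos) > length(unlist(pos))] <-
        ifelse(.is_upstream(win, tss[i], strand[i]), "promoter", "gene_body")

      p <- rate_of[paste(gid, all_kind, all_ctx, sep = "|")]
      # TSS dip, Gaussian in distance, deeper for expressed genes
      dip_depth <- if (gid %in% expressed_ids) cfg$tss_dip[[1]] else cfg$tss_dip[[2]]
      d <- abs(all_pos - tss[i])
      p <- p * (1 - dip_depth * exp(-(d / 300)^2))
      cov <- rpois(length(p), cfg$coverage_mean)
      m <- rbinom(length(p), cov, p)
      gr <- GenomicRanges::GRanges(chrom[i],
                                   IRanges::IRanges(all_pos, width = 1L),
                                   strand = sample(c("+", "-"), length(all_pos),
                                                   replace = TRUE))
      gr$context <- all_ctx
      gr$n_meth <- m
      gr$n_total <- cov
      gr$gene_id <- gid
      out[[i]] <- gr
    }
    sites <- sort(do.call(c, out))
    list(sites = sites, rates = region_rates)
  })
}

.is_upstream <- function(pos, tss, strand) {
  if (strand == "-") pos > tss else pos < tss
}

#' Generate matched methylation for both genomes with planted DMRs
#'
#' Draws one shared true rate per (pair, region, context) so that null units
#' are exactly equal across genomes, then plants true DMRs in a fraction of
#' units by shifting the hexaploid rate by the configured per-context delta
#' (direction chosen at random among those keeping the rate inside `[0, 1]`).
#' The truth table is a sidecar, never read by the calling pipeline.
#'
#' @param cfg a [generatorConfig()].
#' @param models output of [generateGeneModels()].
#' @param expressed_ids list with `diploid` and `hexaploid` expressed gene ids.
#' @return list with `diploid`, `hexaploid` (each as [generateMethylation()])
#'   and `truth` (data.frame `pair_id`, `region_kind`, `context`, `is_dmr`,
#'   `delta` as hexaploid - diploid proportion).
#' @export
generateMethylationPair <- function(cfg, models,
                                    expressed_ids = list(diploid = character(),
                                                         hexaploid = character())) {
  stopifnot(inherits(cfg, "generator_config"))
  rates_dip <- withr::with_seed(.stage_seed(cfg, "methylation"),
                                .region_rates(cfg, models$diploid, "diploid"))
  # hexaploid base rate: shared with diploid up to the context-mean offset so
  # null units differ by ~0 and planted units by the configured delta
  map <- setNames(models$hexaploid$gene_id, models$diploid$gene_id)
  rates_hex <- rates_dip
  rates_hex$gene_id <- unname(map[rates_dip$gene_id])
  shift <- cfg$meth_rates$hexaploid[rates_hex$context] -
    cfg$meth_rates$diploid[rates_hex$context]
  rates_hex$rate <- pmin(pmax(rates_hex$rate + shift, 1e-4), 1 - 1e-4)

  withr::with_seed(.stage_seed(cfg, "methylation") + 7L, {
    n_units <- nrow(rates_hex)
    planted <- runif(n_units) < cfg$dmr_fraction
    delta <- cfg$dmr_delta[rates_hex$context]
    up_ok <- rates_hex$rate + delta <= 1 - 1e-4
    dn_ok <- rates_hex$rate - delta >= 1e-4
    dirn <- ifelse(up_ok & dn_ok, sample(c(1, -1), n_units, replace = TRUE),
                   ifelse(up_ok, 1, ifelse(dn_ok, -1, 0)))
    if (any(planted & dirn == 0))
      warning("some planted DMR rates clipped to [0,1]")
    rates_hex$rate[planted] <- pmin(pmax(
      rates_hex$rate[planted] + (dirn * delta)[planted], 1e-4), 1 - 1e-4)
  })

  dip <- generateMethylation(cfg, models$diploid, "diploid",
                             expressed_ids = expressed_ids$diploid,
                             region_rates = rates_dip, seed_offset = 11L)
  hex <- generateMethylation(cfg, models$hexaploid, "hexaploid",
                             expressed_ids = expressed_ids$hexaploid,
                             region_rates = rates_hex, seed_offset = 13L)

  pair_of <- setNames(models$pairs$pair_id, models$pairs$diploid_gene_id)
  truth <- data.frame(
    pair_id = unname(pair_of[rates_dip$gene_id]),
    diploid_gene_id = rates_dip$gene_id,
    hexaploid_gene_id = rates_hex$gene_id,
    region_kind = rates_dip$region_kind,
    context = rates_dip$context,
    is_dmr = rates_hex$rate - rates_dip$rate != 0 &
      abs(rates_hex$rate - rates_dip$rate) >=
        0.5 * cfg$dmr_delta[rates_dip$context],
    delta = rates_hex$rate - rates_dip$rate,
    stringsAsFactors = FALSE)
  list(diploid = dip, hexaploid = hex, truth = truth)
}

#' Generate ATAC replicate peaks and fragment lengths for one genome
#'
#' Latent true peaks are placed around gene TSSs with Laplace-distributed
#' offsets (per-genome scale: broad in the diploid, tight in the hexaploid)
#' and log-normal widths (narrower in the hexaploid). Each replicate observes
#' every latent peak with edge jitter, plus its own spurious noise peaks, so
#' per-base replicate intersection recovers the latent set. Fragment lengths
#' follow a sub-nucleosomal/mono-/di-nucleosomal mixture thinned by a
#' multiplicative comb of period `fragment_period`.
#'
#' @param cfg a [generatorConfig()].
#' @param genes gene-model `GRanges` for the arm.
#' @param genome `"diploid"` or `"hexaploid"`.
#' @return list with `replicate_peaks` (list of `GRanges`, one per replicate),
#'   `latent_peaks` (truth sidecar `GRanges` with `gene_id`), and `fragments`
#'   (integer lengths in bp).
#' @export
generateAtac <- function(cfg, genes, genome = c("diploid", "hexaploid")) {
  stopifnot(inherits(cfg, "generator_config"))
  genome <- match.arg(genome)
  withr::with_seed(.stage_seed(cfg, paste0("atac_", genome)), {
    chrom <- as.character(GenomicRanges::seqnames(genes))[1]
    chrom_len <- cfg$chrom_len
    tss <- tssPositions(genes)
    has_peak <- runif(length(genes)) < cfg$atac_peak_rate[[genome]]
    idx <- which(has_peak)
    n_extra <- rpois(length(idx), 0.5)  # some genes carry >1 latent peak
    gene_of <- rep(idx, 1L + n_extra)
    n_lat <- length(gene_of)
    # Laplace offsets from the TSS
    sc <- cfg$atac_tss_scale[[genome]]
    off <- round(rexp(n_lat, 1 / sc) * sample(c(-1, 1), n_lat, replace = TRUE))
    w <- pmax(80, round(rlnorm(n_lat, cfg$atac_width_meanlog[[genome]],
                               cfg$atac_width_sdlog)))
    centre <- pmin(pmax(tss[gene_of] + off, w %/% 2 + 1), chrom_len - w %/% 2 - 1)
    latent <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(centre - w %/% 2, width = w))
    latent$gene_id <- genes$gene_id[gene_of]
    latent <- sort(latent)

    reps <- lapply(seq_len(cfg$atac_replicates), function(r) {
      s <- pmax(1, GenomicRanges::start(latent) +
                  round(rnorm(n_lat, 0, cfg$atac_jitter_sd)))
      e <- pmin(chrom_len, GenomicRanges::end(latent) +
                  round(rnorm(n_lat, 0, cfg$atac_jitter_sd)))
      keep <- e > s
      obs <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s[keep], e[keep]))
      n_noise <- rpois(1, cfg$atac_noise_rate * length(genes))
      if (n_noise > 0) {
        nw <- pmax(80, round(rlnorm(n_noise, cfg$atac_width_meanlog[[genome]],
                                    cfg$atac_width_sdlog)))
        ns <- round(runif(n_noise, 1, chrom_len - max(nw) - 1))
        obs <- c(obs, GenomicRanges::GRanges(chrom, IRanges::IRanges(ns, width = nw)))
      }
      sort(GenomicRanges::reduce(obs))
    })

    frags <- .sample_fragments(cfg$n_fragments, cfg$fragment_period,
                               cfg$fragment_comb_amp)
    list(replicate_peaks = reps, latent_peaks = latent, fragments = frags)
  })
}

# mixture base law thinned by a multiplicative cosine comb
.sample_fragments <- function(n, period, amp) {
  out <- integer(0)
  while (length(out) < n) {
    m <- 2L * (n - length(out)) + 100L
    comp <- sample(1:3, m, replace = TRUE, prob = c(0.6, 0.32, 0.08))
    len <- ifelse(comp == 1L, 40 + rexp(m, 1 / 60),
           ifelse(comp == 2L, rnorm(m, 200, 35), rnorm(m, 390, 45)))
    len <- round(len[len >= 30 & len <= 600])
    acc <- runif(length(len)) < (1 + amp * cos(2 * pi * len / period)) / (1 + amp)
    out <- c(out, as.integer(len[acc]))
  }
  out[seq_len(n)]
}

#' Write a complete synthetic dataset to disk
#'
#' Materialises one seeded run of all generators into the standard formats the
#' analysis stages read: GFF3 gene models, TSV TPM matrices and design, a
#' cytosine report per genome, replicate peak BED files, a fragment-length
#' TSV, and truth-label sidecar TSVs (which the pipeline never reads).
#'
#' @param cfg a [generatorConfig()].
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
writeSyntheticDataset <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  models <- generateGeneModels(cfg)
  expr <- generateExpression(cfg, models$pairs)
  meth <- generateMethylationPair(cfg, models)
  atac_d <- generateAtac(cfg, models$diploid, "diploid")
  atac_h <- generateAtac(cfg, models$hexaploid, "hexaploid")

  writeGeneModels(models$diploid, file.path(outdir, "diploid.gff3"))
  writeGeneModels(models$hexaploid, file.path(outdir, "hexaploid.gff3"))
  wtsv <- function(x, f) data.table::fwrite(data.table::as.data.table(x, keep.rownames = "id"),
                                            file.path(outdir, f), sep = "\t")
  wtsv(expr$tpm_diploid, "tpm_diploid.tsv")
  wtsv(expr$tpm_hexaploid, "tpm_hexaploid.tsv")
  data.table::fwrite(expr$design, file.path(outdir, "design.tsv"), sep = "\t")
  data.table::fwrite(models$pairs, file.path(outdir, "pairs.tsv"), sep = "\t")
  data.table::fwrite(expr$truth, file.path(outdir, "truth_expression.tsv"), sep = "\t")
  writeCytosineReport(meth$diploid$sites, file.path(outdir, "cx_diploid.txt"))
  writeCytosineReport(meth$hexaploid$sites, file.path(outdir, "cx_hexaploid.txt"))
  data.table::fwrite(meth$truth, file.path(outdir, "truth_methylation.tsv"), sep = "\t")
  for (g in c("diploid", "hexaploid")) {
    at <- if (g == "diploid") atac_d else atac_h
    for (r in seq_along(at$replicate_peaks))
      writeBed(at$replicate_peaks[[r]],
               file.path(outdir, sprintf("atac_%s_rep%d.bed", g, r)))
    data.table::fwrite(data.table::data.table(length = at$fragments),
                       file.path(outdir, sprintf("fragments_%s.tsv", g)), sep = "\t")
  }
  invisible(outdir)
}
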