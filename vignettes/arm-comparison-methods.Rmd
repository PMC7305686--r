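---
title: "Methods: comparing homologous chromosome arms across ploidy"
author: "armCompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing homologous chromosome arms across ploidy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armCompare)
```

# Scope and model

`armCompare` compares one diploid chromosome arm with its homologous arm in
a polyploid across three regulatory layers — transcription (TPM), DNA
methylation (bisulphite counts) and chromatin accessibility (ATAC peaks and
fragments) — for a set of syntenic 1:1 gene pairs. Everything upstream of
these inputs (read alignment, TPM quantification, methylation extraction,
peak calling, synteny detection) is assumed done by the standard tools;
this package owns the comparison itself, its thresholds, and the statistics
that link the layers.

All genomic data are held in Bioconductor containers: `GRanges` (1-based,
closed intervals; BED's 0-based half-open convention is converted at the
file boundary by rtracklayer) and a `SummarizedExperiment` subclass,
`PairedExpression`, whose rows are syntenic pairs, columns tissues, and
whose two assays carry each genome's replicate-averaged TPM.

# Expression classification

A pair is **expressed** when either copy reaches `tpm_min` (default 1 TPM,
inclusive) in at least one tissue. The either-genome rule is deliberate: a
pair silenced in one genome but active in the other is exactly the kind of
regulatory divergence the comparison must retain.

Because the polyploid copies of most genes run at a roughly constant
fraction of the diploid level, raw cross-ploidy ratios are centred away
from 1. The **normalization factor** is the median of
$(\mathrm{TPM}_{dip} + \varepsilon)/(\mathrm{TPM}_{hex} + \varepsilon)$
over expressed pairs, pooled across the tissues in which each pair is
expressed. Pooling (rather than a per-tissue factor) uses a single global
re-centering, which matches the view that the reduction is a chromosome-
wide, tissue-independent effect; a per-tissue factor would partially absorb
genuine tissue-specific differences into the normalization. A fixed factor
(`method = "fixed"`, default 1.7604) reproduces published analyses exactly.
The pseudocount $\varepsilon = 0.01$ TPM guards against infinite folds at
zero expression; it is far below the expression threshold, so it never
changes the class of an expressed measurement away from a boundary.

Per tissue, the scaled ratio
$r = (f\cdot\mathrm{TPM}_{hex} + \varepsilon)/(\mathrm{TPM}_{dip} +
\varepsilon)$ is compared with the fold threshold (default 4, inclusive on
both sides): $r \ge 4$ and $r \le 1/4$ are DEG calls, anything between is
balanced, and tissues where neither copy reaches `tpm_min` are
`not_expressed`. A pair is a DEG overall when it is a DEG in any tissue;
expressed non-DEG pairs are the proportionately reduced class. Conserved
DEGs across several diploid accessions are the intersection of pairs called
DEG **in the same direction** against every accession.

Replicates are combined by the arithmetic mean: TPM is already length- and
depth-normalized upstream, so no reweighting is appropriate.

# Methylation

The **weighted methylation** of any site set is
$\sum m_i / \sum n_i$ over covered sites — reads, not sites, are the unit,
so the estimator is invariant to how reads are split across duplicate site
records.

**Region aggregates** (gene body; promoter = 2 kb upstream of the TSS,
strand-aware) include a site when it matches the context, has coverage
$\ge$ `min_cov` (defaults 5× diploid / 10× hexaploid, reflecting unequal
sequencing depth), and carries $\ge 1$ methylated read. A region is
reported only with $\ge 5$ such sites. We read "five methylated cytosines"
literally — five cytosines each showing methylation — rather than five
covered cytosines; both the count and the region level use only qualifying
sites, and the alternative is one argument away (`min_sites`, `min_cov`).

**DMRs** are called on regions matched across genomes by (pair, region
kind, context). The p-value is a two-sided two-proportion test with
continuity correction (`prop.test`) on the pooled (methylated, total)
counts — the natural companion to read-weighted region levels — with BH
adjustment within each context, since the three contexts have very
different baseline rates and region counts. A region is a DMR when
$q < 0.05$ **and** $|\Delta| \ge$ 50 (CpG), 25 (CHG) or 10 (CHH)
percentage points, $\Delta$ = hexaploid − diploid. The CHH rule is applied
at region level, like the other contexts, for symmetry of the filter
pipeline. With identical inputs on both sides the caller returns zero DMRs
at any positive threshold.

**Metaprofiles** bin sites into 50 fixed-width upstream bins (3 kb flank),
40 normalized gene-body bins and 50 downstream bins, strand-aware; each
bin is the read-weighted methylation of its sites. The bin counts are free
layout choices — enough body bins to resolve the TSS/TTS dips without
emptying bins at desk-scale site densities. A site exactly at the TSS
belongs to the first body bin; each site contributes to a single bin (for
genes shorter than the bin count this simply leaves some body bins empty —
no fractional spreading is attempted, which matters only for genes tens of
bp long).

The **TSS-window test** compares expressed and non-expressed genes over
TSS ± 20 bp: per position, the weighted methylation across genes is
computed in each group, and the two 41-length vectors are compared by a
pooled-variance two-sample t-test — 80 degrees of freedom when every
position is covered in both groups. Positions uncovered in either group
are dropped from both (df = 2k − 2 over k retained positions, reported).
When both vectors are constant the t statistic is defined directly (0 if
equal, ±∞ otherwise) rather than erroring.

# ATAC post-processing

Reads are shifted **+4 bp (forward) / −5 bp (reverse)** to centre them on
the Tn5 insertion point; whole reads shift, lengths are preserved, and the
asymmetry is intentional. **Reproducible peaks** are the per-base
intersection of the replicate peak sets — the strictest reading of "present
in all replicates"; an any-overlap mode is kept behind a flag. Intersection
runs first, then peaks separated by **< 10 bp** are merged (exclusive
threshold: a 9 bp gap merges, a 10 bp gap survives). Intersect-then-merge
is the conservative order: merging first would let near-adjacent peaks in
single replicates manufacture reproducibility.

Annotation classifies each peak by overlap with strand-aware windows:
promoter+5′UTR = start codon to 2 kb upstream; CDS+intron = start codon to
the end of the coding region; 3′UTR+downstream = past the coding region to
2 kb beyond the TTS; intergenic otherwise. The promoter class is anchored
at the ATG (with a TSS fallback for pseudogene models without a start
codon) while methylation promoters are TSS-anchored — the two analyses
define "promoter" differently on purpose, and both anchors are arguments.
Peaks touching several classes take the highest-precedence class
(promoter > CDS > downstream); peaks touching several genes go to the
nearest TSS. The TSS distance is measured from the peak midpoint — stable
under merging, unlike proximal edges — and signed in gene orientation.

**Fragment periodicity** detrends the integer-bp length histogram with a
centred moving average (window 21 bp) and scans spectral power over a
0.05 bp period grid in the 5–15 bp band. The dominant period is reported
with its power relative to the in-band median; "significant" requires a
ratio ≥ 15, a conservative cutoff because the maximum of a white-noise
spectrum over the scanned band already reaches ratios of ~6–9. Below 1,000
fragments the estimate is flagged low-confidence.

**Differential accessibility** has no published quantitative definition, so
the package declares one: a pair is differential in a region class when
peak presence/absence differs between genomes there, or when both have
peaks but total peak bp differs by ≥ 2-fold **and** ≥ 50 bp. The double
condition keeps ratio blow-ups on tiny peaks and trivial absolute
differences on long peaks from being called; both thresholds are exposed.

# Integration statistics

Set overlaps use the upper-tail hypergeometric distribution; peak-length
comparisons use fixed-effects one-way ANOVA on raw lengths; chromosome-
scale positional trends use Spearman correlation (average ranks for ties)
between 8-Mb bin indices and bin means; percent identity is computed from
a Needleman–Wunsch global alignment (match +1, mismatch −1, gap −2) as
matches over alignment columns; and promoter motif screening uses k-mer
(default k = 6) presence/absence per promoter with a hypergeometric test
and BH adjustment — a deliberately simple surrogate for motif discovery
that avoids length confounding between promoter sets.

# The synthetic-data generator

The generator exists so that every stage of the pipeline can be exercised
and scored without the original sequencing archives. Its defaults are the
study conditions the package is calibrated against, and they are not
tuning knobs:

* **Gene models** — collinear 1:1 pairs along one arm per genome, 1.5–4 kb
  bodies, 1–4 exons, 100–300 bp UTRs, 5% pseudogenes.
* **Expression** — diploid base TPM log-normal (meanlog 2.5, sdlog 1);
  70% of pairs balanced at ratio $0.40\,e^{N(0,\,0.2)}$; 30% DEGs with
  post-normalization folds log-uniform in [4, 16] and random direction
  (spreading effects beyond the boundary so threshold tests are
  informative); shared tissue effects (sdlog 0.5); replicate noise
  sdlog 0.2 (the replicate dispersion is not published; 0.2 is a typical
  RNA-seq TPM spread and is the one free choice here); three diploid
  accessions differing by pair-level effects of sdlog 0.1.
* **Methylation** — context rates CpG/CHG/CHH = 89.9/59.4/3.8% (hexaploid)
  and 87.1/53.4/3.4% (diploid); per-(gene, region, context) rates
  Beta-distributed around the context mean with concentration 20 (real
  methylation is overdispersed across genes; without this, a DMR test has
  nothing realistic to beat); pseudogene CpG/CHG elevation +13.2/+12.6
  points (clipped into [0, 1] with a warning — the CpG offset saturates by
  construction, so the CHG offset is the one used for quantitative
  recovery checks); Poisson coverage (mean 10); binomial methylated
  counts; a Gaussian TSS dip (300 bp scale, deeper for expressed genes)
  that reproduces the expressed/non-expressed metaprofile contrast; a
  densely sited TSS ± 20 bp window so the TSS-window test is well defined.
  The paired generator shares one rate draw per unit across genomes, so
  null units differ only by the genome-wide context offset, and plants
  DMRs in a configurable fraction of units by shifting the hexaploid rate
  by the per-context delta toward whichever direction stays in [0, 1].
* **ATAC** — latent peaks near TSSs with Laplace offsets (scale 80 kb
  diploid, 4.3 kb hexaploid, putting ~50% of hexaploid peaks within 3 kb
  of a TSS while diploid accessibility spreads much farther) and
  log-normal widths (450 bp diploid, 280 bp hexaploid — fewer, narrower
  hexaploid peaks); replicates observe every latent peak with 15 bp edge
  jitter plus their own spurious peaks, so per-base intersection recovers
  the latent set; fragment lengths from a sub-/mono-/di-nucleosomal
  mixture thinned by a multiplicative cosine comb of period 10.5 bp.

Truth labels (pair class, planted DMR units, latent peaks) are sidecar
outputs that the analysis stages never read.

**What the generator does not emulate:** sequence-driven site placement
(sites are positional abstractions, not real cytosines in a reference),
linkage between the layers (methylation and accessibility are generated
independently of the expression class, so cross-layer overlaps are null by
construction), repeat structure, mapping artefacts, and biological
covariance between neighbouring genes. Passing tests therefore demonstrate
that the estimators and filters recover planted parameters under the
stated statistical structure — not that the pipeline's biological
conclusions transfer to any particular real dataset.

# Calibration experiments and problem sizes

The test suite runs each recovery experiment at the smallest size that
gives stable statistics: 5,000 pairs for classification recovery (balanced
fraction within ±2 points of 70%, median ratio within ±2 points of 40%),
100,000 sites per context for the methylation estimator (within 3
Monte-Carlo standard deviations, with the MC sd itself estimated from
independent replicate simulations), 250 genes at 30× coverage for DMR
recovery (recall ≥ 0.9 of DMRs planted at threshold + 10 points; empirical
FDR within binomial error of the nominal 5%), and ≤ 10 kb instances for
the per-base interval oracles. In the DMR experiment the TSS dip is turned
off so the planted effect equals its nominal size at every site; with the
dip on, sites near the TSS carry a multiplicatively shrunken difference
and the experiment would no longer test the stated condition.

# Numerical choices and degenerate inputs

Zero-coverage cytosines are retained by the reader and excluded by every
estimator; regions failing the filters are silently absent rather than
NA-filled; `callDmrs` skips regions with zero totals; empty replicate peak
sets yield an empty reproducible set; peaks shifted below position 1 are
clipped with a warning; context calls within 2 bp of a contig end are NA
with a warning; Spearman on fewer than 3 bins or constant bin means is
flagged undefined instead of guessing; and all generators are pure
functions of their seeded configuration (stage-scoped seeds derived from
the master seed, so adding a stage never perturbs another).

# Known limitations

The DMR test treats sites within a region as exchangeable (no
autocorrelation along the region); the per-base intersection is stricter
than any-overlap reproducibility and shrinks peaks by the replicate jitter;
the differential-accessibility rule is a declared surrogate, not a
published definition; and the promoter k-mer screen is presence/absence
only. These are the points to revisit first when adapting the package to
data whose structure departs from the generator's assumptions.
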