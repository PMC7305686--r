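#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats aggregate aov anova cor.test lm median p.adjust phyper
#'   prop.test quantile rbinom rlnorm rnorm rpois runif sd setNames t.test
#'   rexp complete.cases
#' @importFrom utils head
NULL

#' Paired cross-ploidy expression container
#'
#' `PairedExpression` extends [SummarizedExperiment::SummarizedExperiment] to
#' hold replicate-averaged TPM values for syntenic gene pairs. Rows are pairs,
#' columns are tissues, and the two mandatory assays `"diploid"` and
#' `"hexaploid"` carry the TPM of each member of the pair in its own genome.
#' Classification (see [classifyPairs()]) adds a `"class"` assay with the
#' per-tissue call and `overall_class` / `overall_direction` columns to
#' `rowData`.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment]; no extra slots.
#' @seealso [PairedExpression()], [flagExpressed()], [classifyPairs()]
#' @export
setClass("PairedExpression", contains = "SummarizedExperiment")

setValidity("PairedExpression", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("diploid", "hexaploid") %in% an))
    return("assays 'diploid' and 'hexaploid' are required")
  d <- SummarizedExperiment::assay(object, "diploid")
  h <- SummarizedExperiment::assay(object, "hexaploid")
  if (!identical(dim(d), dim(h)))
    return("'diploid' and 'hexaploid' assays must have identical dimensions")
  if (anyNA(d) || anyNA(h))
    return("TPM assays must not contain NA/NaN")
  if (any(d < 0) || any(h < 0))
    return("TPM values must be non-negative")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("diploid_gene_id", "hexaploid_gene_id") %in% colnames(rd)))
    return("rowData must contain diploid_gene_id and hexaploid_gene_id")
  TRUE
})

#' Methylation metaprofile across scaled gene bodies
#'
#' Holds the binned weighted-methylation means for one sequence context and one
#' gene group (expressed or non-expressed), laid out as a fixed-width upstream
#' flank, a normalized-length gene body, and a fixed-width downstream flank.
#'
#' @slot context single sequence context, one of `"CpG"`, `"CHG"`, `"CHH"`.
#' @slot group gene group label, typically `"expressed"` or `"non_expressed"`.
#' @slot bins numeric vector of per-bin weighted methylation means in `[0, 1]`
#'   (`NaN` for bins with no covered sites).
#' @slot bin_counts integer vector, number of sites contributing to each bin.
#' @slot layout integer triple: number of upstream, gene-body and downstream
#'   bins.
#' @slot flank size in bp of each fixed-width flank.
#' @export
setClass("MethylationMetaprofile",
  representation(
    context = "character",
    group = "character",
    bins = "numeric",
    bin_counts = "integer",
    layout = "integer",
    flank = "numeric"
  )
)

setValidity("MethylationMetaprofile", function(object) {
  if (length(object@layout) != 3L)
    return("layout must give (upstream, body, downstream) bin counts")
  if (length(object@bins) != sum(object@layout))
    return("bins length must equal sum(layout)")
  if (length(object@bin_counts) != length(object@bins))
    return("bin_counts must match bins")
  ok <- is.nan(object@bins) | (object@bins >= 0 & object@bins <= 1)
  if (!all(ok)) return("bin means must lie in [0, 1]")
  TRUE
})

#' @describeIn MethylationMetaprofile compact display.
#' @param object a `MethylationMetaprofile`.
#' @export
setMethod("show", "MethylationMetaprofile", function(object) {
  cat("MethylationMetaprofile:", object@context, "/", object@group, "\n")
  cat(sprintf("  layout: %d upstream + %d body + %d downstream bins (flank %g bp)\n",
              object@layout[1], object@layout[2], object@layout[3], object@flank))
  covered <- object@bin_counts > 0L
  if (any(covered))
    cat(sprintf("  mean level over covered bins: %.4f (%d/%d bins covered)\n",
                mean(object@bins[covered]), sum(covered), length(covered)))
  invisible(NULL)
})

#' @describeIn PairedExpression compact display.
#' @param object a `PairedExpression`.
#' @export
setMethod("show", "PairedExpression", function(object) {
  callNextMethod()
  rd <- SummarizedExperiment::rowData(object)
  if ("overall_class" %in% colnames(rd)) {
    tab <- table(rd$overall_class)
    cat("pair classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  } else if ("expressed" %in% colnames(rd)) {
    cat("expressed pairs:", sum(rd$expressed), "/", nrow(rd), "\n")
  }
  invisible(NULL)
})
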