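#' Average TPM replicates into per-tissue means
#'
#' @param tpm numeric matrix, genes x samples (TPM; already length- and
#'   depth-normalized upstream, so the arithmetic mean is appropriate).
#' @param design data.frame with columns `sample` and `tissue`; every sample
#'   must be a column of `tpm`.
#' @return matrix genes x tissues of replicate means.
#' @export
aggregateReplicates <- function(tpm, design) {
  stopifnot(is.matrix(tpm), all(c("sample", "tissue") %in% names(design)))
  missing_cols <- setdiff(design$sample, colnames(tpm))
  if (length(missing_cols))
    stop("sample column(s) missing from TPM matrix: ",
         paste(missing_cols, collapse = ", "))
  if (anyNA(tpm[, design$sample]))
    stop("TPM matrix contains NA/NaN values")
  tissues <- unique(design$tissue)
  out <- vapply(tissues, function(t) {
    cols <- design$sample[design$tissue == t]
    rowMeans(tpm[, cols, drop = FALSE])
  }, numeric(nrow(tpm)))
  out <- matrix(out, nrow = nrow(tpm),
                dimnames = list(rownames(tpm), tissues))
  out
}

#' Construct a PairedExpression object
#'
#' Aggregates replicate TPM for both genomes into per-tissue means and binds
#' them row-wise by syntenic pair.
#'
#' @param pairs data.frame with `pair_id`, `diploid_gene_id`,
#'   `hexaploid_gene_id` (extra columns are kept in `rowData`).
#' @param tpm_diploid,tpm_hexaploid replicate TPM matrices with rows matching
#'   `pairs` (rownames are pair or gene ids; row order must match `pairs`).
#' @param design replicate design, see [aggregateReplicates()].
#' @return a [PairedExpression] object.
#' @export
PairedExpression <- function(pairs, tpm_diploid, tpm_hexaploid, design) {
  d <- aggregateReplicates(tpm_diploid, design)
  h <- aggregateReplicates(tpm_hexaploid, design)
  if (!identical(dim(d), dim(h)) || nrow(d) != nrow(pairs))
    stop("pair table and TPM matrices disagree on dimensions")
  rd <- S4Vectors::DataFrame(pairs)
  rownames(d) <- rownames(h) <- pairs$pair_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(diploid = d, hexaploid = h), rowData = rd)
  rownames(se) <- pairs$pair_id
  methods::new("PairedExpression", se)
}

#' @rdname diploidTPM
#' @param x a [PairedExpression].
#' @return the per-tissue replicate-mean TPM matrix for the requested genome.
#' @export
setMethod("diploidTPM", "PairedExpression", function(x)
  SummarizedExperiment::assay(x, "diploid"))

#' @rdname diploidTPM
#' @export
setMethod("hexaploidTPM", "PairedExpression", function(x)
  SummarizedExperiment::assay(x, "hexaploid"))

#' Flag expressed syntenic pairs
#'
#' A pair is expressed when either member reaches the TPM threshold
#' (inclusive) in at least one tissue — matching the "and/or" reading of
#' cross-genome expression.
#'
#' @param x a [PairedExpression].
#' @param tpm_min TPM threshold (default 1).
#' @return `x` with a logical `expressed` column in `rowData`.
#' @export
setMethod("flagExpressed", "PairedExpression", function(x, tpm_min = 1) {
  mx <- pmax(apply(diploidTPM(x), 1, max), apply(hexaploidTPM(x), 1, max))
  SummarizedExperiment::rowData(x)$expressed <- mx >= tpm_min
  x
})

#' Cross-ploidy TPM normalization factor
#'
#' With `method = "median_ratio"` the factor is the median, over expressed
#' pairs pooled across the tissues in which the pair is expressed, of
#' `(diploid TPM + eps) / (hexaploid TPM + eps)`. Multiplying hexaploid TPM by
#' this factor centres the balanced class at ratio 1, which is what makes a
#' symmetric fold-change threshold meaningful when ~70% of pairs sit near a
#' common reduced ratio. `method = "fixed"` returns a configured constant
#' (default 1.7604, the factor used for the wheat 3DL / Ae. tauschii 3L
#' comparison this package was built around).
#'
#' @param x a [PairedExpression] that has been through [flagExpressed()].
#' @param method `"median_ratio"` or `"fixed"`.
#' @param fixed_factor constant returned by `method = "fixed"`.
#' @param eps pseudocount (TPM) guarding against zero denominators.
#' @param tpm_min per-tissue expression threshold used to select the pooled
#'   (pair, tissue) cells.
#' @return list with `factor`, `method`, `n_pairs_used`.
#' @export
setMethod("computeNormalizationFactor", "PairedExpression",
  function(x, method = c("median_ratio", "fixed"), fixed_factor = 1.7604,
           eps = 0.01, tpm_min = 1) {
    method <- match.arg(method)
    if (method == "fixed")
      return(list(factor = fixed_factor, method = "fixed", n_pairs_used = 0L))
    rd <- SummarizedExperiment::rowData(x)
    if (!"expressed" %in% colnames(rd))
      stop("run flagExpressed() first")
    keep <- rd$expressed
    if (sum(keep) < 10L)
      stop("median_ratio needs >= 10 expressed pairs (got ", sum(keep), ")")
    d <- diploidTPM(x)[keep, , drop = FALSE]
    h <- hexaploidTPM(x)[keep, , drop = FALSE]
    cell <- pmax(d, h) >= tpm_min
    ratios <- ((d + eps) / (h + eps))[cell]
    list(factor = stats::median(ratios), method = "median_ratio",
         n_pairs_used = sum(keep))
  })

#' Classify syntenic pairs into balanced and differential classes
#'
#' Per tissue, the scaled ratio r = (factor * hexaploid + eps) /
#' (diploid + eps) is compared to the fold threshold: ratio at or above
#' `fold` calls `deg_up_hexaploid`, at or below `1/fold` calls
#' `deg_up_diploid` (both inclusive),
#' anything in between is `balanced`; tissues where neither gene reaches
#' `tpm_min` are `not_expressed`. A pair is a DEG overall when it is a DEG in
#' at least one tissue; expressed non-DEG pairs form the proportionately
#' reduced (balanced) class.
#'
#' @param x a [PairedExpression] after [flagExpressed()].
#' @param norm output of [computeNormalizationFactor()] (or a bare positive
#'   number).
#' @param fold DEG fold-change threshold (> 1; default 4).
#' @param eps pseudocount (TPM).
#' @param tpm_min per-tissue expression threshold.
#' @return `x` with a `"class"` assay (per-tissue calls) and `rowData`
#'   columns `overall_class` (`balanced`/`deg`/`not_expressed`),
#'   `overall_direction` (`up_hexaploid`/`up_diploid`/`mixed`/`NA`) and
#'   `ratio_hexdip` (median unscaled hexaploid/diploid ratio over expressed
#'   tissues).
#' @export
setMethod("classifyPairs", "PairedExpression",
  function(x, norm, fold = 4, eps = 0.01, tpm_min = 1) {
    factor <- if (is.list(norm)) norm$factor else norm
    if (!is.numeric(factor) || factor <= 0) stop("normalization factor must be > 0")
    if (fold <= 1) stop("fold threshold must exceed 1")
    rd <- SummarizedExperiment::rowData(x)
    if (!"expressed" %in% colnames(rd)) stop("run flagExpressed() first")
    d <- diploidTPM(x); h <- hexaploidTPM(x)
    r <- (factor * h + eps) / (d + eps)
    cls <- matrix("balanced", nrow(r), ncol(r), dimnames = dimnames(r))
    cls[r >= fold] <- "deg_up_hexaploid"
    cls[r <= 1 / fold] <- "deg_up_diploid"
    cls[pmax(d, h) < tpm_min] <- "not_expressed"

    is_deg_t <- cls == "deg_up_hexaploid" | cls == "deg_up_diploid"
    any_deg <- rowSums(is_deg_t) > 0L
    overall <- ifelse(!rd$expressed, "not_expressed",
                      ifelse(any_deg, "deg", "balanced"))
    up_h <- rowSums(cls == "deg_up_hexaploid") > 0L
    up_d <- rowSums(cls == "deg_up_diploid") > 0L
    dirn <- rep(NA_character_, nrow(r))
    dirn[overall == "deg" & up_h & !up_d] <- "up_hexaploid"
    dirn[overall == "deg" & up_d & !up_h] <- "up_diploid"
    dirn[overall == "deg" & up_d & up_h] <- "mixed"

    raw <- (h + eps) / (d + eps)
    expr_t <- pmax(d, h) >= tpm_min
    ratio_med <- vapply(seq_len(nrow(r)), function(i) {
      v <- raw[i, expr_t[i, ]]
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1))

    SummarizedExperiment::assay(x, "class") <- cls
    rd$overall_class <- overall
    rd$overall_direction <- dirn
    rd$ratio_hexdip <- ratio_med
    SummarizedExperiment::rowData(x) <- rd
    methods::validObject(x)
    x
  })

#' @rdname pairClasses
#' @param x a classified [PairedExpression].
#' @return `pairClasses()`: the per-tissue class matrix; `overallClass()`: the
#'   per-pair overall class vector named by pair id.
#' @export
setMethod("pairClasses", "PairedExpression", function(x) {
  if (!"class" %in% SummarizedExperiment::assayNames(x))
    stop("run classifyPairs() first")
  SummarizedExperiment::assay(x, "class")
})

#' @rdname pairClasses
#' @export
setMethod("overallClass", "PairedExpression", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"overall_class" %in% colnames(rd)) stop("run classifyPairs() first")
  setNames(rd$overall_class, rownames(x))
})

#' Direction-consistent DEGs across accession comparisons
#'
#' Intersects DEG calls from two or more diploid-accession comparisons,
#' keeping only pairs called DEG in the same direction versus every
#' accession.
#'
#' @param deg_sets list (length >= 2) of data.frames with columns `pair_id`
#'   and `direction` (`"up_hexaploid"`/`"up_diploid"`).
#' @return data.frame `pair_id`, `direction` of conserved DEGs (possibly
#'   empty).
#' @export
conservedDegs <- function(deg_sets) {
  if (length(deg_sets) < 2L) stop("need >= 2 accession comparisons")
  for (d in deg_sets)
    stopifnot(all(c("pair_id", "direction") %in% names(d)))
  ids <- Reduce(intersect, lapply(deg_sets, `[[`, "pair_id"))
  if (!length(ids))
    return(data.frame(pair_id = character(), direction = character()))
  dirs <- sapply(deg_sets, function(d)
    d$direction[match(ids, d$pair_id)])
  dirs <- matrix(dirs, nrow = length(ids))
  same <- apply(dirs, 1, function(v) length(unique(v)) == 1L & !anyNA(v))
  data.frame(pair_id = ids[same], direction = dirs[same, 1],
             stringsAsFactors = FALSE)
}

#' Per-tissue DEG direction tallies
#'
#' @param x a classified [PairedExpression].
#' @return data.frame with one row per tissue: counts of pairs up in the
#'   hexaploid, up in the diploid, balanced and not expressed in that tissue.
#' @export
stageSpecificSummary <- function(x) {
  cls <- pairClasses(x)
  counts <- t(apply(cls, 2, function(v)
    c(deg_up_hexaploid = sum(v == "deg_up_hexaploid"),
      deg_up_diploid = sum(v == "deg_up_diploid"),
      balanced = sum(v == "balanced"),
      not_expressed = sum(v == "not_expressed"))))
  data.frame(tissue = colnames(cls), counts, row.names = NULL,
             stringsAsFactors = FALSE)
}
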