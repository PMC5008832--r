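# Frozen-reference normalization: each sample is quantile-mapped onto the
# reference intensity distribution independently of every other sample, so
# arrays processed at different times/sites become comparable without
# re-estimating anything from the cohort. This is the gene-level analogue
# of frozen normalization against a reference corpus: the downstream
# stages consume only gene-level values and frozen cutoffs, so the frozen
# parameters here are a sorted reference quantile vector plus per-gene
# unexpressed-distribution parameters (see the package vignette for the
# relationship to probe-level frozen methods).

#' Quantile-map every sample onto the frozen reference distribution
#'
#' Each sample's values are replaced, rank for rank, by reference
#' quantiles: the value of within-sample rank r maps to the reference
#' quantile at the matching relative rank (linear interpolation when the
#' matrix and reference lengths differ; tied values receive the average of
#' the tied reference quantiles). Within-sample ranks are preserved
#' exactly and the operation is idempotent.
#'
#' @param m An [expression_matrix()].
#' @param ref A [frozen_reference()] covering every gene of `m`.
#' @return An `expr_matrix` of the same shape and metadata.
#' @export
normalize_frozen <- function(m, ref) {
  missing <- setdiff(gene_ids(m), ref$gene_ids)
  if (length(missing)) {
    bp_stop(
      paste0(
        "gene(s) missing from the frozen reference: ",
        paste(utils::head(missing, 10), collapse = ", "),
        if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10)
      ),
      "missing_reference_gene"
    )
  }
  refq <- ref$ref_quantiles
  R <- length(refq)
  G <- nrow(m$values)
  out <- m$values
  for (j in seq_len(ncol(out))) {
    r <- rank(out[, j], ties.method = "average")
    idx <- (r - 0.5) / G * R + 0.5
    idx <- pmin(pmax(idx, 1), R)
    lo <- floor(idx)
    hi <- ceiling(idx)
    out[, j] <- refq[lo] + (idx - lo) * (refq[hi] - refq[lo])
  }
  expression_matrix(out, m$samples)
}

#' Pool normalized datasets into one meta-cohort matrix
#'
#' Column-concatenates matrices over their common gene set (sorted
#' lexicographically, C locale, for a deterministic row order); the sample
#' manifests are stacked. All inputs are expected to have been normalized
#' against the same frozen reference.
#'
#' @param matrices List of [expression_matrix()] objects.
#' @return A single `expr_matrix` over the common genes.
#' @export
pool_datasets <- function(matrices) {
  if (!length(matrices)) bp_stop("no matrices to pool", "invalid_input")
  common <- Reduce(intersect, lapply(matrices, gene_ids))
  if (!length(common)) bp_stop("empty gene intersection across datasets", "empty_intersection")
  common <- sort(common, method = "radix")
  vals <- do.call(cbind, lapply(matrices, function(m) m$values[common, , drop = FALSE]))
  cols <- intersect(
    c("sample_id", "dataset_id", "group", "patient_id", "timepoint"),
    Reduce(intersect, lapply(matrices, function(m) names(m$samples)))
  )
  samples <- do.call(rbind, lapply(matrices, function(m) m$samples[, cols, drop = FALSE]))
  rownames(samples) <- NULL
  expression_matrix(vals, samples)
}
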