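# Expression-barcode stage: binarize intensities against frozen cutoffs,
# build per-dataset barcodes under group-specific frequency rules, combine
# them by intersection, and derive the progressor-exclusive gene set that
# restricts the differential-expression candidates.

#' Binarize an expression matrix against frozen cutoffs
#'
#' A gene is called expressed (1) in a sample iff its intensity lies at or
#' above `mu_unexpr + z_cut * sigma_unexpr` for that gene, i.e. the
#' standardized distance from the unexpressed distribution reaches the
#' frozen z cutoff (inclusive).
#'
#' @param m An [expression_matrix()].
#' @param ref A [frozen_reference()] covering all genes of `m`.
#' @return Integer matrix of 0/1 calls, same dimnames as `m$values`.
#' @export
binarize <- function(m, ref) {
  missing <- setdiff(gene_ids(m), ref$gene_ids)
  if (length(missing)) {
    bp_stop(
      paste0(
        "gene(s) missing from the frozen reference: ",
        paste(utils::head(missing, 10), collapse = ", ")
      ),
      "missing_reference_gene"
    )
  }
  mu <- ref$mu_unexpr[gene_ids(m)]
  sigma <- ref$sigma_unexpr[gene_ids(m)]
  z <- (m$values - mu) / sigma
  out <- (z >= ref$z_cut) + 0L
  dimnames(out) <- dimnames(m$values)
  out
}

#' Build a dataset barcode from binary calls
#'
#' The dataset barcode keeps genes expressed in a sufficient fraction of
#' the dataset's samples: 100% for P-BE datasets and >= 75% for nonP-BE
#' and EA datasets by default (both inclusive).
#'
#' @param b Binary matrix (genes x samples of one dataset), from
#'   [binarize()].
#' @param dataset_id Dataset identifier.
#' @param group Group label of the dataset's samples.
#' @param frac_rule Required expressed fraction; default 1.0 for `"P-BE"`
#'   and 0.75 otherwise.
#' @return An object of class `barcode`: list with `dataset_id`, `group`,
#'   `freq` (named per-gene expressed fraction) and `gene_set`.
#' @export
dataset_barcode <- function(b, dataset_id, group, frac_rule = NULL) {
  if (is.null(dim(b)) || ncol(b) == 0) {
    bp_stop("dataset barcode needs at least one sample", "empty_dataset")
  }
  if (!group %in% GROUP_LEVELS) {
    bp_stop(paste0("unknown group label: ", group), "invalid_group")
  }
  if (is.null(frac_rule)) frac_rule <- if (group == "P-BE") 1.0 else 0.75
  if (frac_rule < 0 || frac_rule > 1) bp_stop("frac_rule must be in [0,1]", "invalid_config")
  freq <- rowMeans(b)
  structure(
    list(
      dataset_id = dataset_id, group = group, freq = freq,
      frac_rule = frac_rule,
      gene_set = names(freq)[freq >= frac_rule]
    ),
    class = "barcode"
  )
}

#' Intersect dataset barcodes into a group barcode
#'
#' The group-specific barcode is the intersection of the gene sets of all
#' dataset barcodes of that group.
#'
#' @param barcodes List of `barcode` objects, all of the same group.
#' @return Character vector of gene ids (sorted).
#' @export
group_barcode <- function(barcodes) {
  if (!length(barcodes)) bp_stop("need at least one barcode", "invalid_input")
  groups <- unique(vapply(barcodes, `[[`, character(1), "group"))
  if (length(groups) != 1) {
    bp_stop(
      paste0("mixed groups in barcode list: ", paste(groups, collapse = ", ")),
      "mixed_groups"
    )
  }
  sort(Reduce(intersect, lapply(barcodes, `[[`, "gene_set")), method = "radix")
}

#' Genes exclusively expressed in the progressor barcode
#'
#' Set difference of the P-BE group barcode minus the nonP-BE group
#' barcode (optionally also minus the EA barcode).
#'
#' @param pbe,nonpbe Character vectors of gene ids (group barcodes).
#' @param ea Optional EA group barcode, subtracted when
#'   `subtract_ea = TRUE`.
#' @param subtract_ea Default `FALSE`: the EA barcode is computed and
#'   reported by the pipeline but does not enter the default exclusivity
#'   rule.
#' @return Character vector of gene ids (sorted).
#' @export
exclusive_genes <- function(pbe, nonpbe, ea = NULL, subtract_ea = FALSE) {
  out <- setdiff(pbe, nonpbe)
  if (subtract_ea && !is.null(ea)) out <- setdiff(out, ea)
  sort(out, method = "radix")
}

#' Restrict DE candidates to barcode-exclusive genes
#'
#' Filters a candidate set to genes in the exclusive barcode set,
#' preserving order and recording the extra filter in the provenance.
#'
#' @param candidates A `candidate_set` (from [select_candidates()]).
#' @param exclusive Character vector of barcode-exclusive gene ids.
#' @return A filtered `candidate_set`.
#' @export
intersect_candidates <- function(candidates, exclusive) {
  keep <- candidates$gene_id %in% exclusive
  out <- candidates[keep, , drop = FALSE]
  out$provenance <- if (nrow(out)) paste0(out$provenance, "+barcode-exclusive") else character()
  rownames(out) <- NULL
  class(out) <- c("candidate_set", "data.frame")
  out
}
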