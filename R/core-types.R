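# Core domain containers. All are light S3 wrappers around base structures
# (matrix + data.frame), validated at construction, in the style of limma's
# list-based classes.

#' Construct an expression matrix bound to its sample manifest
#'
#' The central container of the discovery arm: a dense genes x samples grid
#' of log2 intensities together with one [sample_info()]-style row per
#' column. All downstream stages (normalization, differential expression,
#' barcoding) consume this class.
#'
#' @param values Numeric matrix of log2 intensities, genes in rows (unique
#'   rownames required), samples in columns. All values must be finite.
#' @param samples Data frame with columns `sample_id`, `dataset_id`,
#'   `group` (one of `"P-BE"`, `"nonP-BE"`, `"EA"`) and optionally
#'   `patient_id`, `timepoint` (`"t0"`/`"t1"`). Row order is matched to the
#'   column order of `values` by `sample_id`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `samples`.
#' @export
expression_matrix <- function(values, samples) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    bp_stop("expression values must carry gene ids as rownames", "invalid_matrix")
  }
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup)) {
    bp_stop(
      paste0("duplicated gene id(s): ", paste(dup, collapse = ", ")),
      "duplicate_gene"
    )
  }
  if (!all(is.finite(values))) {
    bp_stop("expression values must all be finite", "invalid_matrix")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  needed <- c("sample_id", "dataset_id", "group")
  miss <- setdiff(needed, names(samples))
  if (length(miss)) {
    bp_stop(
      paste0("sample manifest lacks column(s): ", paste(miss, collapse = ", ")),
      "invalid_manifest"
    )
  }
  if (anyDuplicated(samples$sample_id)) {
    bp_stop("sample ids must be unique within a cohort", "invalid_manifest")
  }
  bad_grp <- setdiff(unique(samples$group), GROUP_LEVELS)
  if (length(bad_grp)) {
    bp_stop(
      paste0(
        "unknown group label(s): ", paste(bad_grp, collapse = ", "),
        " (expected ", paste(GROUP_LEVELS, collapse = ", "), ")"
      ),
      "invalid_group"
    )
  }
  if ("timepoint" %in% names(samples)) {
    bad_tp <- setdiff(stats::na.omit(unique(samples$timepoint)), TIMEPOINT_LEVELS)
    if (length(bad_tp)) {
      bp_stop(
        paste0("unknown timepoint label(s): ", paste(bad_tp, collapse = ", ")),
        "invalid_timepoint"
      )
    }
  }
  if (is.null(colnames(values))) {
    if (nrow(samples) != ncol(values)) {
      bp_stop("manifest rows must match expression columns", "invalid_manifest")
    }
    colnames(values) <- samples$sample_id
  }
  unmatched <- setdiff(colnames(values), samples$sample_id)
  if (length(unmatched)) {
    bp_stop(
      paste0(
        "sample(s) in matrix but not in manifest: ",
        paste(unmatched, collapse = ", ")
      ),
      "unknown_sample"
    )
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(
    "expr_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples;",
    "groups:", paste(unique(x$samples$group), collapse = ", "), "\n"
  )
  invisible(x)
}

#' Gene ids of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(m) rownames(m$values)

#' Construct a frozen normalization/barcode reference
#'
#' The frozen reference plays the role of the parameter vectors a
#' frozen-normalization method carries per platform: a sorted vector of
#' reference intensities that every sample is quantile-mapped onto, plus a
#' per-gene location/scale of the unexpressed-intensity distribution that
#' drives the expressed/unexpressed barcode call.
#'
#' @param gene_ids Character vector of unique gene ids.
#' @param mu_unexpr,sigma_unexpr Numeric vectors (length 1 or
#'   `length(gene_ids)`): location and scale (log2 units) of each gene's
#'   unexpressed-intensity distribution; `sigma_unexpr` must be positive.
#' @param z_cut Scalar expression cutoff in sd units above `mu_unexpr`
#'   (default 5, a conservative call threshold; see the package vignette).
#' @param ref_quantiles Non-decreasing numeric vector of reference
#'   intensities the quantile mapping targets.
#'
#' @return An object of class `frozen_reference`.
#' @export
frozen_reference <- function(gene_ids, mu_unexpr, sigma_unexpr, z_cut = 5,
                             ref_quantiles) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) bp_stop("reference gene ids must be unique", "invalid_reference")
  n <- length(gene_ids)
  mu_unexpr <- rep_len(as.numeric(mu_unexpr), n)
  sigma_unexpr <- rep_len(as.numeric(sigma_unexpr), n)
  if (any(!is.finite(sigma_unexpr)) || any(sigma_unexpr <= 0)) {
    bp_stop("sigma_unexpr must be positive and finite for every gene", "invalid_reference")
  }
  if (!is.numeric(z_cut) || length(z_cut) != 1 || !is.finite(z_cut)) {
    bp_stop("z_cut must be a finite scalar", "invalid_reference")
  }
  ref_quantiles <- as.numeric(ref_quantiles)
  if (is.unsorted(ref_quantiles)) {
    bp_stop("ref_quantiles must be non-decreasing", "invalid_reference")
  }
  names(mu_unexpr) <- names(sigma_unexpr) <- gene_ids
  structure(
    list(
      gene_ids = gene_ids, mu_unexpr = mu_unexpr,
      sigma_unexpr = sigma_unexpr, z_cut = z_cut,
      ref_quantiles = ref_quantiles
    ),
    class = "frozen_reference"
  )
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (unique names, non-empty
#'   sets). Members are deduplicated preserving order.
#' @param descriptions Optional character vector of free-text descriptions,
#'   one per set.
#' @return An object of class `gene_set_collection` (a named list with a
#'   `descriptions` attribute).
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) && is.null(names(sets))) {
    bp_stop("gene sets must be named", "invalid_gene_sets")
  }
  if (anyDuplicated(names(sets))) {
    bp_stop("gene set names must be unique", "invalid_gene_sets")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) {
    bp_stop("gene sets must be non-empty", "invalid_gene_sets")
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' Construct a weighted undirected gene network
#'
#' Edges are stored once in canonical orientation; duplicate edges (either
#' orientation) have their weights summed. Self-loops and non-positive
#' weights are rejected.
#'
#' @param edges Data frame with columns `from`, `to`, `weight`.
#' @return An object of class `weighted_network`: list with `nodes`
#'   (character) and `edges` (data frame).
#' @export
weighted_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to", "weight") %in% names(edges))) {
    bp_stop("edges need columns from, to, weight", "invalid_network")
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
    bp_stop("edge weights must be positive and finite", "invalid_network")
  }
  loops <- edges$from == edges$to
  if (any(loops)) {
    bp_stop(
      paste0("self-loop(s) not allowed: ", paste(unique(edges$from[loops]), collapse = ", ")),
      "invalid_network"
    )
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  w <- tapply(edges$weight, key, sum)
  ab <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  edges <- data.frame(
    from = ab[, 1], to = ab[, 2], weight = as.numeric(w),
    stringsAsFactors = FALSE
  )
  o <- order(edges$from, edges$to, method = "radix")
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$from, edges$to)), method = "radix")
  structure(list(nodes = nodes, edges = edges), class = "weighted_network")
}
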