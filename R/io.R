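# Readers/writers for the external formats the pipeline touches:
# TSV expression matrix + CSV manifest, GMT gene sets, 3-column edge lists.

#' Read a tab-delimited expression matrix with its sample manifest
#'
#' The matrix file is tab-separated with gene ids in the first column and a
#' header row of sample ids; lines starting with `#` are ignored. The
#' manifest is a CSV mapping every sample id to its dataset, group and
#' optional patient/timepoint metadata. Samples present in the matrix but
#' absent from the manifest are a hard error (named in the message).
#'
#' @param path Path to the TSV expression matrix.
#' @param manifest Path to the CSV sample manifest (columns `sample_id`,
#'   `dataset_id`, `group`, optionally `patient_id`, `timepoint`).
#' @param collapse If `TRUE`, duplicated gene ids are collapsed by keeping
#'   the row with the highest mean intensity (the package's probe-to-gene
#'   collapse rule); if `FALSE` (default) duplicates are an error.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, manifest, collapse = FALSE) {
  tab <- utils::read.delim(path,
    check.names = FALSE, stringsAsFactors = FALSE,
    comment.char = "#"
  )
  if (ncol(tab) < 2) bp_stop("expression file needs a gene column plus samples", "invalid_matrix")
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- NULL
  if (anyDuplicated(ids)) {
    if (collapse) {
      vals <- collapse_duplicate_genes(vals, ids)
    } else {
      dup <- unique(ids[duplicated(ids)])
      bp_stop(
        paste0("duplicated gene id(s) in ", path, ": ", paste(dup, collapse = ", ")),
        "duplicate_gene"
      )
    }
  } else {
    rownames(vals) <- ids
  }
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  expression_matrix(vals, man)
}

#' Collapse duplicated gene rows, keeping the highest-mean row
#'
#' Deterministic probe-to-gene collapse: among rows sharing a gene id, the
#' row with the highest mean intensity is retained.
#'
#' @param values Numeric matrix.
#' @param ids Gene id per row (defaults to rownames).
#' @return Matrix with unique rownames, original relative row order kept.
#' @export
collapse_duplicate_genes <- function(values, ids = rownames(values)) {
  ids <- as.character(ids)
  means <- rowMeans(values)
  # stable: first occurrence wins ties
  keep <- !logical(nrow(values))
  best <- tapply(seq_len(nrow(values)), ids, function(i) i[which.max(means[i])])
  keep <- sort(unname(unlist(best)))
  out <- values[keep, , drop = FALSE]
  rownames(out) <- ids[keep]
  out
}

#' Write an expression matrix (and optionally its manifest) to disk
#'
#' Values are written at full double precision (`%.17g`) so that a
#' write/read cycle round-trips exactly.
#'
#' @param m An `expr_matrix`.
#' @param path Output TSV path.
#' @param manifest Optional CSV path for the sample manifest.
#' @param meta Character vector of `#`-prefixed header lines to prepend.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, manifest = NULL, meta = character()) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  writeLines(paste(c("gene_id", colnames(m$values)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m$values)), function(i) {
    paste(c(rownames(m$values)[i], sprintf("%.17g", m$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  if (!is.null(manifest)) {
    utils::write.csv(m$samples, manifest, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Duplicate members within a line are deduplicated; lines
#' with fewer than three fields are an error reporting the line number.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()]; empty file gives an empty collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection(stats::setNames(list(), character())))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    bp_stop(
      paste0("GMT line ", short[1], " has fewer than 3 fields"),
      "invalid_gmt"
    )
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  gene_set_collection(sets, vapply(parts, `[[`, character(1), 2))
}

#' Read a weighted edge list as an undirected network
#'
#' Three whitespace/tab-separated columns: nodeA, nodeB, weight. Duplicate
#' edges in either orientation have their weights summed; self-loops and
#' non-positive weights are errors.
#'
#' @param path Path to the edge-list file.
#' @return A [weighted_network()].
#' @export
read_network <- function(path) {
  tab <- utils::read.table(path,
    header = FALSE, stringsAsFactors = FALSE,
    comment.char = "#", col.names = c("from", "to", "weight")
  )
  weighted_network(tab)
}

#' Write a gene list, one id per line
#' @param genes Character vector.
#' @param path Output path.
#' @param meta `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path, meta = character()) {
  writeLines(c(if (length(meta)) paste0("# ", meta), genes), path)
  invisible(path)
}

#' Path to a packaged example/fixture file
#' @param file File name under the package's `extdata/`; with no argument,
#'   lists the available files.
#' @return Full path (or a character vector of file names).
#' @export
beprog_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "beprog")))
  }
  p <- system.file("extdata", file, package = "beprog")
  if (!nzchar(p)) bp_stop(paste0("no packaged file called ", file), "missing_file")
  p
}
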