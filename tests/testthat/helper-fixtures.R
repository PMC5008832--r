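# Shared fixture builders and independent oracles used across test files.

# Quick expression_matrix from a values matrix and group labels.
make_expr <- function(values, groups, dataset_id = "d1") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("%s_s%02d", dataset_id, seq_len(ncol(values)))
  }
  expression_matrix(values, data.frame(
    sample_id = colnames(values),
    dataset_id = dataset_id,
    group = groups,
    stringsAsFactors = FALSE
  ))
}

# Write a small expression TSV + manifest CSV; returns the two paths.
write_expr_fixture <- function(values, groups,
                               dir = withr::local_tempdir(.local_envir = parent.frame()),
                               gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(values)))
  sample_ids <- sprintf("s%02d", seq_len(ncol(values)))
  mat_path <- file.path(dir, "expr.tsv")
  man_path <- file.path(dir, "manifest.csv")
  lines <- c(
    paste(c("gene_id", sample_ids), collapse = "\t"),
    vapply(seq_len(nrow(values)), function(i) {
      paste(c(gene_ids[i], sprintf("%.17g", values[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, mat_path)
  utils::write.csv(
    data.frame(sample_id = sample_ids, dataset_id = "d1", group = groups),
    man_path,
    row.names = FALSE, quote = FALSE
  )
  list(matrix = mat_path, manifest = man_path)
}

# Exact hypergeometric upper-tail oracle by full enumeration: distribution
# of |query ∩ set| over all size-n subsets of a size-N universe.
enum_hyper_tail <- function(N, K, n) {
  subsets <- utils::combn(N, n)
  overlaps <- apply(subsets, 2, function(s) sum(s <= K))
  function(k) mean(overlaps >= k)
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all assignments of
# ranks to the first sample, mirroring the exact test's two-sided rule.
enum_wilcox_p <- function(x, y) {
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  # no ties by construction: every size-n set of ranks is equally likely
  all_w <- colSums(utils::combn(n + m, n)) - n * (n + 1) / 2
  center <- n * m / 2
  p <- if (w_obs > center) 2 * mean(all_w >= w_obs) else 2 * mean(all_w <= w_obs)
  min(1, p)
}

# Closed-form Pearson X2 (no correction) from expected counts.
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Random Erdos-Renyi weighted network over the given node names.
random_network <- function(nodes, p_edge = 0.05, seed = 1) {
  set.seed(seed)
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  weighted_network(data.frame(
    from = pairs[1, keep], to = pairs[2, keep],
    weight = stats::runif(sum(keep), 0.5, 1.5)
  ))
}
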