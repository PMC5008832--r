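# Over-representation analysis and guilt-by-association network
# prioritization of the candidate genes.

#' Hypergeometric gene-set over-representation test
#'
#' For each set, the one-sided p-value P(X >= k) of the observed overlap k
#' under the hypergeometric(N, K, n) null is computed by exact summation
#' of the density over the upper tail; p-values are Benjamini-Hochberg
#' adjusted across sets and results are sorted by p. Query genes outside
#' the universe are dropped with a warning; each set is intersected with
#' the universe.
#'
#' @param query Character vector of candidate gene ids.
#' @param sets A [gene_set_collection()].
#' @param universe Character vector: all genes the query was drawn from
#'   (typically the pooled matrix's genes).
#' @return Data frame of class `enrichment_result`: `set_name`, `k`
#'   (overlap), `K` (set size in universe), `n` (query size), `N`
#'   (universe size), `p`, `p_adj`.
#' @export
hypergeom_enrich <- function(query, sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) bp_stop("empty universe", "empty_universe")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(
      length(outside), " query gene(s) outside the universe dropped: ",
      paste(utils::head(outside, 5), collapse = ", ")
    )
    query <- intersect(query, universe)
  }
  if (!length(query)) bp_stop("empty query after universe filtering", "empty_query")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    K <- length(s)
    k <- length(intersect(query, s))
    kk <- seq(k, min(n, K))
    p <- if (k == 0) 1 else min(1, sum(stats::dhyper(kk, K, N - K, n)))
    data.frame(
      set_name = nm, k = k, K = K, n = n, N = N, p = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_name, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotonicity enforced), input
#' order preserved. Values outside `[0, 1]` are an error.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    bp_stop("p-values must lie in [0, 1]", "invalid_pvalues")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Dense symmetric-normalized adjacency and seed indicator for a network.
network_operator <- function(net, seeds) {
  nodes <- net$nodes
  seeds <- intersect(seeds, nodes)
  if (!length(seeds)) bp_stop("no seed gene present in the network", "no_seeds")
  V <- length(nodes)
  W <- matrix(0, V, V, dimnames = list(nodes, nodes))
  ij <- cbind(match(net$edges$from, nodes), match(net$edges$to, nodes))
  W[ij] <- net$edges$weight
  W[ij[, 2:1, drop = FALSE]] <- net$edges$weight
  d <- rowSums(W)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  S <- W * (dinv %o% dinv)
  y <- as.numeric(nodes %in% seeds)
  list(nodes = nodes, S = S, d = d, y = y, seeds = seeds)
}

#' Guilt-by-association label propagation on a weighted network
#'
#' Scores solve the regularized propagation system
#' `(I + lambda * L) f = y`, where `L` is the symmetric-normalized graph
#' Laplacian and `y` indicates the seed genes. Scores are non-negative,
#' zero on components containing no seed, and larger for nodes closer (in
#' the diffusion sense) to the seed set.
#'
#' @param net A [weighted_network()].
#' @param seeds Character vector of seed gene ids (at least one must be a
#'   network node).
#' @param lambda Regularization strength, > 0 (default 1): larger values
#'   spread more score mass onto neighbors.
#' @return Data frame sorted by descending score (ties by gene id):
#'   `gene_id`, `score`, `is_seed`.
#' @export
propagate_labels <- function(net, seeds, lambda = 1) {
  if (!is.numeric(lambda) || lambda <= 0) bp_stop("lambda must be > 0", "invalid_config")
  op <- network_operator(net, seeds)
  V <- length(op$nodes)
  # L = I - S on non-isolated nodes; isolated nodes have zero Laplacian row
  L <- diag(as.numeric(op$d > 0), V) - op$S
  f <- solve(diag(V) + lambda * L, op$y)
  f <- pmax(f, 0) # clip tiny negative round-off
  out <- data.frame(
    gene_id = op$nodes, score = f,
    is_seed = op$nodes %in% op$seeds,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score, out$gene_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand a seed gene set with its top network neighbors
#'
#' Returns the seeds plus the `k` highest-scoring non-seed nodes under
#' [propagate_labels()] (ties broken by gene id); nodes with zero score
#' (unreachable from any seed) are never added.
#'
#' @param net A [weighted_network()].
#' @param seeds Character vector of seed gene ids.
#' @param k Number of neighbors to add (default 100).
#' @param lambda Passed to [propagate_labels()].
#' @return Sorted character vector of gene ids.
#' @export
expand_neighbors <- function(net, seeds, k = 100, lambda = 1) {
  if (k < 0) bp_stop("k must be >= 0", "invalid_config")
  scores <- propagate_labels(net, seeds, lambda = lambda)
  nonseed <- scores[!scores$is_seed & scores$score > 0, , drop = FALSE]
  add <- utils::head(nonseed$gene_id, k)
  sort(union(seeds, add), method = "radix")
}
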