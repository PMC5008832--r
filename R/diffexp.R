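# Empirical-Bayes moderated two-group differential expression.
#
# Per gene the pooled residual variance s_g^2 (d_g = n_a + n_b - 2 df) is
# shrunk toward a prior variance s0^2 with prior df d0, both estimated by
# matching moments of log s_g^2 to its theoretical scaled chi-square form:
#   e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2),  E[e_g] = log sigma_g^2,
#   Var[e_g] = trigamma(d0/2) + trigamma(d_g/2) under the hierarchical
# model, so d0 solves trigamma(d0/2) = var(e) - trigamma(d_g/2). The
# moderated t uses the posterior variance and d0 + d_g degrees of freedom,
# and the selection score is the log posterior odds of differential
# expression (the B-statistic / "Lods"), whose threshold is calibrated on
# a negative-control contrast (see calibrate_null).

# Inverse of the trigamma function by Newton iteration on 1/trigamma
# (monotone, well-conditioned on the scales arising here).
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

# Prior variance of the (scaled) effect for the B-statistic, estimated by
# matching upper quantiles of |t| against the assumed mixture with prior
# proportion p_de of differential genes. All genes share vu and df here
# (balanced two-group design).
estimate_v0 <- function(tstat, vu, df, p_de) {
  G <- length(tstat)
  ntarget <- ceiling(p_de / 2 * G)
  if (ntarget < 1) return(0)
  p <- max(ntarget / G, p_de)
  ta <- sort(abs(tstat), decreasing = TRUE)[seq_len(ntarget)]
  p0 <- 2 * stats::pt(-ta, df = df)
  ptarget <- ((seq_len(ntarget) - 0.5) / G - (1 - p) * p0) / p
  v0 <- numeric(ntarget)
  pos <- ptarget > p0
  if (any(pos)) {
    qtarget <- stats::qt(ptarget[pos] / 2, df = df, lower.tail = FALSE)
    v0[pos] <- vu * ((ta[pos] / qtarget)^2 - 1)
  }
  mean(pmax(v0, 0))
}

LODS_FLOOR <- -1e6

#' Moderated two-group differential expression with log-odds scoring
#'
#' Fits the empirical-Bayes moderated t for the contrast
#' `group_a - group_b` on a pooled, normalized expression matrix and
#' scores each gene with the log posterior odds of differential
#' expression (`lods`, the B-statistic), assuming a prior proportion
#' `p_de` of differential genes. Two-sided p-values come from the t
#' distribution on `d0 + d_g` degrees of freedom and are
#' Benjamini-Hochberg adjusted.
#'
#' Zero-variance genes are floored at machine epsilon and flagged in the
#' `zero_var` column, never dropped. When the between-gene variability of
#' `log s_g^2` does not exceed its sampling variability the prior df `d0`
#' is infinite and the common variance is estimated as `mean(s_g^2)`, so
#' with identical gene variances the moderated t equals the ordinary
#' pooled two-sample t exactly. `lods` values are floored at `-1e6`.
#'
#' @param m An [expression_matrix()] containing both groups.
#' @param group_a,group_b Group labels (each needs >= 2 samples);
#'   `log2fc` is `mean(group_a) - mean(group_b)`.
#' @param p_de Assumed prior proportion of differentially expressed genes,
#'   in (0,1); shifts `lods` by a constant in `logit(p_de)`. Default 0.01.
#' @return List with `result` (data frame of class `de_result`: `gene_id`,
#'   `mean_expr`, `log2fc`, `t_mod`, `df_total`, `p`, `p_adj`, `lods`,
#'   `zero_var`) and `params` (list `d0`, `s0_sq`, `v0`, `p_de`).
#' @export
fit_moderated <- function(m, group_a = "P-BE", group_b = "nonP-BE", p_de = 0.01) {
  if (p_de <= 0 || p_de >= 1) bp_stop("p_de must be in (0,1)", "invalid_config")
  ia <- which(m$samples$group == group_a)
  ib <- which(m$samples$group == group_b)
  na <- length(ia)
  nb <- length(ib)
  if (na < 2 || nb < 2) {
    bp_stop(
      sprintf("each group needs >= 2 samples (got %d in %s, %d in %s)",
        na, group_a, nb, group_b),
      "group_too_small"
    )
  }
  xa <- m$values[, ia, drop = FALSE]
  xb <- m$values[, ib, drop = FALSE]
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  lfc <- ma - mb
  mean_expr <- rowMeans(m$values[, c(ia, ib), drop = FALSE])
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  dg <- na + nb - 2
  s2 <- ((na - 1) * va + (nb - 1) * vb) / dg
  zero_var <- s2 <= .Machine$double.eps
  if (all(zero_var)) bp_stop("all genes have zero residual variance", "degenerate_data")
  s2 <- pmax(s2, .Machine$double.eps)

  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  evar <- stats::var(e) - trigamma(dg / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no evidence of variance heterogeneity beyond sampling noise: all
    # genes share one variance, estimated without the log-scale bias
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  s2_post <- if (is.finite(d0)) (d0 * s0_sq + dg * s2) / (d0 + dg) else rep(s0_sq, length(s2))
  vu <- 1 / na + 1 / nb
  t_mod <- lfc / sqrt(s2_post * vu)
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p_adj <- stats::p.adjust(p, method = "BH")

  v0 <- estimate_v0(t_mod, vu, df_total, p_de)
  # strictly positive prior effect variance keeps lods strictly
  # increasing in |t_mod| even on pure-null data
  v0 <- max(v0, 1e-8 * vu)
  r <- (vu + v0) / vu
  t2 <- t_mod^2
  kernel <- if (is.finite(df_total)) {
    (1 + df_total) / 2 * log((t2 + df_total) / (t2 / r + df_total))
  } else {
    t2 * (1 - 1 / r) / 2
  }
  lods <- log(p_de / (1 - p_de)) - log(r) / 2 + kernel
  lods[!is.finite(lods) | lods < LODS_FLOOR] <- LODS_FLOOR

  result <- data.frame(
    gene_id = rownames(m$values),
    mean_expr = mean_expr, log2fc = lfc,
    t_mod = t_mod, df_total = df_total,
    p = p, p_adj = p_adj, lods = lods,
    zero_var = zero_var,
    stringsAsFactors = FALSE
  )
  rownames(result) <- NULL
  class(result) <- c("de_result", "data.frame")
  list(
    result = result,
    params = list(d0 = d0, s0_sq = s0_sq, v0 = v0, p_de = p_de)
  )
}

#' Select differential-expression candidates by log-odds and fold change
#'
#' Keeps genes with `lods >= lods_min` and `|log2fc| >= abs_log2fc_min`
#' (both inclusive; defaults 5 and 0.58, i.e. a 1.5-fold change), ordered
#' by descending `lods` with ties broken by gene id.
#'
#' @param de A `de_result` data frame (from [fit_moderated()]), or the
#'   list returned by it.
#' @param lods_min Minimum log posterior odds (default 5, the
#'   negative-control-calibrated threshold; see [calibrate_null()]).
#' @param abs_log2fc_min Minimum absolute log2 ratio (default 0.58).
#' @param up_only If `TRUE`, keep only up-regulated genes
#'   (`log2fc >= abs_log2fc_min`).
#' @return A data frame of class `candidate_set` with columns `gene_id`,
#'   `lods`, `log2fc`, `provenance`.
#' @export
select_candidates <- function(de, lods_min = 5, abs_log2fc_min = 0.58,
                              up_only = FALSE) {
  if (is.list(de) && !is.data.frame(de) && !is.null(de$result)) de <- de$result
  if (!all(is.finite(c(lods_min, abs_log2fc_min)))) {
    bp_stop("selection thresholds must be finite", "invalid_config")
  }
  lfc_ok <- if (up_only) de$log2fc >= abs_log2fc_min else abs(de$log2fc) >= abs_log2fc_min
  keep <- de$lods >= lods_min & lfc_ok
  out <- de[keep, c("gene_id", "lods", "log2fc"), drop = FALSE]
  out <- out[order(-out$lods, out$gene_id, method = "radix"), , drop = FALSE]
  out$provenance <- rep("DE", nrow(out))
  rownames(out) <- NULL
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Negative-control calibration of the log-odds threshold
#'
#' Runs the moderated fit between two matrices that should not differ
#' biologically (e.g. tumor samples of the same type from two different
#' datasets, or two random halves of one dataset), treating
#' dataset-of-origin as the two groups. A threshold passes calibration
#' when no gene reaches it on this contrast — the rationale for the
#' conservative default of 5: any inter-dataset variability surviving
#' normalization must stay below the selection threshold.
#'
#' Internally the two origins are relabeled to the two BE group labels so
#' the standard two-group fit applies; this is a pure relabeling.
#'
#' @param m_a,m_b Two [expression_matrix()] objects over the same genes,
#'   normalized against the same reference.
#' @param lods_min Threshold under calibration (default 5).
#' @param p_de As in [fit_moderated()].
#' @return List with `n_above` (genes at or above `lods_min`), `max_lods`,
#'   and `de` (the full `de_result`).
#' @export
calibrate_null <- function(m_a, m_b, lods_min = 5, p_de = 0.01) {
  if (!identical(sort(gene_ids(m_a)), sort(gene_ids(m_b)))) {
    bp_stop("calibration inputs must cover the same gene set", "gene_mismatch")
  }
  g <- sort(gene_ids(m_a), method = "radix")
  vals <- cbind(m_a$values[g, , drop = FALSE], m_b$values[g, , drop = FALSE])
  samples <- data.frame(
    sample_id = colnames(vals),
    dataset_id = rep(c("origin_a", "origin_b"), c(ncol(m_a$values), ncol(m_b$values))),
    group = rep(c("P-BE", "nonP-BE"), c(ncol(m_a$values), ncol(m_b$values))),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(samples$sample_id)) {
    samples$sample_id <- paste(samples$dataset_id, samples$sample_id, sep = ".")
    colnames(vals) <- samples$sample_id
  }
  fit <- fit_moderated(expression_matrix(vals, samples),
    group_a = "P-BE", group_b = "nonP-BE", p_de = p_de
  )
  list(
    n_above = sum(fit$result$lods >= lods_min),
    max_lods = max(fit$result$lods),
    de = fit$result
  )
}
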