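# Moderated t / log-odds machinery, candidate selection, and the
# negative-control calibration.

# Fixture where every gene has exactly the same pooled residual variance.
equal_var_fixture <- function(n_genes = 100, seed = 10) {
  set.seed(seed)
  delta <- c(-1.5, -0.5, 0.5, 1.5) # within-group pattern, var = 5/3 everywhere
  vals <- t(vapply(seq_len(n_genes), function(g) {
    c(rnorm(1, 8) + delta, rnorm(1, 8) + delta)
  }, numeric(8)))
  rownames(vals) <- sprintf("g%03d", seq_len(n_genes))
  make_expr(vals, groups = rep(c("P-BE", "nonP-BE"), each = 4))
}

ordinary_t <- function(m, s2 = NULL) {
  ia <- m$samples$group == "P-BE"
  ib <- m$samples$group == "nonP-BE"
  xa <- m$values[, ia]; xb <- m$values[, ib]
  na <- sum(ia); nb <- sum(ib)
  if (is.null(s2)) {
    s2 <- ((na - 1) * apply(xa, 1, var) + (nb - 1) * apply(xb, 1, var)) / (na + nb - 2)
  }
  (rowMeans(xa) - rowMeans(xb)) / sqrt(s2 * (1 / na + 1 / nb))
}

test_that("with identical gene variances the moderated t collapses to the ordinary t", {
  m <- equal_var_fixture()
  fit <- fit_moderated(m)
  expect_equal(fit$result$t_mod, unname(ordinary_t(m)), tolerance = 1e-9)
  expect_false(is.finite(fit$params$d0))
  expect_equal(fit$params$s0_sq, 5 / 3, tolerance = 1e-9)
})

test_that("a gene with identical group means has zero fold change and statistic", {
  m <- equal_var_fixture(n_genes = 20)
  m$values[3, 5:8] <- m$values[3, 1:4] # same values in both groups
  fit <- fit_moderated(m)
  expect_equal(fit$result$log2fc[3], 0)
  expect_equal(fit$result$t_mod[3], 0)
  expect_equal(fit$result$p[3], 1)
})

test_that("lods is strictly increasing in |t_mod| at fixed df", {
  set.seed(21)
  vals <- matrix(rnorm(500 * 10, 8, 1), 500)
  vals[1:10, 1:5] <- vals[1:10, 1:5] + 3 # some signal so v0 > 0
  m <- make_expr(vals, rep(c("P-BE", "nonP-BE"), each = 5))
  fit <- fit_moderated(m)
  o <- order(abs(fit$result$t_mod))
  expect_true(all(diff(fit$result$lods[o]) > 0))
  expect_true(all(is.finite(fit$result$lods)))
})

test_that("moderated t lies between the per-gene and common-variance analyses", {
  set.seed(33)
  n_genes <- 50
  sigma2 <- exp(rnorm(n_genes, 0, 1.5))
  vals <- t(vapply(seq_len(n_genes), function(g) {
    rnorm(6, 8, sqrt(sigma2[g]))
  }, numeric(6)))
  rownames(vals) <- sprintf("g%03d", seq_len(n_genes))
  m <- make_expr(vals, rep(c("P-BE", "nonP-BE"), each = 3))
  fit <- fit_moderated(m)
  t_gene <- abs(unname(ordinary_t(m)))
  t_common <- abs(unname(ordinary_t(m, s2 = fit$params$s0_sq)))
  t_mod <- abs(fit$result$t_mod)
  lo <- pmin(t_gene, t_common) - 1e-9
  hi <- pmax(t_gene, t_common) + 1e-9
  expect_true(all(t_mod >= lo & t_mod <= hi))
})

test_that("the moderated fit agrees with an independent moderated-statistic implementation", {
  skip_if_not_installed("limma")
  # heteroscedastic genes give a finite prior df, exercising the shrinkage
  set.seed(45)
  sigma2 <- exp(rnorm(300, 0, 1))
  vals <- matrix(rnorm(300 * 12, 8, sqrt(sigma2)), 300)
  vals[1:15, 1:6] <- vals[1:15, 1:6] + 2
  rownames(vals) <- sprintf("g%03d", 1:300)
  m <- make_expr(vals, rep(c("P-BE", "nonP-BE"), each = 6))
  fit <- fit_moderated(m)

  design <- cbind(1, rep(c(1, 0), each = 6))
  lfit <- limma::eBayes(limma::lmFit(vals, design), proportion = 0.01)
  expect_true(is.finite(fit$params$d0))
  expect_equal(fit$params$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(fit$params$s0_sq, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(fit$result$t_mod, unname(lfit$t[, 2]), tolerance = 1e-8)
  expect_equal(fit$result$p, unname(lfit$p.value[, 2]), tolerance = 1e-8)
  # the prior effect-variance estimate differs in implementation detail,
  # shifting lods by a small amount
  expect_lt(max(abs(fit$result$lods - lfit$lods[, 2])), 0.05)
})

test_that("candidate selection applies inclusive log-odds and fold-change gates", {
  de <- data.frame(
    gene_id = c("TWIST1", "MAPKAPK2", "highLodsLowFC", "boundary"),
    log2fc = c(1.1, 0.1, 0.5, 0.58),
    lods = c(5.84, -2.7, 10, 5.0),
    stringsAsFactors = FALSE
  )
  class(de) <- c("de_result", "data.frame")
  sel <- select_candidates(de)
  expect_identical(sel$gene_id, c("TWIST1", "boundary"))
  expect_true("boundary" %in% sel$gene_id) # lods = 5.0, |lfc| = 0.58: inclusive
  expect_false("MAPKAPK2" %in% sel$gene_id)
  expect_false("highLodsLowFC" %in% sel$gene_id) # fold-change gate

  # ordering: descending lods, ties by gene id; down-regulation counts too
  de2 <- data.frame(
    gene_id = c("b", "a", "c"), log2fc = c(-1, 2, 1), lods = c(7, 7, 6)
  )
  sel2 <- select_candidates(de2)
  expect_identical(sel2$gene_id, c("a", "b", "c"))
  expect_identical(select_candidates(de2, up_only = TRUE)$gene_id, c("a", "c"))
})

test_that("zero-variance genes are floored and flagged, never dropped", {
  m <- equal_var_fixture(n_genes = 30)
  m$values[7, ] <- 5 # constant gene
  fit <- fit_moderated(m)
  expect_equal(nrow(fit$result), 30)
  expect_true(fit$result$zero_var[7])
  expect_equal(sum(fit$result$zero_var), 1)

  flat <- make_expr(matrix(3, 4, 8), rep(c("P-BE", "nonP-BE"), each = 4))
  expect_error(fit_moderated(flat), class = "beprog_degenerate_data")
  expect_error(
    fit_moderated(equal_var_fixture(10), group_a = "EA"),
    class = "beprog_group_too_small"
  )
})

test_that("BH adjustment follows the step-up rule and its invariants", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "beprog_invalid_pvalues")

  set.seed(9)
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj <= 1))
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= 0))
})

test_that("null splits calibrate the threshold; unnormalized shifts fail it", {
  cfg <- sim_config(n_genes = 1000,
    datasets = list(list(dataset_id = "ea", group = "EA", n_samples = 16)),
    batch_shift_sd = 0, seed = 17)
  co <- generate_meta_cohort(cfg)
  m <- normalize_frozen(co$matrices[[1]], co$reference)
  odd <- seq(1, 15, 2); even <- seq(2, 16, 2)
  ma <- expression_matrix(m$values[, odd], m$samples[odd, ])
  mb <- expression_matrix(m$values[, even], m$samples[even, ])
  cal <- calibrate_null(ma, mb, lods_min = 5)
  expect_equal(cal$n_above, 0)
  expect_lt(cal$max_lods, 5)

  # positive control: a +3 global shift on one half, no normalization
  mb_shift <- expression_matrix(mb$values + 3, mb$samples)
  cal2 <- calibrate_null(ma, mb_shift, lods_min = 5)
  expect_gt(cal2$n_above, 0)
})

test_that("type-I error on null cohorts stays near nominal", {
  fracs <- vapply(c(101, 102), function(s) {
    co <- generate_meta_cohort(sim_config(n_genes = 2000, batch_shift_sd = 0, seed = s))
    pooled <- pool_datasets(lapply(co$matrices, normalize_frozen, ref = co$reference))
    mean(fit_moderated(pooled)$result$p < 0.05)
  }, numeric(1))
  expect_true(all(fracs >= 0.03 & fracs <= 0.07))
})
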