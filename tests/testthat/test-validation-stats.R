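# Validation-arm statistics: ddCt, standard curves, rank-sum and
# chi-squared tests.

make_ct <- function(rows, calibrator = "GAPDH") {
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      patient_id = r$patient, group = r$group, timepoint = r$tp %||% "t0",
      gene_id = r$gene, replicate = seq_along(r$ct), ct = r$ct,
      stringsAsFactors = FALSE
    )
  }))
  attr(out, "calibrator_gene") <- calibrator
  class(out) <- c("ct_table", "data.frame")
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("ddCt arithmetic matches the closed forms", {
  # all Ct equal everywhere: every fold change is 1
  ct <- make_ct(list(
    list(patient = "p1", group = "P-BE", gene = "CYR61", ct = c(25, 25)),
    list(patient = "p1", group = "P-BE", gene = "GAPDH", ct = c(25, 25)),
    list(patient = "c1", group = "nonP-BE", gene = "CYR61", ct = c(25, 25)),
    list(patient = "c1", group = "nonP-BE", gene = "GAPDH", ct = c(25, 25))
  ))
  fc <- delta_delta_ct(ct, "CYR61")
  expect_equal(fc$fold_change, c(1, 1))

  # one cycle lower target in the case, calibrator flat: fold change 2
  ct2 <- make_ct(list(
    list(patient = "p1", group = "P-BE", gene = "CYR61", ct = c(24, 24)),
    list(patient = "p1", group = "P-BE", gene = "GAPDH", ct = c(20, 20)),
    list(patient = "c1", group = "nonP-BE", gene = "CYR61", ct = c(25, 25)),
    list(patient = "c1", group = "nonP-BE", gene = "GAPDH", ct = c(20, 20))
  ))
  fc2 <- delta_delta_ct(ct2, "CYR61")
  expect_equal(fc2$fold_change[fc2$group == "P-BE"], 2)

  # case (24, 20) against control mean (26, 20): ddCt = -2, fold 4
  ct3 <- make_ct(list(
    list(patient = "p1", group = "P-BE", gene = "CYR61", ct = c(24, 24)),
    list(patient = "p1", group = "P-BE", gene = "GAPDH", ct = c(20, 20)),
    list(patient = "c1", group = "nonP-BE", gene = "CYR61", ct = c(27, 27)),
    list(patient = "c1", group = "nonP-BE", gene = "GAPDH", ct = c(20, 20)),
    list(patient = "c2", group = "nonP-BE", gene = "CYR61", ct = c(25, 25)),
    list(patient = "c2", group = "nonP-BE", gene = "GAPDH", ct = c(20, 20))
  ))
  fc3 <- delta_delta_ct(ct3, "CYR61")
  p1 <- fc3[fc3$patient_id == "p1", ]
  expect_equal(p1$delta_delta_ct, -2)
  expect_equal(p1$fold_change, 4)
})

test_that("duplicates are averaged before dCt and input shifts cancel", {
  # asymmetric duplicates: mean Ct is what matters
  ct <- make_ct(list(
    list(patient = "p1", group = "P-BE", gene = "CYR61", ct = c(23, 25)), # mean 24
    list(patient = "p1", group = "P-BE", gene = "GAPDH", ct = c(19, 21)), # mean 20
    list(patient = "c1", group = "nonP-BE", gene = "CYR61", ct = c(25, 25)),
    list(patient = "c1", group = "nonP-BE", gene = "GAPDH", ct = c(20, 20))
  ))
  fc <- delta_delta_ct(ct, "CYR61")
  expect_equal(fc$fold_change[fc$group == "P-BE"], 2)

  # adding a constant to one patient's target AND calibrator changes nothing
  ct_shift <- ct
  sel <- ct_shift$patient_id == "p1"
  ct_shift$ct[sel] <- ct_shift$ct[sel] + 3.7
  expect_equal(
    delta_delta_ct(ct_shift, "CYR61")$fold_change,
    fc$fold_change
  )
})

test_that("a missing calibrator measurement is an error naming the patient", {
  ct <- make_ct(list(
    list(patient = "p9", group = "P-BE", gene = "CYR61", ct = c(24, 24)),
    list(patient = "c1", group = "nonP-BE", gene = "CYR61", ct = c(25, 25)),
    list(patient = "c1", group = "nonP-BE", gene = "GAPDH", ct = c(20, 20))
  ))
  expect_error(delta_delta_ct(ct, "CYR61"), "p9",
    class = "beprog_missing_calibrator")
})

test_that("standard curves recover slope, efficiency and fit quality", {
  ng <- qpcr_dilution_series()
  expect_length(ng, 7)
  # perfect doubling chemistry: Ct drops 1/log10(2) per 10-fold input
  ct <- 30 - log10(ng) / log10(2)
  sc <- fit_standard_curve(ng, ct)
  expect_equal(sc$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(sc$efficiency, 1, tolerance = 1e-6)
  expect_equal(sc$r_squared, 1, tolerance = 1e-9)

  # closed-form efficiency for a slope of -3.6
  ct36 <- 30 + -3.6 * log10(ng)
  sc36 <- fit_standard_curve(ng, ct36)
  expect_equal(sc36$efficiency, 10^(1 / 3.6) - 1, tolerance = 1e-9)

  expect_error(fit_standard_curve(c(1, 0, 10), c(1, 2, 3)),
    class = "beprog_invalid_input")
  expect_error(fit_standard_curve(c(1, 1, 1), c(1, 2, 3)),
    class = "beprog_invalid_input")
})

test_that("rank-sum test is exact for small untied samples", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_true(res$exact)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)

  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  expect_error(wilcoxon_rank_sum(numeric(), 1:3), class = "beprog_empty_sample")
})

test_that("exact rank-sum p matches permutation enumeration for n + m <= 10", {
  set.seed(12)
  for (i in 1:8) {
    n <- sample(2:5, 1)
    m <- sample(2:5, 1)
    repeat {
      x <- round(rnorm(n), 3)
      y <- round(rnorm(m, 0.5), 3)
      if (!anyDuplicated(c(x, y))) break
    }
    res <- wilcoxon_rank_sum(x, y)
    expect_true(res$exact)
    expect_equal(res$p, enum_wilcox_p(x, y), tolerance = 1e-12)
  }
})

test_that("exact and approximate rank-sum p agree closely at n = m = 10", {
  set.seed(13)
  for (i in 1:5) {
    x <- rnorm(10)
    y <- rnorm(10, 0.8)
    p_exact <- wilcoxon_rank_sum(x, y)$p
    p_approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    )
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("chi-squared matches its closed 2x2 forms", {
  prop <- matrix(c(5, 5, 5, 5), 2)
  res <- chi_squared(prop)
  expect_equal(res$X2, 0)
  expect_equal(res$p, 1)

  tab <- matrix(c(8, 2, 2, 8), 2)
  # N (ad - bc)^2 / (r1 r2 c1 c2) = 20 * 60^2 / 10^4 = 7.2
  expect_equal(chi_squared(tab, correction = FALSE)$X2, 7.2, tolerance = 1e-12)
  # Yates: N (|ad - bc| - N/2)^2 / (r1 r2 c1 c2) = 20 * 50^2 / 10^4 = 5.0
  expect_equal(chi_squared(tab, correction = TRUE)$X2, 5.0, tolerance = 1e-12)
  expect_equal(chi_squared(tab)$df, 1)

  expect_error(chi_squared(matrix(c(1, 2), 1)), class = "beprog_invalid_table")
  expect_error(chi_squared(matrix(c(0, 0, 1, 2), 2)), class = "beprog_degenerate_table")
})

test_that("uncorrected chi-squared matches brute-force expected counts", {
  set.seed(14)
  shapes <- list(c(2, 2), c(2, 3))
  for (shape in shapes) {
    for (i in 1:50) {
      repeat {
        tab <- matrix(sample(0:6, prod(shape), replace = TRUE), shape[1])
        if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
      }
      res <- chi_squared(tab, correction = FALSE)
      expect_equal(res$X2, oracle_chisq(tab), tolerance = 1e-10)
      expect_equal(res$df, (shape[1] - 1) * (shape[2] - 1))
    }
  }
})
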