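# Validation arm: relative qPCR quantification (2^-ddCt), standard-curve
# amplification efficiency, and the group-comparison tests used on the
# clinical cohort (Wilcoxon rank-sum on fold changes, Pearson chi-squared
# on ordinal IHC scores).

#' Relative quantification by the 2^-ddCt method
#'
#' Duplicate Ct measurements are averaged first; then per patient and
#' timepoint dCt = Ct(target) - Ct(calibrator), ddCt = dCt minus the mean
#' dCt of the control group at the same timepoint, and the fold change is
#' `2^-ddCt`. A missing calibrator measurement is an error naming the
#' patient.
#'
#' @param ct A `ct_table` data frame (columns `patient_id`, `group`,
#'   `timepoint`, `gene_id`, `replicate`, `ct`); see [generate_qpcr()].
#' @param target Target gene id.
#' @param control_group Group whose mean dCt is the baseline (default
#'   `"nonP-BE"`).
#' @param calibrator Calibrator gene id; defaults to the table's
#'   `calibrator_gene` attribute, else `"GAPDH"`.
#' @return Data frame: `patient_id`, `group`, `timepoint`, `delta_ct`,
#'   `delta_delta_ct`, `fold_change`.
#' @export
delta_delta_ct <- function(ct, target, control_group = "nonP-BE",
                           calibrator = NULL) {
  if (is.null(calibrator)) calibrator <- attr(ct, "calibrator_gene") %||% "GAPDH"
  if (any(ct$ct <= 0)) bp_stop("Ct values must be positive", "invalid_ct")
  ct <- ct[ct$gene_id %in% c(target, calibrator), , drop = FALSE]
  if (!nrow(ct)) bp_stop("no rows for target or calibrator gene", "invalid_ct")
  # mean quantification cycle of replicates, per patient/timepoint/gene
  agg <- stats::aggregate(
    ct ~ patient_id + group + timepoint + gene_id,
    data = ct, FUN = mean
  )
  tgt <- agg[agg$gene_id == target, , drop = FALSE]
  cal <- agg[agg$gene_id == calibrator, , drop = FALSE]
  key <- function(d) paste(d$patient_id, d$timepoint, sep = "\r")
  mi <- match(key(tgt), key(cal))
  if (anyNA(mi)) {
    miss <- tgt$patient_id[is.na(mi)]
    bp_stop(
      paste0("missing calibrator measurement for patient(s): ",
        paste(unique(miss), collapse = ", ")),
      "missing_calibrator"
    )
  }
  dct <- tgt$ct - cal$ct[mi]
  out <- data.frame(
    patient_id = tgt$patient_id, group = tgt$group,
    timepoint = tgt$timepoint, delta_ct = dct,
    stringsAsFactors = FALSE
  )
  base <- tapply(
    out$delta_ct[out$group == control_group],
    out$timepoint[out$group == control_group], mean
  )
  if (anyNA(match(unique(out$timepoint), names(base)))) {
    bp_stop(
      paste0("control group ", control_group, " missing at some timepoint"),
      "missing_control"
    )
  }
  out$delta_delta_ct <- as.numeric(out$delta_ct - base[out$timepoint])
  out$fold_change <- 2^(-out$delta_delta_ct)
  rownames(out) <- NULL
  out
}

#' Per-group fold-change summary
#'
#' Fold changes are ratios, so the geometric mean is the primary
#' aggregate; the arithmetic mean is also reported.
#'
#' @param fc Output of [delta_delta_ct()].
#' @return Data frame: `group`, `timepoint`, `n`, `geo_mean_fc`,
#'   `arith_mean_fc`.
#' @export
summarize_fold_changes <- function(fc) {
  sp <- split(fc, list(fc$group, fc$timepoint), drop = TRUE)
  rows <- lapply(sp, function(d) {
    data.frame(
      group = d$group[1], timepoint = d$timepoint[1], n = nrow(d),
      geo_mean_fc = 2^mean(log2(d$fold_change)),
      arith_mean_fc = mean(d$fold_change),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit a qPCR standard dilution curve
#'
#' Least-squares line of Ct on log10(input mass). The amplification
#' efficiency is `10^(-1/slope) - 1` (1.0 = perfect doubling per cycle,
#' i.e. slope -1/log10(2) ~ -3.32 cycles per 10-fold input). The default
#' dilution grid used by [qpcr_dilution_series()] spans 100 ng down to
#' 0.0001 ng in 10-fold steps.
#'
#' @param input_ng Positive input masses (ng); at least 3 distinct values.
#' @param ct Measured Ct values, same length.
#' @return An object of class `standard_curve`: list with `slope`
#'   (cycles per log10 ng), `intercept`, `r_squared`, `efficiency`.
#' @export
fit_standard_curve <- function(input_ng, ct) {
  if (any(input_ng <= 0)) bp_stop("input masses must be positive", "invalid_input")
  if (length(unique(input_ng)) < 3) {
    bp_stop("need >= 3 distinct input masses", "invalid_input")
  }
  if (length(input_ng) != length(ct)) bp_stop("input and ct lengths differ", "invalid_input")
  fit <- stats::lm(ct ~ log10(input_ng))
  slope <- unname(stats::coef(fit)[2])
  # r^2 computed directly so an exactly collinear (noise-free) series is
  # handled without complaint
  tss <- sum((ct - mean(ct))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(
    list(
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      efficiency = 10^(-1 / slope) - 1
    ),
    class = "standard_curve"
  )
}

#' Default standard-curve dilution series (ng of input RNA)
#' @return Numeric vector: 100, 10, 1, 0.1, 0.01, 0.001, 0.0001.
#' @export
qpcr_dilution_series <- function() c(100, 10, 1, 0.1, 0.01, 0.001, 0.0001)

#' Wilcoxon rank-sum test for two groups
#'
#' Two-sided p-value; the exact null distribution (full enumeration) is
#' used when `n + m <= 20` and there are no ties, otherwise the normal
#' approximation with continuity and tie correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @return List: `W` (rank-sum statistic of `x`), `p`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) bp_stop("samples must be non-empty", "empty_sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Pearson chi-squared test on a contingency table
#'
#' Tests independence of rows and columns; degrees of freedom
#' `(r-1)(c-1)`. The Yates continuity correction is applied by default
#' for 2x2 tables only.
#'
#' @param tab Integer matrix of counts, at least 2x2; no row or column
#'   may sum to zero.
#' @param correction Apply Yates correction on 2x2 tables (default
#'   `TRUE`).
#' @return List: `X2`, `df`, `p`.
#' @export
chi_squared <- function(tab, correction = TRUE) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) bp_stop("need at least a 2x2 table", "invalid_table")
  if (any(tab < 0)) bp_stop("counts must be non-negative", "invalid_table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    bp_stop("rows and columns must have positive totals", "degenerate_table")
  }
  use_yates <- correction && all(dim(tab) == 2)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = use_yates))
  list(X2 = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}
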