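# Synthetic-data generators with planted ground truth. The cohort generator
# emulates the structure of the public discovery data: three small
# microarray datasets (one progressor series of 8 samples, two
# non-progressor series of 7 and 18), bimodal expressed/unexpressed log2
# intensities, additive per-dataset batch effects, and a configurable set
# of planted progression genes (shifted in mean and/or exclusively
# expressed in P-BE samples).

#' Build a simulation configuration
#'
#' Defaults mirror the discovery meta-cohort: three datasets of 8 P-BE, 7
#' nonP-BE and 18 nonP-BE samples; a two-component normal intensity model
#' on the log2 scale (unexpressed N(4, 0.5), expressed N(9, 1)); and a
#' gene-wise additive batch shift per dataset.
#'
#' @param n_genes Number of genes.
#' @param datasets List of `list(dataset_id, group, n_samples)` specs.
#' @param frac_expressed_baseline Baseline fraction of genes expressed in
#'   the tissue, in (0,1).
#' @param mu_unexpr,sigma_unexpr,mu_expr,sigma_expr Component parameters
#'   (log2 units); `mu_expr` must exceed `mu_unexpr` and scales must be
#'   positive.
#' @param batch_shift_sd SD (log2 units) of the per-dataset, per-gene
#'   additive batch shift.
#' @param planted_de Data frame (or list coercible to one) with columns
#'   `gene` (index) and `effect` (log2 shift added to P-BE samples).
#' @param planted_exclusive Integer indices of genes expressed only in
#'   P-BE samples (unexpressed everywhere else, including the reference).
#' @param z_cut Expression-call cutoff (sd units) stored in the generated
#'   frozen reference.
#' @param seed Integer seed; generators are pure functions of
#'   (config, seed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       datasets = list(
                         list(dataset_id = "ds1", group = "P-BE", n_samples = 8),
                         list(dataset_id = "ds2", group = "nonP-BE", n_samples = 7),
                         list(dataset_id = "ds3", group = "nonP-BE", n_samples = 18)
                       ),
                       frac_expressed_baseline = 0.5,
                       mu_unexpr = 4, sigma_unexpr = 0.5,
                       mu_expr = 9, sigma_expr = 1,
                       batch_shift_sd = 0.5,
                       planted_de = NULL,
                       planted_exclusive = integer(),
                       z_cut = 5,
                       seed = 1L) {
  if (sigma_unexpr <= 0 || sigma_expr <= 0) {
    bp_stop("intensity scale parameters must be > 0", "invalid_config")
  }
  if (batch_shift_sd < 0) bp_stop("batch_shift_sd must be >= 0", "invalid_config")
  if (mu_expr <= mu_unexpr) bp_stop("mu_expr must exceed mu_unexpr", "invalid_config")
  if (frac_expressed_baseline <= 0 || frac_expressed_baseline >= 1) {
    bp_stop("frac_expressed_baseline must be in (0,1)", "invalid_config")
  }
  if (is.null(planted_de)) {
    planted_de <- data.frame(gene = integer(), effect = numeric())
  }
  planted_de <- as.data.frame(planted_de)
  if (nrow(planted_de) && (!all(is.finite(planted_de$effect)) ||
    any(planted_de$gene < 1) || any(planted_de$gene > n_genes))) {
    bp_stop("planted_de effects must be finite and indices within 1..n_genes", "invalid_config")
  }
  planted_exclusive <- as.integer(planted_exclusive)
  if (length(planted_exclusive) &&
    (any(planted_exclusive < 1) || any(planted_exclusive > n_genes))) {
    bp_stop("planted_exclusive indices must be within 1..n_genes", "invalid_config")
  }
  structure(
    list(
      n_genes = as.integer(n_genes), datasets = datasets,
      frac_expressed_baseline = frac_expressed_baseline,
      mu_unexpr = mu_unexpr, sigma_unexpr = sigma_unexpr,
      mu_expr = mu_expr, sigma_expr = sigma_expr,
      batch_shift_sd = batch_shift_sd,
      planted_de = planted_de,
      planted_exclusive = planted_exclusive,
      z_cut = z_cut, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Convenience config with markers planted both DE and P-BE-exclusive
#'
#' Picks `n_planted` gene indices (seeded draw) and plants them with the
#' given log2 effect in P-BE and exclusive expression in P-BE — the
#' signature of a true progression marker that the full funnel is designed
#' to recover.
#'
#' @param n_genes,seed As in [sim_config()].
#' @param n_planted Number of planted marker genes.
#' @param effect Log2 effect added in P-BE samples.
#' @param ... Passed to [sim_config()].
#' @return A `sim_config`.
#' @export
planted_marker_config <- function(n_genes = 2000, n_planted = 20, effect = 2,
                                  seed = 1L, ...) {
  idx <- with_seed(seed, sample.int(n_genes, n_planted))
  sim_config(
    n_genes = n_genes,
    planted_de = data.frame(gene = idx, effect = effect),
    planted_exclusive = idx,
    seed = seed, ...
  )
}

# Quantile function of the two-component reference mixture, by grid
# inversion of the CDF (accurate to the grid resolution, deterministic).
mixture_quantiles <- function(p, pi_expr, mu_u, s_u, mu_e, s_e, n_grid = 20001) {
  lo <- min(mu_u - 8 * s_u, mu_e - 8 * s_e)
  hi <- max(mu_u + 8 * s_u, mu_e + 8 * s_e)
  x <- seq(lo, hi, length.out = n_grid)
  cdf <- (1 - pi_expr) * stats::pnorm(x, mu_u, s_u) + pi_expr * stats::pnorm(x, mu_e, s_e)
  stats::approx(cdf, x, xout = p, rule = 2, ties = "ordered")$y
}

#' Generate a multi-dataset synthetic cohort with planted truth
#'
#' Per dataset, each (gene, sample) intensity is drawn from the unexpressed
#' or expressed normal component according to the gene's baseline state
#' (decided once per gene) and the planted truth: planted-exclusive genes
#' are expressed in every P-BE sample and in no other sample. Planted DE
#' effects are added to P-BE samples. A per-dataset gene-wise batch shift
#' is added on top. The frozen reference is built from the generating
#' parameters (not re-estimated from the data): per-gene unexpressed
#' location/scale, the configured z cutoff, and reference quantiles of the
#' batch-free intensity mixture.
#'
#' @param config A [sim_config()].
#' @return List with `matrices` (named list of [expression_matrix()], one
#'   per dataset), `reference` (a [frozen_reference()]), and `truth` (list
#'   with `gene_ids`, `planted_de`, `planted_exclusive`, and the per-gene,
#'   per-sample logical `expressed` state matrix).
#' @export
generate_meta_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    G <- config$n_genes
    ids <- sprintf("g%05d", seq_len(G))
    baseline <- stats::runif(G) < config$frac_expressed_baseline
    # exclusive genes are unexpressed at baseline (and in the reference)
    baseline[config$planted_exclusive] <- FALSE
    effect <- numeric(G)
    if (nrow(config$planted_de)) {
      effect[config$planted_de$gene] <- config$planted_de$effect
    }

    all_samples <- list()
    matrices <- list()
    truth_state <- NULL
    for (ds in config$datasets) {
      n <- ds$n_samples
      sample_ids <- sprintf("%s_s%02d", ds$dataset_id, seq_len(n))
      is_pbe <- ds$group == "P-BE"
      state <- matrix(baseline, nrow = G, ncol = n)
      if (is_pbe && length(config$planted_exclusive)) {
        state[config$planted_exclusive, ] <- TRUE
      }
      mu <- ifelse(state, config$mu_expr, config$mu_unexpr)
      sd <- ifelse(state, config$sigma_expr, config$sigma_unexpr)
      vals <- matrix(stats::rnorm(G * n, mu, sd), nrow = G, ncol = n)
      if (is_pbe) vals <- vals + effect
      if (config$batch_shift_sd > 0) {
        vals <- vals + stats::rnorm(G, 0, config$batch_shift_sd)
      }
      dimnames(vals) <- list(ids, sample_ids)
      dimnames(state) <- list(ids, sample_ids)
      samples <- data.frame(
        sample_id = sample_ids, dataset_id = ds$dataset_id,
        group = ds$group, stringsAsFactors = FALSE
      )
      matrices[[ds$dataset_id]] <- expression_matrix(vals, samples)
      truth_state <- cbind(truth_state, state)
      all_samples[[ds$dataset_id]] <- samples
    }

    pi_ref <- mean(baseline)
    refq <- mixture_quantiles(
      (seq_len(G) - 0.5) / G, pi_ref,
      config$mu_unexpr, config$sigma_unexpr,
      config$mu_expr, config$sigma_expr
    )
    reference <- frozen_reference(
      gene_ids = ids,
      mu_unexpr = config$mu_unexpr, sigma_unexpr = config$sigma_unexpr,
      z_cut = config$z_cut, ref_quantiles = refq
    )
    truth <- list(
      gene_ids = ids,
      planted_de = data.frame(
        gene_id = ids[config$planted_de$gene],
        effect = config$planted_de$effect, stringsAsFactors = FALSE
      ),
      planted_exclusive = ids[config$planted_exclusive],
      expressed = truth_state,
      samples = do.call(rbind, c(all_samples, list(make.row.names = FALSE)))
    )
    list(matrices = matrices, reference = reference, truth = truth)
  })
}

#' Generate a synthetic qPCR Ct table with duplicates
#'
#' Two patient groups (P-BE cases, nonP-BE controls), one target gene and
#' one calibrator gene measured in duplicate. Per patient, a common input
#' shift (RNA amount) moves target and calibrator alike — the component
#' the ddCt normalization is designed to cancel. The target's Ct is
#' lowered by `effect_log2` cycles in the P-BE group (one cycle = one
#' log2 unit of expression); the calibrator is unaffected.
#'
#' @param n_per_group Patients per group (>= 2).
#' @param effect_log2 True log2 fold change of the target in P-BE.
#' @param sd_ct Technical SD of a single Ct replicate (>= 0).
#' @param seed Integer seed.
#' @param target,calibrator Gene names (defaults `"CYR61"`, `"GAPDH"`).
#' @param base_ct_target,base_ct_calib Baseline mean Ct values.
#' @param sd_input SD of the per-patient common input shift (cycles).
#' @return Data frame of class `ct_table` with columns `patient_id`,
#'   `group`, `timepoint`, `gene_id`, `replicate`, `ct`, and attribute
#'   `calibrator_gene`.
#' @export
generate_qpcr <- function(n_per_group, effect_log2, sd_ct, seed = 1L,
                          target = "CYR61", calibrator = "GAPDH",
                          base_ct_target = 26, base_ct_calib = 20,
                          sd_input = 0.8) {
  if (n_per_group < 2) bp_stop("n_per_group must be >= 2", "invalid_config")
  if (sd_ct < 0) bp_stop("sd_ct must be >= 0", "invalid_config")
  with_seed(seed, {
    patients <- data.frame(
      patient_id = c(
        sprintf("P%02d", seq_len(n_per_group)),
        sprintf("N%02d", seq_len(n_per_group))
      ),
      group = rep(c("P-BE", "nonP-BE"), each = n_per_group),
      stringsAsFactors = FALSE
    )
    input_shift <- stats::rnorm(nrow(patients), 0, sd_input)
    rows <- lapply(seq_len(nrow(patients)), function(i) {
      true_target <- base_ct_target + input_shift[i] -
        if (patients$group[i] == "P-BE") effect_log2 else 0
      true_calib <- base_ct_calib + input_shift[i]
      data.frame(
        patient_id = patients$patient_id[i],
        group = patients$group[i],
        timepoint = "t0",
        gene_id = rep(c(target, calibrator), each = 2),
        replicate = rep(1:2, times = 2),
        ct = c(
          true_target + stats::rnorm(2, 0, sd_ct),
          true_calib + stats::rnorm(2, 0, sd_ct)
        ),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    if (any(out$ct <= 0)) bp_stop("generated non-positive Ct; adjust baselines", "invalid_config")
    attr(out, "calibrator_gene") <- calibrator
    class(out) <- c("ct_table", "data.frame")
    out
  })
}

#' Generate a synthetic clinical follow-up table
#'
#' Valid records with follow-up years drawn uniformly from per-group
#' ranges (defaults match the validation cohort's observed ranges: 1-13
#' years for progressors, 3-17 for non-progressors) and categorical
#' marker calls drawn from the schema alphabets with group-biased
#' probabilities (progressors skew High / strongly stained).
#'
#' @param n_p,n_np Number of progressor / non-progressor records (>= 1).
#' @param seed Integer seed.
#' @param fup_range_p,fup_range_np Integer follow-up ranges (years).
#' @return A `clinical_table` data frame (same schema as
#'   [read_clinical()]).
#' @export
generate_clinical <- function(n_p, n_np, seed = 1L,
                              fup_range_p = c(1, 13), fup_range_np = c(3, 17)) {
  if (n_p < 1 || n_np < 1) bp_stop("need at least one record per group", "invalid_config")
  with_seed(seed, {
    n <- n_p + n_np
    group <- c(rep("P-BE", n_p), rep("nonP-BE", n_np))
    years <- c(
      sample(seq(fup_range_p[1], fup_range_p[2]), n_p, replace = TRUE),
      sample(seq(fup_range_np[1], fup_range_np[2]), n_np, replace = TRUE)
    )
    age_first <- sample(40:70, n, replace = TRUE)
    draw <- function(levels, p_pbe, p_npbe) {
      ifelse(group == "P-BE",
        sample(levels, n, replace = TRUE, prob = p_pbe),
        sample(levels, n, replace = TRUE, prob = p_npbe)
      )
    }
    tab <- data.frame(
      patient_id = sprintf("sim%02d", seq_len(n)),
      group = group,
      age_first = age_first,
      age_last = age_first + years,
      years_fup = years,
      qpcr_cyr61_t0 = draw(QPCR_LEVELS, c(0.3, 0.7), c(0.9, 0.1)),
      qpcr_taz_t0 = draw(QPCR_LEVELS, c(0.2, 0.8), c(0.8, 0.2)),
      ihc_cyr61_t0 = draw(IHC_CYR61_LEVELS, c(0.05, 0.2, 0.3, 0.45), c(0.2, 0.45, 0.3, 0.05)),
      ihc_taz_t0 = draw(IHC_TAZ_LEVELS, c(0.15, 0.35, 0.5), c(0.5, 0.35, 0.15)),
      qpcr_cyr61_t1 = draw(QPCR_LEVELS, c(0.5, 0.5), c(0.95, 0.05)),
      qpcr_taz_t1 = draw(QPCR_LEVELS, c(0.4, 0.6), c(0.9, 0.1)),
      ihc_cyr61_t1 = draw(IHC_CYR61_LEVELS, c(0.1, 0.3, 0.35, 0.25), c(0.2, 0.5, 0.25, 0.05)),
      ihc_taz_t1 = draw(IHC_TAZ_LEVELS, c(0.25, 0.4, 0.35), c(0.45, 0.4, 0.15)),
      stringsAsFactors = FALSE
    )
    validate_clinical(tab)
  })
}
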