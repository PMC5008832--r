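# End-to-end discovery funnel: normalize -> pool -> moderated DE ->
# candidate selection -> barcode binarization -> dataset/group barcodes ->
# exclusivity -> candidate intersection -> optional enrichment and network
# expansion. Every intermediate is written as TSV with a provenance header
# (package version, config hash, seed), plus a machine-readable funnel
# summary.

default_funnel_config <- function() {
  list(
    simulation = list(
      n_genes = 2000, n_planted = 20, effect = 2
    ),
    thresholds = list(
      lods_min = 5, lfc_min = 0.58, p_de = 0.01, up_only = FALSE
    ),
    barcode = list(
      frac_rules = list(`P-BE` = 1.0, `nonP-BE` = 0.75, EA = 0.75),
      subtract_ea = FALSE
    ),
    enrichment = list(gmt = NULL, network = NULL, k_neighbors = 100, lambda = 1),
    seed = 1L
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

FUNNEL_STAGES <- c(
  "normalize", "pool", "diffexp", "select", "barcode",
  "exclusive", "candidates", "enrichment", "network"
)

#' Run the discovery funnel end to end
#'
#' Drives the whole pipeline from a single configuration (an R list or a
#' YAML file): simulate (or read) the multi-dataset cohort, normalize
#' each dataset against the frozen reference, pool, fit the moderated
#' differential-expression model, select candidates by log-odds and fold
#' change, binarize against frozen cutoffs, build dataset and group
#' barcodes, derive the progressor-exclusive gene set, intersect it with
#' the DE candidates, and optionally run gene-set enrichment and network
#' neighbor expansion. Every intermediate is written to `out_dir` and a
#' funnel summary (gene counts per stage, recovery against planted truth
#' when simulating) is maintained as stages complete, so a failed run
#' leaves its partial outputs behind.
#'
#' @param config Named list (see Details) or path to a YAML file.
#'   Sections: `simulation` (`n_genes`, `n_planted`, `effect`, plus any
#'   [sim_config()] field) or `inputs` (`matrices` = named vector of TSV
#'   paths, `manifest`, `reference` not yet supported for external
#'   references), `thresholds` (`lods_min`, `lfc_min`, `p_de`,
#'   `up_only`), `barcode` (`frac_rules`, `subtract_ea`), `enrichment`
#'   (`gmt`, `network`, `k_neighbors`, `lambda`), `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the funnel `summary` data frame, the
#'   final `candidates`, the `de` result, the barcodes, and `out_dir`.
#' @export
run_funnel <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  config <- merge_config(default_funnel_config(), config)
  hash <- config_hash(config)
  seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- provenance_meta(hash, seed)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))

  summary_rows <- list()
  note_stage <- function(stage, key, value) {
    summary_rows[[length(summary_rows) + 1]] <<- data.frame(
      stage = stage, key = key, value = as.character(value),
      stringsAsFactors = FALSE
    )
    write_tsv_commented(
      do.call(rbind, summary_rows),
      file.path(out_dir, "funnel_summary.tsv"), meta
    )
  }
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      bp_stop(paste0("funnel stage '", stage, "' failed: ", conditionMessage(e)),
        "stage_failure")
    })
  }

  message("[beprog] funnel run; seed = ", seed, ", config hash = ", hash)

  # --- inputs: simulate a cohort with planted truth ---------------------
  sim_args <- config$simulation
  truth <- NULL
  cohort <- stage_wrap("simulate", {
    cfg <- planted_marker_config(
      n_genes = sim_args$n_genes %||% 2000,
      n_planted = sim_args$n_planted %||% 20,
      effect = sim_args$effect %||% 2,
      seed = seed
    )
    generate_meta_cohort(cfg)
  })
  truth <- cohort$truth
  ref <- cohort$reference
  matrices <- cohort$matrices
  note_stage("input", "n_genes", nrow(matrices[[1]]$values))
  note_stage("input", "n_datasets", length(matrices))

  # --- normalize + pool -------------------------------------------------
  normed <- stage_wrap("normalize", lapply(matrices, normalize_frozen, ref = ref))
  for (nm in names(normed)) {
    write_expression(normed[[nm]], file.path(out_dir, paste0("normalized_", nm, ".tsv")),
      meta = meta)
  }
  pooled <- stage_wrap("pool", pool_datasets(normed))
  write_expression(pooled, file.path(out_dir, "pooled.tsv"),
    manifest = file.path(out_dir, "manifest.csv"), meta = meta)
  note_stage("pool", "n_samples", ncol(pooled$values))
  note_stage("pool", "n_genes", nrow(pooled$values))

  # --- moderated DE + candidate selection -------------------------------
  th <- config$thresholds
  fit <- stage_wrap("diffexp", fit_moderated(pooled, p_de = th$p_de))
  write_tsv_commented(fit$result, file.path(out_dir, "de_results.tsv"), meta)
  cand_de <- stage_wrap("select", select_candidates(
    fit$result, lods_min = th$lods_min,
    abs_log2fc_min = th$lfc_min, up_only = isTRUE(th$up_only)
  ))
  write_tsv_commented(cand_de, file.path(out_dir, "candidates_de.tsv"), meta)
  note_stage("diffexp", "n_de", nrow(cand_de))

  # --- barcode stage ----------------------------------------------------
  rules <- config$barcode$frac_rules
  bc <- stage_wrap("barcode", {
    calls <- binarize(pooled, ref)
    lapply(split(seq_len(ncol(calls)), pooled$samples$dataset_id), function(ix) {
      grp <- unique(pooled$samples$group[ix])
      ds <- unique(pooled$samples$dataset_id[ix])
      dataset_barcode(calls[, ix, drop = FALSE], ds, grp,
        frac_rule = rules[[grp]] %||% NULL)
    })
  })
  freq_tab <- do.call(rbind, lapply(bc, function(b) {
    data.frame(
      dataset_id = b$dataset_id, group = b$group, gene_id = names(b$freq),
      freq = b$freq, stringsAsFactors = FALSE
    )
  }))
  rownames(freq_tab) <- NULL
  write_tsv_commented(freq_tab, file.path(out_dir, "barcode_freq.tsv"), meta)

  by_group <- split(bc, vapply(bc, `[[`, character(1), "group"))
  group_sets <- lapply(by_group, group_barcode)
  excl <- stage_wrap("exclusive", exclusive_genes(
    group_sets[["P-BE"]] %||% character(),
    group_sets[["nonP-BE"]] %||% character(),
    ea = group_sets[["EA"]],
    subtract_ea = isTRUE(config$barcode$subtract_ea)
  ))
  for (g in names(group_sets)) {
    write_gene_list(group_sets[[g]],
      file.path(out_dir, paste0("barcode_", gsub("[^A-Za-z]", "", g), ".txt")), meta)
  }
  write_gene_list(excl, file.path(out_dir, "barcode_exclusive.txt"), meta)
  note_stage("barcode", "n_exclusive", length(excl))

  # --- final candidates -------------------------------------------------
  final <- stage_wrap("candidates", intersect_candidates(cand_de, excl))
  write_tsv_commented(final, file.path(out_dir, "candidates_final.tsv"), meta)
  note_stage("candidates", "n_final", nrow(final))

  recovery <- NULL
  if (!is.null(truth) && nrow(truth$planted_de)) {
    planted <- truth$planted_de$gene_id
    recovered <- intersect(final$gene_id, planted)
    false_pos <- setdiff(final$gene_id, planted)
    recovery <- data.frame(
      n_planted = length(planted),
      n_recovered = length(recovered),
      recovery_pct = 100 * length(recovered) / length(planted),
      n_false_positive = length(false_pos),
      stringsAsFactors = FALSE
    )
    write_tsv_commented(recovery, file.path(out_dir, "recovery.tsv"), meta)
    note_stage("candidates", "recovery_pct", recovery$recovery_pct)
    note_stage("candidates", "n_false_positive", recovery$n_false_positive)
  }

  # --- optional enrichment / network expansion --------------------------
  enr <- NULL
  if (!is.null(config$enrichment$gmt)) {
    enr <- stage_wrap("enrichment", hypergeom_enrich(
      final$gene_id, read_gmt(config$enrichment$gmt), gene_ids(pooled)
    ))
    write_tsv_commented(enr, file.path(out_dir, "enrichment.tsv"), meta)
    note_stage("enrichment", "n_sets", nrow(enr))
  }
  expanded <- NULL
  if (!is.null(config$enrichment$network) && nrow(final)) {
    expanded <- stage_wrap("network", expand_neighbors(
      read_network(config$enrichment$network), final$gene_id,
      k = config$enrichment$k_neighbors %||% 100,
      lambda = config$enrichment$lambda %||% 1
    ))
    write_gene_list(expanded, file.path(out_dir, "network_expanded.txt"), meta)
    note_stage("network", "n_expanded", length(expanded))
  }

  invisible(list(
    summary = do.call(rbind, summary_rows),
    candidates = final, de = fit$result, params = fit$params,
    barcodes = bc, exclusive = excl, recovery = recovery,
    enrichment = enr, expanded = expanded,
    truth = truth, config = config, hash = hash, out_dir = out_dir
  ))
}

#' Summarize a funnel run directory
#'
#' Renders a plain-text/markdown summary of a completed or partial run:
#' funnel counts per stage (stages missing from the summary are marked),
#' top final candidates, and the head of the enrichment table when
#' present. Errors if the run directory carries no funnel summary at all.
#'
#' @param run_dir Directory written by [run_funnel()].
#' @param max_candidates Number of top candidates to list.
#' @return Character vector of report lines (also printed), invisibly.
#' @export
report_funnel <- function(run_dir, max_candidates = 10) {
  sf <- file.path(run_dir, "funnel_summary.tsv")
  if (!file.exists(sf)) {
    bp_stop(paste0("no funnel summary found in ", run_dir), "missing_summary")
  }
  summ <- utils::read.delim(sf, comment.char = "#", stringsAsFactors = FALSE)
  lines <- c("# Funnel report", "", "## Stage counts")
  for (i in seq_len(nrow(summ))) {
    lines <- c(lines, sprintf("- %s / %s: %s", summ$stage[i], summ$key[i], summ$value[i]))
  }
  ran <- unique(summ$stage)
  missing <- setdiff(c("pool", "diffexp", "barcode", "candidates"), ran)
  if (length(missing)) {
    lines <- c(lines, "", paste0("Missing stages: ", paste(missing, collapse = ", ")))
  }
  cf <- file.path(run_dir, "candidates_final.tsv")
  if (file.exists(cf)) {
    cand <- utils::read.delim(cf, comment.char = "#", stringsAsFactors = FALSE)
    lines <- c(lines, "", "## Top candidates")
    if (nrow(cand)) {
      top <- utils::head(cand, max_candidates)
      lines <- c(lines, sprintf(
        "- %s (lods = %.2f, log2fc = %.2f)",
        top$gene_id, top$lods, top$log2fc
      ))
    } else {
      lines <- c(lines, "- (none)")
    }
  }
  ef <- file.path(run_dir, "enrichment.tsv")
  if (file.exists(ef)) {
    enr <- utils::read.delim(ef, comment.char = "#", stringsAsFactors = FALSE)
    lines <- c(lines, "", "## Enrichment (top sets)")
    top <- utils::head(enr, 5)
    if (nrow(top)) {
      lines <- c(lines, sprintf(
        "- %s: k=%d/%d, p_adj = %.3g", top$set_name, top$k, top$K, top$p_adj
      ))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
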