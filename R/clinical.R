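# Clinical follow-up tables: per-patient qPCR (Low/High) and ordinal IHC
# calls at the index biopsy (t0) and at the latest/progression biopsy (t1),
# plus years of follow-up. The packaged fixture table2_clinical.csv
# transcribes the validation cohort (9 progressors, 10 non-progressors).

QPCR_LEVELS <- c("Low", "High")
IHC_CYR61_LEVELS <- c("-", "+", "++", "+++")
IHC_TAZ_LEVELS <- c("-", "+", "++")
CLINICAL_MARKERS <- c("qpcr_cyr61", "qpcr_taz", "ihc_cyr61", "ihc_taz")

marker_levels <- function(marker) {
  switch(marker,
    qpcr_cyr61 = ,
    qpcr_taz = QPCR_LEVELS,
    ihc_cyr61 = IHC_CYR61_LEVELS,
    ihc_taz = IHC_TAZ_LEVELS,
    bp_stop(paste0("unknown marker: ", marker), "invalid_marker")
  )
}

#' Read a clinical follow-up table
#'
#' CSV schema: `patient_id`, `group` (`P-BE`/`nonP-BE`), `age_first`,
#' `age_last`, `years_fup`, and per-timepoint categorical calls
#' `qpcr_cyr61_t0`, `qpcr_taz_t0`, `ihc_cyr61_t0`, `ihc_taz_t0` and the
#' `_t1` counterparts. qPCR calls are `Low`/`High`; CYR61 IHC scores range
#' over `-`, `+`, `++`, `+++`; TAZ IHC scores over `-`, `+`, `++`. Any
#' token outside its alphabet is an error naming the row and token.
#'
#' @param path CSV path; see [beprog_example()] (`"table2_clinical.csv"`)
#'   for the packaged validation-cohort fixture.
#' @return A data frame of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(
    "patient_id", "group", "age_first", "age_last", "years_fup",
    paste0(rep(CLINICAL_MARKERS, each = 2), "_", TIMEPOINT_LEVELS)
  )
  miss <- setdiff(needed, names(tab))
  if (length(miss)) {
    bp_stop(
      paste0("clinical table lacks column(s): ", paste(miss, collapse = ", ")),
      "invalid_clinical"
    )
  }
  validate_clinical(tab)
}

validate_clinical <- function(tab) {
  bad_grp <- which(!tab$group %in% c("P-BE", "nonP-BE"))
  if (length(bad_grp)) {
    bp_stop(
      paste0("row ", bad_grp[1], ": unknown group '", tab$group[bad_grp[1]], "'"),
      "invalid_clinical"
    )
  }
  if (any(tab$years_fup < 0)) {
    bp_stop("years_fup must be non-negative", "invalid_clinical")
  }
  if (any(tab$age_last < tab$age_first)) {
    bp_stop("age_last must be >= age_first", "invalid_clinical")
  }
  for (marker in CLINICAL_MARKERS) {
    lv <- marker_levels(marker)
    for (tp in TIMEPOINT_LEVELS) {
      col <- paste0(marker, "_", tp)
      bad <- which(!tab[[col]] %in% lv)
      if (length(bad)) {
        bp_stop(
          paste0(
            "row ", bad[1], ", column ", col, ": token '",
            tab[[col]][bad[1]], "' outside alphabet {",
            paste(lv, collapse = ", "), "}"
          ),
          "invalid_category"
        )
      }
    }
  }
  class(tab) <- c("clinical_table", "data.frame")
  tab
}

#' Per-group follow-up summary
#'
#' Mean (rounded to one decimal), minimum and maximum years of follow-up
#' per patient group.
#'
#' @param records A `clinical_table` (see [read_clinical()]).
#' @param groups Groups to summarize (default: all present).
#' @return Data frame with columns `group`, `n`, `mean_years`,
#'   `min_years`, `max_years`.
#' @export
summarize_followup <- function(records, groups = NULL) {
  if (is.null(groups)) groups <- unique(records$group)
  rows <- lapply(groups, function(g) {
    y <- records$years_fup[records$group == g]
    if (!length(y)) bp_stop(paste0("no records in group ", g), "empty_group")
    data.frame(
      group = g, n = length(y),
      mean_years = round(mean(y), 1),
      min_years = min(y), max_years = max(y),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Group-by-score contingency table for a clinical marker
#'
#' Counts patients per group and ordinal score level for the chosen marker
#' and timepoint. Zero-count score levels are retained, so the table shape
#' is determined by the marker's alphabet, not by the data.
#'
#' @param records A `clinical_table`.
#' @param marker One of `"qpcr_cyr61"`, `"qpcr_taz"`, `"ihc_cyr61"`,
#'   `"ihc_taz"`.
#' @param timepoint `"t0"` or `"t1"`.
#' @return An integer matrix (groups x score levels) suitable for
#'   [chi_squared()].
#' @export
score_table <- function(records, marker, timepoint = "t0") {
  if (!marker %in% CLINICAL_MARKERS) {
    bp_stop(paste0("unknown marker: ", marker), "invalid_marker")
  }
  if (!timepoint %in% TIMEPOINT_LEVELS) {
    bp_stop(paste0("unknown timepoint: ", timepoint), "invalid_timepoint")
  }
  col <- paste0(marker, "_", timepoint)
  lv <- marker_levels(marker)
  tab <- table(
    factor(records$group, levels = c("nonP-BE", "P-BE")),
    factor(records[[col]], levels = lv)
  )
  out <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  names(dimnames(out)) <- c("group", marker)
  out
}
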