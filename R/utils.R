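# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
bp_stop <- function(msg, class = "error") {
  stop(errorCondition(msg,
    class = c(paste0("beprog_", class), "beprog_error", "error", "condition")
  ))
}

# Recognized sample group and timepoint labels.
GROUP_LEVELS <- c("P-BE", "nonP-BE", "EA")
TIMEPOINT_LEVELS <- c("t0", "t1")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits. Used to stamp
# pipeline outputs with a config fingerprint; collision resistance at the
# level of "two different configs in one analysis never share a hash".
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619, split to keep
    # intermediate products inside double precision.
    a_lo <- h %% 65536
    a_hi <- (h - a_lo) / 65536
    h <- ((a_hi * 16777619) %% 65536) * 65536 + a_lo * 16777619
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Deterministic fingerprint of an R config object.
config_hash <- function(config) {
  fnv1a32(yaml::as.yaml(config))
}

# Write a data.frame as TSV with '#'-prefixed provenance header lines.
write_tsv_commented <- function(df, path, meta = character()) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
}

# Standard provenance header lines for pipeline outputs.
provenance_meta <- function(hash, seed = NULL) {
  c(
    paste0("beprog version: ", as.character(utils::packageVersion("beprog"))),
    paste0("config hash: ", hash),
    if (!is.null(seed)) paste0("seed: ", seed)
  )
}
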