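#' @import methods
#' @importFrom stats p.adjust phyper fisher.test runif
#' @importFrom utils read.delim write.table head
#' @importFrom BiocGenerics sort
#' @importClassesFrom GenomicRanges GRanges
NULL

# Deterministic per-artifact seed: one RNG stream per (seed, artifact-name)
# so adding a new simulated artifact never perturbs existing ones.
# Kept strictly below 2^31 - 1.
artifactSeed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1000003L
  as.integer((as.numeric(seed) %% 2147480L) * 1000 + h %% 1000)
}

withArtifactSeed <- function(seed, name, code) {
  withr::with_seed(artifactSeed(seed, name), code)
}

# Trim + upper-case gene identifiers (AGI ids are conventionally upper-case,
# but user lists vary in case and padding).
normalizeGeneIds <- function(ids) {
  toupper(trimws(as.character(ids)))
}

# Stable numeric formatting for TSV output: fixed-point, switching to
# scientific notation below 1e-4, '.' decimal separator.
formatP <- function(p) {
  ifelse(p < 1e-4, sprintf("%.6e", p), sprintf("%.6f", p))
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stopUser <- function(...) stop(..., call. = FALSE)
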