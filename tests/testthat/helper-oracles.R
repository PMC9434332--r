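suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Build a GRanges from 0-based half-open coordinates (the BED convention
# used in interval examples throughout the tests).
bedGR <- function(chrom, start0, end0, ...) {
  GRanges(chrom, IRanges(start0 + 1, end0), ...)
}

# Independent hypergeometric upper-tail oracle for the one-sided Fisher
# test: direct summation of the pmf written from the choose() definition,
# never via phyper.
oracleHyperTail <- function(a, b, c, d) {
  k <- a + b            # foreground size (drawn)
  K <- a + c            # total hit genes (white balls)
  N <- a + b + c + d
  if (a == 0) return(1)
  x <- a:min(k, K)
  sum(exp(lchoose(K, x) + lchoose(N - K, k - x) - lchoose(N, k)))
}

# Independent Benjamini-Hochberg step-up re-implementation: sort
# descending, take cumulative minima of p * n / rank, clip at 1.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * n / (n:1)))
  out <- numeric(n)
  out[o] <- adj
  out
}

oracleBonferroni <- function(p) pmin(1, p * length(p))

# Naive all-pairs overlap scan on 0-based half-open coordinate frames:
# a gene is a hit when any peak on the same chromosome satisfies
# peak.start < prom.end && peak.end > prom.start.
naiveHitNames <- function(prom, pk) {
  hits <- vapply(seq_len(nrow(prom)), function(i) {
    same <- pk$chrom == prom$chrom[i]
    any(pk$start[same] < prom$end[i] & pk$end[same] > prom$start[i])
  }, logical(1))
  prom$name[hits]
}

# Per-base boolean mask of covered positions on a small toy genome
# (named chromosome lengths), from 1-based closed GRanges.
baseMask <- function(gr, chromLens) {
  offs <- c(0, cumsum(as.numeric(chromLens)))
  names(offs) <- c(names(chromLens), "_end")
  mask <- logical(sum(chromLens))
  if (length(gr)) {
    ch <- as.character(seqnames(gr))
    for (i in seq_along(gr)) {
      o <- offs[[ch[i]]]
      mask[(o + start(gr)[i]):(o + end(gr)[i])] <- TRUE
    }
  }
  mask
}

# Independent restatement of the replica-selection rule, straight from its
# verbal definition: take the IDR-merged set when it has more than
# `idrMin` peaks or at least `fold` times the largest replica; otherwise
# the maximal-FRIP replica (ties: more peaks, then name order). Returns
# the index 0 for the IDR set or the 1-based replica index.
ruleOracle <- function(nIdr, repCounts, repFrips, repNames,
                       idrMin = 2000, fold = 2) {
  if (nIdr == 0 && length(repCounts) == 1) return(1L)
  if (nIdr > idrMin) return(0L)
  if (nIdr >= fold * max(repCounts)) return(0L)
  best <- which(repFrips == max(repFrips))
  if (length(best) > 1) best <- best[repCounts[best] == max(repCounts[best])]
  if (length(best) > 1) best <- best[order(repNames[best])][1]
  as.integer(best[1])
}

# Cheap PeakSet of a given size: subset of a shared template so the
# randomized truth-table test does not pay GRanges construction costs.
.peakPool <- GenomicRanges::GRanges(
  "c1", IRanges::IRanges(seq(1, by = 10, length.out = 5000), width = 5))
makePeakSetOfSize <- function(n, name, frip = NA_real_) {
  PeakSet(name, .peakPool[seq_len(n)], frip = frip)
}

# Small two-gene annotation used across unit tests (1-based GRanges,
# chromosome lengths attached).
tinyAnnotation <- function() {
  g <- GRanges(c("Chr1", "Chr1"), IRanges(c(1001, 5001), c(2000, 6000)),
               c("+", "-"),
               seqinfo = GenomeInfoDb::Seqinfo(c("Chr1", "Chr2"),
                                               c(10000L, 8000L)))
  names(g) <- c("G1", "G2")
  g
}

writeTempLines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
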