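#' Genes whose promoter overlaps a peak set
#'
#' A gene counts as a hit when its promoter window overlaps at least one
#' peak by at least 1 bp; strand is ignored for the overlap and a gene
#' with multiple peaks in its promoter still counts once.
#'
#' @param peaks a [PeakSet-class] or a `GRanges` of peaks.
#' @param promoters a [PromoterSet-class] (non-empty).
#' @return Character vector of hit gene ids (a set, input-order of the
#'   promoter set).
#' @export
promoterHits <- function(peaks, promoters) {
  if (length(promoters) == 0L) stopUser("promoter set is empty")
  gr <- if (is(peaks, "PeakSet")) peaks@peaks else peaks
  names(promoters)[IRanges::overlapsAny(promoters, gr, ignore.strand = TRUE)]
}

#' One-sided Fisher's exact test for a 2x2 enrichment table
#'
#' The table rows are foreground/background genes, columns overlap /
#' no-overlap: `a` foreground hits, `b` foreground misses, `c` background
#' hits, `d` background misses. The one-sided ("greater") p-value is the
#' hypergeometric upper tail P(X >= a) with margins fixed, i.e. the
#' probability of at least `a` foreground hits had hit genes been
#' distributed at random. Vectorized over tables. `a = 0` gives exactly 1.
#'
#' @param a,b,c,d non-negative counts (vectors recycle).
#' @param alternative "greater" (enrichment; default) or "two.sided".
#' @return p-value(s) in (0, 1\].
#' @examples
#' fisherEnrichmentP(5, 0, 0, 5)  # 1 / choose(10, 5)
#' @export
fisherEnrichmentP <- function(a, b, c, d,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (any(c(a, b, c, d) < 0)) stopUser("counts must be non-negative")
  if (alternative == "greater") {
    # upper tail P(X >= a), X ~ Hypergeometric(white = a+c, black = b+d,
    # drawn = a+b)
    p <- stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
    return(pmin(p, 1))
  }
  mapply(function(a, b, c, d)
    stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value,
    a, b, c, d)
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up FDR (with the usual monotonicity
#' enforcement and clipping at 1) or Bonferroni. Output order matches the
#' input order.
#'
#' @param p numeric vector of raw p-values in (0, 1\].
#' @param method "BH" (default) or "bonferroni".
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjustPvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stopUser("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = method)
}

#' Rank candidate upstream regulators for a gene list
#'
#' The core enrichment procedure. The input gene list (after id
#' normalization and deduplication) is intersected with the promoter
#' universe to form the foreground; the rest of the universe is the
#' background. For every peak set in the collection a 2x2 table of
#' promoter-overlap counts is compiled and scored with a one-sided
#' Fisher's exact test; p-values are corrected across the collection and
#' results are returned sorted by adjusted significance (ties by raw p,
#' then name), with ranks 1..N.
#'
#' @param geneList character vector of input gene ids (or a file path read
#'   via [readGeneList()] by the CLI).
#' @param promoters a [PromoterSet-class] defining universe + windows.
#' @param collection a [PeakCollection-class] (QC-filtered; non-empty).
#' @param method multiple-testing correction, "BH" or "bonferroni".
#' @param alternative Fisher sidedness (default one-sided "greater").
#' @return A [S4Vectors::DataFrame] with columns `rank`, `peakSet`, `tfId`,
#'   `tfFamily`, `a`, `b`, `c`, `d`, `pRaw`, `pAdj` and `hitGenes` (a
#'   `CharacterList` of foreground hit ids); metadata fields
#'   `foregroundSize`, `universeSize`, `unmatchedIds`, `method`,
#'   `promoterLength`.
#' @examples
#' fx <- simulateFixture(fixtureSpec(seed = 1, nGenes = 300, nPeakSets = 8,
#'   foregroundSize = 40, peaksPerSet = 150,
#'   planted = list(list(name = "TF001_col", pFg = 0.6, pBg = 0.05))))
#' res <- predictRegulators(fx$foreground, fx$promoters, fx$collection)
#' res[1, c("rank", "peakSet", "pAdj")]
#' @export
predictRegulators <- function(geneList, promoters, collection,
                              method = c("BH", "bonferroni"),
                              alternative = c("greater", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (!is(collection, "PeakCollection") || length(collection) == 0L)
    stopUser("collection must be a non-empty PeakCollection")
  univ <- universe(promoters)
  ids <- unique(normalizeGeneIds(geneList))
  ids <- ids[nzchar(ids)]
  fg <- intersect(ids, univ)
  unmatched <- setdiff(ids, univ)
  if (length(unmatched))
    warning(length(unmatched), " input id(s) absent from the universe were ",
            "dropped", call. = FALSE)
  if (!length(fg))
    stopUser("no input gene matches the universe; unmatched ids: ",
             paste(head(unmatched, 20L), collapse = ", "),
             if (length(unmatched) > 20L) ", ...")
  if (length(fg) == length(univ))
    stopUser("the input list covers the whole universe; no background left")

  nFg <- length(fg)
  nBg <- length(univ) - nFg
  sets <- collection@peakSets

  # One overlap query over the pooled collection, then per-set gene sets.
  # Semantically identical to promoterHits() per set (>= 1 bp, any strand,
  # one count per gene) but avoids rebuilding the interval index per track.
  pkList <- lapply(sets, function(p) GenomicRanges::granges(p@peaks))
  nPer <- lengths(pkList)
  allPk <- suppressWarnings(do.call(c, unname(pkList)))
  setIdx <- rep(seq_along(sets), nPer)
  ov <- GenomicRanges::findOverlaps(promoters, allPk, ignore.strand = TRUE)
  gi <- S4Vectors::queryHits(ov)
  si <- setIdx[S4Vectors::subjectHits(ov)]
  keep <- !duplicated((si - 1) * as.numeric(length(promoters)) + gi)
  gi <- gi[keep]; si <- si[keep]
  hitList <- unname(split(names(promoters)[gi],
                          factor(si, levels = seq_along(sets))))
  fgFlag <- names(promoters) %in% fg
  a <- unname(vapply(split(fgFlag[gi], factor(si, levels = seq_along(sets))),
                     sum, integer(1)))
  c_ <- lengths(hitList) - a
  b <- nFg - a
  d <- nBg - c_
  pRaw <- fisherEnrichmentP(a, b, c_, d, alternative = alternative)
  pAdj <- adjustPvalues(pRaw, method = method)

  nm <- vapply(sets, function(p) p@name, character(1))
  ord <- order(pAdj, pRaw, nm)
  fgHits <- lapply(hitList, function(h) sort(h[h %in% fg]))

  res <- S4Vectors::DataFrame(
    rank = seq_along(ord),
    peakSet = unname(nm[ord]),
    tfId = unname(vapply(sets, function(p) p@tfId, character(1))[ord]),
    tfFamily = unname(vapply(sets, function(p) p@tfFamily,
                             character(1))[ord]),
    a = a[ord], b = b[ord], c = c_[ord], d = d[ord],
    pRaw = unname(pRaw[ord]), pAdj = unname(pAdj[ord]),
    hitGenes = IRanges::CharacterList(fgHits[ord])
  )
  rownames(res) <- NULL
  S4Vectors::metadata(res) <- list(
    foregroundSize = nFg, universeSize = length(univ),
    unmatchedIds = unmatched, method = method,
    promoterLength = promoterLength(promoters),
    collection = versionLabel(collection))
  res
}

#' Peaks detected in the upstream region of one gene
#'
#' The per-gene lookup mode: every peak, from every set in the collection,
#' that overlaps the given gene's promoter window, with its genomic
#' coordinates and originating track.
#'
#' @param geneId a single gene id present in the promoter universe.
#' @param promoters a [PromoterSet-class].
#' @param collection a [PeakCollection-class].
#' @return A `GRanges` of peaks (possibly empty) with metadata columns
#'   `peakSet` and `tfId`.
#' @export
upstreamPeaks <- function(geneId, promoters, collection) {
  id <- normalizeGeneIds(geneId)
  if (length(id) != 1L) stopUser("geneId must be a single identifier")
  if (!id %in% universe(promoters))
    stopUser("gene id '", id, "' is not in the promoter universe")
  prom <- promoters[id]
  parts <- lapply(collection@peakSets, function(ps) {
    hit <- IRanges::overlapsAny(ps@peaks, prom, ignore.strand = TRUE)
    gr <- GenomicRanges::granges(ps@peaks[hit])
    if (length(gr)) {
      gr$peakSet <- ps@name
      gr$tfId <- ps@tfId
    }
    gr
  })
  parts <- parts[lengths(parts) > 0L]
  if (!length(parts)) {
    out <- GenomicRanges::GRanges()
    out$peakSet <- character(0)
    out$tfId <- character(0)
    return(out)
  }
  do.call(c, unname(parts))
}

#' Overlap between two significant-regulator lists
#'
#' Significant sets are those with adjusted p below `fdrCut`; the overlap
#' percentage is `100 * |A intersect B| / |A union B|` keyed by peak-set
#' name. Two empty significant lists are defined as 100% overlap and
#' flagged.
#'
#' @param resA,resB results from [predictRegulators()].
#' @param fdrCut significance cutoff on the adjusted p (default 0.05).
#' @return A list with `overlapPercent`, `shared`, `onlyA`, `onlyB`,
#'   `nA`, `nB`, `bothEmpty`.
#' @export
compareRegulatorLists <- function(resA, resB, fdrCut = 0.05) {
  if (!NROW(resA) || !NROW(resB)) stopUser("both result lists must be non-empty")
  sigA <- resA$peakSet[resA$pAdj < fdrCut]
  sigB <- resB$peakSet[resB$pAdj < fdrCut]
  un <- union(sigA, sigB)
  sh <- intersect(sigA, sigB)
  bothEmpty <- length(un) == 0L
  pct <- if (bothEmpty) 100 else 100 * length(sh) / length(un)
  list(overlapPercent = pct, shared = sort(sh),
       onlyA = sort(setdiff(sigA, sigB)), onlyB = sort(setdiff(sigB, sigA)),
       nA = length(sigA), nB = length(sigB), bothEmpty = bothEmpty)
}

#' Write a ranked regulator table as TSV
#'
#' Columns: rank, peak_set, tf_id, tf_family, a, b, c, d, p_raw, p_adj,
#' hit_genes (semicolon-joined). Numbers use '.' decimals and scientific
#' notation below 1e-4, so repeated runs are byte-identical.
#'
#' @param res result of [predictRegulators()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeResultsTsv <- function(res, path) {
  df <- data.frame(
    rank = res$rank, peak_set = res$peakSet, tf_id = res$tfId,
    tf_family = res$tfFamily, a = res$a, b = res$b, c = res$c, d = res$d,
    p_raw = formatP(res$pRaw), p_adj = formatP(res$pAdj),
    hit_genes = vapply(res$hitGenes, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  writeTsv(df, path)
}

#' Gene-to-TF table for a run
#'
#' One row per (foreground gene, peak set) pair with at least one peak in
#' the gene's promoter, with the number of such peaks.
#'
#' @param geneIds foreground gene ids (normalized).
#' @param promoters a [PromoterSet-class].
#' @param collection a [PeakCollection-class].
#' @return data.frame with columns `gene`, `peak_set`,
#'   `n_peaks_in_promoter`.
#' @export
geneToTfTable <- function(geneIds, promoters, collection) {
  ids <- intersect(unique(normalizeGeneIds(geneIds)), universe(promoters))
  prom <- promoters[ids]
  rows <- lapply(collection@peakSets, function(ps) {
    cnt <- GenomicRanges::countOverlaps(prom, ps@peaks, ignore.strand = TRUE)
    keep <- cnt > 0L
    if (!any(keep)) return(NULL)
    data.frame(gene = names(prom)[keep], peak_set = ps@name,
               n_peaks_in_promoter = unname(cnt[keep]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(gene = character(0), peak_set = character(0),
                      n_peaks_in_promoter = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene, out$peak_set), , drop = FALSE]
}
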