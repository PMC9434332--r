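#' Jaccard statistic between two tracks
#'
#' Both tracks are merged to disjoint intervals; the statistic is the
#' number of bases covered by both divided by the number of bases covered
#' by either. An empty union gives 0 with a flag.
#'
#' @param trackA,trackB `GRanges` tracks.
#' @return A list with `jaccard`, `intersectionBp`, `unionBp`,
#'   `emptyUnion`.
#' @examples
#' a <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("c1", IRanges::IRanges(51, 150))
#' trackJaccard(a, b)$jaccard  # 50 / 150
#' @export
trackJaccard <- function(trackA, trackB) {
  ra <- mergeIntervals(trackA)
  rb <- mergeIntervals(trackB)
  lev <- union(GenomeInfoDb::seqlevels(ra), GenomeInfoDb::seqlevels(rb))
  GenomeInfoDb::seqlevels(ra) <- lev
  GenomeInfoDb::seqlevels(rb) <- lev
  inter <- sum(GenomicRanges::width(
    GenomicRanges::intersect(ra, rb, ignore.strand = TRUE)))
  uni <- sum(GenomicRanges::width(
    GenomicRanges::union(ra, rb, ignore.strand = TRUE)))
  list(jaccard = if (uni > 0) inter / uni else 0,
       intersectionBp = inter, unionBp = uni, emptyUnion = uni == 0)
}

#' Genomic co-localization Fisher test for two tracks
#'
#' Tests whether the intervals of two (merged) tracks co-occur more often
#' than expected on a genome of `genomeBp` bases. The 2x2 table is built
#' at interval level: `n11` merged-A intervals overlapping B, `n12` the
#' remaining A intervals, `n21` merged-B intervals overlapping A beyond
#' those already paired (floored at 0), and `n22` the remaining genome
#' "slots", `max(0, floor(genomeBp / mu) - n11 - n12 - n21)` where `mu` is
#' the mean length of the pooled merged intervals. The one-sided
#' ("greater") Fisher p-value is returned together with the table so the
#' construction is auditable. The construction is this package's own
#' documented convention; agreement with any particular external
#' interval toolkit is not implied.
#'
#' @param trackA,trackB non-empty `GRanges` tracks.
#' @param genomeBp genome size in bp; must be at least the union span of
#'   the two tracks.
#' @return A list with `p`, `table` (2x2 integer matrix), `n11`, `n12`,
#'   `n21`, `n22`, `meanIntervalBp`.
#' @export
colocalizationFisher <- function(trackA, trackB, genomeBp) {
  if (length(trackA) == 0L || length(trackB) == 0L)
    stopUser("both tracks must be non-empty")
  ra <- mergeIntervals(trackA)
  rb <- mergeIntervals(trackB)
  lev <- union(GenomeInfoDb::seqlevels(ra), GenomeInfoDb::seqlevels(rb))
  GenomeInfoDb::seqlevels(ra) <- lev
  GenomeInfoDb::seqlevels(rb) <- lev
  unionBp <- sum(GenomicRanges::width(
    GenomicRanges::union(ra, rb, ignore.strand = TRUE)))
  if (genomeBp < unionBp)
    stopUser("genomeBp (", genomeBp, ") is smaller than the union span (",
             unionBp, ")")
  n11 <- sum(IRanges::overlapsAny(ra, rb, ignore.strand = TRUE))
  bHits <- sum(IRanges::overlapsAny(rb, ra, ignore.strand = TRUE))
  n12 <- length(ra) - n11
  n21 <- max(0L, bHits - n11)
  mu <- mean(GenomicRanges::width(c(GenomicRanges::granges(ra),
                                    GenomicRanges::granges(rb))))
  n22 <- max(0L, as.integer(floor(genomeBp / mu)) - n11 - n12 - n21)
  tab <- matrix(c(n11, n12, n21, n22), nrow = 2, byrow = TRUE,
                dimnames = list(c("inA", "notInA"), c("inB", "notInB")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(p = p, table = tab, n11 = n11, n12 = n12, n21 = n21, n22 = n22,
       meanIntervalBp = mu)
}

#' Mean peak length of a track
#'
#' @param track a non-empty `GRanges`.
#' @return Arithmetic mean of peak lengths in bp.
#' @export
meanPeakLength <- function(track) {
  if (length(track) == 0L) stopUser("mean peak length undefined for an empty track")
  mean(GenomicRanges::width(track))
}

#' Classify the change in peak count between two collection versions
#'
#' "New" when the set is absent from the old collection (`oldCount` NA);
#' "Increase"/"Decrease" when the count changed at least twofold (the
#' exact 2x boundary counts as a change); otherwise "Small changes".
#' Vectorized.
#'
#' @param oldCount old peak counts (NA = absent from the old collection).
#' @param newCount new peak counts (non-negative).
#' @return Character vector of labels.
#' @examples
#' classifyChange(c(NA, 636, 16775, 3266), c(382, 3695, 1654, 2055))
#' @export
classifyChange <- function(oldCount, newCount) {
  if (any(newCount < 0, na.rm = TRUE)) stopUser("newCount must be >= 0")
  n <- max(length(oldCount), length(newCount))
  oldCount <- rep_len(oldCount, n)
  newCount <- rep_len(newCount, n)
  out <- character(n)
  absent <- is.na(oldCount)
  out[absent] <- "New"
  inc <- !absent & newCount >= 2 * oldCount
  out[inc] <- "Increase"
  dec <- !absent & !inc & newCount <= oldCount / 2
  out[dec] <- "Decrease"
  out[!absent & !inc & !dec] <- "Small changes"
  out
}
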