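#' Fraction of reads in peaks (FRIP)
#'
#' The standard track-level quality statistic: the fraction of aligned
#' reads (here: aligned intervals) that overlap at least one peak by at
#' least 1 bp. Alignment files can be converted to intervals upstream
#' (e.g. `bedtools bamtobed`); the computation itself is alignment-format
#' free.
#'
#' @param reads a `GRanges` of read intervals (non-empty).
#' @param peaks a `GRanges` of peaks (may be empty, giving FRIP 0).
#' @return A fraction in \[0,1\].
#' @examples
#' pk <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 200))
#' rd <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(150, 500), width = 50))
#' computeFrip(rd, pk)  # 0.5
#' @export
computeFrip <- function(reads, peaks) {
  if (length(reads) == 0L)
    stopUser("FRIP is undefined for an empty read set")
  if (length(peaks) == 0L) return(0)
  mean(IRanges::overlapsAny(reads, peaks, ignore.strand = TRUE))
}

#' Apply the collection-level QC filters
#'
#' Removes peak sets with FRIP below `minFrip` (when FRIP is known; sets
#' with unknown FRIP skip that criterion with a warning) and sets with
#' fewer than `minPeaks` peaks. The thresholds are boundary-inclusive for
#' retention: FRIP exactly `minFrip` and exactly `minPeaks` peaks are kept
#' ("less than" / "at least" semantics).
#'
#' @param coll a [PeakCollection-class].
#' @param minFrip minimum FRIP to retain (default 0.01).
#' @param minPeaks minimum number of peaks to retain (default 200).
#' @return A list with `collection` (the filtered [PeakCollection-class])
#'   and `removed` (data.frame with columns `name`, `reason`).
#' @export
filterCollection <- function(coll, minFrip = 0.01, minPeaks = 200) {
  nm <- names(coll)
  fr <- vapply(coll@peakSets, function(p) p@frip, numeric(1))
  np <- vapply(coll@peakSets, function(p) length(p@peaks), integer(1))
  if (any(is.na(fr)))
    warning(sum(is.na(fr)), " peak set(s) without FRIP skip the FRIP ",
            "criterion", call. = FALSE)
  badFrip <- !is.na(fr) & fr < minFrip
  badSize <- np < minPeaks
  reason <- character(0); name <- character(0)
  drop <- badFrip | badSize
  if (any(drop)) {
    name <- nm[drop]
    reason <- ifelse(badFrip[drop],
                     ifelse(badSize[drop],
                            sprintf("FRIP<%g;peaks<%d", minFrip, as.integer(minPeaks)),
                            sprintf("FRIP<%g", minFrip)),
                     sprintf("peaks<%d", as.integer(minPeaks)))
  }
  kept <- PeakCollection(coll@peakSets[!drop], versionLabel = coll@versionLabel,
                         provenance = coll@provenance)
  list(collection = kept,
       removed = data.frame(name = name, reason = reason,
                            stringsAsFactors = FALSE))
}

#' Choose the final track from an IDR-merged set and its replicas
#'
#' The selection rule: take the IDR-merged set if it contains more than
#' 2000 peaks, or if its size is at least twice the largest individual
#' replica; otherwise take the replica with the maximal FRIP (ties broken
#' by larger peak count, then by name order). A bundle with a single
#' replica and an empty IDR set returns that replica.
#'
#' @param bundle a [ReplicaBundle-class].
#' @param idrMinPeaks the "more than" threshold on the IDR set (default 2000).
#' @param idrFoldOverReplica the fold threshold versus the largest replica
#'   (default 2, "at least twice").
#' @return A list with `peakSet` (the chosen [PeakSet-class]) and
#'   `decision` (one of "idr-large", "idr-dominant", "replica-max-frip",
#'   "single-replica").
#' @export
selectFinalPeakset <- function(bundle, idrMinPeaks = 2000,
                               idrFoldOverReplica = 2) {
  nIdr <- length(bundle@idr@peaks)
  nRep <- vapply(bundle@replicas, function(p) length(p@peaks), integer(1))
  if (nIdr == 0L && length(bundle@replicas) == 1L)
    return(list(peakSet = bundle@replicas[[1L]], decision = "single-replica"))
  if (nIdr > idrMinPeaks)
    return(list(peakSet = bundle@idr, decision = "idr-large"))
  if (nIdr >= idrFoldOverReplica * max(nRep))
    return(list(peakSet = bundle@idr, decision = "idr-dominant"))
  fr <- vapply(bundle@replicas, function(p) p@frip, numeric(1))
  nm <- vapply(bundle@replicas, function(p) p@name, character(1))
  # max FRIP; ties -> larger peak count, then lexicographic name
  ord <- order(-fr, -nRep, nm)
  list(peakSet = bundle@replicas[[ord[1L]]], decision = "replica-max-frip")
}

#' Merge a track into disjoint sorted intervals
#'
#' Returns the minimal set of disjoint intervals covering exactly the same
#' bases, sorted by (chromosome, start). Touching intervals (BED bookends)
#' are merged. Strand is ignored.
#'
#' @param track a `GRanges`.
#' @return A sorted, strandless, disjoint `GRanges`.
#' @export
mergeIntervals <- function(track) {
  sort(GenomicRanges::reduce(track, ignore.strand = TRUE),
       ignore.strand = TRUE)
}
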