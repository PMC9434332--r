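#' PromoterSet: strand-aware upstream windows for a gene universe
#'
#' A `PromoterSet` is a named [GenomicRanges::GRanges] of promoter windows —
#' the `upstreamLength` bases strictly upstream of each gene's transcription
#' start site (TSS), clipped to the chromosome. Names are gene identifiers;
#' the set of names is the gene universe used as foreground + background in
#' enrichment testing. Genes whose window is empty after clipping (TSS at a
#' chromosome edge) are excluded at construction time.
#'
#' @slot upstreamLength integer(1), the requested window length L in bp.
#' @seealso [buildPromoters()]
#' @export
setClass("PromoterSet",
  contains = "GRanges",
  representation(upstreamLength = "integer")
)

setValidity("PromoterSet", function(object) {
  msg <- character()
  if (length(object@upstreamLength) != 1L || is.na(object@upstreamLength) ||
      object@upstreamLength <= 0L)
    msg <- c(msg, "upstreamLength must be a single positive integer")
  if (length(object) && is.null(names(object)))
    msg <- c(msg, "promoters must be named by gene id")
  if (any(duplicated(names(object))))
    msg <- c(msg, "gene ids must be unique")
  if (length(object) && any(GenomicRanges::width(object) > object@upstreamLength))
    msg <- c(msg, "promoter width exceeds upstreamLength")
  sl <- GenomeInfoDb::seqlengths(object)
  if (length(object) && !any(is.na(sl))) {
    idx <- as.integer(GenomicRanges::seqnames(object))
    if (any(GenomicRanges::start(object) < 1L) ||
        any(GenomicRanges::end(object) > sl[idx]))
      msg <- c(msg, "promoter extends past chromosome bounds")
  }
  if (length(msg)) msg else TRUE
})

#' PeakSet: one TF-binding track with collection metadata
#'
#' A named peak track (one TF experiment) together with the manifest
#' metadata the enrichment pipeline needs: the TF locus identifier, its
#' family, the genomic-DNA library type (`col` native leaf gDNA, `colamp`
#' PCR-amplified methylation-free gDNA, or `unknown`), and optionally the
#' fraction of reads in peaks (FRIP) from quality control.
#'
#' @slot name character(1), unique within a collection (e.g. "WUS_colamp").
#' @slot tfId character(1), TF locus id (e.g. "AT2G17950"); may be NA.
#' @slot tfFamily character(1); may be NA.
#' @slot sampleType character(1), one of "col", "colamp", "unknown".
#' @slot frip numeric(1) in \[0,1\], or NA when not measured.
#' @slot peaks [GenomicRanges::GRanges] of peak intervals (width >= 1).
#' @seealso [PeakSet()], [computeFrip()], [filterCollection()]
#' @export
setClass("PeakSet",
  representation(
    name = "character",
    tfId = "character",
    tfFamily = "character",
    sampleType = "character",
    frip = "numeric",
    peaks = "GRanges"
  )
)

setValidity("PeakSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (!object@sampleType %in% c("col", "colamp", "unknown"))
    msg <- c(msg, "sampleType must be 'col', 'colamp' or 'unknown'")
  if (length(object@frip) != 1L ||
      (!is.na(object@frip) && (object@frip < 0 || object@frip > 1)))
    msg <- c(msg, "frip must be NA or a fraction in [0,1]")
  if (length(object@peaks) && any(GenomicRanges::width(object@peaks) < 1L))
    msg <- c(msg, "every peak must have start < end")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param name track name, unique within a collection.
#' @param peaks a `GRanges` of peak intervals.
#' @param tfId,tfFamily TF locus id and family (NA when unknown).
#' @param sampleType "col", "colamp" or "unknown".
#' @param frip fraction of reads in peaks, NA when not measured.
#' @return A [PeakSet-class] object.
#' @examples
#' ps <- PeakSet("TF1_col", GenomicRanges::GRanges("Chr1",
#'   IRanges::IRanges(101, 200)), tfId = "AT1G00001")
#' nPeaks(ps)
#' @export
PeakSet <- function(name, peaks, tfId = NA_character_, tfFamily = NA_character_,
                    sampleType = "unknown", frip = NA_real_) {
  new("PeakSet",
    name = as.character(name), peaks = peaks,
    tfId = as.character(tfId), tfFamily = as.character(tfFamily),
    sampleType = as.character(sampleType), frip = as.numeric(frip))
}

#' PeakCollection: an ordered, named set of PeakSet tracks
#'
#' The unit over which enrichment and its multiple-testing correction run:
#' one version of a TF-binding profile collection. Multiplicity correction
#' is applied across exactly the member sets, so collections of different
#' sizes yield different adjusted significances for the same track.
#'
#' @slot peakSets named list of [PeakSet-class] objects (names match
#'   each member's own name slot).
#' @slot versionLabel character(1) free-form label (e.g. "MACS2-reprocessed").
#' @slot provenance list of free-form manifest provenance fields.
#' @seealso [PeakCollection()], [loadCollection()], [predictRegulators()]
#' @export
setClass("PeakCollection",
  representation(
    peakSets = "list",
    versionLabel = "character",
    provenance = "list"
  )
)

setValidity("PeakCollection", function(object) {
  msg <- character()
  ok <- vapply(object@peakSets, is, logical(1), class2 = "PeakSet")
  if (!all(ok)) msg <- c(msg, "all members must be PeakSet objects")
  nm <- vapply(object@peakSets, function(p) p@name, character(1))
  if (any(duplicated(nm))) msg <- c(msg, "peak-set names must be unique")
  if (!identical(unname(nm), unname(names(object@peakSets))) &&
      length(object@peakSets))
    msg <- c(msg, "list names must equal the member names")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakCollection
#'
#' @param peakSets list of [PeakSet-class] objects.
#' @param versionLabel free-form collection label.
#' @param provenance list of free-form provenance fields.
#' @return A [PeakCollection-class].
#' @export
PeakCollection <- function(peakSets, versionLabel = "collection",
                           provenance = list()) {
  names(peakSets) <- vapply(peakSets, function(p) p@name, character(1))
  new("PeakCollection", peakSets = peakSets,
      versionLabel = as.character(versionLabel), provenance = provenance)
}

#' ReplicaBundle: an IDR-merged peak set plus its individual replicas
#'
#' Input to the final-track selection rule: the replicate-consistency
#' (IDR) merged set, which may be empty, and the individual replica sets,
#' each carrying a measured FRIP.
#'
#' @slot idr [PeakSet-class], the IDR-merged track (possibly 0 peaks).
#' @slot replicas non-empty list of [PeakSet-class], each with frip set.
#' @seealso [selectFinalPeakset()]
#' @export
setClass("ReplicaBundle",
  representation(idr = "PeakSet", replicas = "list")
)

setValidity("ReplicaBundle", function(object) {
  msg <- character()
  if (!length(object@replicas)) msg <- c(msg, "at least one replica required")
  ok <- vapply(object@replicas, is, logical(1), class2 = "PeakSet")
  if (!all(ok)) msg <- c(msg, "replicas must be PeakSet objects")
  else if (any(vapply(object@replicas, function(p) is.na(p@frip), logical(1))))
    msg <- c(msg, "every replica must have frip defined")
  if (length(msg)) msg else TRUE
})

#' Construct a ReplicaBundle
#' @param idr the IDR-merged [PeakSet-class] (may be empty).
#' @param replicas list of replica [PeakSet-class] objects, FRIP set on each.
#' @return A [ReplicaBundle-class].
#' @export
ReplicaBundle <- function(idr, replicas) {
  new("ReplicaBundle", idr = idr, replicas = replicas)
}
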