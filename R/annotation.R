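#' Read a chromosome-sizes file
#'
#' Two whitespace-separated columns: chromosome name, length in bp.
#'
#' @param path path to the sizes file.
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  if (!file.exists(path)) stopUser("chromosome sizes file not found: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (!nrow(df)) stopUser("empty chromosome sizes file: ", path)
  if (any(is.na(df$length)) || any(df$length <= 0) || any(df$length %% 1 != 0))
    stopUser("chromosome lengths must be positive integers in ", path)
  if (any(duplicated(df$chrom)))
    stopUser("duplicated chromosome names in ", path)
  stats::setNames(as.integer(df$length), df$chrom)
}

#' Load a gene annotation from GFF3 + chromosome sizes
#'
#' Parses a GFF3 file (1-based inclusive coordinates), keeps features of the
#' requested type, extracts the `ID=` attribute as the gene identifier
#' (upper-cased, trimmed), and attaches chromosome lengths as the `Seqinfo`.
#' Genes on chromosomes absent from the sizes file are dropped with a
#' warning; the drop count is stored in `metadata(ann)$droppedChromCount`.
#' Duplicate gene ids keep the first record with a warning, or raise an
#' error when `onDuplicate = "error"`.
#'
#' @param gff3Path path to a GFF3 annotation.
#' @param chromSizesPath path to a two-column chromosome sizes file.
#' @param featureType GFF3 `type` column value to keep (default "gene").
#' @param onDuplicate "first" (keep first record, warn) or "error".
#' @return A named `GRanges` of genes with strand and `Seqinfo` lengths;
#'   metadata fields `droppedChromCount` and `duplicateIdCount`.
#' @examples
#' fx <- generateFixture(fixtureSpec(seed = 1, nGenes = 50, nPeakSets = 2),
#'                       dir = tempfile())
#' ann <- loadAnnotation(fx$gff3, fx$chromSizes)
#' length(ann)
#' @export
loadAnnotation <- function(gff3Path, chromSizesPath, featureType = "gene",
                           onDuplicate = c("first", "error")) {
  onDuplicate <- match.arg(onDuplicate)
  if (!file.exists(gff3Path)) stopUser("GFF3 file not found: ", gff3Path)
  sizes <- readChromSizes(chromSizesPath)

  # Pre-scan for line-numbered diagnostics; rtracklayer does the parsing.
  lines <- readLines(gff3Path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1L]]
    stopUser("unparseable GFF3 line ", bad, " in ", gff3Path,
             " (expected 9 tab-separated fields, found ", nf[nf != 9L][1L], ")")
  }

  gr <- rtracklayer::import(gff3Path, format = "gff3")
  gr <- gr[as.character(gr$type) == featureType]
  if (!length(gr))
    stopUser("no features of type '", featureType, "' in ", gff3Path)
  ids <- as.character(gr$ID)
  if (any(is.na(ids) | !nzchar(ids)))
    stopUser("feature of type '", featureType, "' without an ID attribute in ",
             gff3Path)
  ids <- normalizeGeneIds(ids)

  dup <- duplicated(ids)
  if (any(dup)) {
    if (onDuplicate == "error")
      stopUser("duplicate gene ids in ", gff3Path, ": ",
               paste(unique(ids[dup]), collapse = ", "))
    warning(sum(dup), " duplicate gene id(s) in ", gff3Path,
            "; keeping the first record of each", call. = FALSE)
    gr <- gr[!dup]
    ids <- ids[!dup]
  }

  onKnown <- as.character(GenomicRanges::seqnames(gr)) %in% names(sizes)
  nDropped <- sum(!onKnown)
  if (nDropped) {
    warning(nDropped, " gene(s) on chromosomes absent from the sizes file ",
            "were dropped", call. = FALSE)
    gr <- gr[onKnown]
    ids <- ids[onKnown]
  }
  if (!length(gr)) stopUser("no genes left after chromosome filtering")

  st <- as.character(GenomicRanges::strand(gr))
  if (any(st == "*"))
    stopUser("gene(s) without strand in ", gff3Path, ": ",
             paste(head(ids[st == "*"], 5L), collapse = ", "))

  lens <- sizes[as.character(GenomicRanges::seqnames(gr))]
  if (any(GenomicRanges::end(gr) > lens) || any(GenomicRanges::start(gr) < 1L))
    stopUser("gene coordinates outside chromosome bounds in ", gff3Path)

  out <- GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    ranges = IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)),
    strand = st,
    seqinfo = GenomeInfoDb::Seqinfo(names(sizes), unname(sizes))
  )
  names(out) <- ids
  S4Vectors::metadata(out) <- list(droppedChromCount = nDropped,
                                   duplicateIdCount = sum(dup))
  out
}

#' Build strand-aware promoter windows
#'
#' For a "+" gene the promoter is the `upstream` bases ending just before
#' the gene start (the TSS base itself is excluded); for a "-" gene, the
#' `upstream` bases starting just after the gene end. Windows are clipped
#' to chromosome bounds; genes whose window is empty after clipping are
#' excluded from the universe with a warning.
#'
#' @param ann a named `GRanges` of genes (see [loadAnnotation()]).
#' @param upstream window length L in bp. The conventional choices are
#'   500, 1000, 1500, 2000 or 2500; other positive values are accepted with
#'   a message flagging them as non-standard.
#' @return A [PromoterSet-class].
#' @examples
#' g <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(1001, 2000), "+",
#'        seqinfo = GenomeInfoDb::Seqinfo("Chr1", 10000))
#' names(g) <- "G1"
#' pr <- buildPromoters(g, 500)
#' GenomicRanges::start(pr)  # 501 (1-based): the 500 bp upstream of the TSS
#' @export
buildPromoters <- function(ann, upstream = 1000) {
  if (length(upstream) != 1L || is.na(upstream) || upstream <= 0)
    stopUser("upstream length must be a single positive number")
  if (!upstream %in% c(500, 1000, 1500, 2000, 2500))
    message("note: promoter length ", upstream,
            " bp is outside the conventional set {500, 1000, 1500, 2000, 2500}")
  if (is.null(names(ann)) || any(duplicated(names(ann))))
    stopUser("annotation must carry unique gene ids as names")
  if (any(is.na(GenomeInfoDb::seqlengths(ann))))
    stopUser("annotation must carry chromosome lengths (Seqinfo)")

  prom <- suppressWarnings(
    GenomicRanges::trim(
      GenomicRanges::promoters(ann, upstream = as.integer(upstream),
                               downstream = 0L)))
  empty <- GenomicRanges::width(prom) == 0L
  if (any(empty))
    warning(sum(empty), " gene(s) with an empty promoter after clipping were ",
            "excluded from the universe", call. = FALSE)
  prom <- prom[!empty]
  if (!length(prom)) stopUser("no genes with a non-empty promoter")
  prom <- sort(prom, ignore.strand = TRUE)
  new("PromoterSet", prom, upstreamLength = as.integer(upstream))
}

#' Export promoters as BED6
#'
#' BED is 0-based half-open; the gene id goes in the name column and the
#' gene strand in column 6.
#'
#' @param promoters a [PromoterSet-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
exportPromotersBed <- function(promoters, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(promoters)),
    start = GenomicRanges::start(promoters) - 1L,
    end = GenomicRanges::end(promoters),
    name = names(promoters),
    score = 0L,
    strand = as.character(GenomicRanges::strand(promoters))
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a gene annotation back to GFF3
#'
#' Inverse of [loadAnnotation()] for gene features (used by the fixture
#' generator and for round-trip checks).
#'
#' @param ann a named `GRanges` of genes with strand.
#' @param path output file path.
#' @param source value for the GFF3 source column.
#' @return The path, invisibly.
#' @export
writeGenesGff3 <- function(ann, path, source = "peakRegulators") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  sl <- GenomeInfoDb::seqlengths(ann)
  if (!any(is.na(sl)))
    writeLines(sprintf("##sequence-region %s 1 %d", names(sl), sl), con)
  writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     as.character(GenomicRanges::seqnames(ann)),
                     source,
                     GenomicRanges::start(ann),
                     GenomicRanges::end(ann),
                     as.character(GenomicRanges::strand(ann)),
                     names(ann)), con)
  invisible(path)
}
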