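#' Specification for a synthetic benchmark fixture
#'
#' Describes a toy genome, gene annotation, and a peak-set collection with
#' optionally "planted" regulators: sets that drop a peak into each gene's
#' promoter with probability `pFg` for foreground genes and `pBg` for
#' background genes. Non-planted sets place peaks uniformly at random.
#' Identical seeds give bit-identical fixtures; each artifact draws from
#' its own RNG stream keyed off (seed, artifact-name), so adding an
#' artifact never perturbs the others.
#'
#' The defaults describe the standard benchmark condition used throughout
#' the package's tests: 2000 genes on two 6 Mb chromosomes, 100 foreground
#' genes, a 100-track collection with one planted regulator
#' (pFg = 0.5, pBg = 0.05), 1000-bp promoters.
#'
#' @param seed integer RNG seed.
#' @param nChroms number of chromosomes.
#' @param chromLengths chromosome lengths in bp (recycled to `nChroms`).
#' @param nGenes number of genes (placed without overlap).
#' @param geneLength c(min, max) gene length in bp.
#' @param promoterLength promoter window L in bp.
#' @param nPeakSets number of peak sets in the collection.
#' @param peaksPerSet peaks per non-planted set.
#' @param peakLength c(min, max) peak length in bp.
#' @param foregroundSize number of foreground (input-list) genes.
#' @param planted list of `list(name=, pFg=, pBg=)` entries naming the
#'   planted sets; `NULL` or empty for a null (no-signal) fixture.
#' @return A validated fixture specification (list, class "fixtureSpec").
#' @export
fixtureSpec <- function(seed = 1L, nChroms = 2L, chromLengths = 6e6,
                        nGenes = 2000L, geneLength = c(800L, 3000L),
                        promoterLength = 1000L, nPeakSets = 100L,
                        peaksPerSet = 1000L, peakLength = c(150L, 400L),
                        foregroundSize = 100L,
                        planted = list(list(name = "TF001_col",
                                            pFg = 0.5, pBg = 0.05))) {
  spec <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
               chromLengths = rep_len(as.numeric(chromLengths), nChroms),
               nGenes = as.integer(nGenes),
               geneLength = as.integer(geneLength),
               promoterLength = as.integer(promoterLength),
               nPeakSets = as.integer(nPeakSets),
               peaksPerSet = as.integer(peaksPerSet),
               peakLength = as.integer(peakLength),
               foregroundSize = as.integer(foregroundSize),
               planted = if (is.null(planted)) list() else planted)
  for (pl in spec$planted) {
    stopifnot(is.character(pl$name),
              pl$pFg >= 0, pl$pFg <= 1, pl$pBg >= 0, pl$pBg <= 1)
  }
  stopifnot(spec$nGenes > 0, spec$foregroundSize > 0,
            spec$foregroundSize < spec$nGenes,
            spec$geneLength[1] <= spec$geneLength[2],
            spec$peakLength[1] <= spec$peakLength[2],
            spec$promoterLength > 0, spec$nPeakSets >= 1)
  class(spec) <- "fixtureSpec"
  spec
}

peakSetNamesFor <- function(spec) {
  lib <- rep_len(c("col", "colamp"), spec$nPeakSets)
  nm <- sprintf("TF%03d_%s", seq_len(spec$nPeakSets), lib)
  for (pl in spec$planted)
    if (!pl$name %in% nm)
      stopUser("planted set '", pl$name, "' is not among the generated set ",
               "names (", nm[1], " ... )")
  nm
}

placeGenes <- function(spec) {
  # slot-per-gene placement guarantees non-overlap deterministically
  perChrom <- diff(round(c(0, cumsum(spec$chromLengths) /
                             sum(spec$chromLengths) * spec$nGenes)))
  chrom <- character(0); start <- integer(0); end <- integer(0)
  for (k in seq_len(spec$nChroms)) {
    n <- perChrom[k]
    if (n == 0) next
    slot <- floor(spec$chromLengths[k] / n)
    if (slot <= spec$geneLength[2] + 1)
      stopUser("genome too small to place ", spec$nGenes,
               " non-overlapping genes")
    glen <- sample(spec$geneLength[1]:spec$geneLength[2], n, replace = TRUE)
    off <- floor(runif(n, min = 0, max = slot - glen))
    s <- as.integer((seq_len(n) - 1) * slot + off + 1)
    chrom <- c(chrom, rep(sprintf("Chr%d", k), n))
    start <- c(start, s)
    end <- c(end, as.integer(s + glen - 1L))
  }
  strand <- sample(c("+", "-"), length(start), replace = TRUE)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand,
    seqinfo = GenomeInfoDb::Seqinfo(sprintf("Chr%d", seq_len(spec$nChroms)),
                                    as.integer(spec$chromLengths)))
  names(gr) <- sprintf("G%05d", seq_along(gr))
  gr
}

randomTrack <- function(spec, n) {
  chrom <- sample.int(spec$nChroms, n, replace = TRUE,
                      prob = spec$chromLengths / sum(spec$chromLengths))
  w <- sample(spec$peakLength[1]:spec$peakLength[2], n, replace = TRUE)
  start <- floor(runif(n, min = 1, max = spec$chromLengths[chrom] - w + 1))
  ord <- order(chrom, start)
  GenomicRanges::GRanges(sprintf("Chr%d", chrom[ord]),
                         IRanges::IRanges(as.integer(start[ord]),
                                          width = w[ord]))
}

plantedTrack <- function(spec, promoters, foreground, pFg, pBg) {
  ids <- universe(promoters)
  p <- ifelse(ids %in% foreground, pFg, pBg)
  pick <- runif(length(ids)) < p
  if (!any(pick)) return(GenomicRanges::GRanges())
  prom <- promoters[pick]
  pw <- GenomicRanges::width(prom)
  w <- pmin(sample(spec$peakLength[1]:spec$peakLength[2], length(prom),
                   replace = TRUE), pw)
  # peak placed fully inside the promoter window: a guaranteed hit
  start <- GenomicRanges::start(prom) +
    floor(runif(length(prom), min = 0, max = pw - w + 1))
  chrom <- as.integer(GenomicRanges::seqnames(prom))
  ord <- order(chrom, start)
  GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(prom))[ord],
    IRanges::IRanges(as.integer(start)[ord], width = w[ord]))
}

#' Simulate a fixture in memory
#'
#' Builds the annotation, promoter set, peak collection, foreground list
#' and truth record described by a [fixtureSpec()] without touching disk.
#' [generateFixture()] writes the same objects to files.
#'
#' @param spec a [fixtureSpec()].
#' @return A list with `spec`, `genes` (named `GRanges`), `promoters`
#'   ([PromoterSet-class]), `collection` ([PeakCollection-class]),
#'   `foreground` (gene ids), `truth` (data.frame name/pFg/pBg/planted),
#'   `chromSizes` (named integer vector).
#' @export
simulateFixture <- function(spec) {
  stopifnot(inherits(spec, "fixtureSpec"))
  genes <- withArtifactSeed(spec$seed, "genes", placeGenes(spec))
  promoters <- suppressWarnings(buildPromoters(genes, spec$promoterLength))
  foreground <- withArtifactSeed(spec$seed, "foreground",
                                 sort(sample(names(genes),
                                             spec$foregroundSize)))
  nm <- peakSetNamesFor(spec)
  plantedMap <- stats::setNames(spec$planted,
                                vapply(spec$planted, `[[`, character(1), "name"))
  families <- withArtifactSeed(spec$seed, "families",
    sample(c("WRKY", "NAC", "MYB", "bZIP", "AP2/ERF", "C2C2 (Zn)", "HD-ZIP",
             "B3-domain", "TCP", "GARP"), spec$nPeakSets, replace = TRUE))
  frips <- withArtifactSeed(spec$seed, "frips",
                            round(runif(spec$nPeakSets, 0.05, 0.5), 4))
  sets <- vector("list", spec$nPeakSets)
  for (i in seq_len(spec$nPeakSets)) {
    name <- nm[i]
    pk <- withArtifactSeed(spec$seed, paste0("peaks:", name), {
      if (name %in% names(plantedMap)) {
        pl <- plantedMap[[name]]
        plantedTrack(spec, promoters, foreground, pl$pFg, pl$pBg)
      } else {
        randomTrack(spec, spec$peaksPerSet)
      }
    })
    sets[[i]] <- PeakSet(name, pk,
      tfId = sprintf("AT%dG%05d", (i - 1) %% 5 + 1, 1000 + i * 10),
      tfFamily = families[i],
      sampleType = sub("^.*_", "", name),
      frip = frips[i])
  }
  truth <- data.frame(
    name = nm,
    pFg = vapply(nm, function(n)
      if (n %in% names(plantedMap)) plantedMap[[n]]$pFg else NA_real_,
      numeric(1)),
    pBg = vapply(nm, function(n)
      if (n %in% names(plantedMap)) plantedMap[[n]]$pBg else NA_real_,
      numeric(1)),
    stringsAsFactors = FALSE)
  truth$planted <- !is.na(truth$pFg) & truth$pFg != truth$pBg
  rownames(truth) <- NULL
  list(spec = spec, genes = genes, promoters = promoters,
       collection = PeakCollection(sets, versionLabel = "synthetic"),
       foreground = foreground, truth = truth,
       chromSizes = stats::setNames(as.integer(spec$chromLengths),
                                    sprintf("Chr%d", seq_len(spec$nChroms))))
}

#' Write a fixture to disk
#'
#' Emits exactly the formats the other modules consume: a GFF3 gene
#' annotation, a chromosome-sizes file, one BED per peak set, a collection
#' manifest TSV, the foreground gene list, and a truth TSV naming the
#' planted sets. Deterministic: the same spec yields byte-identical files.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if needed).
#' @return A list of file paths (`dir`, `gff3`, `chromSizes`, `manifest`,
#'   `geneList`, `truth`, `bedDir`) plus the in-memory `fixture`.
#' @export
generateFixture <- function(spec, dir) {
  fx <- simulateFixture(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bedDir <- file.path(dir, "peaks")
  dir.create(bedDir, showWarnings = FALSE)

  chromSizes <- file.path(dir, "genome.chrom.sizes")
  writeLines(sprintf("%s\t%d", names(fx$chromSizes), fx$chromSizes),
             chromSizes)
  gff3 <- file.path(dir, "genes.gff3")
  writeGenesGff3(fx$genes, gff3)
  geneList <- file.path(dir, "foreground_genes.txt")
  writeLines(fx$foreground, geneList)

  mf <- data.frame(
    name = names(fx$collection),
    tf_id = vapply(fx$collection@peakSets, tfId, character(1)),
    tf_family = vapply(fx$collection@peakSets, tfFamily, character(1)),
    sample_type = vapply(fx$collection@peakSets, sampleType, character(1)),
    frip = vapply(fx$collection@peakSets, frip, numeric(1)),
    bed_path = file.path("peaks", paste0(names(fx$collection), ".bed")),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mf)))
    writeBed(peaks(fx$collection[[i]]), file.path(dir, mf$bed_path[i]))
  manifest <- file.path(dir, "manifest.tsv")
  writeTsv(mf, manifest)

  truth <- file.path(dir, "truth.tsv")
  writeTsv(fx$truth, truth)

  list(dir = dir, gff3 = gff3, chromSizes = chromSizes, manifest = manifest,
       geneList = geneList, truth = truth, bedDir = bedDir, fixture = fx)
}

#' Simulate read intervals with a controlled in-peak fraction
#'
#' Places `ceiling(inPeakFraction * nReads)` reads overlapping a randomly
#' chosen peak (by at least 1 bp) and the remainder uniformly on the
#' genome, so [computeFrip()] on the output is at least `inPeakFraction`
#' (uniform reads may also land in peaks).
#'
#' @param peaks a `GRanges` of peaks (may be empty when
#'   `inPeakFraction = 0`).
#' @param chromLengths named integer vector of chromosome lengths, or a
#'   single unnamed length for a one-chromosome genome named "Chr1".
#' @param nReads number of reads (> 0).
#' @param inPeakFraction target fraction of in-peak reads.
#' @param readLen read length in bp (must fit on every chromosome).
#' @param seed RNG seed.
#' @return A `GRanges` of read intervals.
#' @export
generateReads <- function(peaks, chromLengths, nReads, inPeakFraction = 0.3,
                          readLen = 50L, seed = 1L) {
  if (is.null(names(chromLengths))) {
    stopifnot(length(chromLengths) == 1L)
    names(chromLengths) <- "Chr1"
  }
  stopifnot(nReads > 0, inPeakFraction >= 0, inPeakFraction <= 1)
  if (readLen > min(chromLengths))
    stopUser("read length ", readLen, " exceeds a chromosome length")
  if (inPeakFraction > 0 && length(peaks) == 0L)
    stopUser("cannot place in-peak reads: the peak track is empty")
  withr::with_seed(as.integer(seed), {
    nIn <- as.integer(ceiling(inPeakFraction * nReads))
    nOut <- nReads - nIn
    parts <- list()
    if (nIn > 0) {
      idx <- sample.int(length(peaks), nIn, replace = TRUE)
      pc <- as.character(GenomicRanges::seqnames(peaks))[idx]
      ps <- GenomicRanges::start(peaks)[idx]
      pe <- GenomicRanges::end(peaks)[idx]
      len <- chromLengths[pc]
      lo <- pmax(1, ps - readLen + 1)         # any start here overlaps >=1 bp
      hi <- pmin(len - readLen + 1, pe)
      start <- floor(runif(nIn, min = lo, max = hi + 1))
      parts$inPeak <- GenomicRanges::GRanges(pc,
        IRanges::IRanges(as.integer(start), width = readLen))
    }
    if (nOut > 0) {
      ci <- sample.int(length(chromLengths), nOut, replace = TRUE,
                       prob = chromLengths / sum(chromLengths))
      len <- chromLengths[ci]
      start <- floor(runif(nOut, min = 1, max = len - readLen + 2))
      parts$background <- GenomicRanges::GRanges(names(chromLengths)[ci],
        IRanges::IRanges(as.integer(start), width = readLen))
    }
    unname(do.call(c, unname(parts)))
  })
}
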