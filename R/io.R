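#' Read a BED track (3-6 columns)
#'
#' Tolerates `track`, `browser` and `#` comment lines and blank lines,
#' preserves input order, and retains the score column when present.
#' BED coordinates are 0-based half-open and are converted to the 1-based
#' closed convention of `GRanges` on read. Malformed coordinates raise an
#' error naming the offending line.
#'
#' @param path path to a BED file.
#' @return A `GRanges`, with a numeric `score` metadata column when the
#'   input has 5+ columns and a `name` column when it has 4+.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("track name=demo", "Chr1\t100\t200", "Chr1\t500\t650"), f)
#' readBed(f)
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stopUser("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  skip <- startsWith(lines, "track") | startsWith(lines, "browser") |
    startsWith(lines, "#") | !nzchar(trimws(lines))
  keep <- which(!skip)
  if (!length(keep)) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines[keep], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stopUser("BED line ", keep[which(nf < 3L)[1L]], " in ", path,
             " has fewer than 3 columns")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  startC <- vapply(fields, `[[`, character(1), 2L)
  endC <- vapply(fields, `[[`, character(1), 3L)
  start <- suppressWarnings(as.numeric(startC))
  end <- suppressWarnings(as.numeric(endC))
  bad <- is.na(start) | is.na(end) | start %% 1 != 0 | end %% 1 != 0
  if (any(bad))
    stopUser("non-integer coordinate at BED line ", keep[which(bad)[1L]],
             " in ", path)
  if (any(start < 0))
    stopUser("negative coordinate at BED line ", keep[which(start < 0)[1L]],
             " in ", path)
  rev <- start >= end
  if (any(rev))
    stopUser("start >= end at BED line ", keep[which(rev)[1L]], " in ", path)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  if (max(nf) >= 4L && all(nf >= 4L))
    gr$name <- vapply(fields, `[[`, character(1), 4L)
  if (max(nf) >= 5L && all(nf >= 5L)) {
    sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5L)))
    gr$score <- sc
  }
  gr
}

#' Write intervals as BED
#'
#' 0-based half-open on disk. Writes BED3 by default, BED5 when the ranges
#' carry `name` and `score` metadata columns, BED6 when `strand = TRUE`.
#'
#' @param gr a `GRanges`.
#' @param path output file path.
#' @param strand write the strand column (forces BED6).
#' @return The path, invisibly.
#' @export
writeBed <- function(gr, path, strand = FALSE) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  mc <- S4Vectors::mcols(gr)
  hasName <- "name" %in% colnames(mc)
  hasScore <- "score" %in% colnames(mc)
  if (hasName || hasScore || strand) {
    df$name <- if (hasName) as.character(mc$name) else "."
    df$score <- if (hasScore) mc$score else 0
  }
  if (strand) df$strand <- as.character(GenomicRanges::strand(gr))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a collection manifest
#'
#' A tab-separated table with columns `name`, `tf_id`, `tf_family`,
#' `sample_type`, `frip`, `bed_path`. `frip` may be empty/NA (the QC filter
#' then skips the FRIP criterion for that set, with a warning).
#'
#' @param path path to the manifest TSV.
#' @return A data.frame with one row per peak set.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stopUser("manifest not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "tf_id", "tf_family", "sample_type", "frip", "bed_path")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stopUser("manifest ", path, " lacks column(s): ",
             paste(miss, collapse = ", "))
  if (any(duplicated(df$name)))
    stopUser("duplicated peak-set names in manifest ", path)
  df$frip <- suppressWarnings(as.numeric(df$frip))
  df
}

#' Load a peak collection from a manifest
#'
#' Reads each listed BED track (paths resolved relative to the manifest's
#' directory unless absolute) and assembles a [PeakCollection-class].
#'
#' @param manifestPath path to the manifest TSV (see [readManifest()]).
#' @param versionLabel label for the collection.
#' @return A [PeakCollection-class].
#' @export
loadCollection <- function(manifestPath, versionLabel = "collection") {
  mf <- readManifest(manifestPath)
  base <- dirname(manifestPath)
  sets <- lapply(seq_len(nrow(mf)), function(i) {
    p <- mf$bed_path[i]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    st <- mf$sample_type[i]
    if (is.na(st) || !st %in% c("col", "colamp")) st <- "unknown"
    PeakSet(mf$name[i], readBed(p), tfId = mf$tf_id[i],
            tfFamily = mf$tf_family[i], sampleType = st, frip = mf$frip[i])
  })
  PeakCollection(sets, versionLabel = versionLabel,
                 provenance = list(manifest = manifestPath))
}

#' Read an input gene list
#'
#' One identifier per line; `#` comments and blank lines are ignored;
#' identifiers are trimmed and upper-cased; duplicates are collapsed.
#'
#' @param path path to the gene-list file.
#' @return Character vector of unique normalized gene ids.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stopUser("gene list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  ids <- normalizeGeneIds(lines)
  unique(ids[nzchar(ids)])
}

#' Read a key=value run-configuration file
#'
#' Lines of the form `key = value`; `#` comments ignored. Used by the
#' command-line interface; flags given on the command line override the
#' file.
#'
#' @param path path to the config file.
#' @return Named list of character values.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopUser("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)\\s*[=:]\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad))
    stopUser("unparseable config line in ", path, ": '",
             lines[which(bad)[1L]], "'")
  stats::setNames(
    lapply(kv, function(m) trimws(m[[3L]])),
    vapply(kv, function(m) m[[2L]], character(1)))
}
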