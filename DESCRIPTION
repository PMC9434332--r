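Package: peakRegulators
Title: Upstream Transcription-Factor Regulator Prediction from Peak-Set Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-list enrichment against collections of transcription-factor
    binding tracks (DAP-seq or ChIP-seq peak sets) to rank candidate upstream
    regulators of Arabidopsis-style gene lists. Builds strand-aware promoter
    windows from a GFF3 annotation, counts foreground/background genes whose
    promoters overlap each peak set, scores enrichment with a one-sided
    Fisher's exact test and Benjamini-Hochberg or Bonferroni correction, and
    reports a ranked regulator table plus a per-gene peak lookup mode. Also
    implements peak-set quality control (fraction of reads in peaks, minimum
    set size, IDR-versus-replica selection), pairwise track statistics
    (Jaccard, genomic co-localization Fisher test, mean peak length, peak-count
    change classes), a deterministic synthetic fixture generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
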