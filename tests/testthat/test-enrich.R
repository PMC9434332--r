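smallFixture <- function(seed = 5, ...) {
  simulateFixture(fixtureSpec(seed = seed, nGenes = 300, nPeakSets = 10,
                              foregroundSize = 40, peaksPerSet = 150,
                              chromLengths = 2e6, ...))
}

test_that("promoter-peak overlap uses half-open >= 1 bp semantics", {
  prom <- bedGR("Chr1", 500, 1000)
  names(prom) <- "G1"
  expect_identical(promoterHits(bedGR("Chr1", 999, 1200), prom), "G1")
  # touching at the half-open boundary is not an overlap
  expect_identical(promoterHits(bedGR("Chr1", 1000, 1200), prom),
                   character(0))
  expect_error(promoterHits(bedGR("Chr1", 0, 10), prom[0]), "empty")
})

test_that("one-sided Fisher p equals the hypergeometric upper tail", {
  expect_identical(fisherEnrichmentP(0, 10, 5, 20), 1)
  expect_equal(fisherEnrichmentP(5, 0, 0, 5), 1 / choose(10, 5),
               tolerance = 1e-12)
  # vectorized over tables
  expect_equal(fisherEnrichmentP(c(0, 5), c(10, 0), c(5, 0), c(20, 5)),
               c(1, 1 / choose(10, 5)), tolerance = 1e-12)
  expect_error(fisherEnrichmentP(-1, 1, 1, 1), "non-negative")
})

test_that("p-value adjustment matches the step-up/Bonferroni definitions", {
  expect_equal(adjustPvalues(0.03, "BH"), 0.03)
  expect_equal(adjustPvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjustPvalues(c(0.01, 0.5), "bonferroni"), c(0.02, 1))
  expect_error(adjustPvalues(c(0.5, 0)), "0, 1")
})

test_that("ranked output is deterministic and invariant to collection order", {
  fx <- smallFixture()
  res <- predictRegulators(fx$foreground, fx$promoters, fx$collection)
  expect_identical(res$rank, seq_len(length(fx$collection)))
  expect_true(all(diff(res$pAdj) >= 0))
  expect_true(all(res$pAdj >= res$pRaw))
  # a+b equals the foreground size everywhere
  expect_true(all(res$a + res$b == S4Vectors::metadata(res)$foregroundSize))

  perm <- sample(length(fx$collection))
  res2 <- predictRegulators(fx$foreground, fx$promoters, fx$collection[perm])
  key <- function(r) r[order(r$peakSet), c("peakSet", "pRaw", "pAdj", "rank")]
  expect_equal(as.data.frame(key(res)), as.data.frame(key(res2)))
})

test_that("a peak set with no hits anywhere gets p = 1 and cannot harm others", {
  fx <- smallFixture()
  # a collection of one set with zero promoter hits: p raw and adjusted 1
  far <- PeakSet("far", bedGR("Chr2", 10, 20))
  lone <- PeakCollection(list(far))
  res <- suppressWarnings(predictRegulators(fx$foreground, fx$promoters, lone))
  expect_identical(res$a[1], 0L)
  expect_equal(res$pRaw[1], 1)
  expect_equal(res$pAdj[1], 1)
  expect_identical(res$rank[1], 1L)

  # appending it to a real collection never changes any other raw p
  aug <- PeakCollection(c(fx$collection@peakSets, list(far)))
  resA <- predictRegulators(fx$foreground, fx$promoters, fx$collection)
  resB <- suppressWarnings(
    predictRegulators(fx$foreground, fx$promoters, aug))
  ord <- match(resA$peakSet, resB$peakSet)
  expect_equal(resA$pRaw, resB$pRaw[ord])
})

test_that("input normalization collapses duplicates and reports unknown ids", {
  fx <- smallFixture()
  fg <- fx$foreground
  messy <- c(tolower(fg), paste0(" ", fg, " "), "AT9G99999")
  expect_warning(res <- predictRegulators(messy, fx$promoters, fx$collection),
                 "absent from the universe")
  expect_identical(S4Vectors::metadata(res)$foregroundSize, length(fg))
  expect_identical(S4Vectors::metadata(res)$unmatchedIds, "AT9G99999")

  expect_error(
    suppressWarnings(predictRegulators("AT9G99999", fx$promoters,
                                       fx$collection)),
    "AT9G99999")
  expect_error(predictRegulators(universe(fx$promoters), fx$promoters,
                                 fx$collection),
               "whole universe")
})

test_that("per-gene peak lookup enumerates peaks and matches the hit sets", {
  prom <- buildPromoters(tinyAnnotation(), 500)  # G1: 501..1000
  setA <- PeakSet("A", bedGR("Chr1", c(520, 700, 3000), c(560, 760, 3100)),
                  tfId = "ATA")
  setB <- PeakSet("B", bedGR("Chr1", 900, 1100), tfId = "ATB")
  coll <- PeakCollection(list(setA, setB))
  pk <- upstreamPeaks("G1", prom, coll)
  expect_identical(length(pk), 3L)
  expect_identical(sort(unique(pk$peakSet)), c("A", "B"))
  expect_error(upstreamPeaks("NOPE", prom, coll), "NOPE")

  # consistency: a gene is a promoterHits hit for a set iff the lookup
  # returns at least one row for that set
  fx <- smallFixture()
  genes <- sample(universe(fx$promoters), 30)
  for (nm in names(fx$collection)[1:4]) {
    hits <- promoterHits(fx$collection[[nm]], fx$promoters)
    for (g in genes) {
      rows <- upstreamPeaks(g, fx$promoters, fx$collection[nm])
      expect_identical(g %in% hits, length(rows) > 0)
    }
  }
})

test_that("regulator-list overlap follows the Jaccard-style percentage", {
  mk <- function(sets, sig) S4Vectors::DataFrame(
    peakSet = sets, pAdj = ifelse(sets %in% sig, 0.01, 0.5))
  all <- c("w", "x", "y", "z")
  expect_equal(compareRegulatorLists(mk(all, c("x", "y")),
                                     mk(all, c("x", "y")))$overlapPercent, 100)
  expect_equal(compareRegulatorLists(mk(all, "x"),
                                     mk(all, "y"))$overlapPercent, 0)
  cmp <- compareRegulatorLists(mk(all, c("x", "y", "z")),
                               mk(all, c("y", "z", "w")))
  expect_equal(cmp$overlapPercent, 50)
  expect_identical(cmp$shared, c("y", "z"))
  expect_identical(cmp$nA, 3L)
  emp <- compareRegulatorLists(mk(all, character(0)), mk(all, character(0)))
  expect_equal(emp$overlapPercent, 100)
  expect_true(emp$bothEmpty)
})

test_that("results export as a stable ranked TSV", {
  fx <- smallFixture()
  res <- predictRegulators(fx$foreground, fx$promoters, fx$collection)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  writeResultsTsv(res, f1)
  writeResultsTsv(res, f2)
  expect_identical(readLines(f1), readLines(f2))
  tab <- read.delim(f1)
  expect_identical(tab$peak_set, res$peakSet)
  expect_identical(names(tab)[1:4], c("rank", "peak_set", "tf_id", "tf_family"))
})
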