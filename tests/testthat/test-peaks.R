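test_that("FRIP is the fraction of reads overlapping any peak by >= 1 bp", {
  peaks <- bedGR("c1", c(100, 500), c(200, 600))
  reads <- bedGR("c1", c(150, 190, 550, 580, 800, 900, 1000, 1100, 1200, 1300),
                 c(180, 250, 560, 650, 850, 950, 1050, 1150, 1250, 1350))
  expect_equal(computeFrip(reads, peaks), 0.4)
  expect_equal(computeFrip(reads, GRanges()), 0)
  expect_error(computeFrip(GRanges(), peaks), "empty")
})

test_that("FRIP matches a brute-force per-read scan and survives peak merging", {
  set.seed(21)
  for (rep in 1:3) {
    nR <- 1000; nP <- 80; G <- 100000
    reads <- GRanges("c1", IRanges(sample(1:(G - 100), nR), width = 75))
    peaks <- GRanges("c1", IRanges(sample(1:(G - 500), nP), width =
                                     sample(100:400, nP, TRUE)))
    naive <- mean(vapply(seq_len(nR), function(i)
      any(start(peaks) <= end(reads)[i] & end(peaks) >= start(reads)[i]),
      logical(1)))
    expect_equal(computeFrip(reads, peaks), naive)
    expect_equal(computeFrip(reads, mergeIntervals(peaks)),
                 computeFrip(reads, peaks))
  }
})

test_that("QC filter applies the FRIP and size thresholds with boundary semantics", {
  mk <- function(name, n, frip) makePeakSetOfSize(n, name, frip)
  coll <- PeakCollection(list(
    mk("lowFrip", 300, 0.005), mk("atFrip", 300, 0.01),
    mk("small", 150, 0.2), mk("atSize", 200, 0.2),
    mk("good", 500, 0.3)))
  out <- filterCollection(coll)
  expect_setequal(names(out$collection), c("atFrip", "atSize", "good"))
  expect_identical(out$removed$reason[out$removed$name == "lowFrip"],
                   "FRIP<0.01")
  expect_identical(out$removed$reason[out$removed$name == "small"],
                   "peaks<200")
  # idempotent: filtering the filtered collection removes nothing
  again <- filterCollection(out$collection)
  expect_identical(nrow(again$removed), 0L)
  expect_identical(names(again$collection), names(out$collection))
})

test_that("QC filter skips the FRIP criterion for sets without FRIP, with warning", {
  coll <- PeakCollection(list(makePeakSetOfSize(250, "noFrip", NA_real_)))
  expect_warning(out <- filterCollection(coll), "without FRIP")
  expect_identical(names(out$collection), "noFrip")
})

test_that("final-track selection follows the IDR-versus-replica rule", {
  mkRep <- function(name, n, frip) makePeakSetOfSize(n, name, frip)
  bundle <- function(nIdr, reps)
    ReplicaBundle(makePeakSetOfSize(nIdr, "idr"), reps)

  # IDR set with more than 2000 peaks wins outright
  s <- selectFinalPeakset(bundle(2500, list(mkRep("r1", 800, 0.02),
                                            mkRep("r2", 700, 0.09))))
  expect_identical(peakSetName(s$peakSet), "idr")
  expect_identical(s$decision, "idr-large")

  # 1500 >= 2 x 700: IDR set dominates the largest replica
  s <- selectFinalPeakset(bundle(1500, list(mkRep("r1", 700, 0.09))))
  expect_identical(peakSetName(s$peakSet), "idr")
  expect_identical(s$decision, "idr-dominant")

  # otherwise the maximal-FRIP replica wins
  s <- selectFinalPeakset(bundle(1500, list(mkRep("r1", 800, 0.02),
                                            mkRep("r2", 700, 0.09))))
  expect_identical(peakSetName(s$peakSet), "r2")
  expect_identical(s$decision, "replica-max-frip")

  # FRIP tie: larger peak count, then name order
  s <- selectFinalPeakset(bundle(100, list(mkRep("rB", 900, 0.05),
                                           mkRep("rA", 900, 0.05),
                                           mkRep("rC", 700, 0.05))))
  expect_identical(peakSetName(s$peakSet), "rA")

  # single replica with an empty IDR set
  s <- selectFinalPeakset(ReplicaBundle(makePeakSetOfSize(0, "idr"),
                                        list(mkRep("only", 50, 0.1))))
  expect_identical(peakSetName(s$peakSet), "only")
  expect_identical(s$decision, "single-replica")
})

test_that("interval merging is disjoint, sorted, bookend-merging and base-exact", {
  m <- mergeIntervals(bedGR("c1", c(100, 150), c(200, 250)))
  expect_identical(start(m), 101L)
  expect_identical(end(m), 250L)
  m2 <- mergeIntervals(bedGR("c1", c(100, 200), c(200, 300)))
  expect_identical(length(m2), 1L)
  expect_identical(end(m2), 300L)

  set.seed(33)
  lens <- c(c1 = 6000L, c2 = 4000L)
  for (rep in 1:3) {
    n <- 500
    ch <- sample(names(lens), n, TRUE)
    st <- sapply(lens[ch], function(l) sample.int(l - 100, 1))
    gr <- GRanges(ch, IRanges(st, width = sample(1:80, n, TRUE)))
    m <- mergeIntervals(gr)
    expect_true(all(width(m) > 0))
    expect_identical(m, sort(m, ignore.strand = TRUE))
    # disjoint and non-touching
    expect_true(all(countOverlaps(m, m, maxgap = 0L) == 1))
    # covers exactly the same bases as the input
    expect_identical(baseMask(m, lens), baseMask(gr, lens))
  }
})
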