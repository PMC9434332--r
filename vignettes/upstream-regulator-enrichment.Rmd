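---
title: "Predicting upstream TF regulators from peak-set collections"
author: "peakRegulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting upstream TF regulators from peak-set collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Transcriptome experiments routinely produce lists of co-regulated genes —
differentially expressed genes, cluster markers, pathway members. A
natural follow-up question is which transcription factors (TFs) sit
upstream of such a list. When genome-wide binding tracks (DAP-seq or
ChIP-seq peak sets) exist for hundreds of TFs, the question can be asked
statistically: are the promoters of the input genes overlapped by a TF's
peaks more often than the promoters of the remaining genes?

`peakRegulators` implements this enrichment procedure for collections of
peak tracks over an Arabidopsis-style genome annotation, together with
the quality-control steps such collections need (fraction of reads in
peaks, minimum set size, choosing between a replicate-merged track and
individual replicas) and the pairwise track statistics used to compare
collection versions.

## The model

Fix a promoter length $L$ and an annotation with $N$ genes that have a
non-empty promoter (the *universe*). The promoter of a gene is the $L$
bases strictly upstream of its transcription start site on its strand,
clipped to the chromosome; the TSS base itself is excluded. The input
list, intersected with the universe, is the *foreground* ($n$ genes);
the remaining $N - n$ genes are the *background*.

For one peak set, each gene either has at least one peak overlapping its
promoter (by $\ge 1$ bp, strand ignored, counted once however many peaks
fall there) or it does not, giving a $2 \times 2$ table

|              | overlap | no overlap |
|--------------|---------|------------|
| foreground   | $a$     | $b$        |
| background   | $c$     | $d$        |

with $a + b = n$ and $a + b + c + d = N$. Under the null hypothesis that
hit genes are distributed independently of the list, $a$ follows a
hypergeometric distribution with the table's margins, and the one-sided
Fisher exact p-value is the upper tail

$$p = P(X \ge a), \qquad
  X \sim \mathrm{Hypergeom}(N,\; a + c,\; n).$$

The test is run for every peak set in the selected collection and the
p-values are corrected for multiplicity across exactly those sets —
Benjamini–Hochberg FDR by default, Bonferroni as an option. Because the
correction spans the collection, the same track can change its adjusted
significance when the collection version (and hence the number of
simultaneous tests) changes; this is a property of the method, not an
artifact. Output is sorted by ascending adjusted p, ties broken by raw p
and then by track name, so runs are fully reproducible.

A second, non-statistical mode answers the converse question for a
single gene: which peaks, from which tracks, lie in its upstream region
(`upstreamPeaks()`).

### Sidedness

Enrichment is a one-sided question, so the default is the "greater"
tail. A two-sided option exists for users who also want significant
*depletion* to surface, but it is not the default because depleted
tracks are not candidate upstream regulators.

### The universe

The universe is whatever the supplied annotation contains after the
feature-type filter (default `gene`), minus genes whose promoter is
empty after clipping. Input identifiers absent from the universe are
dropped from both margins and reported, never silently kept. Matching is
case-insensitive after whitespace trimming, since locus identifiers are
conventionally upper-case but user lists vary.

## Peak-set quality control

Three rules clean a collection before testing:

* **FRIP** (fraction of reads in peaks): tracks with FRIP < 0.01 are
  removed. FRIP is computed from aligned-read intervals: a read counts
  as in-peak when it overlaps any peak by $\ge 1$ bp. Tracks with
  unknown FRIP skip this criterion with a warning.
* **Minimum size**: tracks with fewer than 200 peaks are removed. Both
  thresholds are boundary-inclusive for retention (FRIP exactly 0.01
  and exactly 200 peaks stay).
* **Replica selection**: when an experiment has a replicate-consistency
  (IDR) merged track plus individual replicas, the merged track is used
  if it has more than 2000 peaks or at least twice as many as the
  largest replica; otherwise the replica with the maximal FRIP is used.
  The FRIP tie-break (larger peak count, then name order) is this
  package's own choice, made so output is deterministic. The IDR model
  itself is out of scope; the selection rule consumes an already-merged
  track.

## Track comparison statistics

For comparing two collection versions track by track:

* **Jaccard**: shared covered bases over bases covered by either track,
  after merging each track to disjoint intervals. An empty union yields
  0 with a flag.
* **Co-localization Fisher test**: a $2\times2$ interval-level table:
  merged-A intervals hitting B ($n_{11}$), the remaining A intervals
  ($n_{12}$), merged-B intervals hitting A beyond those already paired,
  floored at zero ($n_{21}$), and the remaining genome capacity
  $n_{22} = \max(0, \lfloor G/\mu \rfloor - n_{11} - n_{12} - n_{21})$,
  where $G$ is the genome size and $\mu$ the mean length of the pooled
  merged intervals. The construction of such a table from interval data
  is genuinely under-determined — different toolkits differ in detail —
  so this package commits to the convention above, documents it, and
  always returns the table alongside the one-sided p-value so the input
  to the test is auditable. Numeric agreement with any external tool's
  variant is deliberately not claimed.
* **Change classes**: comparing peak counts between versions, a track is
  "New" when absent from the old version, "Increase"/"Decrease" when the
  count changed at least twofold (the exact $2\times$ boundary counts as
  a change; a track growing from 0 peaks classifies as "Increase"), and
  "Small changes" otherwise.

## Parameters that matter

| parameter | default | meaning |
|-----------|---------|---------|
| promoter length $L$ | 1000 bp | upstream window; 500–2500 bp in steps of 500 are the conventional choices, others are accepted with a note. 1000 bp is the middle of that range and a common choice for compact plant genomes. |
| correction | BH | FDR control across the collection; Bonferroni for strict FWER. |
| reporting cutoff | FDR < 0.05 | the usual screening threshold; affects reporting and list comparison only, never the statistics. |
| min FRIP | 0.01 | QC floor for track quality. |
| min peaks | 200 | QC floor for track size. |

## The synthetic benchmark generator

Real peak collections derive from large sequencing datasets that cannot
be bundled; the package therefore ships a deterministic generator
(`fixtureSpec()` / `simulateFixture()` / `generateFixture()`) that
emulates the *structure* of such data: a multi-chromosome genome,
non-overlapping genes on both strands, uniform random peak tracks, and
optionally *planted* regulators that drop a peak fully inside a gene's
promoter with probability $p_{fg}$ for foreground genes and $p_{bg}$ for
background genes. Planting fully inside the window makes recovery tests
sharp: a planted peak is a guaranteed hit at any compatible $L$.

The default specification is the condition used throughout the test
suite: 2000 genes (800–3000 bp) on two 6 Mb chromosomes, 100 foreground
genes, 100 tracks of 1000 peaks (150–400 bp), $L = 1000$, and one
planted regulator with $p_{fg} = 0.5$, $p_{bg} = 0.05$ — an effect size
chosen to emulate a genuine but imperfect regulator (half the input
genes carry a binding site; background binding is rare but present).
Each artifact draws from its own RNG stream keyed off (seed,
artifact-name), so identical seeds give byte-identical files and adding
an artifact never perturbs the others.

What the generator does **not** emulate: peak-length and peak-density
heterogeneity between TF families, GC/mappability biases, clustered
binding (peak hotspots), promoter-proximal peak enrichment, and any
sequence content. Passing the recovery and null-control tests therefore
demonstrates the statistical machinery is correct, not that any
particular biological collection is well calibrated.

## Numerical and degenerate-input choices

* All internal intervals are 1-based closed `GRanges`; BED input/output
  converts at the boundary. Overlap semantics ("$\ge 1$ bp", half-open
  touching is not an overlap) are identical in both conventions.
* $a = 0$ gives $p = 1$ exactly; the upper tail is computed via the
  hypergeometric distribution function, not by summing the pmf, for
  numerical stability at large margins.
* An empty foreground after normalization, or a foreground equal to the
  universe, is a hard error — both make the table degenerate.
* A collection whose every track has zero hits still returns a full
  ranked table (all $p = 1$); ranks remain a permutation of $1..K$.
* Duplicate gene identifiers in the annotation keep the first record
  with a warning (configurable to a hard error); duplicate input-list
  identifiers collapse to one.
* Promoters of neighbouring genes may overlap each other and gene
  bodies; no masking is applied.

## Problem sizes used by the validation suite

The test suite validates the Fisher tail against exhaustive
hypergeometric enumeration (all tables with total $\le 40$, plus 1000
random tables with margins up to 10,000), the BH/Bonferroni adjustments
against an independent step-up implementation, the overlap engine
against a naive all-pairs scan (200 random instances up to 1000
promoters × 5000 peaks), the Jaccard statistic against per-base boolean
masks on 10 kb toy genomes, and the replica-selection rule against an
independently coded predicate on 10,000 random bundles. Pipeline-level
behaviour is checked by planted-regulator recovery (100 seeds of the
default fixture; rank 1 at FDR < 0.05 required in at least 95) and a
null control (200 unplanted seeds; at most 10% of runs may report any
FDR < 0.05 track — a loose bound absorbing the discreteness of the
hypergeometric null). These sizes were chosen as the smallest that make
the checks sharp.

## Known limitations

* One promoter per gene, anchored at the gene-body 5′ boundary: no
  transcript-isoform TSSs, no alternative promoters. This matches the
  gene-level phrasing of list-enrichment practice but is a
  simplification for genes with distant alternative TSSs.
* The enrichment model treats genes as exchangeable; promoter length
  variation (clipping), GC content and mappability are ignored.
* Peak calling, read mapping, the IDR model, motif analysis and
  TF-family curation are out of scope; the package consumes called
  peak tracks.
* The co-localization table construction is a documented convention
  (see above), not a reimplementation of any specific external tool.
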