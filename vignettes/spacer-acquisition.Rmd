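---
title: "Detecting naive CRISPR spacer acquisition from amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting naive CRISPR spacer acquisition from amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaceracq)
```

## The problem

During naive CRISPR-Cas adaptation, the Cas1-Cas2 integrase inserts a new
spacer-plus-repeat unit at the leader end of a CRISPR array. In *E. coli*
assays this is read out in two complementary ways:

* **Gel densitometry.** PCR across the leader-proximal end of the array
  yields a parental product (C) and a one-unit-longer product (C+1);
  the fraction of expanded arrays is estimated from band intensities.
* **Amplicon sequencing.** The expanded (C+1) band is gel-purified and
  sequenced (2 x 150 paired-end). Each read that spans
  repeat-spacer-repeat reveals one acquired spacer, which can then be
  mapped back to the chromosome or the Cas1-Cas2 expression plasmid to ask
  where protospacers come from: chromosome vs plasmid, strand balance, and
  enrichment near the replication origin and terminus.

`spaceracq` implements the complete computational side of this readout,
plus a synthetic-data generator that produces references, expanded-array
amplicons and error-bearing reads with known ground truth, so that every
stage is testable without access to the original sequencing data.

## The pipeline and its rules

1. **Quality trimming.** Reads are truncated at the 3' end so that no
   retained base has Phred quality below 20. The literature this package
   follows states the threshold but not the algorithm; the default rule
   truncates at the first base with Q < 20 scanning 5' to 3', which is
   simple, deterministic and idempotent. A sliding-window alternative
   (`rule = "sliding"`, mean quality over complete windows of 4) is
   provided; windows shorter than the window size at the 3' end are not
   evaluated, which keeps that rule idempotent too.
2. **Repeat detection.** Every window whose Hamming distance to the CRISPR
   repeat is at most 2 is reported, on both orientations. `N` counts as a
   mismatch (conservative: low-quality tails cannot fabricate repeats).
   Overlapping candidate matches are resolved best-first: repeatedly keep
   the match with the fewest mismatches (ties broken leftmost) and discard
   matches overlapping it — physically, repeats in an array never overlap.
   Indel-tolerant matching is deliberately out of scope.
3. **Orientation.** A read whose matches are predominantly in
   reverse-complement orientation is reverse-complemented wholesale before
   extraction, so spacers are always reported in array orientation. Mates
   are processed independently; merging pairs is out of scope.
4. **Selection and extraction.** Only reads with two or more resolved
   repeats are kept ("filtered" is read as *filtered for*: a spacer needs
   two flanking repeats, and the next step extracts the sequence between
   them — the opposite reading would leave nothing to extract). The
   substring strictly between consecutive repeats becomes a candidate
   spacer. Candidates outside 20-50 nt (bounds configurable) or containing
   `N` are dropped and counted: over- and under-length gaps are PCR or
   chimera artifacts, and `N`-bearing spacers cannot be mapped
   unambiguously.
5. **Deduplication.** Statistics are computed over *distinct* spacer
   sequences — every spacer counts once, whatever its read support.
   Deduplication is identity-only; collapsing near-identical spacers that
   differ by sequencing errors is out of scope (at nonzero error rates
   identity dedup inflates the unique count, which the pipeline mitigates
   upstream: errored bases get low qualities and are trimmed away).
   Dedup is orientation-naive by design — strand is recovered at mapping.
6. **Hierarchical mapping.** Spacers are searched exactly, on both strands
   of both circular references (occurrences across the circular junction
   included; positions reported modulo length). Plasmid first: any plasmid
   hit assigns the spacer to the plasmid — "unique mapping for plasmid
   locations" is read as scoping *uniqueness* to the reported location, so
   a multi-hit plasmid spacer keeps its plasmid origin with the position
   withheld. Spacers absent from the plasmid map to the chromosome only if
   the hit is unique; multi-hit spacers are discarded as ambiguous, no-hit
   spacers as unmapped. Exact matching is the strictest reading of
   "mapped"; a Hamming tolerance is exposed (`max_mismatch`) for
   robustness studies only.
7. **Summaries.** Chromosome/plasmid origin fractions are computed over
   mapped spacers (ambiguous and unmapped excluded from the denominator,
   counts reported). Strand balance among chromosome-mapped spacers is
   tested with a two-sided exact binomial test against 0.5. Regional
   enrichment counts unique spacers in equal-width windows (default
   670 kb) around declared origin, terminus and CRISPR-locus positions and
   divides by the count in a reference window spanning coordinates
   0-670 kb.

### Regional enrichment details

Window coordinates are configuration: the source material fixes only the
window width (670 kb) and the reference span (0-670 kb), so windows are
built from user-declared centres (defaults use *E. coli* K-12 scale
coordinates: *oriC* near 3.93 Mb, *dif*/terminus near 1.59 Mb, CRISPR loci
near 2.89 Mb). A spacer is counted by its *start* position, in at most one
region; overlapping region definitions are rejected up front, and multiple
intervals sharing one name (e.g. two terminus arms) are summed before
normalization. The 95% interval on the ratio count/ref is the exact
Clopper-Pearson interval of the conditional proportion
k/(k + k_ref), transformed to the odds scale — closed-form, exact at the
small counts these windows produce, and easily testable.

### Gel quantification details

Percent acquisition is `100 * C1 / (C1 + C)`; it is scale-invariant, so
arbitrary densitometry units are fine. Background from the empty-vector
(pBad) lane of the *same strain and passage* is subtracted on the percent
scale by default (the alternative reading — subtracting intensities before
forming the percentage — is available via `on = "intensity"`); negative
corrected values are floored at 0 because a fraction of expanded arrays
cannot be negative. Replicates are summarized as mean and range (not SD):
the assay promises only "at least two" independent experiments, too few
for a meaningful SD. Image densitometry itself is out of scope; band
intensities enter as numbers (TSV).

## The synthetic-data generator

The generator emulates the structure of the real experiment:

* circular chromosome (default 4 641 652 bp, *E. coli* K-12 scale) and
  plasmid (default 6 600 bp, the scale of a pBad-based Cas1-Cas2 vector),
  pseudo-random with any exact repeat occurrence mutated away so repeat
  detection cannot fire on reference-derived sequence;
* acquisition events with configurable plasmid fraction (default 0.15,
  the midpoint of the reported 79-90% chromosomal range), strand balance
  (default 0.5, no bias) and per-region position weights (default 4x for
  origin and terminus windows, the reported 3-4x regime), so enrichment is
  planted *by construction* and parameter recovery can be tested;
* amplicons with the expanded-array structure
  leader-repeat-new spacer-repeat-ancestral spacer-repeat. The amplicon
  begins at the forward primer, taken to anneal 20 nt before the first
  repeat (`amplicon_leader_len`): with the default 29-nt repeat and 33-nt
  spacer this lets mate 1 span repeat-spacer-repeat within 150 nt, which
  the full 60-nt leader would prevent — by one base;
* 2 x 150 paired reads; the fragment is the whole amplicon when it is at
  most twice the read length (always, for these short PCR products).
  Substitution errors are injected per base (default 0.001) with a
  two-valued quality model: errored bases get Q11, clean bases Q37 —
  enough to exercise Phred trimming, with no claim to instrument realism.
  Sequencing depth defaults to one pair per amplicon, which makes
  error-free recovery deterministic; sampling with replacement at any
  depth is available via `n_read_pairs`.

The default repeat is the canonical 29-nt *E. coli* type I-E (CRISPR-1)
repeat; leader and ancestral-spacer defaults are fixed arbitrary strings.
All are configuration, not biology claims. What the generator does *not*
model: PCR bias and chimeras, indel errors, learned quality profiles,
multi-spacer acquisition in one array. A green end-to-end test therefore
establishes that the pipeline's logic is exact on structurally faithful
input — not that it is robust to every artifact of real libraries.

## Numerical and degenerate-case choices

* Coordinates are 0-based half-open internally; BED output matches.
* Both references are circular everywhere: searches scan the sequence
  extended by its first L-1 bases and report positions modulo length.
* A spacer's position is always its leftmost forward-strand coordinate,
  for both strands (ground truth uses the same convention).
* Zero-gap adjacent repeats emit no spacer but are logged; a reference
  window with zero spacers is an error (more data or a different window),
  as is a gel lane with both band intensities zero.
* Phred+64-looking FASTQ is rejected with an explanatory error rather
  than silently mis-decoded.
* Ties in overlap resolution go to the leftmost match, making the whole
  pipeline deterministic for a fixed input.

## Limitations

* Exact mapping means a single sequencing error in a retained spacer
  sends it to "unmapped" rather than to its true origin (quality trimming
  removes most such cases upstream).
* Identity-only dedup and no pair merging mirror the method being
  reimplemented, not best current practice.
* The enrichment statistic conditions on fixed windows; it does not
  discover hotspots, model Chi-site effects, or annotate PAMs.
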