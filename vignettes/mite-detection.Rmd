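---
title: "Structure-based MITE detection: model, thresholds, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based MITE detection: model, thresholds, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitescan)
```

## The detection model

Miniature inverted-repeat transposable elements (MITEs) are short
non-autonomous DNA transposons. `mitescan` detects them from structure alone:
an element body of 50–800 nt bounded by a terminal inverted repeat (TIR) pair,
flanked outside the body by a direct repeat of 2–10 nt (the target site
duplication, TSD) created on insertion. No homology library is used, so novel
families are found as readily as known ones; the trade-off is that structure
alone also matches chance sequence, which is why more than half of this
package is filtration.

### The complex-number screen

Each base maps to a unit complex number: A → 1, T → −1, C → *i*, G → −*i*.
The mapping is chosen so that Watson–Crick partners are negatives of each
other. If a right-hand window is the reversed complement of a left-hand
window, every aligned pair contributes a score and its negative, so the
combined statistic **C** (sum of both window sums) is 0; each
non-complementary pair shifts **C** by a vector of L1 norm exactly 2. The
screen keeps window pairs with |Re(**C**)| + |Im(**C**)| ≤ 2, i.e. at most
one mismatched TIR pair, and is evaluated for every span from prefix sums —
an exhaustive scan at a handful of vector operations per span.

The statistic is order-insensitive: an A↔A pair (+2) and a T↔T pair (−2) at
symmetric positions cancel, so the screen is a *necessary* condition only.
Every screened pair is re-checked position-wise (`verify_tir()`), counting
non-complementary aligned pairs directly; the screen prunes, verification
decides. The same reasoning fixes the screen tolerance at 2·m for m permitted
mismatches; both numbers are configuration fields (`score_tolerance`,
`max_tir_mismatch`).

TSDs are required to match as exact strings, not merely by equal window
score: equal complex sums only establish equal base multisets ("AT" vs "TA"),
and a direct repeat is a string property. When several TSD lengths qualify at
one locus the longest is reported — the maximal annotated structure, and a
deterministic tie-break. Bases outside {A,C,G,T} (and, with
`skip_masked = TRUE`, soft-masked bases) invalidate any candidate containing
them; no IUPAC expansion is attempted. Only the forward strand is scanned: a
TIR pair plus direct repeat is invariant under reverse complement, so a
reverse-strand scan finds the same loci (a property the test suite asserts).

Long chromosomes are scanned in chunks (`chunk_size`, default 1 Mb) with an
overlap of `max_len + 2·tsd_max`, which guarantees every element lies wholly
inside some chunk; chunked and unchunked scans are asserted to agree exactly.

### Filtration

Four rules remove the bulk of chance structure, each evaluated for every
candidate so the audit report attributes all failures:

* **TIR stretch** — an arm containing a period-1 or period-2 run of ≥ 8 nt
  (`min_stretch`). Both cases reduce to one autocorrelation test at lag 2; a
  stretch must lie within an arm — the arms are what define the element, and
  a repeat run crossing into the body is not a TIR property.
* **TIR composition** — each arm needs G+C ≥ 20% *and* A+T ≥ 20%
  (`min_comp_frac`); heavily skewed arms are indistinguishable from
  low-complexity background.
* **Body complexity** — normalized Lempel–Ziv (LZ76) complexity of the body
  (TIRs included, TSDs excluded) must reach `lz_threshold` = 0.675. The
  parser implements the exhaustive production history: a phrase extends while
  it can be copied (self-overlap allowed) from the preceding sequence, and
  the first non-copyable extension closes it; the final, possibly
  reproducible, phrase counts. The phrase count c(n) is normalized as
  c(n)·log₄(n)/n so uniform-random DNA approaches 1. Under this
  normalization a 100-nt homopolymer scores ≈ 0.066 and, empirically, over
  99.9% of uniform-random 300-mers score above 0.675 — the threshold passes
  essentially all genuinely complex bodies while rejecting repeat-driven
  candidates. Because several LZ variants and normalizations exist in the
  literature, both the parser variant (fixed) and the threshold
  (configurable) are documented here as this package's operating point, and
  the Monte-Carlo calibration is part of the test suite.
* **The TA rule** — a 2-nt TSD must be exactly `TA` (the Tourist/Stowaway
  insertion signature); dinucleotide direct repeats other than TA are too
  frequent by chance to be evidence of insertion. Longer TSDs are
  unconstrained.

### Clustering, flank validation, representatives

Mobility is the remaining evidence: a real MITE family has ≥ 3 full-length
copies. Candidates are clustered greedily, longest first; a candidate joins
the first family whose *seed* it matches at identity ≥ 80% of the shorter
sequence and coverage ≥ 99% of the longer (evaluated by end-gap-free global
alignment, match +1 / mismatch −1 / gap −2; all configurable). Seed-only
membership mirrors the greedy strategy of standard nucleotide clusterers,
keeps the partition deterministic, and makes every membership decision
re-checkable by a single alignment. An optional `cd-hit-est` backend maps the
same thresholds onto the external clusterer for cross-validation and falls
back to the internal one when the binary is absent.

Copy number alone is not enough: a segmental duplication carries a candidate
*with its flanks*. Within each family the 50-nt flanks outside the TSDs are
compared pairwise (left with left, right with right — never across); members
whose flank shares ≥ 25 aligned matching bases with a retained member
collapse to the first copy in genomic order. Genomic-order retention is a
deterministic stand-in for an unspecified "keep one" rule, and dropped
members do not disqualify later ones — with two similar pairs among five
members, exactly three survive. Flanks truncated by a contig end compare with
what remains and are therefore biased toward "divergent"; empirically, two
random 50-mers reach 25 alignment matches ~7% of the time, which is the
per-pair false-collapse rate this stage accepts. Families with < 3 surviving
members are discarded.

Each surviving family is represented by the member maximizing the summed
optimal local alignment score (match +2, mismatch −3, gap open −5, gap
extend −2) against all other members; ties break to the smallest
(seq_id, start). Sum versus mean is immaterial for the argmax at fixed family
size; the sum is used. A representative is a real genomic interval — unlike a
consensus it can be located in the genome exactly, which is the point of the
whole exercise.

## The synthetic-data generator

`generate_planted_genome()` plants families into uniform-random background:
per family a base element is constructed (random TIR arm passing the
composition/stretch rules, spacer resampled until the body clears the LZ
threshold, right arm the reverse complement of the left with a prescribed
number of substitutions, TSDs appended), and copies diverge by independent
spacer substitutions at 2% per base — comfortably inside the 80%/99%
clustering thresholds, approximating a young, active family. Placements are
non-overlapping with ≥ 2 flank-lengths of separation. Designed negatives
(2-copy families, identical-flank families, low-complexity bodies, non-TA
dinucleotide TSDs, 2-mismatch TIRs) exercise each rejection rule
individually.

The generator *guarantees* its truth table: after assembly, every planted
locus is re-scanned and must yield exactly the planted candidate after
filtration. This matters because a TA TSD is its own reverse complement, so
every planted element intrinsically admits slightly extended or contracted
TIR-pair geometries; whenever a chance direct repeat happens to flank one of
those geometries, a competing candidate appears and can displace a true
member during flank validation. The generator repairs such accidents —
point-mutating one background base inside the chance repeat, redrawing shared
flanks, or redrawing a family body that harbors an internal decoy structure —
until the locus is unambiguous. Within-family flank pairs are likewise
checked against the 25-match bar and redrawn on violation.

What the simulator does **not** emulate: nested or overlapping insertions,
TIR indels (outside the detector's model by design), GC-content and
repeat-density heterogeneity of real genomes, truncated or decayed copies,
and autonomous donor elements. Passing tests therefore demonstrate
correctness of the structural algorithm and its filters under the stated
model, not field performance on real chromatin — on real genomes the
candidate load and the behaviour of the complexity filter will differ.

## Numerical and engineering choices

* Internal coordinates are 1-based inclusive (the R/IRanges convention);
  all emitted formats are 1-based inclusive as well.
* The LZ76 parser runs in C++ (quadratic worst case, trivial at ≤ 800 nt
  bodies); the test suite holds it to exact agreement with a literal pure-R
  parser on 10,000 random strings, and the scanner to set-equality with a
  brute-force structural scanner on 100 random sequences.
* All alignments delegate to `Biostrings::pairwiseAlignment` (end-gap-free
  "overlap" type for identity/coverage/flanks, "local" for representative
  scores). Gap penalties follow the Biostrings convention (a gap of length L
  costs opening + L·extension).
* Determinism is a contract: candidates are pooled genome-wide and sorted
  canonically before clustering, output rows are ordered by
  (seq_id, start, end), logs carry no timestamps, and identical inputs
  produce byte-identical outputs.
* Problem sizes used by the validation suite: scanner/oracle equivalence on
  100 sequences of 0.2–2 kb; LZ calibration on 1,000 random 300-mers;
  recovery on one 200-kb genome with 10 families × 5 copies plus five 100-kb
  background-only genomes; determinism on a 50-kb instance. These sizes give
  non-vacuous candidate counts (hundreds of chance structures per run) while
  keeping the suite quick on one CPU.

## Known limitations

* TIRs containing insertions or deletions are invisible to the numeric
  screen — an inherent limit of the window-sum model.
* A single TIR length per scan (default 10 nt); elements whose arms diverge
  beyond one substitution in their terminal 10 nt are missed.
* The 50–800 nt bound applies to the element body (TIR start to TIR end),
  excluding TSDs.
* Flank validation is greedy in genomic order; when two members share a
  flank, which copy is kept is a convention, not an inference.
* No homology-based post-annotation: families are reported structurally and
  are not assigned to known superfamilies.
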