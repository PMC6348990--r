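---
title: "Building splicing regulatory maps from CLIP signal"
author: "splicemapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building splicing regulatory maps from CLIP signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicemapr)
```

# The problem

RNA binding proteins (RBPs) regulate alternative splicing in a
position-dependent way: the same protein can promote exon inclusion when
bound on one side of a splice site and exon skipping when bound on the
other. A *splicing map* summarizes this by averaging CLIP binding signal
over many alternatively spliced events after aligning each event to its
splice sites. `splicemapr` builds such maps from two inputs:

* differential-splicing event tables (rMATS `JunctionCountsOnly` format for
  SE, A3SS, A5SS, MXE and RI events, or minimal MISO-style SE identifiers),
  typically from an RBP knockdown RNA-seq experiment; and
* CLIP signal, either strand-specific read-density tracks (bigWig or
  bedGraph; IP and, ideally, a size-matched input) or significantly
  enriched peak intervals.

# Event handling

## Significance filter

Events are kept when `|delta Psi| >= 0.05`, `p <= 0.05` and `FDR <= 0.1`
(all three adjustable). Positive delta Psi (the rMATS
`IncLevelDifference`) means the exon is *more included upon knockdown*, so
"knockdown-excluded" sets are selected with `direction = "excluded"`.

## Deduplication

Splicing callers frequently report multiple overlapping "events" that share
junctions; averaging CLIP signal over all of them counts the same reads
several times and can fabricate peaks in the map. `deduplicate_overlapping()`
groups events by transitive overlap of their full genomic spans (same
chromosome and strand — signal extraction is stranded, so opposite-strand
events never merge) and keeps the event with the highest summed inclusion
junction count (IJC). The IJC aggregate sums every comma-separated replicate
value in both sample columns — the least lossy reading of "highest IJC".
Ties are broken by lexicographically smallest event id so the operation is
deterministic; it is idempotent and its output contains no overlapping
spans (both properties are tested on 1000 random fixtures).

## Background classes

Interpretation requires a background of non-responsive events.
`classify_background()` builds five sets from control-condition Psi values:

| class            | criterion (fraction of controls `>= min_fraction`, default 0.5) |
|------------------|------------------------------------------------------------------|
| constitutive     | Psi exactly 1 in *all* controls (exclusion never observed)       |
| native           | `0.05 < Psi < 0.95`                                              |
| native included  | native and `Psi > 0.67`                                          |
| native central   | native and `0.33 < Psi < 0.67`                                   |
| native excluded  | native and `Psi < 0.33`                                          |

The three subsets are defined as intersections with `native` so that the
containment invariant (every `native_*` event is native) holds even for
degenerate Psi vectors; an event may satisfy no class at all. Native
cassette exons are the recommended background: constitutive exons differ
systematically from alternative exons (size, splice-site strength,
conservation, baseline RBP binding), and comparing against them can mask
genuine enrichment at responsive events.

# Meta-event geometry

Each event is vectorized into splice-site-anchored windows of
`exon_offset` (50) exonic plus `intron_offset` (300) intronic nucleotides,
ordered 5' to 3' in transcript orientation (minus-strand events are built by
reflecting the event onto the plus strand and mapping positions back, which
makes the geometry exactly mirror-symmetric). Window counts per type:

* **SE** (4): upstream-exon 3' end, cassette 5' end, cassette 3' end,
  downstream-exon 5' end — 1400 positions under defaults (350 x 4).
* **A3SS** (3): flanking-exon 5' splice site, long-exon 3' splice site,
  short-exon 3' splice site.
* **A5SS** (3): long-exon 5' splice site, short-exon 5' splice site,
  flanking-exon 3' splice site. (The long-before-short order is a
  documented convention of this package; only the SE layout is fixed by
  common usage, and each window is independent of the others.)
* **RI** (2): the retained intron's 5' and 3' splice sites.
* **MXE** (6): upstream-exon 3' end, both ends of each mutually exclusive
  exon, downstream-exon 5' end.

For exons shorter than `2 * exon_offset` and introns shorter than
`2 * intron_offset`, signal is only counted until the boundary of the
neighbouring feature; positions beyond it are masked and excluded from all
denominators. Read literally, this rule lets the two windows that share a
short feature cover the same genomic positions within one event. That
default (`mask_mode = "boundary"`) is kept because it matches the published
procedure; `mask_mode = "midpoint"` instead truncates shared features at
their midpoint (the 5'-side window taking the ceiling half), which forbids
within-event double counting. Masked runs are always contiguous at window
edges, and positions before the chromosome start are clamped and masked.

# Signal and normalization

Density tracks are assumed RPM-scaled; the library size (`total_reads`) is
carried alongside so pseudocounts expressed in *reads* can be converted to
RPM. Negative-strand files commonly store negated values, so absolute
values are taken on load (`neg_values = "keep"` disables this). For
crosslink-resolution maps, `five_prime_collapse()` reduces each read to its
5' terminal position (interval start on `+`, `end - 1` on `-`), the
position where reverse transcriptase stops at the crosslink site.

Three density normalizations are available (`norm_method`, CLI codes 0/1/2):

* **raw** — IP density only, scaled per event exactly like subtraction with
  a zero input (so the two modes are directly comparable; `raw_unscaled`
  keeps plain RPM).
* **subtraction** (default) — per event, `d_i = IP_i - input_i`, then
  `out_i = d_i / (sum_j |d_j| + n_unmasked * pc)` with
  `pc = pseudocount_reads * 1e6 / ip_total_reads`. Scaling each event to
  (pseudocounted) unit absolute sum equalizes every event's contribution
  and prioritizes the shape of enrichment. The per-position pseudocount
  placement follows the stated procedure; `pc_per_position = FALSE` adds a
  single pseudocount instead (the two differ only in scale).
* **entropy** — the relative information `p_i * log2(p_i / q_i)`, where
  `p_i` and `q_i` are the fractions of total IP and input reads at the
  position. Pseudocount accounting: one read is added to each position in
  *both* libraries and each library total is incremented accordingly,
  `p_i = (count_i + pc) / (total + pc)` — symmetric treatment avoids a zero
  numerator as well as a zero denominator. Probabilities are computed from
  raw counts with library-total denominators ("fraction of total reads"),
  not from RPM. No per-event renormalization is applied, so events with
  high read density dominate — which is exactly why outlier trimming
  matters most in this mode.

In **peak mode**, intervals are filtered on the raw scale
(`p <= 0.001`, `fold >= 8` by default; the score columns carrying
`-log10 p` and `log2 fold` are configurable) and each position of each
event is scored 1 if it lies within a same-strand peak. The map value is
the fraction of events (with that position unmasked) containing a peak —
each event weighs equally and no further normalization is needed.

# Outlier trimming

Single events overlapping snoRNAs, miRNAs or other multicopy transcripts
can contribute enormous local signal and fabricate a peak in the averaged
map. At each position the `k = floor(n * (1 - conf) / 2)` largest and `k`
smallest non-missing values are dropped before averaging; the default
`conf = 0.95` keeps the middle 95% of values. With `n < 2 / (1 - conf)`,
`k = 0` and trimming is a no-op; positions with no survivors are recorded
as missing. The same trimming is applied to subtraction and entropy
outputs, inside each bootstrap permutation, and to both samples of the
position-wise KS test.

# Significance

* **Fisher exact** (peak mode): at each position, a two-sided exact test on
  the 2x2 table (test events with/without a peak vs background events
  with/without), missing entries excluded. The two-sided p sums the
  probabilities of all tables at most as probable as the observed one
  (verified against a hand-written hypergeometric enumeration to 1e-10 on
  all tables with margins up to 12).
* **Kolmogorov-Smirnov** (density mode): two-sample, asymptotic two-sided
  p, after trimming both samples. Exact small-sample p-values are out of
  scope (typical sample sizes are >= 50). KS tends to flag positions where
  *many* events shift slightly and to miss positions where a small subset
  changes dramatically, hence the bootstrap alternative.
* **Permutation bounds**: `n_permutations` (1000) samples of `n_test`
  background events with replacement; each is trimmed and averaged, and
  the per-position 0.5th/99.5th percentiles (type-7 interpolation) of the
  permutation means form the confidence envelope. One master seed drives a
  single R RNG stream, so results are bit-reproducible. Per-permutation
  trimming (rather than trimming the pool once) matches the stated order
  of operations. When several test conditions are shown together,
  `combine_condition_bounds()` takes the element-wise extrema — the
  conservative envelope. No multiple-testing correction is applied by
  default (maps display raw per-position significance); Benjamini-Hochberg
  can be applied downstream via `p.adjust` on the exported p-values.

The permutation kernel is implemented in C++ (Rcpp): per permutation it
gathers sampled rows and computes trimmed column means by partial
selection, which keeps 20 calibration replicates of 1000 permutations each
within a couple of minutes on one CPU.

# The synthetic study

`fixture_spec()` + `generate_events()` + `generate_coverage()` define the
self-contained study used by the tests:

* 100 test (knockdown-excluded) SE events and a background pool of
  `n_background = 5 x n_events` native-like events on one synthetic
  chromosome. The background is deliberately several-fold larger than the
  test set, mirroring real usage where native cassette-exon backgrounds
  (thousands of events) dwarf responsive sets; a bootstrap envelope drawn
  from a pool no larger than the test sample would be shifted by the
  pool's own sampling noise and over-reject under the null.
* exons 100–250 nt and introns 600–1500 nt (uniform), long enough that
  default windows are unmasked; events are placed disjointly so
  deduplication is a no-op by construction.
* per-nt Poisson(`baseline_rate = 1`) counts in both libraries — the
  simplest model of nonnegative sparse CLIP coverage; IP enrichment is
  multiplicative.
* planted enrichment centred 67 nt downstream of the cassette 5' splice
  site (a position reported as a regulatory hotspot for well-characterized
  splicing factors) with a triangular profile of half-width 10 nt (a 20-nt
  window approximating a crosslink pileup) and peak amplitude
  `planted_amplitude x baseline` (10), carried by `planted_fraction = 0.8`
  of test events — not every responsive event is directly bound. Peaks are
  emitted over the planted windows with scores passing the default
  thresholds.
* an optional single-event spike (1000x baseline) emulating a
  multicopy-RNA artifact; spike draws happen after all base draws so
  spiked and unspiked runs share identical base coverage.

What the generator does *not* emulate: read-length and crosslink-position
structure (coverage is per-nt independent), motif sequence content,
expression-level heterogeneity between genes, multimapping artifacts, and
correlated replicate structure. Tests passing on these fixtures therefore
demonstrate correctness of the pipeline's arithmetic and calibration under
a clean noise model, not robustness to every pathology of real eCLIP data.

Problem sizes used by the test suite and acceptance script — 100-event test
sets, 500-event backgrounds, 1000 permutations, 20 (tests) or 5 (script)
calibration seeds — were chosen as the smallest study at which the planted
offset is recovered within a few nt and the bootstrap calibration is
stable.

# Numerical choices and edge cases

* All intervals are 0-based half-open (`length = end - start`), matching
  rMATS `*Start_0base` columns and BED; `*End` columns are taken as
  half-open ends.
* Trim count `k` uses `floor`; ties in trimming resolve by sort order and
  never affect the mean. Bound percentiles use R's default (type 7)
  quantile interpolation.
* An all-masked event row normalizes to a missing row with a warning; a
  zero difference vector with zero pseudocount normalizes to zeros rather
  than NaN.
* Fisher positions with an empty margin and KS positions with fewer than
  two survivors record p = 1 with a warning rather than failing.
* Querying a position or chromosome absent from a track returns 0 (with a
  warning at matrix extraction for absent chromosomes).

# Known limitations

* Upstream processing (alignment, PCR deduplication, peak calling, Psi
  quantification) is out of scope; inputs are taken at face value.
* MISO support is a minimal SE-only identifier converter.
* Non-SE window anatomies are documented conventions — field usage for
  A3SS/A5SS/MXE/RI layouts varies and no single layout is canonical.
* The KS p-value is asymptotic; for very small event sets prefer the
  permutation envelope.
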