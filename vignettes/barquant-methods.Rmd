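---
title: "barquant: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{barquant: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barquant)
```

## The measurement problem

Chromosomal lineage barcoding labels every founding cell of a population
with a short random DNA tag -- here 25 random base pairs integrated at a
single site -- so that the abundance of each clonal lineage can be read
out over time by amplicon sequencing. The quantity of scientific interest
is the vector of barcode frequencies per sample; everything else
(merging, anchor matching, filtering) is instrumentation between raw
paired-end reads and that vector. `barquant` implements the full
instrumentation chain plus a ground-truthed simulator, so every step can
be validated against known inputs.

The sequenced molecule has the layout

```
[8N UMI] [heterospacer: 0/1/2 nt] [left flank ~120 bp] [25N barcode] [right flank ~120 bp]
```

read from both ends with 150-bp paired-end reads. The two conserved
flanks surround the barcode; the 8N unique molecular identifier (UMI,
"randomer") is attached by the first-round PCR primer, before
amplification, so distinct UMIs per barcode count founder molecules and
expose amplification bias. The heterospacer phase-shifts reads across the
flow cell and is mixed at lengths 0, 1 and 2. A `barcode_construct`
records this geometry; `example_construct()` ships a synthetic instance
with arbitrary screened flanks (they are not any real vector's sequence).

## The simulator and what it emulates

`generate_library()` draws distinct uniform-random barcodes and assigns
frequencies either uniformly or from a normalised lognormal. The default
is lognormal with `sigma = 1`: real transformation-derived libraries are
never flat, because colony counts per barcode, growth and pooling each
multiply in roughly independent factors.

`simulate_reads()` then emits read pairs with the noise structure of the
protocol:

* **Library skew** from the frequency model.
* **Template sampling.** By default (`n_molecules = NULL`) each read pair
  is an independent draw from the true frequencies. This is the deep-pool
  limit: nanogram-scale plasmid input corresponds to upward of 10^8
  template molecules, so the finite-pool bottleneck is negligible in a
  realistic prep. Setting a finite `n_molecules` instead routes reads
  through `simulate_pcr()`.
* **PCR bias.** `simulate_pcr()` runs an explicit Galton--Watson
  branching process: every copy duplicates with probability
  `pcr_efficiency` per cycle. Jackpots -- molecules lucky in early
  cycles -- emerge from the process itself rather than from an ad-hoc
  jackpot parameter; low efficiency with few molecules reproduces strong
  jackpot skew. Protocols keep total cycles at or below 18 because more
  cycles produce aberrant long amplicons; that failure mode is
  deliberately not modelled, it is what the protocol avoids.
* **UMIs.** In the finite pool every founder gets a distinct UMI (drawn
  without replacement; with 8N there are 65,536, which bounds
  `n_molecules`). In the deep-pool limit UMIs are i.i.d. draws -- the
  molecules are conceptually unbounded and per-barcode collisions at
  tested depths are negligible, so they are accepted as a small
  undercount rather than corrected.
* **Ancestral contamination.** With probability `ancestral_fraction` a
  template lacks the barcode segment entirely (residual non-barcoded
  vector). The default 0.01 matches the level observed in undigested
  libraries; an enzymatically digested library is below 1e-5 and can be
  simulated by setting the parameter accordingly.
* **Sequencing error.** Substitutions (default 1e-3 per base) and indels
  (default 1e-4) are applied per read. These defaults are user
  parameters in the spirit of short-read error rates, not claims about
  any particular instrument.
* **Qualities.** A deliberate two-tier model: faithful bases get Q37,
  miscalled or inserted bases Q14. This is the idealised limit in which
  base-caller confidence tracks miscalls; it is exactly the information
  the merger's higher-quality-base rule consumes, and extraction uses
  qualities nowhere else, so more elaborate quality realism would add
  parameters without exercising any additional code path. Consequently,
  consensus error correction in the overlap is *optimistic* relative to
  real data, where quality only correlates with error -- passing
  recovery tests here bounds what real data can achieve, it does not
  guarantee it.

The generator does **not** model chimera formation, polymerase slippage,
per-cycle PCR nucleotide errors (sequencing error subsumes them at the
rates involved), or quality-dependent error profiles along the read.

## Merging

`merge_pairs()` reverse-complements read 2, enumerates every
suffix-prefix overlap of length at least `min_overlap` (default 20), and
scores each by matching bases (`N` never matches and carries quality 0).
Candidates must satisfy `mismatches / overlap <= max_mismatch_frac`
(default 0.1); among the valid candidates the maximal score wins, ties
going to the longest overlap and then the smallest offset. This is a
score-and-threshold rule, a deliberate simplification of the statistical
overlap tests used by dedicated mergers; whether such a test would
change barcode counts on real data is untested here.

Consensus takes the higher-quality base and its quality. Equal-quality
disagreements keep read 1's base with quality `max(q1, q2) - 3`: the
choice is arbitrary but deterministic, and the penalty flags the
uncertainty. At the default geometry (~273-bp template, 2x150 reads) the
physical overlap is ~25-27 bp, comfortably above `min_overlap`; for
longer amplicons where no overlap exists, `run_pipeline()` falls back to
read 1 alone as the extraction substrate (on by default), since a
barcode near the 5' end is reachable from a single read.

## Extraction

Orientation and extraction use 12-bp flank anchors (the left flank's
last 12 bases and the right flank's first 12), allowing 1 mismatch by
default: a 12-mer is effectively unique in a ~300-bp amplicon and one
mismatch tolerates the per-base error rate without opening the door to
spurious hits. Matching is a Hamming-window scan over all offsets; an
offset-free scan already absorbs indels outside the anchor, and indels
inside a 12-bp window are rare at the modelled rates.

Two tie-break decisions protect closure properties at scale:

* **Orientation.** The left anchor is scanned on both strands; the
  strand with the better score wins. On an exact tie the right anchor is
  consulted, and only a double tie is reported `ambiguous_strand` (such
  reads are discarded, never guessed). Without the second-anchor step, a
  chance exact 12-mer inside the random barcode on the opposite strand
  (~1e-6 per read) would sporadically poison otherwise perfect runs.
* **Right anchor position.** Among minimal-mismatch occurrences
  downstream of the left anchor, the one whose implied barcode length is
  closest to the expected length is chosen, so a chance 12-mer hit
  *inside* the barcode cannot truncate the extraction.

The barcode is the substring strictly between the anchors. Reads where
only one anchor is found are rejected (`no_left_anchor` /
`no_right_anchor`) rather than extended to the read end, which would
inflate length-filter failures with truncated barcodes. The UMI is
recorded only when the prefix upstream of the left flank has length
`umi_len` plus a configured heterospacer length; a missing UMI never
fails a read. The paper-style mapping route (a reference with an
N-filled barcode, `build_reference()`, and a mapping-quality floor) is
represented by the anchor method plus an optional mean-barcode-quality
floor (`min_merge_quality`, default off); no external mapper is wrapped.

`length_filter()` keeps `ok` observations, whose length lies within
`barcode_len +/- len_tol` (23-27 bp at defaults), and reports the
length histogram over every observation where a barcode was found,
including `bad_length` ones -- that histogram is the length-spectrum
analysis, and ancestral templates appear in it as length-0 extractions.

## Counting, UMI collapse and clustering

`count_barcodes()` tallies exact strings; frequencies are computed after
the length filter, on kept reads. `umi_collapse()` counts distinct UMIs
per barcode and attaches the read/molecule ratio distribution as the
amplification-bias report.

`cluster_barcodes()` is explicitly an extension -- the default analysis
works on raw barcodes -- and uses a deterministic directional rule:
processing barcodes by decreasing count (ties lexicographic), a barcode
joins a cluster when some member is within `max_dist` edit distance
(default 2) and the cluster's accumulated count is at least
`count_ratio` (default 5) times its own. Member-linkage matters: a
two-error variant typically sits within distance 2 of an absorbed
one-error variant even when it is distance 3 from the seed, so error
chains collapse onto the true barcode. Passes repeat until the table is
stable, making the operation idempotent; totals are conserved by
construction. The quadratic distance matrix makes this appropriate for
thousands of distinct barcodes, not hundreds of thousands; probabilistic
error-channel models and cross-sample clustering are out of scope.

## Assessment battery

* `replicate_intersections()` -- exact subset membership counts over the
  barcode union (UpSet tabulation); the subset counts always sum to the
  union size.
* `pairwise_frequency_correlation()` -- Pearson r of frequency vectors.
  The scope question (shared barcodes vs the union with zeros) is
  genuinely open for published replicate comparisons, so both scopes are
  computed; `assess_replicates()` reports shared by default and attaches
  the union figure whenever the two differ by more than 0.01. Zero
  variance is reported as undefined, not as `NaN`.
* `diversity_metrics()` -- Shannon entropy in nats, evenness
  `H / ln(richness)` (defined for at least two barcodes), and the
  maximum frequency. Nats convert to bits by dividing by `ln 2`.
* `frequency_trajectories()` -- union-by-time frequency matrix in long
  format, absences imputed as 0 frequency rather than a pseudo-count;
  fitness inference, which would need pseudo-counts, is out of scope.

## Replicate-concordance study conditions

The replicate-mirror check in the acceptance suite correlates two
independently sequenced replicates of one library at depth 5e5 and
requires r >= 0.999. The library dispersion for that study is lognormal
`sigma = 2`, and the value is derived, not tuned: with N barcodes at
depth D, sampling noise alone caps the expected Pearson r near
`1 / (1 + N / (CV^2 D))`. Near-perfect correlations over ~1.8e5 barcodes
at ~1.5e6 reads -- the regime reported for real replicate libraries --
therefore imply a frequency coefficient of variation of at least ~5,
i.e. lognormal sigma around 2. At the generic default `sigma = 1` the
same expression caps r at ~0.9988 regardless of implementation quality,
so the mirror uses the dispersion the observed concordance implies.

## Numerical and degenerate-input choices

* Quality encoding is fixed to phred+33; input that looks phred+64 (a
  majority of quality characters above `'J'`) is rejected with a
  message, never silently converted.
* Frequencies are written at 17 significant digits so count tables
  round-trip below 1e-15; the contract only requires 1e-9.
* An empty observation set counts to an empty table (not an error);
  diversity of an empty table *is* an error, as is intersecting fewer
  than two tables.
* Collisions while drawing a library are resolved by bounded redraws and
  only matter for toy barcode lengths, where generation refuses to run.
* All stochastic stages consume R's RNG only (including the C++ error
  model), so a single `seed` makes every output bit-reproducible.

## Problem sizes used by the test suite

Unit tests run on a 30-bp-flank construct with 60-bp reads to keep them
instant. The end-to-end property tests use the full-geometry
`example_construct()` at the sizes the properties are stated for: 1e5
pairs for closure, ancestral-rate and clustering-recovery checks, 5e5
pairs for frequency recovery and per-replicate depth, 1e4 instances for
the merge oracle and strand invariance. `scripts/acceptance.R` re-runs
the same studies from scratch and writes the resulting figures as JSON.

## Known limitations

* The anchor scan is substitution-only within the 12-bp window; an indel
  inside an anchor costs the read (rejected, not mis-extracted).
* Overlap scoring is ungapped, so an indel inside the physical overlap
  region degrades that pair's consensus rather than being realigned.
* Barcodes are extracted only from merged reads or read 1; discordant
  unmerged pairs are not rescued.
* UMI collisions are accepted as undercount; with 65,536 possible UMIs
  this is negligible at tested depths but would not be at much greater
  per-barcode molecule counts.
* The directional clustering choice (distance 2, ratio 5, member
  linkage) is one defensible resolution of an intentionally open design
  point; published pipelines differ, and no claim is made that it
  matches any of them.
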