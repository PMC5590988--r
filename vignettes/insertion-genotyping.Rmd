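---
title: "Insertion genotyping by gap filling on de Bruijn graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insertion genotyping by gap filling on de Bruijn graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Resequencing projects call variants by aligning donor reads to a reference.
Insertions are the hardest structural variant to genotype because the
inserted sequence does not exist in the reference: it must be assembled
from the reads.  `insfill` assumes the *location* of each insertion is
already known (breakpoint detection is a separate problem) together with a
length estimate, typically inferred from paired-end insert sizes, and
reconstructs the inserted sequence itself.

The key observation is that this is exactly the *gap filling* problem from
de novo assembly: treat the reference as an assembly with a gap of the
estimated length `d` at the breakpoint, and fill it.  Filling every
insertion site this way reconstructs the donor genome.

## The model

### De Bruijn graph

The reads are summarized as a k-th order de Bruijn graph `G = (V, E)`:
vertices are the k-mers present in the reads, and a directed edge connects
`v` to `v'` whenever the (k+1)-mer `v + last(v')` was observed.
Consecutive vertices overlap by `k - 1` bases, so a path of `n` vertices
spells `k + n - 1` bases.  Two practical choices:

* **Reverse complements.** Sequencers read both strands, so by default
  every read's reverse complement is added before k-mer extraction.  The
  graph stays a plain directed graph (no canonical-k-mer collapsing),
  which keeps the path-length dynamic program stated on the graph as-is.
  A flag disables the augmentation for controlled experiments.
* **Abundance threshold.** `min_abundance` drops k-mers (and (k+1)-mers)
  seen fewer times.  The default of 2 removes singleton k-mers created by
  sequencing errors without touching genuine 30x signal; error-free
  simulations use 1 so that even singly-covered positions stay in the
  graph.  Reads are split at ambiguous bases, so no k-mer spans an N.

`k` is capped at 31 so a (k+1)-mer packs into a 64-bit word; `k = 31` is
the default and the value used throughout the experiments.

### The path-length dynamic program

Given source and target k-mers `s`, `t` and an accepted cost interval
`[d'..d]` (unit cost per edge, so cost = spelled extension), the solver
fills `M[v][i]` = number of walks from `s` to `v` of cost exactly `i`,
layer by layer up to the largest accepted cost.  Any `i` in `[d'..d]` with
`M[t][i] > 0` admits a witness path recovered by walking backwards through
positive table entries.

Determinism and robustness choices:

* Counts are *walk* counts (vertices may repeat), matching the recurrence;
  they saturate at `2^31 - 1` because only positivity is needed for
  traceback.  The saturated total over accepted costs is reported as
  `n_paths`; `n_paths == 1` certifies that the fill is the unique
  sequence of acceptable length spelled by the reads.
* Among accepted costs, the one closest to the interval midpoint is taken
  (ties to the smaller cost): the midpoint of the interval is the length
  estimate itself.
* At each backward step the lexicographically smallest predecessor k-mer
  is chosen, making results reproducible.
* The table is stored sparsely per cost layer; only reachable `(v, i)`
  pairs materialize, and the computation is capped at `max_cost` layers
  (default: the largest accepted cost), which bounds work when the target
  is unreachable.

A pure-R implementation of the same dynamic program over explicit edge
lists (`count_paths()` / `traceback_path()` / `spell_path()`) is exported
for inspection and serves as a cross-check of the compiled solver in the
test suite.

### Gap filling with flank errors

The flanks adjacent to a breakpoint may themselves carry errors or
overlapping variation, so the source and target k-mers are additionally
tried at offsets up to `fuzz` bases *into* each flank (default 10).  With
source offset `a` and target offset `b`, a path of cost `c` spells
`m = c - k - a - b` bases strictly between the original flank boundaries;
the solver accepts `m` within `est_length ± slack` and therefore searches
costs `c` in `[d - slack + k + a + b, d + slack + k + a + b]`.  This
arithmetic is the only one consistent with the `k - 1` overlap of
consecutive vertices.  Offsets are searched in the deterministic order
`a + b` ascending, then `a` ascending, returning the first success;
offset-skipped flank bases are re-spelled from the path (i.e. from the
reads), not from the possibly erroneous flank, but only the bases strictly
between the original boundaries are reported as the insertion.  Offsets
search *inward* only; extending outward would re-spell reference sequence
the caller already trusts.

The default slack is `max(10, ceil(0.1 d))` nt: wide enough to absorb the
noise of insert-size-based length estimates, narrow enough to keep the
layer count (and false-length paths) small.  Because nonzero offsets
raise the largest accepted cost by `a + b`, the default `max_cost` is
`d + slack + k + 2 fuzz`.

## Read filtering

Building the graph from *all* reads works, but for long insertions the
genome-wide graph becomes tangled and fills fail; restricting each site's
graph to reads that plausibly cover it is what makes genotyping long
insertions work.  A read is selected when

1. it is mapped and overlaps the gap interval by ≥ 1 bp, or
2. it is unmapped and its mapped mate starts inside one of the mate
   regions
   `S_left = [s - (max + 2l) .. e - (min + l)]`,
   `S_right = [s + (min + l) .. e + (max + l)]`,

where `l` is the read length and `[min, max]` bound the insert size at the
two-sided 95% level, `mu ± 1.96 sigma`.  Coordinates are clamped at 0; an
interval inverted after clamping is empty.  Orientation is ignored — the
formulas are orientation-free — and pairs with both ends unmapped are
reachable only through the fallback below.

**Insert-size convention.** In this package the insert size is the *inner*
mate distance (fragment = insert + 2 read lengths).  This is the
convention under which the mate-region formulas are exact: expanding
"mate interval overlaps `[s..e]` and insert within `[min, max]`" yields
precisely the printed intervals.  Under the outer-fragment reading the
same formulas are misaligned by about two read lengths, which measurably
collapses filter recall; the test suite exploits the exactness by
asserting recall 1.0 on the provably covered pairs (read starting inside
the gap, mate mapped, realized insert within bounds).

**Coordinates.** Alignments are against the reference, but the formulas
live on a reference with a gap of length `d` opened at the breakpoint, so
coordinates at or beyond the breakpoint are shifted by `d` (exclusive end
coordinates only when strictly beyond) before filtering.  Everything
internal is 0-based half-open; VCF I/O converts from/to 1-based.

**Unmapped-read fallback.** Reads inside a long insertion are unmapped and
their mates may be too, so the filter can come up short.  Selection
quality is monitored through fold coverage: selected reads × `l` over the
gap extended by `l` on each side (reads partially overlapping still
contribute).  If it falls below a threshold, all unmapped reads are added.
The threshold should be close to but below the library coverage —
`floor(0.85 × coverage)` by default (25 at 30x), 25 when coverage is
unknown.  The reported `realized_coverage` stays the pre-fallback value,
since post-fallback coverage over one region is not meaningful for a
genome-wide unmapped set.

A GapFiller-style baseline (all unmapped reads whose mate aligns within a
maximum distance of the gap, default `max_insert`) is provided for
evaluation comparisons.

## Evaluation

Calls are scored by normalized edit distance,
`Score(output, correct) = ed(output, correct) / |correct|`: 0 is a perfect
reconstruction; an ungenotyped insertion is scored as an empty output, so
its score is exactly 1.  The denominator is always the truth length, so
the score is asymmetric and can exceed 1 when the output is longer than
the truth.  Filtering is evaluated by precision and recall against the
reads that truly overlap each insertion; empty denominators yield `NA`
rather than 0.

## The simulator

`simulate_insertion_dataset()` generates the entire study world from one
seed: a uniform-random reference, insertions of uniform random length
planted at breakpoints kept `2 (mu + 2l + 4 sigma)` apart (rejection-free
placement via compacted-space sampling) so neighbouring filter regions do
not interact, error-free-by-default paired reads with Normal insert sizes,
and *truth-mode alignments* — alignment records projected from the known
read positions, in which any read crossing a breakpoint or inside an
insertion is unmapped.  Truth mode is a conservative stand-in for a real
aligner (which would soft-clip some crossing reads rather than drop them)
and requires no external tools.

What the simulator does not emulate: indel or quality-profiled sequencing
errors (substitutions only, uniform), coverage biases, diploidy or
heterozygous sites, repeats (the reference is i.i.d. random, so k-mer
repeats are essentially absent at `k = 31`), and other variant classes
overlapping the flanks.  Consequently, passing tests demonstrate the
correctness of the machinery and the behaviour of the filter under the
stated model, not performance on repetitive real genomes.

## Problem sizes used in the checks

The acceptance suite runs the full protocol at desk scale: a 1 Mb
reference with 100 insertions of 10–1000 nt, 30x error-free 100 bp pairs
with `mu = 1500`, `sigma = 150`, `k = 31`, threshold 25 — about half a
minute end to end — and requires ≥ 90% of the sites with a certified
unique fill (`n_paths == 1`) to be reconstructed with score 0.  The filter
experiment uses a 400 kb reference with 40 insertions and the short-insert
`mu = 150`, `sigma = 15` library, asserting recall 1.0 on the provably
covered pairs and decaying overall recall once insertions outgrow the
insert size.  The path-counting solver is checked against exhaustive walk
enumeration on 100 random graphs of up to 8 vertices and cost 10.

## Known limitations

* Heterozygous insertions are not modelled: one haplotype is assembled.
* The length estimate gates the search; a grossly wrong `d` (beyond
  `slack`) makes the true fill unreachable by construction.
* `n_paths > 1` signals ambiguity but the reported sequence is still just
  one witness path; no per-base safety classification is attempted.
* Repeat-induced cycles can inflate walk counts up to the saturation cap;
  counts are reliable as "0, 1, or many".
* Breakpoints closer than `k + fuzz` to a contig end cannot be genotyped.
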