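---
title: "Quantifying feature barcodes with a single-base mismatch map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying feature barcodes with a single-base mismatch map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbquant)
```

## The problem

Feature-barcode assays attach a short designed oligonucleotide to an
orthogonal feature — an antibody, a sample hashtag, an sgRNA — and read it
out in one mate of a paired sequencing read while the other mate carries
the cell barcode and UMI. Quantification must cope with three
complications at once: the tag's position in the read varies (flanking
adapter or vector sequence shifts it), the tag's bases carry substitution
errors, and PCR duplicates inflate raw read counts. fbquant addresses
each with, respectively, window scanning, a single-base mismatch map, and
UMI deduplication.

## The mismatch map and its collision policy

For a whitelist of $n$ barcodes of uniform length $L$,
`build_mismatch_map()` expands each barcode into itself plus its $3L$
single-base substitution variants, each labelled with its parent — at
most $n(3L + 1)$ entries. A lookup in this map implements maximum-
likelihood 1-substitution correction: under any per-base error model the
most probable origin of an observed sequence at Hamming distance 1 of a
single parent is that parent.

Two kinds of collisions arise, and both are resolved conservatively so
that no retained sequence is claimed by two parents:

* a variant equal to **another parent's exact sequence** is removed from
  the generating parent's variant set (the exact sequence always maps to
  its own parent — an error-free read must never be reassigned);
* a variant **generated by two or more parents** is removed entirely.
  Discarding rather than majority-voting keeps assignment deterministic
  and order-independent; the observable effect is the same as a
  multi-mapping read being dropped.

A parent pair at distance $d \le 2$ necessarily loses variants
(distance-1 neighborhoods of the pair intersect exactly when $d \le 2$),
so map construction warns in that case. Exhaustive enumeration over all
$4^L$ sequences for small $L$ verifies, in the test suite, that
membership equals the brute-force rule "exact match wins, else unique
distance-1 parent".

Variants are substitutions only; indel-tolerant matching is out of scope,
consistent with correcting mismatch errors only. Variant order is
deterministic (position-major, then alphabetical substitute base) so the
serialized mismatch FASTA (`>{parent}` / `>{parent}-{pos}.{base}`
headers, 0-based positions) is byte-reproducible.

## Scanning and the choice of window length

`scan_read()` looks up every length-$L$ window of the trimmed tag read
(windows containing non-ACGT characters never match). Window length
equals tag length: this is the only choice under which exact-lookup
scanning is equivalent to distance-$\le 1$ matching of the whole tag, and
it sidesteps any separate k-mer parameter. A read whose windows hit one
distinct parent is assigned; two or more parents, ambiguous; none,
unassigned. Ambiguous reads are discarded rather than resolved — a
declared policy favouring determinism over yield.

Tie-breaks within an assigned read: the reported window is the leftmost
one, preferring exact-sequence windows over variant windows (the designed
tag position is the more plausible origin) and the forward strand over
the reverse. `n_mismatches` is 0 when any hit window equals the parent
sequence. Reverse-complement scanning is off by default because tag reads
are sequenced in a known orientation in the assays this package targets;
`revcomp = TRUE` (CLI `--revcomp`) enables it.

Trimming happens before scanning: the first exact occurrence of an
optional anchor sequence splits the read (keeping the flank the layout
names; reads without the anchor are discarded), then fixed 5′/3′ trims
are applied. Trimming matters when barcodes share subsequences with each
other *and* with the constant sequence flanking them — the window scan
then hits two parents and loses the read, as the worked example in the
README shows on the bundled synthetic Multiseq-style design.

## Cells, UMIs and the count matrix

Cell barcode and UMI are taken from fixed 0-based half-open spans of read
1. Cell barcodes containing N are discarded; UMIs may contain N (they
deduplicate as literal strings — an N-containing UMI can only collide
with itself). With an on-list, a cell barcode is kept if exact, corrected
if exactly one on-list member lies at distance 1, and discarded
otherwise. Quality strings are ignored throughout: the method uses no
base-quality information.

Deduplication collapses identical (cell, UMI, feature) triples; a (cell,
UMI) pair observed with two distinct features is dropped entirely
(conservative and permutation-invariant, unlike majority voting). The
matrix entry $(i, j)$ is therefore the number of distinct UMIs for cell
$i$ and feature $j$; rows are lexicographically sorted cells, columns
follow whitelist order, and the serialization is MatrixMarket coordinate
integer plus `barcodes.txt` / `features.txt`, with the seven run counters
(pairs read, two discard classes, unassigned, ambiguous, assigned, UMIs
after deduplication) in `run_info.json`. Conservation — the five
disposition counters sum to the pair count — is asserted in the tests.

## QC metrics

`qc_report()` bundles five design metrics. The diversity entry reports
*both* the Singleton bound $4^{L-d+1}$ and the sphere-packing bound
$\lfloor 4^L / \sum_{i \le t} \binom{L}{i} 3^i \rfloor$,
$t = \lfloor (d-1)/2 \rfloor$, because the two standard bounds bracket
achievable code sizes and neither alone is canonical for "potential
library diversity"; the tests confirm each dominates greedily constructed
codes. Arithmetic is exact (integers below $2^{53}$; $L \le 26$
enforced). "Subsequence" is used in the contiguous sense throughout —
the design clashes the metric exists to catch (7-bp and 16-bp sharing)
are substrings. The reverse-complement histogram covers unordered pairs
of *distinct* barcodes; each barcode's distance to its own reverse
complement is reported separately, since folding self-pairs into the
histogram would change its mass. Ragged-length whitelists restrict
pairwise metrics to equal-length pairs and count the skipped pairs
explicitly, Hamming distance being undefined otherwise. Homopolymer runs
are maximal runs only. Warnings flag minimum distance $\le 2$ and shared
substrings of length $\ge L - 1$.

## The simulation and its assumptions

`simulate_assignment()` draws a parent uniformly per read (a weight
vector is accepted; uniform is the default, as no abundance profile is
part of a design), substitutes each base independently with probability
$p$ uniformly over the three alternatives, and looks the whole mutated
sequence up in the map — no windowing, isolating the design's intrinsic
error tolerance from positional effects. Outcomes partition into correct,
lost (no hit: beyond every retained neighborhood or on a pruned variant)
and misassigned (hit on a foreign parent); the three fractions sum to 1
by construction. "Lost" corresponds to unassigned-plus-ambiguous;
misassignment is tracked separately because it is the more damaging
failure and the sum is recoverable. Sweeps derive the seed for rate index
$i$ as `seed + i − 1`, making each rate reproducible independently.

For a single barcode, $P(\text{correct}) = (1-p)^L + Lp(1-p)^{L-1}$; the
acceptance checks require simulated agreement within four standard errors
at $n = 10^5$ for $p \in \{0.005, 0.01, 0.05\}$ and $L \in \{8, 15\}$.
One qualitative consequence worth stating: at a fixed per-base rate,
longer barcodes of well-separated designs lose *more* reads (multi-error
probability grows with $L$); short barcodes are worse only through their
limited code diversity — small pairwise distances and shared
subsequences — which the same-length clash comparison in the test suite
demonstrates.

## The fixture generator

`generate_fixture()` emulates the structural features the quantifier must
handle: fixed-layout R1 (cell barcode then UMI), R2 with the tag at a
fixed or uniformly random offset inside random filler, substitution
errors at a set per-base rate confined to the tag region, and PCR
duplicates as exact repeats of whole molecules. Cell barcodes are drawn
at pairwise distance $\ge 2$ by rejection so that on-list correction is
unambiguous. It does **not** emulate: quality-score structure (ignored by
the method), indels, chimeric reads, abundance skew across cells or
features, or sequencing-cycle-dependent error profiles. Passing tests on
these fixtures therefore demonstrate the combinatorial correctness of
scanning, collapse and deduplication — not robustness to every artefact
of real libraries. Filler is uniform random sequence, so a filler window
can in principle sit within distance 1 of a parent; fixtures in the tests
use fixed seeds and well-separated whitelists, where this is rare, and
the truth table records every read's intended origin so such events are
visible when they occur.

Default fixture dimensions (16-bp cell barcodes, 10-bp UMIs, tags inside
~10 bases of filler) mirror common droplet chemistries; test and
acceptance runs use a few hundred read pairs and simulations of
$2 \times 10^4$–$10^5$ reads, sizes at which every stochastic check has
comfortable statistical power.

## Numerical and degenerate-input choices

Empty whitelists, non-uniform lengths for quantification, duplicate ids
or sequences, and non-ACGT characters (including N and lowercase) in
whitelist sequences are hard errors — silent fixing would change the
code's distance structure. An empty mismatch map refuses to serialize.
Reads shorter than the window yield "unassigned", not an error. A
whitelist of one barcode yields empty pairwise histograms with a warning.
All randomness flows through explicit integer seeds; equal results for
equal seeds is part of the contract and is tested byte-for-byte on
FASTQ and MatrixMarket output.

## Limitations

Indel errors are not corrected and indel-tolerant matching is not
attempted. Ambiguous reads are never rescued. The simulation's uniform
error model ignores quality information and position-dependent error
rates. No cell calling (knee-point filtering) or sample demultiplexing is
performed — the output is the raw cells × features matrix.
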