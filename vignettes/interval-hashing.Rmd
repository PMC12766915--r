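---
title: "Interval hashing: disambiguating minimizer seeds in tandem-repeat arrays"
author: "ivhash package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval hashing: disambiguating minimizer seeds in tandem-repeat arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivhash)
```

## The problem

Centromeric alpha satellite consists of ~171 bp monomers arranged in
higher-order repeat (HOR) units of typically 4–20 monomers, which themselves
repeat near-identically over megabases. All-vs-all overlap detection between
long reads from such arrays fails with ordinary minimizer seeding: a given
k-mer occurs in every copy of its monomer, so seed matches between two reads
are dominated by spurious off-diagonal hits between *different* repeat
copies, and the rare haplotype-distinguishing variants drown in them.

The saving property of real HOR arrays is that they are not perfectly
periodic. Monomers within a unit are diverged from one another, units are
occasionally truncated, and unrelated sequence (e.g. transposable elements)
interrupts the array. A k-mer that is private to one monomer therefore
recurs with a characteristic, locally distinctive pattern of occurrence
intervals. **Interval hashing** turns that pattern into a seed signature:
each occurrence of a minimizer value is annotated with a 64-bit hash of its
local interval context, and two occurrences match only if both value and
context hash agree.

## The hash

For one minimizer value on one sequence, let the occurrence positions be
$p_0 < p_1 < \dots < p_N$ and the intervals $d_j = p_{j+1} - p_j$. With wing
length $W$ (default 3), the hash of occurrence $i$ is computed in five
steps:

1. **Slice.** Extract $s_{2W} = (d_{i-W}, \dots, d_{i+W-1})$ and
   $s_{4W} = (d_{i-2W}, \dots, d_{i+2W-1})$; out-of-bounds entries are
   $\infty$. If the central k-mer was sampled from the reverse strand, both
   slices are reversed — this makes the hash strand-canonical:
   $h(v, i, +) = h(\mathrm{rev}(v), N-i, -)$.
2. **Unit interval.** $u = \min(s_{4W})$, the local canonical repeat length.
   Taking it from the wider slice makes the normalisation of the two
   overlapping contexts of neighbouring occurrences agree.
3. **Normalise.** Divide $s_{2W}$ by $u$.
4. **Quantize and mix.** Multiply by the resolution constant $r = 4$ and
   round to the nearest integer; each quantized value is mapped through a
   fixed 64-bit avalanche mixer (the splitmix64 finalizer). $\infty$ maps to
   the reserved partial hash 0 ("no information"). Resolution 4 makes a
   quantization step a quarter unit, fine enough to separate truncated units
   from full ones while absorbing small jitter.
5. **Combine.** XOR the $2W$ partial hashes, partial $j$ rotated left by
   $2W-1-j$ bits (an ntHash-style rolling combination, order-sensitive).

Two consequences are load-bearing. First, an empty context — a singleton
minimizer, or a segment of one occurrence — hashes to exactly 0, and the
combined seed key is defined as $\mathrm{value} \oplus f(\mathrm{ivh})$ with
$f(0) = 0$, so seeds in unique sequence keep their plain minimizer value:
augmentation is a no-op outside repeats. Second, the hash is scale-invariant
in the intervals (everything is normalised by $u$), so it keys on the
*shape* of the local repeat structure, not its absolute size.

Interval vectors are split wherever consecutive occurrences are more than
`maxSeparation` (default 20 kb) apart, so contexts never span unrelated
repeat regions; each segment is hashed independently, with $\infty$ beyond
the cut.

```{r hash-demo}
# a perfectly periodic context collapses to one hash ...
unique(intervalHashes(rep(2052, 20), W = 3)[7:15])
# ... an empty context to zero, so singleton seeds keep their value
intervalHashes(numeric(0))
```

## Seeding, chaining, filtering

Seeds are canonical (w,k)-minimizers, default $(k, w) = (19, 15)$, with
minimap2-style all-minimum tie emission and optional homopolymer compression
(coordinates always report back in original bases; the defaults together
reproduce the all-vs-all ultra-long-read preset $(k, w, W) = (19, 15, 3)$
with 20 kb splitting). Anchors are equal-key seed pairs. Chaining is a
deliberately simplified single-pass DP — score
$f(j) = \max_i f(i) + \min(\mathrm{span}, \Delta q, \Delta t) -
\gamma\,|\Delta q - \Delta t|$ with gaps bounded by $G$ — emitting PAF
records with `residue_matches` = non-overlapping anchor span sum and
`block_len` = the larger mapped extent. The contribution under study is the
seeding; the chainer only needs to be a fixed, fair harness for comparing
plain and augmented seed modes, which is why it has no mapping quality
(fixed 0) and defaults $G = 10\,000$, $\gamma = 0.05$, minimum score 200,
and a 500-anchor DP lookback bound.

Post-filters follow assembly practice: overlaps must have
`residue_matches / block_len` strictly above 0.2, and a miniasm-style
overhang classification drops *internal* matches (unmapped flank beyond
5 kb on either side) while keeping dovetail and contained overlaps.

## The synthetic HOR generator

`simulateHOR()` is the package's data source for validation: a monomer
library (monomer 0 uniform random; the rest derived at 10% divergence — the
scale at which most 19-mers are monomer-private but an appreciable minority
recur in 1–2 other monomers, producing the non-equidistant interval patterns
the hash keys on), `nUnits = 120` copies of a 12-monomer unit (~250 kb), 5%
of unit copies truncated, 2% followed by a 1 kb random insertion standing in
for transposon interruptions, near-identical unit copies (0.2% substitution),
and two haplotypes differing at 25 substitutions. Reads are 30 kb
(sd 5 kb), uniform starts and strands, substitution-only errors at 1%
(high-quality ultra-long nanopore reads are substitution-dominated; an indel
flag exists but is off by default), 10× depth per haplotype. The same
configuration and seed give byte-identical output.

What the generator does *not* emulate: signal-level or homopolymer-biased
nanopore error profiles, monomer-specific higher-order structure (e.g.
pericentromeric layers), segmental duplications, or diploid coverage
fluctuations. Passing tests on it therefore demonstrate the seeding
algebra and its discrimination behaviour under controlled conditions, not
end-to-end assembly performance on real centromeres.

```{r sim-demo}
sim <- simulateHOR(horConfig(nUnits = 20, readDepth = 3, readLenMean = 8000,
                             readLenSd = 800, rngSeed = 3))
sim
```

## What the checks show

On the standard fixture (defaults, seed 7) the package's acceptance script
recomputes, among others:

* **Refinement** — augmented anchors are a subset of plain anchors on every
  pair (keys refine values), with anchor counts dropping by roughly two
  orders of magnitude on cross-read comparisons;
* **Discrimination** — the fraction of cross-haplotype anchors lying off the
  principal dotplot diagonal (offsets binned at one HOR unit) drops
  substantially in augmented mode, the qualitative behaviour that separates
  haplotypes during assembly;
* **Singleton preservation** — on 100 kb of uniform-random sequence, every
  single-occurrence minimizer keeps its plain value as key, exactly;
* **Periodicity** — on an event-free array (all divergence and event rates
  zero) every value's interior occurrences carry exactly one context hash.

## Numerical choices and edge cases

* Rounding in quantization is half-away-from-zero (`floor(x + 0.5)` for the
  positive values that occur), a locale- and platform-independent contract.
* The avalanche mixer maps 0 to 0; because 0 is reserved for "no
  information", a finite quantized value whose mixed hash would be 0 is
  substituted with the nonzero golden-ratio constant. In practice only
  quantized value 0 triggers this.
* With resolution 4 and the unit interval taken from the enclosing 4W
  slice, every finite quantized value is at least 4; no upper clamp is
  applied, so a pathological tiny unit next to a huge interval yields a
  large (but well-defined) quantized value.
* All-minimum tie emission means a window with equal-value k-mers emits all
  of them; strand-ambiguous (palindromic) k-mers are skipped entirely.
* For $k > 32$ the exact 2-bit encoding no longer fits 64 bits and an
  ntHash-style rolling hash is used; distinct k-mers may then collide, which
  is accepted and documented (long-minimizer seeding is out of scope).
* Degenerate inputs: sequences shorter than one window yield empty seed
  tables, not errors; empty anchor sets yield empty PAF data frames;
  zero-length alignment blocks are dropped from filtering with a warning.

## Known limitations

The central one is error sensitivity, inherent to the method: an anchor
survives only if all $2W+1$ occurrences around it survive *in both reads*,
i.e. roughly $p^{2(2W+1)}$ with $p$ the per-k-mer intactness probability.
At the fixture's 1% substitution rate this leaves augmented match rates
(`residue_matches/block_len`) well below the strict \>0.2 match-rate
threshold — a setting appropriate for QV ≈ 25 reads — so the filter rejects
most true overlaps even though chain detection itself remains at 100%; the
acceptance script reports both numbers (`neighbour_chain_detection_pct`,
`dovetail_retention_pct`). Users applying the filter chain to noisier data
should lower `minMatchRate` accordingly or rely on chain scores; the package
keeps the standard defaults.

Chaining is intentionally minimal (no long-gap rescue, no secondary-chain
re-seeding, heuristic DP lookback); absolute match-rate values are not
comparable to minimap2's. The dotplot and offset statistics treat one HOR
unit as the diagonal band width, which is the natural scale for
unit-periodic arrays but coarse for monomer-level analyses.

## Problem sizes

The test suite and acceptance script run entirely on generated data: the
standard ~250 kb, 2 × 10× fixture for discrimination and retention
(~160 reads, ~6 700 cross-haplotype pairs, ~1 200 neighbour pairs), a ~60 kb
fixture for module tests, 10 000 random interval vectors for oracle
agreement, and exhaustive vectors up to $N = 6$ over a 5-value interval
alphabet for canonicalization. These sizes were chosen to exercise every
code path at desk scale while keeping a full run in minutes.
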