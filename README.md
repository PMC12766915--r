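# ivhash — interval-hash-augmented minimizer seeding for tandem-repeat overlap detection

`ivhash` detects overlaps between long reads from highly repetitive tandem
arrays — the motivating case being centromeric **alpha-satellite
higher-order repeats (HORs)**: ~171 bp monomers stacked into multi-monomer
units that repeat near-identically over megabases. Ordinary minimizer
seeding collapses there, because every k-mer recurs in every copy of its
monomer and spurious matches between different repeat copies swamp the true
read overlaps.

The package implements **interval hashing**: identical minimizers are
disambiguated by their local pattern of occurrence intervals. For one
minimizer value with occurrences $p_0 < \dots < p_N$ and intervals
$d_j = p_{j+1} - p_j$, occurrence $i$ receives a 64-bit context hash built
in five steps — slice ($2W$- and $4W$-long windows around $i$, out-of-bounds
= ∞, slices reversed for reverse-strand k-mers), unit interval
$u = \min(s_{4W})$, normalisation by $u$, quantization
$\lfloor d/u \cdot 4 + 0.5 \rfloor$ mapped through a 64-bit avalanche mixer
(∞ → the reserved partial hash 0), and an ntHash-style rotate-XOR
combination. The augmented seed key is `value XOR f(ivh)` with `f(0) = 0`,
so singleton and isolated minimizers keep their plain value and unique
sequence is seeded exactly as before. Interval vectors are split at gaps
over 20 kb so contexts never span unrelated regions. The defaults reproduce
the all-vs-all ultra-long-read preset `(k, w, W) = (19, 15, 3)`.

Around the core the package provides canonical (w,k)-minimizer extraction
with optional homopolymer compression, a simplified colinear chainer
emitting 12-column PAF, the standard `>20%` match-rate and 5 kb overhang
filters, seed-level dotplots, and a synthetic alpha-satellite HOR simulator
(monomer libraries, unit truncations, unrelated-sequence insertions,
haplotype variants, noisy long reads) with full ground truth — the data
source for the test suite.

## Worked example

A truncated HOR unit leaves a signature in the interval pattern; the hash
sees it, and neighbouring occurrences of the same k-mer stop being
interchangeable:

```r
library(ivhash)
# occurrences every 2052 bp (a 12 x 171 bp unit), one unit truncated by half
intervalHashes(c(2052, 2052, 1026, 2052, 2052), W = 1)
#> [1] "b7a4712c74562914" "7fbd20cca53cfa39" "1d724e5b4d817ac5"
#> [4] "ba23fde37447fbc1" "7fbd20cca53cfa39" "6f48e258e8ac5229"
intervalHashes(numeric(0))   # singleton k-mer: empty context hashes to zero
#> [1] "0000000000000000"
```

The six occurrences get five distinct hashes: the two flanks of the
truncation and both array ends are each distinguishable, while the two
occurrences one step away from the truncation (positions 1 and 4) see the
same normalised context — a full unit on either side, the truncated unit
just inside their wider slice — and correctly share one. An end-to-end run on simulated
reads:

```r
sim <- simulateHOR(horConfig(nUnits = 20, readDepth = 3, readLenMean = 8000,
                             readLenSd = 800, rngSeed = 3))
sim
#> HORSimulation
#>   array     : 39159 bp (20 x 12 x 171 bp + events)
#>   layout    : 229 monomer copies, 0 insertions, 1 truncated units
#>   haplotypes: 2, differing at 25 variant(s)
#>   reads     : 30 (mean 7976 bp, error 1%, depth 3x per haplotype)

p <- ivhParams(hpc = TRUE)           # the all-vs-all ONT-UL preset + HPC
paf  <- detectOverlaps(horReads(sim)[1:6], p)
kept <- filterOverlaps(paf, p)       # >20% match rate, <=5 kb overhang
kept[1:2, c("qname", "qstart", "qend", "strand", "tname", "tstart", "tend",
            "residue_matches", "block_len", "class")]
#>          qname qstart qend strand         tname tstart tend residue_matches block_len     class
#>  hapA_read0002    101 7119      + hapA_read0005    595 7442            1589      7018 contained
#>  hapA_read0003    294 8225      - hapA_read0005    342 8102            1991      7931 contained
```

Each kept row is one overlap in PAF terms: query/target intervals (0-based
half-open), relative strand, `residue_matches` (chained anchor bases) over
`block_len` (alignment span), and its overhang classification (`dovetail` /
`contained`; `internal` repeat-induced matches are dropped).

A command-line front-end wraps the same functions:

```sh
Rscript inst/scripts/ivhash overlap reads.fq --hpc -o overlaps.paf
Rscript inst/scripts/ivhash dotplot a.fa b.fa --mode augmented --max-key-freq 10 -o points.tsv
Rscript inst/scripts/ivhash simulate --seed 7 -o simdata/
```

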