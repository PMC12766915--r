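#' Seeding and overlap parameters
#'
#' Bundle of tuning parameters for minimizer extraction, interval hashing,
#' chaining and overlap filtering. The defaults reproduce the
#' all-vs-all preset for high-quality ultra-long
#' nanopore reads: `(k, w, W) = (19, 15, 3)`, resolution 4.0, and a maximum
#' minimizer separation of 20 kb for splitting interval vectors.
#'
#' @slot k k-mer length (bases).
#' @slot w minimizer window: number of consecutive k-mers per window.
#' @slot W wing length: occurrences considered on each side when hashing
#'   intervals.
#' @slot resolution quantization resolution for normalised intervals.
#' @slot maxSeparation maximum minimizer separation (bases); interval vectors
#'   are split at larger gaps before hashing.
#' @slot hpc logical; apply homopolymer compression before k-mer extraction.
#' @slot minMatchRate overlaps are kept only if
#'   `residue_matches / block_len > minMatchRate` (strict).
#' @slot maxOverhang maximum unmapped overhang (bases) tolerated before an
#'   overlap is classified internal.
#' @slot maxKeyFreq optional rarity filter: drop seed keys occurring more than
#'   this many times across the compared set (`NA` disables).
#' @slot mode seed mode, `"augmented"` (interval-hash keys) or `"plain"`
#'   (raw minimizer values).
#' @slot chainGap maximum per-axis gap (bases) between chained anchors.
#' @slot chainGamma gap-difference penalty per base in the chain score.
#' @slot chainMinScore minimum chain score emitted.
#' @slot chainLookback maximum number of predecessor anchors scanned per
#'   anchor in the chaining DP (heuristic bound).
#'
#' @seealso [ivhParams()]
#' @export
setClass("IvhParams",
    representation(
        k = "integer", w = "integer", W = "integer",
        resolution = "numeric", maxSeparation = "numeric", hpc = "logical",
        minMatchRate = "numeric", maxOverhang = "numeric",
        maxKeyFreq = "integer", mode = "character",
        chainGap = "numeric", chainGamma = "numeric",
        chainMinScore = "numeric", chainLookback = "integer"
    )
)

setValidity("IvhParams", function(object) {
    msg <- character()
    if (object@k < 1L) msg <- c(msg, "k must be >= 1")
    if (object@w < 1L) msg <- c(msg, "w must be >= 1")
    if (object@W < 0L) msg <- c(msg, "W must be >= 0")
    if (!(object@resolution > 0)) msg <- c(msg, "resolution must be > 0")
    if (object@maxSeparation < 1) msg <- c(msg, "maxSeparation must be >= 1")
    if (object@minMatchRate < 0 || object@minMatchRate >= 1)
        msg <- c(msg, "minMatchRate must be in [0, 1)")
    if (object@maxOverhang < 0) msg <- c(msg, "maxOverhang must be >= 0")
    if (!is.na(object@maxKeyFreq) && object@maxKeyFreq < 1L)
        msg <- c(msg, "maxKeyFreq must be >= 1 or NA")
    if (!object@mode %in% c("augmented", "plain"))
        msg <- c(msg, "mode must be 'augmented' or 'plain'")
    if (object@chainGap < 1) msg <- c(msg, "chainGap must be >= 1")
    if (object@chainGamma < 0) msg <- c(msg, "chainGamma must be >= 0")
    if (object@chainLookback < 1L) msg <- c(msg, "chainLookback must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Synthetic alpha-satellite HOR array configuration
#'
#' Parameters of the higher-order-repeat simulator. The defaults emulate a
#' desk-scale active alpha-satellite HOR array: 171 bp monomers, 12 monomers
#' per HOR unit, 120 unit copies (about 250 kb), occasional truncated units
#' and unrelated-sequence insertions, 25 haplotype-distinguishing variants,
#' and 30 kb reads at 1% substitution error.
#'
#' @slot monomerLen monomer length in bases (alpha satellite: 171).
#' @slot unitOrder monomers per HOR unit.
#' @slot nUnits HOR unit copies in the array.
#' @slot monomerDivergence substitution rate between distinct monomers of the
#'   unit (library divergence from monomer 0).
#' @slot unitMutationRate per-base substitution rate between unit copies.
#' @slot truncationProb probability that a unit copy is truncated.
#' @slot truncationMonomers number of monomers dropped from the end of a
#'   truncated unit; `NA` draws uniformly from 1..(unitOrder-1).
#' @slot insertionProb probability of an unrelated-sequence insertion after a
#'   unit copy.
#' @slot insertionLen length (bases) of each inserted unrelated sequence.
#' @slot nHapVariants haplotype-distinguishing substitutions between the two
#'   simulated haplotypes.
#' @slot readLenMean,readLenSd normal read-length model (bases).
#' @slot readErrorRate per-base substitution error rate of simulated reads.
#' @slot readIndelRate per-base indel error rate (off by default; the target
#'   reads are high-quality ONT UL where substitutions dominate).
#' @slot readDepth sequencing depth per haplotype.
#' @slot rngSeed seed; the same config and seed give byte-identical output.
#'
#' @seealso [horConfig()], [simulateHOR()]
#' @export
setClass("HORConfig",
    representation(
        monomerLen = "integer", unitOrder = "integer", nUnits = "integer",
        monomerDivergence = "numeric", unitMutationRate = "numeric",
        truncationProb = "numeric", truncationMonomers = "integer",
        insertionProb = "numeric", insertionLen = "integer",
        nHapVariants = "integer",
        readLenMean = "numeric", readLenSd = "numeric",
        readErrorRate = "numeric", readIndelRate = "numeric",
        readDepth = "numeric", rngSeed = "integer"
    )
)

setValidity("HORConfig", function(object) {
    msg <- character()
    rates <- c(monomerDivergence = object@monomerDivergence,
               unitMutationRate = object@unitMutationRate,
               truncationProb = object@truncationProb,
               insertionProb = object@insertionProb,
               readErrorRate = object@readErrorRate,
               readIndelRate = object@readIndelRate)
    bad <- rates < 0 | rates > 1
    if (any(bad))
        msg <- c(msg, paste(names(rates)[bad], "must be in [0, 1]"))
    if (object@monomerLen < 1L || object@unitOrder < 1L || object@nUnits < 1L)
        msg <- c(msg, "monomerLen, unitOrder and nUnits must be >= 1")
    if (!is.na(object@truncationMonomers) &&
        (object@truncationMonomers < 1L ||
         object@truncationMonomers >= object@unitOrder))
        msg <- c(msg, "truncationMonomers must be in 1..(unitOrder-1) or NA")
    if (object@insertionLen < 1L) msg <- c(msg, "insertionLen must be >= 1")
    if (object@nHapVariants < 0L) msg <- c(msg, "nHapVariants must be >= 0")
    if (object@readLenMean < 1 || object@readLenSd < 0)
        msg <- c(msg, "readLenMean must be >= 1 and readLenSd >= 0")
    if (object@readDepth <= 0) msg <- c(msg, "readDepth must be > 0")
    if (length(msg)) msg else TRUE
})

#' Simulated HOR array, haplotypes, reads and ground truth
#'
#' Container returned by [simulateHOR()]: the monomer library, the assembled
#' array and its per-monomer layout, the two haplotypes and their variant
#' table, the simulated reads and their true origins.
#'
#' @slot config the [HORConfig-class] used.
#' @slot monomers character vector: the monomer library.
#' @slot array `DNAString`: haplotype A's array sequence.
#' @slot haplotypes `DNAStringSet` of the two haplotypes (`hapA`, `hapB`).
#' @slot layout data.frame: one row per monomer copy or insertion event
#'   (`start`, `end` 0-based half-open, `unit`, `monomer`, `type`,
#'   `truncated`).
#' @slot variants data.frame of haplotype-B substitutions (`pos`, `ref`,
#'   `alt`).
#' @slot reads `DNAStringSet` of simulated reads.
#' @slot origins data.frame of read truth (`read_id`, `hap`, `start`, `end`,
#'   `strand`).
#'
#' @seealso [simulateHOR()]
#' @export
setClass("HORSimulation",
    representation(
        config = "HORConfig", monomers = "character",
        array = "ANY", haplotypes = "ANY",
        layout = "data.frame", variants = "data.frame",
        reads = "ANY", origins = "data.frame"
    )
)

setValidity("HORSimulation", function(object) {
    msg <- character()
    if (!is(object@array, "DNAString")) msg <- c(msg, "array must be a DNAString")
    if (!is(object@haplotypes, "DNAStringSet"))
        msg <- c(msg, "haplotypes must be a DNAStringSet")
    if (!is(object@reads, "DNAStringSet"))
        msg <- c(msg, "reads must be a DNAStringSet")
    if (nrow(object@origins) != length(object@reads))
        msg <- c(msg, "origins must have one row per read")
    if (length(msg)) msg else TRUE
})
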