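#' Construct a HOR simulator configuration
#'
#' Returns a [HORConfig-class] with desk-scale defaults emulating an active
#' alpha-satellite HOR array: 171 bp monomers, 12 monomers per unit, 120 unit
#' copies (about 250 kb), 10% divergence between monomers, nearly identical
#' unit copies, a 5% unit truncation rate and 2% unrelated-sequence insertion
#' rate, 25 haplotype-distinguishing variants, and 30 kb reads at 1%
#' substitution error and 10x depth per haplotype.
#'
#' @param monomerLen,unitOrder,nUnits array structure (see
#'   [HORConfig-class]).
#' @param monomerDivergence,unitMutationRate,truncationProb,truncationMonomers,insertionProb,insertionLen
#'   divergence and structural-event model.
#' @param nHapVariants haplotype-distinguishing substitutions.
#' @param readLenMean,readLenSd,readErrorRate,readIndelRate,readDepth read
#'   model.
#' @param rngSeed seed for byte-identical reproduction.
#' @return a [HORConfig-class] object.
#' @examples
#' horConfig()
#' horConfig(nUnits = 20, readDepth = 5)
#' @export
horConfig <- function(monomerLen = 171, unitOrder = 12, nUnits = 120,
                      monomerDivergence = 0.1, unitMutationRate = 0.002,
                      truncationProb = 0.05, truncationMonomers = NA,
                      insertionProb = 0.02, insertionLen = 1000,
                      nHapVariants = 25,
                      readLenMean = 30000, readLenSd = 5000,
                      readErrorRate = 0.01, readIndelRate = 0,
                      readDepth = 10, rngSeed = 7) {
    new("HORConfig",
        monomerLen = as.integer(monomerLen), unitOrder = as.integer(unitOrder),
        nUnits = as.integer(nUnits),
        monomerDivergence = as.numeric(monomerDivergence),
        unitMutationRate = as.numeric(unitMutationRate),
        truncationProb = as.numeric(truncationProb),
        truncationMonomers = as.integer(truncationMonomers),
        insertionProb = as.numeric(insertionProb),
        insertionLen = as.integer(insertionLen),
        nHapVariants = as.integer(nHapVariants),
        readLenMean = as.numeric(readLenMean),
        readLenSd = as.numeric(readLenSd),
        readErrorRate = as.numeric(readErrorRate),
        readIndelRate = as.numeric(readIndelRate),
        readDepth = as.numeric(readDepth), rngSeed = as.integer(rngSeed))
}

.BASES <- c("A", "C", "G", "T")

# random sequence as character vector of bases
.rand_bases <- function(n) sample(.BASES, n, replace = TRUE)

# substitute positions of a base vector at rate `rate`, always to a
# different base; returns the mutated vector
.substitute <- function(bases, rate) {
    if (rate <= 0) return(bases)
    n <- length(bases)
    k <- rbinom(1, n, rate)
    if (k == 0) return(bases)
    at <- sample.int(n, k)
    shift <- sample.int(3, k, replace = TRUE)
    idx <- (match(bases[at], .BASES) - 1L + shift) %% 4L
    bases[at] <- .BASES[idx + 1L]
    bases
}

#' Generate a monomer library
#'
#' Monomer 0 is uniform random; monomers `1..n-1` are derived from it by
#' independent substitutions at the given divergence rate, emulating the
#' diverged-but-related monomers of an alpha-satellite HOR unit (specific
#' k-mers then occur only in specific monomers). Uses the current RNG state.
#'
#' @param n number of monomers.
#' @param monomerLen monomer length in bases (default 171).
#' @param divergence per-base substitution rate from monomer 0.
#' @return character vector of `n` monomer sequences.
#' @examples
#' set.seed(1)
#' lib <- makeMonomerLibrary(12, divergence = 0.1)
#' nchar(lib[1])
#' @export
makeMonomerLibrary <- function(n, monomerLen = 171, divergence = 0.1) {
    stopifnot(n >= 1)
    m0 <- .rand_bases(monomerLen)
    out <- character(n)
    out[1] <- paste(m0, collapse = "")
    for (i in seq_len(n - 1))
        out[i + 1] <- paste(.substitute(m0, divergence), collapse = "")
    out
}

#' Build a HOR array from a monomer library
#'
#' Concatenates `nUnits` copies of the HOR unit (monomers `0..unitOrder-1` in
#' order), applying per-copy substitutions at `unitMutationRate`, unit
#' truncations (dropping monomers from the end of the unit) and
#' unrelated-sequence insertions after units. The ground-truth layout records
#' every monomer copy and insertion with 0-based half-open coordinates. Uses
#' the current RNG state.
#'
#' @param config a [HORConfig-class] object.
#' @param library optional monomer library (default: generated from
#'   `config`).
#' @return list with `seq` (array sequence, character) and `layout`
#'   (data.frame: `start`, `end`, `unit`, `monomer`, `type`, `truncated`).
#' @examples
#' set.seed(1)
#' cfg <- horConfig(nUnits = 5, truncationProb = 0, insertionProb = 0)
#' arr <- buildArray(cfg)
#' nchar(arr$seq) == 5 * 12 * 171
#' @export
buildArray <- function(config, library = NULL) {
    stopifnot(is(config, "HORConfig"))
    if (is.null(library))
        library <- makeMonomerLibrary(config@unitOrder, config@monomerLen,
                                      config@monomerDivergence)
    unit_bases <- lapply(library, function(m) strsplit(m, "")[[1]])
    pieces <- list()
    rows <- list()
    cursor <- 0L
    for (u in seq_len(config@nUnits)) {
        n_mono <- config@unitOrder
        truncated <- runif(1) < config@truncationProb
        if (truncated) {
            drop <- if (is.na(config@truncationMonomers))
                sample.int(config@unitOrder - 1L, 1) else config@truncationMonomers
            n_mono <- config@unitOrder - drop
        }
        for (m in seq_len(n_mono)) {
            b <- .substitute(unit_bases[[m]], config@unitMutationRate)
            pieces[[length(pieces) + 1L]] <- b
            rows[[length(rows) + 1L]] <- data.frame(
                start = cursor, end = cursor + length(b),
                unit = u - 1L, monomer = m - 1L, type = "monomer",
                truncated = truncated, stringsAsFactors = FALSE)
            cursor <- cursor + length(b)
        }
        if (runif(1) < config@insertionProb) {
            b <- .rand_bases(config@insertionLen)
            pieces[[length(pieces) + 1L]] <- b
            rows[[length(rows) + 1L]] <- data.frame(
                start = cursor, end = cursor + length(b),
                unit = u - 1L, monomer = NA_integer_, type = "insertion",
                truncated = FALSE, stringsAsFactors = FALSE)
            cursor <- cursor + length(b)
        }
    }
    layout <- do.call(rbind, rows)
    rownames(layout) <- NULL
    list(seq = paste(unlist(pieces), collapse = ""), layout = layout)
}

#' Derive a haplotype pair from an array
#'
#' Haplotype A is the array itself; haplotype B carries `nVariants`
#' substitutions at distinct uniform positions (always to a different base),
#' emulating the haplotype-distinguishing variants whose detection decides
#' whether reads from the two haplotypes can be separated. Uses the current
#' RNG state.
#'
#' @param array array sequence (character).
#' @param nVariants number of substitutions.
#' @return list with `hapA`, `hapB` (character sequences) and `variants`
#'   (data.frame: `pos` 0-based, `ref`, `alt`).
#' @examples
#' set.seed(1)
#' h <- makeHaplotypes(paste(rep("ACGT", 100), collapse = ""), 5)
#' nrow(h$variants)
#' @export
makeHaplotypes <- function(array, nVariants) {
    n <- nchar(array)
    stopifnot(nVariants <= n)
    b <- strsplit(array, "")[[1]]
    if (nVariants == 0)
        return(list(hapA = array, hapB = array,
                    variants = data.frame(pos = integer(0), ref = character(0),
                                          alt = character(0))))
    at <- sort(sample.int(n, nVariants))
    shift <- sample.int(3, nVariants, replace = TRUE)
    ref <- b[at]
    alt <- .BASES[(match(ref, .BASES) - 1L + shift) %% 4L + 1L]
    b[at] <- alt
    list(hapA = array, hapB = paste(b, collapse = ""),
         variants = data.frame(pos = at - 1L, ref = ref, alt = alt,
                               stringsAsFactors = FALSE))
}

#' Simulate noisy long reads from a sequence
#'
#' Read starts are uniform, lengths normal (truncated to the sequence
#' bounds), strands uniform; errors are substitutions at `readErrorRate`
#' (plus indels at `readIndelRate` when enabled, off by default). Uses the
#' current RNG state.
#'
#' @param sequence template sequence (character).
#' @param config a [HORConfig-class] object (read model slots are used).
#' @param prefix read-name prefix (default `"read"`).
#' @param hap haplotype label recorded in the truth table.
#' @return list with `reads` (named character vector) and `origins`
#'   (data.frame: `read_id`, `hap`, `start`, `end` 0-based half-open on the
#'   template, `strand`).
#' @examples
#' set.seed(1)
#' cfg <- horConfig(readLenMean = 500, readLenSd = 50, readErrorRate = 0,
#'                  readDepth = 2)
#' sim <- simulateReads(paste(rep("ACGTT", 400), collapse = ""), cfg)
#' nrow(sim$origins)
#' @export
simulateReads <- function(sequence, config, prefix = "read", hap = "hapA") {
    stopifnot(is(config, "HORConfig"))
    L <- nchar(sequence)
    stopifnot(config@readLenMean <= L)
    n_reads <- ceiling(config@readDepth * L / config@readLenMean)
    lens <- pmin(L, pmax(200, round(rnorm(n_reads, config@readLenMean,
                                          config@readLenSd))))
    starts <- floor(runif(n_reads, 0, L - lens + 1))
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    ids <- sprintf("%s%04d", prefix, seq_len(n_reads))
    reads <- character(n_reads)
    for (i in seq_len(n_reads)) {
        b <- strsplit(substr(sequence, starts[i] + 1, starts[i] + lens[i]),
                      "")[[1]]
        if (strands[i] == "-") b <- rev(c(A = "T", C = "G", G = "C", T = "A")[b])
        b <- .substitute(b, config@readErrorRate)
        if (config@readIndelRate > 0) b <- .apply_indels(b, config@readIndelRate)
        reads[i] <- paste(b, collapse = "")
    }
    names(reads) <- ids
    list(reads = reads,
         origins = data.frame(read_id = ids, hap = hap, start = starts,
                              end = starts + lens, strand = strands,
                              stringsAsFactors = FALSE))
}

# simple indel model: each base independently deleted or followed by a
# random inserted base, each at rate/2
.apply_indels <- function(bases, rate) {
    n <- length(bases)
    del <- runif(n) < rate / 2
    ins <- runif(n) < rate / 2
    out <- ifelse(ins, paste0(bases, sample(.BASES, n, replace = TRUE)), bases)
    out[del] <- ""
    strsplit(paste(out, collapse = ""), "")[[1]]
}

#' Simulate a full HOR dataset: array, haplotypes, reads, truth
#'
#' Seeds the RNG from `config@rngSeed` (identical config and seed give
#' byte-identical output), then generates the monomer library, assembles the
#' array, derives the haplotype pair, and samples reads from both haplotypes
#' at `readDepth` each.
#'
#' @param config a [HORConfig-class] object.
#' @return a [HORSimulation-class] object.
#' @examples
#' sim <- simulateHOR(horConfig(nUnits = 10, readDepth = 2,
#'                    readLenMean = 5000, readLenSd = 500, rngSeed = 11))
#' sim
#' @export
simulateHOR <- function(config = horConfig()) {
    stopifnot(is(config, "HORConfig"))
    set.seed(config@rngSeed)
    lib <- makeMonomerLibrary(config@unitOrder, config@monomerLen,
                              config@monomerDivergence)
    arr <- buildArray(config, lib)
    haps <- makeHaplotypes(arr$seq, config@nHapVariants)
    simA <- simulateReads(haps$hapA, config, prefix = "hapA_read", hap = "hapA")
    simB <- simulateReads(haps$hapB, config, prefix = "hapB_read", hap = "hapB")
    reads <- c(simA$reads, simB$reads)
    origins <- rbind(simA$origins, simB$origins)
    new("HORSimulation", config = config, monomers = lib,
        array = Biostrings::DNAString(arr$seq),
        haplotypes = Biostrings::DNAStringSet(c(hapA = haps$hapA,
                                                hapB = haps$hapB)),
        layout = arr$layout, variants = haps$variants,
        reads = Biostrings::DNAStringSet(reads), origins = origins)
}

#' @describeIn simulateHOR the simulated reads (`DNAStringSet`).
#' @param sim a [HORSimulation-class] object.
#' @export
horReads <- function(sim) sim@reads

#' @describeIn simulateHOR truth table of read origins.
#' @export
horOrigins <- function(sim) sim@origins

#' @describeIn simulateHOR the two haplotype sequences (`DNAStringSet`).
#' @export
horHaplotypes <- function(sim) sim@haplotypes

#' @describeIn simulateHOR the array sequence (`DNAString`).
#' @export
horArray <- function(sim) sim@array

#' @describeIn simulateHOR the per-monomer layout ground truth.
#' @export
horLayout <- function(sim) sim@layout

#' @describeIn simulateHOR the haplotype-B variant table.
#' @export
horVariants <- function(sim) sim@variants

setMethod("show", "HORSimulation", function(object) {
    cfg <- object@config
    cat("HORSimulation\n")
    cat(sprintf("  array     : %d bp (%d x %d x %d bp + events)\n",
                length(object@array), cfg@nUnits, cfg@unitOrder,
                cfg@monomerLen))
    cat(sprintf("  layout    : %d monomer copies, %d insertions, %d truncated units\n",
                sum(object@layout$type == "monomer"),
                sum(object@layout$type == "insertion"),
                length(unique(object@layout$unit[object@layout$truncated]))))
    cat(sprintf("  haplotypes: 2, differing at %d variant(s)\n",
                nrow(object@variants)))
    cat(sprintf("  reads     : %d (mean %.0f bp, error %.2g%%, depth %gx per haplotype)\n",
                length(object@reads),
                mean(object@origins$end - object@origins$start),
                100 * cfg@readErrorRate, cfg@readDepth))
})
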