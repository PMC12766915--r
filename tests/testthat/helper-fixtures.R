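# Shared fixtures, built once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, build) {
    hit <- .fx_cache[[name]]
    if (!is.null(hit)) return(hit)
    val <- build()
    assign(name, val, envir = .fx_cache)
    val
}

# Small HOR simulation for module-level tests: ~60 kb array, 8 kb reads.
fx_small_sim <- function() fx("small_sim", function() {
    simulateHOR(horConfig(nUnits = 30, readDepth = 4,
                          readLenMean = 8000, readLenSd = 1000,
                          rngSeed = 11))
})

# The standard simulator fixture for the discrimination checks: package
# defaults (about 250 kb array, 25 haplotype variants, 30 kb reads at 1%
# error), seed 7.
fx_std_sim <- function() fx("std_sim", function() simulateHOR(horConfig()))

# Augmented/plain per-read seed tables of the standard fixture (HPC preset).
fx_std_seeds <- function(mode) {
    fx(paste0("std_seeds_", mode), function() {
        sim <- fx_std_sim()
        seedTables(horReads(sim), ivhParams(hpc = TRUE, mode = mode))
    })
}

# True overlap length of two reads of one haplotype, from the truth table.
fx_true_overlap <- function(origins, i, j) {
    if (origins$hap[i] != origins$hap[j]) return(0)
    max(0, min(origins$end[i], origins$end[j]) -
           max(origins$start[i], origins$start[j]))
}
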