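#' Construct seeding/overlap parameters
#'
#' Returns an [IvhParams-class] object. The defaults are the
#' all-vs-all ultra-long-read preset: interval-hash-augmented minimizers with
#' `(k, w, W) = (19, 15, 3)`, quantization resolution 4.0, interval-vector
#' splitting at gaps over 20 kb, a strict `> 0.2` match-rate filter and a 5 kb
#' maximum overhang.
#'
#' @param k k-mer length.
#' @param w minimizer window size (consecutive k-mers).
#' @param W wing length: minimizer occurrences considered on each side when
#'   hashing occurrence intervals.
#' @param resolution quantization resolution applied to normalised intervals.
#' @param maxSeparation split interval vectors at gaps above this (bases).
#' @param hpc apply homopolymer compression before k-mer extraction.
#' @param minMatchRate keep overlaps with match rate strictly above this.
#' @param maxOverhang maximum overhang (bases) before an overlap is internal.
#' @param maxKeyFreq optional rarity ceiling on seed-key frequency (`NA` off).
#' @param mode `"augmented"` or `"plain"` seed matching.
#' @param chainGap,chainGamma,chainMinScore,chainLookback chaining
#'   parameters: maximum per-axis anchor gap, gap-difference penalty, minimum
#'   emitted chain score, and DP predecessor lookback bound.
#'
#' @return An [IvhParams-class] object.
#' @examples
#' p <- ivhParams()
#' p
#' ivhParams(k = 15, w = 10, W = 2, hpc = TRUE)
#' @export
ivhParams <- function(k = 19, w = 15, W = 3, resolution = 4.0,
                      maxSeparation = 20000, hpc = FALSE,
                      minMatchRate = 0.2, maxOverhang = 5000,
                      maxKeyFreq = NA, mode = c("augmented", "plain"),
                      chainGap = 10000, chainGamma = 0.05,
                      chainMinScore = 200, chainLookback = 500) {
    mode <- match.arg(mode)
    new("IvhParams",
        k = as.integer(k), w = as.integer(w), W = as.integer(W),
        resolution = as.numeric(resolution),
        maxSeparation = as.numeric(maxSeparation), hpc = as.logical(hpc),
        minMatchRate = as.numeric(minMatchRate),
        maxOverhang = as.numeric(maxOverhang),
        maxKeyFreq = as.integer(maxKeyFreq), mode = mode,
        chainGap = as.numeric(chainGap), chainGamma = as.numeric(chainGamma),
        chainMinScore = as.numeric(chainMinScore),
        chainLookback = as.integer(chainLookback))
}

#' @describeIn ivhParams k-mer length accessor.
#' @param x an `IvhParams` object.
#' @export
kmerLength <- function(x) x@k

#' @describeIn ivhParams minimizer window size accessor.
#' @export
windowSize <- function(x) x@w

#' @describeIn ivhParams wing length accessor.
#' @export
wingLength <- function(x) x@W

#' @describeIn ivhParams seed mode accessor (`"augmented"` or `"plain"`).
#' @export
seedMode <- function(x) x@mode

setMethod("show", "IvhParams", function(object) {
    cat("IvhParams (all-vs-all ONT-UL preset defaults)\n")
    cat(sprintf("  seeds  : (k, w, W) = (%d, %d, %d), hpc = %s, mode = %s\n",
                object@k, object@w, object@W, object@hpc, object@mode))
    cat(sprintf("  hashing: resolution = %g, maxSeparation = %g bp\n",
                object@resolution, object@maxSeparation))
    cat(sprintf("  chain  : gap <= %g, gamma = %g, minScore = %g, lookback = %d\n",
                object@chainGap, object@chainGamma, object@chainMinScore,
                object@chainLookback))
    cat(sprintf("  filter : matchRate > %g, maxOverhang = %g bp, maxKeyFreq = %s\n",
                object@minMatchRate, object@maxOverhang,
                ifelse(is.na(object@maxKeyFreq), "off",
                       as.character(object@maxKeyFreq))))
})

# Serialise parameters to "key=value" strings for output headers.
paramHeader <- function(params) {
    stopifnot(is(params, "IvhParams"))
    sprintf(paste0("k=%d w=%d W=%d resolution=%g maxSeparation=%g hpc=%s ",
                   "mode=%s minMatchRate=%g maxOverhang=%g maxKeyFreq=%s ",
                   "chainGap=%g chainGamma=%g chainMinScore=%g chainLookback=%d"),
            params@k, params@w, params@W, params@resolution,
            params@maxSeparation, params@hpc, params@mode,
            params@minMatchRate, params@maxOverhang,
            ifelse(is.na(params@maxKeyFreq), "NA",
                   as.character(params@maxKeyFreq)),
            params@chainGap, params@chainGamma, params@chainMinScore,
            params@chainLookback)
}
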