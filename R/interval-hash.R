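#' Interval hashing of minimizer occurrence intervals
#'
#' The interval-hash core maps a vector of `N` occurrence intervals (the
#' distances between the `N + 1` occurrences of one minimizer value) to
#' `N + 1` per-occurrence 64-bit hash values that act as signatures of the
#' local repeat context. For each occurrence `i` (0-based, `0 <= i <= N`),
#' five steps are applied:
#'
#' 1. *Slice*: extract the 2W-long slice `intervals[i-W .. i+W)` and the
#'    4W-long slice `intervals[i-2W .. i+2W)` (interval `j` separates
#'    occurrences `j` and `j+1`; out-of-bounds entries are `Inf`). Both slices
#'    are reversed when the central k-mer was sampled from the reverse strand,
#'    which canonicalizes hashes across strands.
#' 2. *Unit interval*: the minimum of the 4W slice, the local length of the
#'    canonical repeat element.
#' 3. *Normalise*: divide the 2W slice by the unit interval.
#' 4. *Quantize*: multiply by `resolution` and round to the nearest integer
#'    (half away from zero); map each quantized integer through a fixed
#'    64-bit avalanche mixer (splitmix64 finalizer). `Inf` maps to the
#'    reserved partial hash 0, marking absent interval information.
#' 5. *Combine*: XOR the 2W partial hashes, partial `j` rotated left by
#'    `2W - 1 - j` bits (an ntHash-style rolling combination).
#'
#' An empty interval vector (a singleton occurrence) or an all-`Inf` context
#' hashes to exactly 0; this keeps singleton and isolated minimizers
#' unchanged after augmentation.
#'
#' @param intervals numeric vector of `N >= 0` positive interval lengths in
#'   bases; `Inf` is allowed and means "no neighbour".
#' @param strand `"+"` or `"-"` per occurrence (recycled if length 1); minus
#'   reverses the slices before hashing.
#' @param W wing length (occurrences considered per side); default 3.
#' @param resolution quantization resolution; default 4.0.
#'
#' @return `intervalHashes()`: character vector of `N + 1` 64-bit hash values
#'   as 16-char hex strings, one per occurrence.
#' @examples
#' intervalHashes(numeric(0))             # singleton: "0000000000000000"
#' h <- intervalHashes(rep(171, 20), W = 3)
#' unique(h[7:15])                        # one hash inside a periodic array
#' # strand canonicalization:
#' v <- c(171, 342, 171, 513)
#' identical(intervalHashes(v, "+"), rev(intervalHashes(rev(v), "-")))
#' @export
intervalHashes <- function(intervals, strand = "+", W = 3, resolution = 4.0) {
    .cpp_interval_hashes(as.numeric(intervals), as.character(strand),
                         as.integer(W), as.numeric(resolution))
}

#' @describeIn intervalHashes hash of a single occurrence `i` (0-based,
#'   `0 <= i <= N`).
#' @param i occurrence index, 0-based.
#' @export
hashOccurrence <- function(intervals, i, strand = "+", W = 3,
                           resolution = 4.0) {
    n <- length(intervals)
    if (i < 0 || i > n) stop("occurrence index i out of range [0, N]")
    intervalHashes(intervals, strand, W, resolution)[i + 1L]
}

#' @describeIn intervalHashes extract the 2W/4W slice pair around occurrence
#'   `i`; returns `list(slice2w, slice4w)` with `Inf` at out-of-bounds
#'   positions.
#' @export
sliceAt <- function(intervals, i, W) {
    n <- length(intervals)
    if (i < 0 || i > n) stop("occurrence index i out of range [0, N]")
    at <- function(idx) vapply(idx, function(j)
        if (j >= 0 && j < n) intervals[j + 1L] else Inf, numeric(1))
    list(slice2w = if (W > 0) at(seq(i - W, i + W - 1L)) else numeric(0),
         slice4w = if (W > 0) at(seq(i - 2L * W, i + 2L * W - 1L)) else numeric(0))
}

#' @describeIn intervalHashes the unit interval of a 4W slice: its minimum
#'   (`Inf` if all entries are `Inf`), the local canonical repeat length.
#' @param slice4w numeric vector of 4W interval values.
#' @export
unitInterval <- function(slice4w) {
    if (length(slice4w) == 0) return(Inf)
    min(slice4w)
}

#' @describeIn intervalHashes normalise a 2W slice by the unit interval and
#'   quantize (`round(d / unit * resolution)`, half away from zero); `Inf`
#'   passes through as the sentinel.
#' @param slice2w numeric vector of 2W interval values.
#' @param unit unit interval (positive, or `Inf` when the whole slice is
#'   `Inf`).
#' @export
quantizeIntervals <- function(slice2w, unit, resolution = 4.0) {
    if (!is.infinite(unit) && unit <= 0) stop("unit interval must be > 0")
    if (is.infinite(unit) && any(is.finite(slice2w)))
        stop("unit may be Inf only when every slice entry is Inf")
    ifelse(is.infinite(slice2w), Inf,
           floor(slice2w / unit * resolution + 0.5))
}

#' @describeIn intervalHashes partial hash of quantized values: `Inf` maps to
#'   0 (the reserved "no information" value), finite integers through the
#'   avalanche mixer (never 0).
#' @param q numeric vector of quantized values (or `Inf`).
#' @export
partialHash <- function(q) .cpp_partial_hash(as.numeric(q))

#' @describeIn intervalHashes combine 2W partial hashes (hex strings) into
#'   the final hash: XOR of partial `j` rotated left by `2W - 1 - j` bits.
#' @param partials character vector of 64-bit partial hashes in hex.
#' @export
combinePartials <- function(partials) .cpp_combine(as.character(partials))

#' Split occurrence positions at large gaps
#'
#' Interval vectors are split wherever consecutive occurrences are separated
#' by more than `maxSeparation` bases, so that hashes never encode intervals
#' spanning unrelated repeat contexts; each resulting segment is hashed
#' independently (its boundary occurrences see `Inf` beyond the cut).
#'
#' @param positions strictly increasing numeric vector of base positions.
#' @param maxSeparation cut between positions with a gap strictly greater
#'   than this (default 20000 bases).
#' @return list of position segments; concatenating them reproduces the
#'   input.
#' @examples
#' splitPositions(c(0, 5000, 30000), 20000)  # gap 25000 cuts
#' splitPositions(c(0, 20000), 20000)        # boundary gap kept
#' @export
splitPositions <- function(positions, maxSeparation = 20000) {
    if (length(positions) == 0) return(list())
    if (is.unsorted(positions, strictly = TRUE))
        stop("positions must be strictly increasing")
    cuts <- which(diff(positions) > maxSeparation)
    seg <- cumsum(c(1L, as.integer(seq_along(positions)[-1] %in% (cuts + 1L))))
    unname(split(positions, seg))
}
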