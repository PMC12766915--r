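#' Homopolymer compression with coordinate maps
#'
#' Collapses maximal runs of one base to a single base and returns, for each
#' compressed position, the original coordinates of the run. Homopolymer
#' compression absorbs run-length sequencing errors before k-mer extraction;
#' seed positions are always reported back in original coordinates.
#'
#' @param x a single sequence: character string, `DNAString`, or a length-1
#'   `DNAStringSet`.
#' @return a list with `bases` (compressed string), `mapEnd` (0-based
#'   original index of each run's last base) and `mapStart` (original index
#'   of each run's first base).
#' @examples
#' hpcCompress("AAACCG")   # bases "ACG", mapEnd 2 4 5
#' hpcCompress("TTTT")     # bases "T",   mapEnd 3
#' @export
hpcCompress <- function(x) {
    res <- .cpp_hpc(.as_seq_string(x))
    list(bases = res$bases, mapEnd = res$map_end, mapStart = res$map_start)
}

#' Canonical k-mer values of a sequence
#'
#' Computes a strand-canonical 64-bit value for every k-mer window: the 2-bit
#' encodings of the forward and reverse-complement k-mer are each passed
#' through an invertible avalanche mixer and the smaller value wins, with the
#' strand recording which one. Windows containing non-ACGT bases are skipped;
#' strand-symmetric (palindromic) k-mers are skipped because their strand is
#' undefined. For `k > 32` an ntHash-style rolling hash replaces the exact
#' encoding, so distinct k-mers may collide (documented caveat).
#'
#' @param x a single sequence (character, `DNAString`, length-1
#'   `DNAStringSet`).
#' @param k k-mer length.
#' @return data.frame with `pos` (0-based index of the k-mer's last base),
#'   `strand`, and `value` (64-bit hex).
#' @examples
#' kmerHashes("ACGTACGTAC", k = 5)
#' @export
kmerHashes <- function(x, k) {
    res <- .cpp_kmer_hashes(.as_seq_string(x), as.integer(k))
    data.frame(pos = res$pos, strand = res$strand, value = res$value,
               stringsAsFactors = FALSE)
}

#' Extract canonical (w,k)-minimizers
#'
#' For every window of `w` consecutive k-mers, all positions attaining the
#' minimum canonical k-mer value are emitted (minimap2-style all-minimum tie
#' handling), with duplicates collapsed across overlapping windows. With
#' `hpc = TRUE`, k-mers are taken in homopolymer-compressed space and `pos` /
#' `span` are mapped back to original coordinates (`pos` is the 0-based
#' original index of the k-mer's last base; `span >= k`).
#'
#' @param x sequences: a named character vector, `DNAString`, or
#'   `DNAStringSet`. Unnamed single sequences get seq_id `"seq1"`.
#' @param k k-mer length (default 19).
#' @param w minimizer window size (default 15).
#' @param hpc apply homopolymer compression (default `FALSE`).
#' @return data.frame with columns `seq_id`, `pos`, `strand`, `value`
#'   (64-bit hex), `span`, sorted by `seq_id` then `pos`. Sequences shorter
#'   than a full window contribute no rows.
#' @examples
#' set.seed(1)
#' s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
#' mm <- extractMinimizers(s, k = 11, w = 5)
#' head(mm)
#' @export
extractMinimizers <- function(x, k = 19, w = 15, hpc = FALSE) {
    seqs <- .as_seq_set(x)
    out <- lapply(names(seqs), function(id) {
        res <- .cpp_minimizers(seqs[[id]], as.integer(k), as.integer(w),
                               as.logical(hpc))
        if (length(res$pos) == 0) return(NULL)
        data.frame(seq_id = id, pos = res$pos, strand = res$strand,
                   value = res$value, span = res$span,
                   stringsAsFactors = FALSE)
    })
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0)
        return(data.frame(seq_id = character(0), pos = integer(0),
                          strand = character(0), value = character(0),
                          span = integer(0), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

# --- internal sequence coercions -------------------------------------------

# single sequence -> plain uppercase character string
.as_seq_string <- function(x) {
    if (is(x, "DNAString")) return(as.character(x))
    if (is(x, "XStringSet")) {
        if (length(x) != 1) stop("expected a single sequence")
        return(as.character(x[[1]]))
    }
    if (is.character(x) && length(x) == 1) return(toupper(x))
    stop("expected a single sequence (character or DNAString)")
}

# sequences -> named character vector
.as_seq_set <- function(x) {
    if (is(x, "DNAString")) {
        out <- stats::setNames(as.character(x), "seq1")
    } else if (is(x, "XStringSet")) {
        out <- as.character(x)
        if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    } else if (is.character(x)) {
        out <- toupper(x)
        if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    } else {
        stop("expected character, DNAString or DNAStringSet input")
    }
    if (anyDuplicated(names(out)))
        stop("sequence identifiers must be unique")
    out
}
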