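#' Group minimizer occurrences by value
#'
#' Collects all positions of each minimizer value within each sequence and
#' derives the occurrence-interval vector (successive position differences in
#' original base coordinates) that interval hashing consumes.
#'
#' @param occurrences data.frame as returned by [extractMinimizers()]
#'   (columns `seq_id`, `pos`, `strand`, `value`, ...), sorted by `pos`
#'   within each sequence.
#' @return data.frame with one row per (`seq_id`, `value`) group and list
#'   columns `positions`, `strands`, `intervals`; `n` is the occurrence
#'   count. Total occurrences are conserved.
#' @examples
#' occs <- data.frame(seq_id = "s", pos = c(10, 181, 352),
#'                    strand = "+", value = "00000000000000aa", span = 19L)
#' groupByValue(occs)$intervals[[1]]   # 171 171
#' @export
groupByValue <- function(occurrences) {
    if (nrow(occurrences) == 0)
        return(data.frame(seq_id = character(0), value = character(0),
                          n = integer(0),
                          positions = I(list()), strands = I(list()),
                          intervals = I(list())))
    key <- paste(occurrences$seq_id, occurrences$value, sep = "\r")
    idx <- split(seq_len(nrow(occurrences)), key)
    rows <- lapply(idx, function(ii) {
        ii <- ii[order(occurrences$pos[ii])]
        pos <- occurrences$pos[ii]
        data.frame(seq_id = occurrences$seq_id[ii[1]],
                   value = occurrences$value[ii[1]],
                   n = length(ii),
                   positions = I(list(pos)),
                   strands = I(list(occurrences$strand[ii])),
                   intervals = I(list(diff(pos))),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$seq_id, vapply(out$positions, `[`, numeric(1), 1L)), ]
    rownames(out) <- NULL
    out
}

#' Augment minimizer seeds with interval hashes
#'
#' Applies interval hashing to every minimizer occurrence: occurrences are
#' grouped per (`seq_id`, `value`), positions are split at gaps larger than
#' `maxSeparation`, each segment's interval vector is hashed (each occurrence
#' with its own strand), and the combined seed key is minted as
#' `value XOR f(ivh)` where `f` is an avalanche mixer with `f(0) = 0`.
#' Singleton and isolated minimizers therefore keep their plain value as key,
#' while occurrences inside repeat arrays get context-specific keys.
#'
#' @param occurrences data.frame from [extractMinimizers()].
#' @param params an [IvhParams-class] object (wing length `W`, `resolution`,
#'   `maxSeparation` are used).
#' @return the input data.frame with columns `ivh` (interval hash, hex) and
#'   `key` (combined seed key, hex) appended, sorted by (`seq_id`, `pos`).
#'   Row count equals the input row count.
#' @examples
#' occs <- data.frame(seq_id = "s", pos = c(0, 171, 342, 513), strand = "+",
#'                    value = "00000000000000aa", span = 19L)
#' augmentSeeds(occs, ivhParams(W = 1))
#' @export
augmentSeeds <- function(occurrences, params = ivhParams()) {
    stopifnot(is(params, "IvhParams"))
    n <- nrow(occurrences)
    if (n == 0) {
        occurrences$ivh <- character(0)
        occurrences$key <- character(0)
        return(occurrences)
    }
    ord <- order(occurrences$seq_id, occurrences$value, occurrences$pos)
    oc <- occurrences[ord, ]
    grp <- cumsum(!duplicated(paste(oc$seq_id, oc$value, sep = "\r")))
    ivh <- .cpp_group_ivh(as.numeric(oc$pos), as.character(oc$strand),
                          as.integer(grp), params@maxSeparation,
                          params@W, params@resolution)
    key <- .cpp_seed_keys(as.character(oc$value), ivh)
    oc$ivh <- ivh
    oc$key <- key
    oc <- oc[order(oc$seq_id, oc$pos), ]
    rownames(oc) <- NULL
    oc
}

#' Seed tables for a set of sequences
#'
#' Convenience wrapper: extract minimizers and augment them for each
#' sequence, returning one seed table per sequence. In `"plain"` mode the
#' seed key is the raw minimizer value; in `"augmented"` mode it is the
#' interval-hash-combined key.
#'
#' @param x sequences (named character vector or `DNAStringSet`).
#' @param params an [IvhParams-class] object.
#' @return named list of per-sequence data.frames with columns `seq_id`,
#'   `pos`, `strand`, `value`, `span`, `ivh`, `key`.
#' @examples
#' set.seed(1)
#' s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
#' st <- seedTables(c(r1 = s), ivhParams(k = 11, w = 5))
#' head(st$r1)
#' @export
seedTables <- function(x, params = ivhParams()) {
    seqs <- .as_seq_set(x)
    out <- lapply(names(seqs), function(id) {
        occs <- extractMinimizers(seqs[id], k = params@k, w = params@w,
                                  hpc = params@hpc)
        if (params@mode == "plain") {
            occs$ivh <- rep(strrep("0", 16), nrow(occs))
            occs$key <- occs$value
            occs
        } else {
            augmentSeeds(occs, params)
        }
    })
    names(out) <- names(seqs)
    out
}

# Drop seed keys whose total frequency across the supplied tables exceeds
# maxKeyFreq (the dotplot rarity filter); NA disables.
.applyKeyFreqCeiling <- function(tables, maxKeyFreq) {
    if (is.na(maxKeyFreq)) return(tables)
    freq <- table(unlist(lapply(tables, `[[`, "key"), use.names = FALSE))
    keep <- names(freq)[freq <= maxKeyFreq]
    lapply(tables, function(tb) tb[tb$key %in% keep, , drop = FALSE])
}
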