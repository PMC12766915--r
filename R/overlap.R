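#' Match anchors between two seed tables
#'
#' One anchor per pair of seeds with equal key; the relative strand is `"+"`
#' when the two occurrences' strands agree, `"-"` otherwise. In augmented
#' mode equal keys imply equal minimizer value *and* equal interval-hash
#' context, so augmented anchor sets refine plain ones.
#'
#' @param seedsQ,seedsT seed tables (data.frames with `pos`, `strand`,
#'   `key`, `span`) for the query and target sequence, as produced by
#'   [seedTables()].
#' @return data.frame with `qpos`, `tpos` (end-standardized, 0-based),
#'   `rel_strand`, `span` (the smaller of the two seed spans).
#' @examples
#' set.seed(1)
#' s <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
#' st <- seedTables(c(a = s, b = s), ivhParams(k = 11, w = 5))
#' a <- matchAnchors(st$a, st$b)
#' all(a$qpos == a$tpos)   # identity: diagonal anchors
#' @export
matchAnchors <- function(seedsQ, seedsT) {
    m <- merge(
        data.frame(key = seedsQ$key, qpos = seedsQ$pos,
                   qstrand = seedsQ$strand, qspan = seedsQ$span,
                   stringsAsFactors = FALSE),
        data.frame(key = seedsT$key, tpos = seedsT$pos,
                   tstrand = seedsT$strand, tspan = seedsT$span,
                   stringsAsFactors = FALSE),
        by = "key")
    out <- data.frame(
        qpos = m$qpos, tpos = m$tpos,
        rel_strand = ifelse(m$qstrand == m$tstrand, "+", "-"),
        span = pmin(m$qspan, m$tspan),
        stringsAsFactors = FALSE)
    out <- out[order(out$tpos, out$qpos), ]
    rownames(out) <- NULL
    out
}

#' Chain anchors into overlap records
#'
#' Single-pass dynamic-programming colinear chaining, a deliberately
#' simplified stand-in for minimap2's chainer used as a fixed harness for
#' comparing seed modes. Within one relative strand, anchors are chained with
#' score `score(i) + min(span, qdiff, tdiff) - chainGamma * |qdiff - tdiff|`,
#' transitions limited to gaps in `(0, chainGap]`; chains scoring at least
#' `chainMinScore` are emitted. `residue_matches` is the sum of
#' non-overlapping anchor spans, `block_len` the larger of the two mapped
#' extents; `mapq` is not computed and fixed at 0.
#'
#' @param anchors data.frame from [matchAnchors()].
#' @param qname,tname,qlen,tlen identifiers and lengths of the two sequences.
#' @param params an [IvhParams-class] object (chaining slots are used).
#' @return data.frame of PAF records (the 12 mandatory columns:
#'   `qname, qlen, qstart, qend, strand, tname, tlen, tstart, tend,
#'   residue_matches, block_len, mapq`) plus `score` and `n_anchors`.
#' @export
chainAnchors <- function(anchors, qname, qlen, tname, tlen,
                         params = ivhParams()) {
    stopifnot(is(params, "IvhParams"))
    out <- lapply(c("+", "-"), function(st) {
        a <- anchors[anchors$rel_strand == st, , drop = FALSE]
        if (nrow(a) == 0) return(NULL)
        ch <- .cpp_chain(as.integer(a$qpos), as.integer(a$tpos),
                         as.integer(a$span), st == "-",
                         as.integer(qlen), as.integer(tlen),
                         params@chainGap, params@chainGamma,
                         params@chainMinScore, params@chainLookback)
        if (nrow(ch) == 0) return(NULL)
        data.frame(qname = qname, qlen = as.integer(qlen),
                   qstart = ch$qstart, qend = ch$qend, strand = st,
                   tname = tname, tlen = as.integer(tlen),
                   tstart = ch$tstart, tend = ch$tend,
                   residue_matches = ch$matches, block_len = ch$block_len,
                   mapq = 0L, score = ch$score, n_anchors = ch$n_anchors,
                   stringsAsFactors = FALSE)
    })
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0) return(.emptyPaf())
    res <- do.call(rbind, out)
    res <- res[order(res$qstart, res$tstart), ]
    rownames(res) <- NULL
    res
}

.emptyPaf <- function() {
    data.frame(qname = character(0), qlen = integer(0), qstart = integer(0),
               qend = integer(0), strand = character(0), tname = character(0),
               tlen = integer(0), tstart = integer(0), tend = integer(0),
               residue_matches = integer(0), block_len = integer(0),
               mapq = integer(0), score = numeric(0), n_anchors = integer(0),
               stringsAsFactors = FALSE)
}

#' All-vs-all overlap detection
#'
#' Builds seed tables for every sequence, matches anchors on seed keys for
#' every unordered pair (self-pairs excluded; the lexicographically smaller
#' identifier is the query), chains them, and returns the raw PAF records.
#' Apply [filterOverlaps()] for the match-rate and overhang post-filters.
#'
#' @param x sequences (named character vector or `DNAStringSet`).
#' @param params an [IvhParams-class] object; `params@mode` selects
#'   augmented or plain seed matching.
#' @param pairs optional two-column matrix or data.frame of sequence names
#'   restricting which pairs are evaluated (default: all unordered pairs).
#' @param seeds optional precomputed [seedTables()] result (skips seeding).
#' @return data.frame of PAF records (see [chainAnchors()]).
#' @examples
#' sim <- simulateHOR(horConfig(nUnits = 12, readDepth = 3,
#'                    readLenMean = 6000, readLenSd = 500, rngSeed = 1))
#' paf <- detectOverlaps(horReads(sim)[1:4], ivhParams(hpc = TRUE))
#' head(paf)
#' @export
detectOverlaps <- function(x, params = ivhParams(), pairs = NULL,
                           seeds = NULL) {
    seqs <- .as_seq_set(x)
    if (is.null(seeds)) seeds <- seedTables(seqs, params)
    seeds <- .applyKeyFreqCeiling(seeds, params@maxKeyFreq)
    lens <- nchar(seqs)
    if (is.null(pairs)) {
        ids <- sort(names(seqs))
        if (length(ids) < 2) return(.emptyPaf())
        pairs <- t(utils::combn(ids, 2))
    } else {
        pairs <- as.matrix(pairs)
        sw <- pairs[, 1] > pairs[, 2]
        pairs[sw, ] <- pairs[sw, 2:1]
        pairs <- unique(pairs)
        pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    }
    out <- vector("list", nrow(pairs))
    for (pi in seq_len(nrow(pairs))) {
        qn <- pairs[pi, 1]; tn <- pairs[pi, 2]
        anc <- matchAnchors(seeds[[qn]], seeds[[tn]])
        if (nrow(anc) == 0) next
        out[[pi]] <- chainAnchors(anc, qn, lens[[qn]], tn, lens[[tn]], params)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0) return(.emptyPaf())
    res <- do.call(rbind, out)
    res <- res[order(res$qname, res$tname, res$qstart), ]
    rownames(res) <- NULL
    res
}

#' Match-rate filter for overlaps
#'
#' Keeps overlaps with strictly more than `minRate` match columns relative to
#' the alignment block length (`residue_matches / block_len > minRate`).
#' Records with a zero block length are dropped with a warning.
#'
#' @param records PAF data.frame.
#' @param minRate minimum match rate, strict (default 0.2).
#' @return the filtered data.frame.
#' @examples
#' rec <- data.frame(residue_matches = c(300L, 150L, 200L),
#'                   block_len = 1000L)
#' nrow(filterMatchRate(rec))   # 1: only 0.3 survives the strict 0.2 bound
#' @export
filterMatchRate <- function(records, minRate = 0.2) {
    if (nrow(records) == 0) return(records)
    zero <- records$block_len <= 0
    if (any(zero)) {
        warning(sum(zero), " record(s) with zero block length dropped")
        records <- records[!zero, , drop = FALSE]
    }
    out <- records[records$residue_matches / records$block_len > minRate, ,
                   drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Classify overlaps by overhang geometry
#'
#' Miniasm-style classification of each overlap from its unmapped flanks in
#' strand-oriented coordinates. With left/right overhangs
#' `oh1 = min(qs', ts)` and `oh2 = min(qlen - qe', tlen - te)` (primes:
#' query coordinates flipped for `-` strand overlaps): an overlap is
#' `internal` if either overhang exceeds `maxOverhang` (a repeat-induced
#' mid-read match, dropped from assembly-bound output), `contained` if one
#' sequence's both flanks are no larger than the other's, and `dovetail`
#' (suffix-prefix) otherwise.
#'
#' @param records PAF data.frame.
#' @param maxOverhang maximum overhang in bases (default 5000).
#' @return character vector (`"dovetail"`, `"contained"`, `"internal"`), one
#'   per record.
#' @examples
#' rec <- data.frame(qlen = 40000L, qstart = 0L, qend = 10000L, strand = "+",
#'                   tlen = 40000L, tstart = 30000L, tend = 40000L)
#' classifyOverhang(rec)   # dovetail: suffix of target joins prefix of query
#' @export
classifyOverhang <- function(records, maxOverhang = 5000) {
    if (nrow(records) == 0) return(character(0))
    qs <- ifelse(records$strand == "-", records$qlen - records$qend,
                 records$qstart)
    qe <- ifelse(records$strand == "-", records$qlen - records$qstart,
                 records$qend)
    lhs_q <- qs
    lhs_t <- records$tstart
    rhs_q <- records$qlen - qe
    rhs_t <- records$tlen - records$tend
    oh1 <- pmin(lhs_q, lhs_t)
    oh2 <- pmin(rhs_q, rhs_t)
    cls <- rep("dovetail", nrow(records))
    q_in_t <- lhs_q <= lhs_t & rhs_q <= rhs_t
    t_in_q <- lhs_q >= lhs_t & rhs_q >= rhs_t
    cls[q_in_t | t_in_q] <- "contained"
    cls[oh1 > maxOverhang | oh2 > maxOverhang] <- "internal"
    cls
}

#' Apply the standard overlap post-filters
#'
#' Composition of [filterMatchRate()] and [classifyOverhang()]: overlaps must
#' have a match rate strictly above `params@minMatchRate`, and internal
#' matches (overhang above `params@maxOverhang`) are dropped. A
#' `class` column with the overhang classification is appended.
#'
#' @param records PAF data.frame from [detectOverlaps()].
#' @param params an [IvhParams-class] object.
#' @return the filtered data.frame with a `class` column.
#' @export
filterOverlaps <- function(records, params = ivhParams()) {
    stopifnot(is(params, "IvhParams"))
    out <- filterMatchRate(records, params@minMatchRate)
    if (nrow(out) == 0) { out$class <- character(0); return(out) }
    out$class <- classifyOverhang(out, params@maxOverhang)
    out <- out[out$class != "internal", , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Seed-level dotplot matches between two sequences
#'
#' Anchor coordinates between two sequences under either seed mode, for
#' dotplot-style inspection of repeat structure. `plain` mode matches raw
#' minimizer values, `augmented` mode matches interval-hash-combined keys;
#' since keys refine values, the augmented point set is a subset of the plain
#' one. An optional rarity ceiling keeps only seed keys occurring at most
#' `maxKeyFreq` times across both sequences.
#'
#' @param seqA,seqB the two sequences (character or `DNAString`).
#' @param mode `"augmented"` or `"plain"`.
#' @param params an [IvhParams-class] object.
#' @param maxKeyFreq optional rarity ceiling (default `params@maxKeyFreq`).
#' @return data.frame with `posA`, `posB` (0-based), `rel_strand`.
#' @examples
#' set.seed(2)
#' s <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
#' pts <- dotplotMatches(s, s, mode = "plain", params = ivhParams(k = 11, w = 5))
#' all(pts$posA[pts$rel_strand == "+"] == pts$posB[pts$rel_strand == "+"])
#' @export
dotplotMatches <- function(seqA, seqB, mode = c("augmented", "plain"),
                           params = ivhParams(), maxKeyFreq = NULL) {
    mode <- match.arg(mode)
    params@mode <- mode
    if (is.null(maxKeyFreq)) maxKeyFreq <- params@maxKeyFreq
    tabs <- seedTables(c(A = .as_seq_string(seqA), B = .as_seq_string(seqB)),
                       params)
    tabs <- .applyKeyFreqCeiling(tabs, as.integer(maxKeyFreq))
    anc <- matchAnchors(tabs$A, tabs$B)
    data.frame(posA = anc$qpos, posB = anc$tpos, rel_strand = anc$rel_strand,
               stringsAsFactors = FALSE)
}

#' Off-diagonal anchor statistics over read pairs
#'
#' For each read pair, counts all equal-key anchors and the fraction lying
#' off the principal diagonal of the pair's dotplot. Anchor offsets
#' (`posA - posB` for same-strand anchors, `posA + posB` for opposite-strand
#' anchors) are binned at `band` bases; the modal bin defines the principal
#' diagonal and anchors outside modal +/- 1 bins count as off-diagonal. Used
#' to quantify how interval hashing suppresses spurious repeat-induced
#' matches between reads.
#'
#' @param seeds list of per-read seed tables ([seedTables()]).
#' @param pairs two-column matrix of read indices (integer) or names.
#' @param band bin width in bases; one HOR unit length is the natural choice.
#' @return data.frame with one row per pair: `total` anchors and `offdiag`
#'   count.
#' @export
anchorOffsetStats <- function(seeds, pairs, band) {
    pairs <- as.matrix(pairs)
    if (is.character(pairs))
        pairs <- matrix(match(pairs, names(seeds)), ncol = 2)
    storage.mode(pairs) <- "integer"
    if (anyNA(pairs)) stop("unknown read name in pairs")
    .cpp_pair_offset_stats(lapply(seeds, `[[`, "key"),
                           lapply(seeds, function(s) as.integer(s$pos)),
                           lapply(seeds, `[[`, "strand"),
                           pairs, as.numeric(band))
}
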