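# Independent, literal reimplementation of the five-step interval hash in
# pure R (on the helper-limbs limb arithmetic), plus brute-force oracles for
# minimizer selection and chain scoring. Used to cross-check the compiled
# production path; deliberately shares no code with it.

.o_c1 <- u64_from_hex("bf58476d1ce4e5b9")
.o_c2 <- u64_from_hex("94d049bb133111eb")
.o_golden <- u64_from_hex("9e3779b97f4a7c15")

o_mix64 <- function(z) {
    z <- u64_xor(z, u64_shr(z, 30))
    z <- u64_mul(z, .o_c1)
    z <- u64_xor(z, u64_shr(z, 27))
    z <- u64_mul(z, .o_c2)
    u64_xor(z, u64_shr(z, 31))
}

.o_partial_cache <- new.env(parent = emptyenv())

o_partial <- function(q) {
    # q: finite non-negative quantized value
    key <- as.character(q)
    hit <- .o_partial_cache[[key]]
    if (!is.null(hit)) return(hit)
    h <- o_mix64(u64_from_num(q))
    if (u64_is_zero(h)) h <- .o_golden
    assign(key, h, envir = .o_partial_cache)
    h
}

# Literal five steps for occurrence i (0-based) of an interval vector.
o_hash_occurrence <- function(intervals, i, strand = "+", W = 3,
                              resolution = 4.0) {
    N <- length(intervals)
    idx4 <- seq(i - 2 * W, i + 2 * W - 1)           # step 1: slices
    idx2 <- seq(i - W, i + W - 1)
    get_iv <- function(j) if (j >= 0 && j < N) intervals[j + 1] else Inf
    s4 <- vapply(idx4, get_iv, numeric(1))
    s2 <- vapply(idx2, get_iv, numeric(1))
    if (strand == "-") { s4 <- rev(s4); s2 <- rev(s2) }
    unit <- min(s4)                                  # step 2: unit interval
    if (!is.finite(unit)) return(u64_to_hex(u64_zero()))
    h <- u64_zero()
    L2 <- 2 * W
    for (j in seq_len(L2)) {
        d <- s2[j]
        p <- if (is.infinite(d)) {
            u64_zero()                               # infinity sentinel
        } else {
            q <- floor(d / unit * resolution + 0.5)  # steps 3-4
            o_partial(q)
        }
        h <- u64_xor(h, u64_rotl(p, (L2 - 1 - (j - 1)) %% 64))  # step 5
    }
    u64_to_hex(h)
}

o_hash_vector <- function(intervals, strand = "+", W = 3, resolution = 4.0) {
    strands <- rep_len(strand, length(intervals) + 1)
    vapply(seq_along(strands),
           function(i) o_hash_occurrence(intervals, i - 1, strands[i], W,
                                         resolution),
           character(1))
}

# Splitting + hashing of one occurrence group (positions sorted).
o_group_hashes <- function(positions, strands, maxSeparation, W = 3,
                           resolution = 4.0) {
    out <- character(length(positions))
    seg_start <- 1
    for (i in seq_along(positions)) {
        last <- i == length(positions)
        cut <- !last && positions[i + 1] - positions[i] > maxSeparation
        if (last || cut) {
            sel <- seg_start:i
            iv <- diff(positions[sel])
            for (j in seq_along(sel))
                out[sel[j]] <- o_hash_occurrence(iv, j - 1, strands[sel[j]],
                                                 W, resolution)
            seg_start <- i + 1
        }
    }
    out
}

# ---- minimizer oracle (k <= 26 so 2-bit codes stay exact doubles) ---------

o_kmer_canonical <- function(bases, k) {
    # bases: character vector of one k-mer's bases; returns list(valhex, strand)
    b <- match(bases, c("A", "C", "G", "T")) - 1
    if (anyNA(b)) return(NULL)
    fwd <- sum(b * 4^((k - 1):0))
    rc <- sum((3 - rev(b)) * 4^((k - 1):0))
    hf <- o_mix64(u64_from_num(fwd))
    hr <- o_mix64(u64_from_num(rc))
    if (identical(hf, hr)) return(NULL)  # palindrome
    if (u64_lt(hf, hr)) list(val = u64_to_hex(hf), strand = "+")
    else list(val = u64_to_hex(hr), strand = "-")
}

# Direct O(L*w) minimizer scan: every window of w consecutive k-mers, all
# positions attaining the window minimum, duplicates collapsed.
o_minimizers <- function(seq, k, w) {
    bases <- strsplit(toupper(seq), "")[[1]]
    L <- length(bases)
    if (L < k) return(data.frame(pos = integer(0), strand = character(0),
                                 value = character(0)))
    km <- lapply(seq_len(L - k + 1),
                 function(s) o_kmer_canonical(bases[s:(s + k - 1)], k))
    valid <- !vapply(km, is.null, logical(1))
    pos <- which(valid) + k - 2L       # 0-based index of last base
    vals <- vapply(km[valid], `[[`, character(1), "val")
    strands <- vapply(km[valid], `[[`, character(1), "strand")
    # runs broken where consecutive valid k-mers are not adjacent in sequence
    emitted <- logical(length(pos))
    if (length(pos) > 0) {
        run_id <- cumsum(c(1, diff(pos) != 1))
        for (r in unique(run_id)) {
            ii <- which(run_id == r)
            if (length(ii) < w) next
            for (s0 in 1:(length(ii) - w + 1)) {
                win <- ii[s0:(s0 + w - 1)]
                mn <- min(vals[win])   # hex strings: lexicographic = numeric
                emitted[win[vals[win] == mn]] <- TRUE
            }
        }
    }
    data.frame(pos = pos[emitted], strand = strands[emitted],
               value = vals[emitted], stringsAsFactors = FALSE)
}

# ---- chain-score oracle ----------------------------------------------------

# Best chain score over all ordered anchor subsets (exponential; tiny n only).
o_best_chain_score <- function(qpos, tpos, span, max_gap, gamma) {
    n <- length(qpos)
    best <- 0
    for (mask in 1:(2^n - 1)) {
        sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
        sel <- sel[order(tpos[sel], qpos[sel])]
        ok <- TRUE
        sc <- span[sel[1]]
        if (length(sel) > 1) {
            for (m in 2:length(sel)) {
                qd <- qpos[sel[m]] - qpos[sel[m - 1]]
                td <- tpos[sel[m]] - tpos[sel[m - 1]]
                if (qd <= 0 || td <= 0 || qd > max_gap || td > max_gap) {
                    ok <- FALSE
                    break
                }
                sc <- sc + min(span[sel[m]], qd, td) - gamma * abs(qd - td)
            }
        }
        if (ok && sc > best) best <- sc
    }
    best
}

# random sequence helper
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
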